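# protlink

Proton-linkage analysis of constant-pH molecular dynamics (CpHMD)
output: titration statistics, Wyman–Tanford linkage free energies,
proton-occupancy correlation networks, ionic concentration fingerprints,
and conformational summaries — all verifiable against an exactly
solvable coupled-site titration model that ships with the package.

## Who this is for

CpHMD simulations of an associating protein yield, for each form
(monomer, dimer), pH value and replicate, a time series of binary proton
occupancies per titratable site, plus conformational ensembles.
`protlink` is the post-processing layer: it answers *how association
shifts titration* and, through linkage thermodynamics, *how pH shifts
association*.

## The core method

For a dimerization reaction 2M ⇌ D, linkage theory gives

    ∂ΔG°/∂pH = RT ln10 · (n̄ᴰ − 2 n̄ᴹ)

where n̄ᴹ, n̄ᴰ are the mean numbers of protons bound to each form.
Because CpHMD samples few pH values, the integrand is represented by a
cubic Hermite spline that is *thermodynamically anchored*: its knot
values are the sampled mean protonations and its knot slopes come from
the exact fluctuation identities

    dn̄/dpH = −ln10 · var(n),        dn̄ᵢ/dpH = −ln10 · cov(nᵢ, n),

both measurable from the same trajectories. The linkage integral is then
evaluated in closed form, relative to a reference pH (the lowest sampled
value by default), and splits exactly into per-site contributions. A
Hill-fit route (closed-form antiderivative of the fitted Hill curves) is
provided for comparison, and the whole pipeline carries two-level
(replicate + block) bootstrap error bands.

Every stage is checked against an enumerable model: the binding
polynomial Ξ(pH) of a coupled-site system is summed over all 2^M
microstates, giving exact means, variances, covariances and the exact
ΔΔG(pH) = −RT[lnΞ_D − 2lnΞ_M] difference that the spline route must
reproduce.

## Worked example

Build a coupled 3-site monomer and its dimer (one interface acid picks
up a repulsive interchain coupling), sample occupancy trajectories with
the built-in Metropolis engine, and run the linkage analysis:

```r
library(protlink)

mono <- titration_model(c("ASP2", "GLU9", "HIS5"), c(4.1, 4.6, 6.4),
                        c("acid", "acid", "base"),
                        W = {W <- matrix(0, 3, 3)
                             W[1, 2] <- W[2, 1] <- 6     # Asp2-Glu9 repulsion
                             W[2, 3] <- W[3, 2] <- -3; W})  # Glu9-His5 attraction
dim3 <- dimerize_model(mono,
                       W_inter = {Wi <- matrix(0, 3, 3)
                                  Wi[1, 1] <- 8             # interface Asp2-Asp2'
                                  Wi[1, 2] <- Wi[2, 1] <- 2; Wi},
                       dG_assoc = -20)

trajs <- list(); sd0 <- 100
for (p in 3:8) for (r in 1:2) {
  sd0 <- sd0 + 2
  trajs <- c(trajs, list(
    sample_occupancies(mono, p, n_steps = 2e5, seed = sd0,
                       replicate_id = paste0("rep", r)),
    sample_occupancies(dim3, p, n_steps = 2e5, seed = sd0 + 1,
                       replicate_id = paste0("rep", r))))
}
systems <- system_set(trajs)

cm <- titration_curve(systems, "monomer")
cd <- titration_curve(systems, "dimer")
titration_table(cm)
#>   pH  n_mean      n_var       slope n_frames
#> 1  3 2.50150 0.25664775 -0.59095328    40000
#> 2  4 2.02645 0.14850040 -0.34193480    40000
#> 3  5 1.57405 0.29071660 -0.66939970    40000
#> 4  6 0.83940 0.32230764 -0.74214077    40000
#> 5  7 0.20955 0.17178880 -0.39555832    40000
#> 6  8 0.02550 0.02484975 -0.05721866    40000
```

`n_mean` is the mean total bound protons, `n_var` its variance, `slope`
the fluctuation-derived dn̄/dpH (always ≤ 0). Hill fits summarize each
site's midpoint — here Asp2's strong coupling pushes its apparent pKa
well below its intrinsic 4.1 and flattens the curve (h < 1):

```r
fit_hill_sites(cm)$ASP2
#> hill_fit: pKa=3.103 h=0.756 rss=0.000662 converged=TRUE
```

The linkage profile and its per-site split (kJ/mol, relative to pH 3):

```r
prof <- ddG_profile(cm, cd, pH_ref = 3)
prof
#> free_energy_profile: ddG(pH) on [3, 8], ref pH 3, range [-2.113, 0.000] kJ/mol

dec <- ddG_site_decomposition(cm, cd, pH_ref = 3)
round(dec$per_site[which.min(abs(dec$pH_grid - 5)), ], 3)
#>   ASP2   GLU9   HIS5
#> -2.475  0.467  0.002
```

Dimerization is favoured at higher pH (ΔΔG decreases by ~2.1 kJ/mol from
pH 3 to 8), and the decomposition attributes essentially all of it to the
interface acid whose titration the dimer perturbs. Against the exact
binding-polynomial reference:

```r
max(abs(prof$ddG - exact_ddG(mono, dim3, prof$pH_grid, 3)))
#> max deviation from the exact model: 0.019 kJ/mol
```

## Command line

A thin wrapper over the stage functions is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/protlink.R", package="protlink"))')" \
    all --out demo_run --seed 1
```

`simulate` writes a complete synthetic data set (occupancy tables, site
definitions, `config.yaml`); `titrate`, `energy` and `correlate` read a
config and write TSV tables plus a machine-readable manifest per stage.

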