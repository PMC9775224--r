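---
title: "Proton linkage analysis of constant-pH MD: models, methods and design"
author: "protlink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proton linkage analysis of constant-pH MD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protlink)
```

## The problem

Constant-pH molecular dynamics (CpHMD) couples conformational sampling to
protonation sampling: at fixed pH, each titratable site (Asp, Glu, His,
termini, ...) carries a binary proton occupancy that is periodically
resampled. A CpHMD study of a dimerizing protein produces, for the monomer
and the dimer at several pH values, time series of these occupancies.
`protlink` turns such series into:

* titration curves and fluctuation-derived titration slopes,
* Hill fits (pKa, Hill coefficient) per site,
* the pH-dependent **relative dimerization free energy** via Wyman–Tanford
  linkage, with per-site decomposition and bootstrap error bands,
* proton-occupancy correlation networks and exchange (correlation) times,
* ionic concentration fingerprints around the protein,
* structural summaries (dissociation filtering, central structures, SASA
  and contact areas, interface dihedrals, decoupled-fit PCA and
  free-energy landscapes).

Everything is testable without external data because the package ships an
exactly solvable coupled-site titration model whose thermodynamics are
computed by direct enumeration of all protonation microstates.

## The linkage method

For a dimerization reaction $2M \rightleftharpoons D$, linkage theory gives

$$\frac{\partial \Delta G^\circ}{\partial \mathrm{pH}}
  = RT \ln 10 \,\left(\bar n^D - 2 \bar n^M\right),$$

where $\bar n^M$ and $\bar n^D$ are the mean numbers of protons bound to
the monomer and the dimer. Integrating from a reference pH (by convention
the lowest sampled value) yields the *shape* of $\Delta G^\circ(\mathrm{pH})$;
the absolute offset is supplied, if at all, by vertical least-squares
anchoring to experimental points (`anchor_to_experiment()`, with
upper-bound points excluded from the fit).

CpHMD studies sample few, widely spaced pH values (here typically
pH 3–8 in unit steps), so naive quadrature of the integrand is inaccurate.
The method implemented here exploits an exact statistical-mechanical
identity: the slope of a titration curve is itself an observable,

$$\frac{d\bar n}{d\,\mathrm{pH}} = -\ln 10\,\operatorname{var}(n),
\qquad
\frac{d\bar n_i}{d\,\mathrm{pH}} = -\ln 10\,\operatorname{cov}(n_i, n),$$

both directly computable from the sampled occupancies. Each titration
curve is then represented by a **cubic Hermite spline** whose knot values
are the sampled means and whose knot slopes are these fluctuation-derived
derivatives, and the linkage integral is evaluated in closed form from
the piecewise-cubic antiderivative (`integrate_spline()`,
`cumulative_spline_integral()`). Because a Hermite spline is linear in its
knot data, per-site splines sum to the total spline, and the per-site
free-energy decomposition is additive to machine precision.

An alternative route replaces each site's curve by its fitted Hill curve
$\bar n_i = 1/(1 + 10^{h(\mathrm{pH}-pK_a)})$ and uses the closed-form
antiderivative
$\int \bar n_i\, d\mathrm{pH} = \mathrm{pH} - \ln(1+10^{h(\mathrm{pH}-pK_a)})/(h \ln 10)$
(`ddG_profile_hill()`). The two routes agree when the observed curves are
exactly Hill-shaped and differ otherwise; the spline route is the primary
one because it passes through the actual sampled means with the exact
local slopes.

### Sign convention and verification

The sign of the linkage relation is pinned by an independent oracle: for
an enumerable model, the exact relative free energy is

$$\Delta\Delta G(\mathrm{pH}) = -RT\left[\ln\Xi_D - 2\ln\Xi_M\right]
  _{\mathrm{pH}_{\mathrm{ref}}}^{\mathrm{pH}},$$

with $\Xi$ the semi-grand binding polynomial. The test suite checks both
that $d(\Delta\Delta G)/d\mathrm{pH} = RT\ln 10(\bar n^D - 2\bar n^M)$
holds for the enumerated model (to $10^{-6}$) and that the spline route
reproduces the exact profile to better than 0.2 kJ/mol over pH 3–8 when
exact moments are supplied.

```{r oracle}
mono <- titration_model(c("ASP2", "GLU9", "HIS5"), c(4.1, 4.6, 6.4),
                        c("acid", "acid", "base"),
                        W = {W <- matrix(0, 3, 3)
                             W[1, 2] <- W[2, 1] <- 6
                             W[2, 3] <- W[3, 2] <- -3; W})
dim3 <- dimerize_model(mono,
                       W_inter = {Wi <- matrix(0, 3, 3)
                                  Wi[1, 1] <- 8
                                  Wi[1, 2] <- Wi[2, 1] <- 2; Wi},
                       dG_assoc = -20)
cm <- exact_titration_curve(enumerate_exact(mono, 3:8))
cd <- exact_titration_curve(enumerate_exact(dim3, 3:8))
prof <- ddG_profile(cm, cd, pH_ref = 3)
max(abs(prof$ddG - exact_ddG(mono, dim3, prof$pH_grid, 3)))  # kJ/mol
```

## Statistical conventions

**Population normalization.** All variances and covariances use the 1/N
normalization: the fluctuation relations are ensemble identities, and the
sample correction would break the exact additivity
$\operatorname{var}(n) = \sum_i \operatorname{cov}(n_i, n)$ that the
decomposition relies on. At MD frame counts the difference is negligible.

**Replicate pooling.** Titration moments pool retained frames across
replicates; per-replicate statistics remain available through the data
model (replicates are separate `occupancy_trajectory` objects until a
statistic combines them).

**Bootstrap.** Errors of protonation-derived quantities use a two-level
scheme: replicates are resampled with replacement, then retained frames
within each chosen replicate are resampled as contiguous circular blocks
(default block 1 ns, configurable) — occupancy series from CpHMD are
strongly autocorrelated, and iid-frame resampling would understate the
errors. With a single replicate the scheme degrades to block-only
resampling with a warning. The free-energy envelope re-runs the entire
moments → slopes → splines → integral pipeline per resample and reports
2.5/97.5 percentile bands. Pointwise 95% bands contain an exact reference
curve at about 95% of grid points *on average*; because errors are
correlated along pH, the realized fraction varies noticeably between
seeds, which is why coverage checks are run at fixed, documented seeds.

**Masking, not deleting.** Frames are excluded by a logical mask
(equilibration via `discard_equilibration()`, dissociated dimer frames
via `dissociation_mask()` + `apply_frame_mask()`); the time axis is never
broken. Autocorrelation functions are computed on the longest contiguous
retained stretch per replicate and averaged across replicates with
frame-count weights; the correlation time is the first lag where the ACF
drops below 0.1 (first crossing — a sustained-crossing rule would be less
noise-sensitive but does not match the definition used in the field; the
full ACF curve is returned so users can judge).

## The synthetic model (the oracle layer)

`titration_model()` defines $M \le 20$ sites with intrinsic pKa values
and a symmetric coupling matrix $W$ (kJ/mol) whose entry $W_{ij}$ is added
to the energy when sites $i$ and $j$ are **both protonated**. The
microstate weight at a given pH is
$\exp(-\beta \sum_{i<j} W_{ij} s_i s_j)\prod_i 10^{-s_i(\mathrm{pH}-pK_{a,i})}$,
summed with log-sum-exp stabilization. `dimerize_model()` duplicates the
sites into chains A/B and adds an interchain coupling block — the minimal
way association perturbs titration (e.g. an interface carboxylate facing
its symmetry mate).

Two consequences of the doubly-protonated-pair convention are worth
noting:

* A pH-independent association offset cancels exactly in
  $\Delta\Delta G$, as it must.
* For two identical acids with repulsion $W$, the stepwise midpoints are
  symmetric about $pK_a - W/(2 RT\ln 10)$, not about $pK_a$: with
  $\Xi = 1 + 2x + x^2 e^{-\beta W}$ and $u = x e^{-\beta W/2}$ one has
  $n(u) + n(1/u) = 2$. The test suite asserts this derived center.

`sample_occupancies()` runs a single-site-flip Metropolis chain on this
distribution (compiled code, R's RNG, so `set.seed()` gives bit
reproducibility). The chain includes a **5% lazy step**: when every
proposed move has $\Delta E = 0$ (uncoupled sites at
$\mathrm{pH} = pK_a$), plain Metropolis accepts deterministically, exactly
one site flips per sweep step and the total-proton parity is conserved —
thinning at an even interval then produces a spurious perfectly
anticorrelated record. The lazy step restores aperiodicity without
changing the stationary distribution. Per-site attempt weights allow
designing slow-exchanging sites with long correlation times.

For Monte-Carlo-driven checks, chains are thinned (`record_every = 50`,
i.e. 20 000 recorded frames per $10^6$ steps) so recorded frames are
effectively independent (measured lag-1 autocorrelation ≈ 0.006); with
weaker thinning the block bootstrap underestimates the autocorrelated
sampling error.

What the generator does **not** emulate: conformation–protonation
coupling (occupancy statistics here are conformation-independent),
tautomer identity (occupancy is the collapsed binding count), and any
real protein's site chemistry. Passing tests therefore demonstrate the
correctness of the estimators and integrals, not the realism of any
particular simulation.

## Ionic densities

`kde_concentration()` estimates per-species ion number densities on a
regular grid (default mesh 1 Å) with an isotropic Gaussian kernel
(default bandwidth 2 Å), averaged over frames and converted to mM
($1\,\text{Å}^{-3} = 10^{30}/N_A$ mM). The kernel is separable and
truncated at $4\sigma$ (mass loss < 0.1%); every build checks that the
grid integrates back to the per-frame ion count within 1% and warns when
the grid fails to cover the cloud. Ion positions are first mapped into
the protein frame by `fit_frames_to_reference()` (Kabsch fit of the
protein selection onto a reference — typically the `central_structure()`
— applied to the ions, after minimum-image wrapping relative to the
protein centroid).

The mean-field counterpart is `boltzmann_concentration()`:
$c_k(\vec r) = c_k^{\mathrm{bulk}} e^{-z_k F \phi(\vec r)/RT}$ on a
user-supplied electrostatic potential grid (OpenDX import/export is
built in). The Poisson–Boltzmann equation itself is *not* solved here —
that is the job of an external solver; this package implements the
potential → concentration map and the sampling-side density so the two
routes can be compared. The self-closure test samples ions from
$e^{-zF\phi/RT}$ on a broad synthetic well and checks the kernel density
against the closed-form map within 15% wherever $c \ge 50$ mM. The study
conditions for that check (2 M bulk electrolyte, 8.7 Å potential well in
a 21 Å grid, 1500 frames, comparison excluding the 5 Å edge shell where
kernel mass leaves the box) were chosen once so that the sampled cloud
has enough counts per kernel volume for a 15% pointwise band at desk
scale — at 150 mM a 20 Å box holds less than one ion per frame.

## Structural analyses

* **Superposition** is Kabsch least squares with proper-rotation
  enforcement (no reflections); `rmsd()` is superposition-minimized.
* **Dissociation filtering** flags dimer frames with COM distance
  > 3.3 nm or backbone RMSD > 1.2 nm to the reference dimer (both
  defaults configurable); the mask feeds the occupancy layer so
  dissociated frames drop out of *all* dimer statistics.
* **Central structure**: the frame minimizing the mean squared pairwise
  RMSD, ties broken by lowest index.
* **SASA** is Shrake–Rupley with a deterministic golden-spiral lattice
  (960 points/atom default, probe 0.14 nm); contact area is
  $SASA(A) + SASA(B) - SASA(AB)$, reported halved by default (the
  per-partner buried surface) with the convention attached to the result
  — the whole-buried convention is one flag away, since either appears in
  the literature.
* **Decoupled-fit PCA** (`pca_decoupled()`): frames are superposed using
  only the fit selection; the analysed coordinates are a disjoint
  selection (e.g. fit chain A backbone, transform chain B backbone, or
  fit all backbone except loop residues 84–90 and transform the loop).
  The disjointness is what isolates relative motion; whole-system rigid
  motions leave projections unchanged to $10^{-8}$. Rank-deficient
  ensembles are allowed (zero-variance components).
* **Landscapes**: 2-D Gaussian KDE over the first two PCs with per-axis
  bandwidth $\sigma\,(4N/3)^{-1/5}$, then
  $F = -k_B T \ln(P/P_{\max})$, so $\min F = 0$ exactly at the density
  maximum. The bandwidth exponent is negative — the printed form
  $\sigma(4/3N)^{1/5}$ found in parts of the literature would grow with
  $N$, which contradicts any kernel rule of thumb, so the decreasing
  variant is used and noted here. 1-D observable histograms
  (`kernel_histogram()`) use the same bandwidth rule and integrate to 1.

## Numerical choices and degenerate inputs

* `RT_ln10()` at 300 K is the single source of the linkage prefactor
  (≈ 5.744 kJ/mol per pH unit); kcal output divides by 4.184.
* Spline evaluation and integration refuse extrapolation outside the
  sampled pH range; no monotonicity filtering is applied to splines —
  the slopes are physical, and any overshoot between knots is reported,
  not clipped.
* Hill fits: Levenberg–Marquardt with $h \in [0.05, 10]$, pKa initialized
  at the interpolated half-occupancy pH; flat curves return a
  not-converged result instead of an error; fits whose pKa falls more
  than 2 units outside the sampled range are flagged not-converged
  (extrapolated midpoints are indicative only).
* Zero-variance sites produce flagged-invalid correlation entries, not
  zeros, so networks cannot contain spurious null edges.
* The isoionic point is reported at 0.1 pH resolution by default, found
  by bracketing the thermodynamic spline of the charge curve.

## Problem sizes used in the tests

Enumerable oracles use 2–10 sites (the enumeration guard is 20). Sampled
checks use $10^5$–$10^6$ Metropolis steps per pH, bootstrap sizes
B = 50–200, ion clouds of $10^3$–$4\times10^4$ points, ensembles of 5–30
frames of a 24-residue two-chain backbone toy. These sizes were chosen to
make every stochastic tolerance comfortable at desk scale while keeping
the full suite around a minute.

## Known limitations

* Occupancy is the collapsed binding count; tautomerism is not
  represented.
* The bootstrap block scheme assumes roughly uniform frame spacing within
  a replicate.
* `anchor_to_experiment()` fits a single vertical offset; it does not
  weight experimental points by their uncertainties.
* The Boltzmann concentration map is mean-field: it inherits every
  limitation of the potential grid it is given (no ion–ion correlations).
* The dimer free-energy machinery assumes a homodimer (two copies of the
  monomer's site list); heterodimers would need an explicit pairing map,
  which `ddG_site_decomposition(pairing = ...)` accepts but the
  convenience wrappers do not construct.
```
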