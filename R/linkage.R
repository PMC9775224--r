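## Wyman-Tanford linkage: pH-dependent relative dimerization free energy.
##
## For M + M <-> D the linkage relation gives
##   d DeltaG / d pH = RT ln10 * (n_bar^D - 2 n_bar^M)
## and the relative free energy is its integral from a reference pH. The
## integrand is represented by cubic Hermite splines whose knot values are
## the sampled mean protonations and whose knot slopes are the
## fluctuation-derived derivatives -ln10*var(n) / -ln10*cov(n_i,n), so the
## integral is analytic and independent of any fitted functional form.
## The sign convention is pinned by the binding-polynomial oracle in
## exact_ddG(): protonation favours whichever form binds more protons as
## pH decreases.

## Thermodynamic spline of the linkage integrand for a pair of curves.
## site = NULL -> total; otherwise per-site (dimer contribution is the sum
## over the homologous sites of the two chains).
linkage_integrand_spline <- function(curve_M, curve_D, site = NULL,
                                     pairing = NULL) {
  if (!isTRUE(all.equal(curve_M$pH, curve_D$pH)))
    stop("monomer and dimer curves must be sampled at the same pH knots")
  pH <- curve_M$pH
  if (is.null(site)) {
    vals <- vapply(seq_along(pH), function(i)
      curve_D$points[[i]]$n_mean - 2 * curve_M$points[[i]]$n_mean, numeric(1))
    slps <- vapply(seq_along(pH), function(i)
      titration_slope_total(curve_D$points[[i]]) -
        2 * titration_slope_total(curve_M$points[[i]]), numeric(1))
  } else {
    dsites <- pairing[[site]]
    vals <- vapply(seq_along(pH), function(i)
      sum(curve_D$points[[i]]$site_means[dsites]) -
        2 * curve_M$points[[i]]$site_means[[site]], numeric(1))
    slps <- vapply(seq_along(pH), function(i)
      sum(titration_slope_site(curve_D$points[[i]])[dsites]) -
        2 * titration_slope_site(curve_M$points[[i]])[[site]], numeric(1))
  }
  hermite_spline(pH, vals, slps)
}

## Default homologous-site pairing: monomer site "X" maps to dimer sites
## "A:X"/"B:X" when chain-tagged, or to the two dimer labels whose
## chain-stripped part equals the chain-stripped monomer label.
default_pairing <- function(monomer_sites, dimer_sites) {
  strip <- function(x) sub("^[^:]*:", "", x)
  ms <- strip(monomer_sites); ds <- strip(dimer_sites)
  pairing <- lapply(seq_along(monomer_sites), function(i) {
    hits <- dimer_sites[ds == ms[i]]
    if (length(hits) != 2)
      stop("cannot pair monomer site '", monomer_sites[i],
           "' with exactly two dimer sites (found ", length(hits), ")")
    hits
  })
  names(pairing) <- monomer_sites
  pairing
}

#' Relative dimerization free-energy profile (spline linkage)
#'
#' Computes \eqn{\Delta\Delta G^\circ(pH) = RT\ln 10 \int_{pH_{ref}}^{pH}
#' (\bar n^D - 2\bar n^M)\, dpH'} by analytic integration of the
#' thermodynamically anchored Hermite spline of the integrand. The profile
#' is reported on a dense pH grid (presentational only; the integration is
#' closed-form).
#'
#' @param curve_M,curve_D Monomer and dimer \code{titration_curve} objects
#'   sampled at the same pH knots; the dimer curve counts protons over both
#'   chains.
#' @param pH_ref Reference pH where \eqn{\Delta\Delta G = 0} (default: the
#'   lowest sampled pH).
#' @param T Temperature in K.
#' @param grid_step Output grid spacing in pH units (default 0.01).
#' @param units \code{"kJ"} (default) or \code{"kcal"}.
#' @return Object of class \code{free_energy_profile}: list with
#'   \code{pH_grid}, \code{ddG}, \code{pH_ref}, \code{temperature},
#'   \code{units}, and \code{integrand_spline}.
#' @export
ddG_profile <- function(curve_M, curve_D, pH_ref = min(curve_M$pH), T = 300,
                        grid_step = 0.01, units = c("kJ", "kcal")) {
  units <- match.arg(units)
  s <- linkage_integrand_spline(curve_M, curve_D)
  grid <- seq(min(curve_M$pH), max(curve_M$pH), by = grid_step)
  if (grid[length(grid)] < max(curve_M$pH))
    grid <- c(grid, max(curve_M$pH))
  fac <- RT_ln10(T)
  if (units == "kcal") fac <- fac / protlink_constants[["kcal_in_kJ"]]
  ddG <- fac * cumulative_spline_integral(s, grid, x0 = pH_ref)
  structure(list(pH_grid = grid, ddG = ddG, pH_ref = pH_ref,
                 temperature = T, units = units,
                 integrand_spline = s),
            class = "free_energy_profile")
}

#' @export
print.free_energy_profile <- function(x, ...) {
  cat(sprintf(
    "free_energy_profile: ddG(pH) on [%g, %g], ref pH %g, range [%.3f, %.3f] %s/mol\n",
    min(x$pH_grid), max(x$pH_grid), x$pH_ref, min(x$ddG), max(x$ddG),
    x$units))
  invisible(x)
}

#' Per-site decomposition of the linkage free energy
#'
#' Splits the relative dimerization free energy into site contributions
#' \eqn{\Delta\Delta G_i(pH) = RT\ln 10 \int (\bar n_i^{A,D} + \bar n_i^{B,D}
#' - 2 \bar n_i^M)\, dpH'}, each with its own thermodynamic spline (knot
#' slopes from the per-site covariance relation). Because a Hermite spline
#' is linear in its knot data, the per-site splines sum to the total spline
#' and the decomposition is additive to machine precision.
#'
#' @inheritParams ddG_profile
#' @param pairing Optional named list mapping each monomer site label to its
#'   two homologous dimer site labels; by default inferred by stripping the
#'   chain tag.
#' @return Object of class \code{free_energy_decomposition}: list with
#'   \code{pH_grid}, \code{per_site} (matrix, grid x sites), \code{total}
#'   (their row sums), \code{pH_ref}, \code{units}.
#' @export
ddG_site_decomposition <- function(curve_M, curve_D,
                                   pH_ref = min(curve_M$pH), T = 300,
                                   grid_step = 0.01,
                                   units = c("kJ", "kcal"),
                                   pairing = NULL) {
  units <- match.arg(units)
  if (is.null(pairing))
    pairing <- default_pairing(curve_M$sites, curve_D$sites)
  grid <- seq(min(curve_M$pH), max(curve_M$pH), by = grid_step)
  if (grid[length(grid)] < max(curve_M$pH))
    grid <- c(grid, max(curve_M$pH))
  fac <- RT_ln10(T)
  if (units == "kcal") fac <- fac / protlink_constants[["kcal_in_kJ"]]
  per_site <- vapply(curve_M$sites, function(st) {
    s <- linkage_integrand_spline(curve_M, curve_D, site = st,
                                  pairing = pairing)
    fac * cumulative_spline_integral(s, grid, x0 = pH_ref)
  }, numeric(length(grid)))
  structure(list(pH_grid = grid, per_site = per_site,
                 total = rowSums(per_site), pH_ref = pH_ref,
                 temperature = T, units = units),
            class = "free_energy_decomposition")
}

#' Antiderivative of the Hill curve
#'
#' Closed form \eqn{\int 1/(1+10^{h(pH-pK_a)})\,dpH = pH -
#' \ln(1+10^{h(pH-pK_a)})/(h \ln 10)}, evaluated with \code{log1p} for
#' numerical stability at extreme arguments.
#'
#' @param pH Numeric vector.
#' @param pKa,h Hill parameters.
#' @return Antiderivative values (defined up to an additive constant).
#' @export
hill_antiderivative <- function(pH, pKa, h) {
  u <- log(10) * h * (pH - pKa)
  ln_term <- ifelse(u > 30, u + log1p(exp(-u)), log1p(exp(u)))
  pH - ln_term / (h * log(10))
}

#' Relative dimerization free energy from Hill fits
#'
#' Alternative linkage route: each site's titration curve is replaced by
#' its fitted Hill curve and the linkage integral is evaluated with the
#' closed-form \code{\link{hill_antiderivative}}. Intended for side-by-side
#' comparison with the spline route; the two agree exactly when all sites
#' are Hill-shaped and differ where the observed curves deviate from the
#' Hill form.
#'
#' @param hill_fits_M Named list of converged \code{hill_fit}, one per
#'   monomer site.
#' @param hill_fits_D Named list of converged \code{hill_fit}, one per dimer
#'   site (both chains).
#' @param pH_range Length-2 numeric range for the output grid.
#' @param pH_ref Reference pH.
#' @param T Temperature (K).
#' @param grid_step Grid spacing.
#' @param units \code{"kJ"} or \code{"kcal"}.
#' @return A \code{free_energy_profile}.
#' @export
ddG_profile_hill <- function(hill_fits_M, hill_fits_D,
                             pH_range, pH_ref = min(pH_range), T = 300,
                             grid_step = 0.01, units = c("kJ", "kcal")) {
  units <- match.arg(units)
  bad <- c(
    names(hill_fits_M)[!vapply(hill_fits_M, `[[`, logical(1), "converged")],
    names(hill_fits_D)[!vapply(hill_fits_D, `[[`, logical(1), "converged")])
  if (length(bad))
    stop("non-converged Hill fit for site(s): ", paste(bad, collapse = ", "))
  grid <- seq(pH_range[1], pH_range[2], by = grid_step)
  if (grid[length(grid)] < pH_range[2]) grid <- c(grid, pH_range[2])
  Fsum <- function(fits, pH) {
    Reduce(`+`, lapply(fits, function(f)
      hill_antiderivative(pH, f$pKa, f$h)))
  }
  G <- function(pH) Fsum(hill_fits_D, pH) - 2 * Fsum(hill_fits_M, pH)
  fac <- RT_ln10(T)
  if (units == "kcal") fac <- fac / protlink_constants[["kcal_in_kJ"]]
  ddG <- fac * (G(grid) - G(pH_ref))
  structure(list(pH_grid = grid, ddG = ddG, pH_ref = pH_ref,
                 temperature = T, units = units, integrand_spline = NULL),
            class = "free_energy_profile")
}

#' Read experimental free-energy points
#'
#' Tab-separated with columns \code{pH}, \code{dG} (kJ/mol),
#' \code{is_upper_bound} (0/1) and optional \code{source}.
#'
#' @param path File path.
#' @return data.frame of class \code{experimental_points}.
#' @export
read_experimental_points <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("pH", "dG") %in% names(tab)))
    stop("experimental table needs columns 'pH' and 'dG'")
  if (is.null(tab$is_upper_bound)) tab$is_upper_bound <- 0L
  if (is.null(tab$source)) tab$source <- ""
  stopifnot(all(is.finite(tab$pH)), all(is.finite(tab$dG)))
  class(tab) <- c("experimental_points", "data.frame")
  tab
}

#' Anchor a relative profile to experimental free energies
#'
#' The linkage integral fixes only the shape of \eqn{\Delta G^\circ(pH)};
#' a single additive offset is fitted by vertical least squares to the
#' experimental points. Points flagged as upper bounds are excluded from
#' the fit and reported with the sign of their residual.
#'
#' @param profile A \code{free_energy_profile}.
#' @param exp_points data.frame with columns \code{pH}, \code{dG} and
#'   optionally \code{is_upper_bound} (0/1); units must match the profile.
#' @return List with \code{offset}, \code{dG} (anchored values on the
#'   profile grid), \code{residuals} (fitted points),
#'   \code{bound_residual_sign} (excluded points), and the input grid.
#' @export
anchor_to_experiment <- function(profile, exp_points) {
  if (is.null(exp_points$is_upper_bound)) exp_points$is_upper_bound <- 0L
  rng <- range(profile$pH_grid)
  if (any(exp_points$pH < rng[1] - 1e-9 | exp_points$pH > rng[2] + 1e-9))
    stop("experimental pH outside the profile range")
  pred <- stats::approx(profile$pH_grid, profile$ddG, xout = exp_points$pH)$y
  free <- exp_points$is_upper_bound == 0
  if (!any(free)) stop("no usable (non-bound) experimental points")
  offset <- mean(exp_points$dG[free] - pred[free])
  resid <- exp_points$dG - (pred + offset)
  list(offset = offset,
       pH_grid = profile$pH_grid,
       dG = profile$ddG + offset,
       residuals = resid[free],
       bound_residual_sign = sign(resid[!free]),
       units = profile$units)
}

#' Bootstrap error envelope of the linkage profile
#'
#' Re-runs the entire spline-linkage pipeline (pooled moments ->
#' fluctuation slopes -> Hermite splines -> analytic integral) on two-level
#' bootstrap resamples of the occupancy data (replicates with replacement,
#' then circular frame blocks within replicates) and returns pointwise
#' percentile bands on the dense pH grid.
#'
#' @param systems A \code{system_set} containing monomer and dimer
#'   trajectories at common pH values.
#' @param pH_ref Reference pH.
#' @param T Temperature (K).
#' @param B Number of bootstrap resamples (>= 50).
#' @param seed Integer seed (mandatory).
#' @param probs Lower/upper percentiles (default 2.5/97.5).
#' @param grid_step Output grid spacing.
#' @param block_ps Bootstrap block length in ps.
#' @param units \code{"kJ"} or \code{"kcal"}.
#' @return List with \code{pH_grid}, \code{central} (profile from the full
#'   data), \code{lower}, \code{upper}, \code{B}.
#' @export
profile_bootstrap_envelope <- function(systems, pH_ref = NULL, T = 300,
                                       B = 100, seed, probs = c(0.025, 0.975),
                                       grid_step = 0.01, block_ps = 1000,
                                       units = c("kJ", "kcal")) {
  units <- match.arg(units)
  if (B < 50) stop("B must be at least 50")
  if (missing(seed)) stop("a seed is required")
  cm <- titration_curve(systems, "monomer")
  cd <- titration_curve(systems, "dimer")
  if (is.null(pH_ref)) pH_ref <- min(cm$pH)
  central <- ddG_profile(cm, cd, pH_ref = pH_ref, T = T,
                         grid_step = grid_step, units = units)
  set.seed(seed)
  boots <- matrix(NA_real_, length(central$pH_grid), B)
  for (b in seq_len(B)) {
    res_trajs <- lapply(split_cells(systems), function(cell) {
      picked <- cell[sample.int(length(cell), replace = TRUE)]
      lapply(picked, resample_blocks, block_ps = block_ps)
    })
    res_sys <- system_set(unlist(res_trajs, recursive = FALSE),
                          temperature = systems$temperature)
    cmb <- titration_curve(res_sys, "monomer")
    cdb <- titration_curve(res_sys, "dimer")
    boots[, b] <- ddG_profile(cmb, cdb, pH_ref = pH_ref, T = T,
                              grid_step = grid_step, units = units)$ddG
  }
  qs <- apply(boots, 1, stats::quantile, probs = probs, names = FALSE)
  list(pH_grid = central$pH_grid, central = central$ddG,
       lower = qs[1, ], upper = qs[2, ], B = B, units = units)
}

## Split a system set into its (form, pH) cells (lists of replicates).
split_cells <- function(systems) {
  key <- vapply(systems$trajectories, function(t)
    paste(t$form, format(t$pH, digits = 12)), character(1))
  split(systems$trajectories, key)
}

#' Write a free-energy profile as TSV
#'
#' @param profile A \code{free_energy_profile} or envelope list.
#' @param path Output path.
#' @export
write_profile_tsv <- function(profile, path) {
  if (!is.null(profile$lower)) {
    tab <- data.frame(pH = profile$pH_grid, ddG = profile$central,
                      lower = profile$lower, upper = profile$upper)
  } else {
    tab <- data.frame(pH = profile$pH_grid, ddG = profile$ddG)
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
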