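## Per-pH titration statistics and fluctuation-derived slopes.
##
## The fluctuation relations are ensemble identities:
##   d n_bar / d pH   = -ln10 * var(n)
##   d n_bar_i / d pH = -ln10 * cov(n_i, n)
## so all variances/covariances use population (1/N) normalization; the
## sample correction would break exact additivity with no practical gain
## at MD frame counts.

#' Per-pH titration statistics from pooled replicates
#'
#' Pools the retained frames of all replicates at one (form, pH) cell and
#' computes the mean and variance of the total number of bound protons,
#' per-site mean occupancies and per-site covariances with the total.
#' These moments feed the fluctuation-derived titration slopes and the
#' thermodynamically anchored Hermite splines.
#'
#' @param trajs A single \code{occupancy_trajectory} or a list of replicate
#'   trajectories sharing form, pH and site list.
#' @return An object of class \code{titration_point}: list with \code{pH},
#'   \code{form}, \code{sites}, \code{n_mean}, \code{n_var},
#'   \code{site_means}, \code{site_cov_total}, \code{site_cov} (full
#'   pairwise covariance matrix), \code{n_frames_used}.
#' @export
compute_titration_point <- function(trajs) {
  if (inherits(trajs, "occupancy_trajectory")) trajs <- list(trajs)
  stopifnot(length(trajs) >= 1)
  sites <- trajs[[1]]$sites
  pH <- trajs[[1]]$pH
  form <- trajs[[1]]$form
  for (t in trajs) {
    if (!identical(t$sites, sites)) stop("replicates have different site lists")
    if (abs(t$pH - pH) > 1e-9) stop("replicates have different pH values")
  }
  occ <- do.call(rbind, lapply(trajs, retained_occupancies))
  N <- nrow(occ)
  if (N == 0L) stop("no retained frames at form=", form, " pH=", pH)
  X <- occ * 1.0
  site_means <- colMeans(X)
  Xc <- sweep(X, 2, site_means)
  site_cov <- crossprod(Xc) / N            # population pairwise covariance
  site_cov_total <- rowSums(site_cov)      # cov(n_i, n) by bilinearity
  structure(list(
    pH = pH, form = form, sites = sites,
    n_mean = sum(site_means),
    n_var = sum(site_cov),
    site_means = site_means,
    site_cov_total = site_cov_total,
    site_cov = site_cov,
    n_frames_used = N
  ), class = "titration_point")
}

#' @export
print.titration_point <- function(x, ...) {
  cat(sprintf(
    "titration_point: form=%s pH=%.2f | n_mean=%.4f var(n)=%.4f | %d frames\n",
    x$form, x$pH, x$n_mean, x$n_var, x$n_frames_used))
  invisible(x)
}

#' Fluctuation-derived slope of the total titration curve
#'
#' Returns \eqn{d\bar n/dpH = -\ln 10 \cdot var(n)}, always non-positive.
#'
#' @param point A \code{titration_point}.
#' @return Numeric slope (protons per pH unit).
#' @export
titration_slope_total <- function(point) -log(10) * point$n_var

#' Fluctuation-derived slope of one site's titration curve
#'
#' Returns \eqn{d\bar n_i/dpH = -\ln 10 \cdot cov(n_i, n)}. Site slopes sum
#' exactly to the total slope (bilinearity of covariance).
#'
#' @param point A \code{titration_point}.
#' @param site Site label, or omitted for all sites.
#' @return Named numeric slope(s).
#' @export
titration_slope_site <- function(point, site = NULL) {
  s <- -log(10) * point$site_cov_total
  if (is.null(site)) return(s)
  if (!site %in% point$sites) stop("unknown site: ", site)
  s[[site]]
}

#' Assemble a titration curve for one form
#'
#' Computes \code{\link{compute_titration_point}} at each pH value present
#' for the form in the system set.
#'
#' @param systems A \code{system_set}.
#' @param form \code{"monomer"} or \code{"dimer"}.
#' @return Object of class \code{titration_curve}: list with \code{form},
#'   \code{pH} (sorted), \code{points} (list of \code{titration_point}),
#'   \code{sites}.
#' @export
titration_curve <- function(systems, form) {
  pHs <- sort(unique(vapply(
    Filter(function(t) t$form == form, systems$trajectories),
    `[[`, numeric(1), "pH")))
  if (!length(pHs)) stop("no trajectories of form '", form, "'")
  points <- lapply(pHs, function(p)
    compute_titration_point(get_replicates(systems, form, p)))
  structure(list(form = form, pH = pHs, points = points,
                 sites = points[[1]]$sites),
            class = "titration_curve")
}

#' @export
print.titration_curve <- function(x, ...) {
  cat(sprintf("titration_curve (%s): %d pH points, %d sites\n",
              x$form, length(x$pH), length(x$sites)))
  invisible(x)
}

#' Tabulate a titration curve
#'
#' @param curve A \code{titration_curve}.
#' @return data.frame with pH, n_mean, n_var, slope, n_frames.
#' @export
titration_table <- function(curve) {
  data.frame(
    pH = curve$pH,
    n_mean = vapply(curve$points, `[[`, numeric(1), "n_mean"),
    n_var = vapply(curve$points, `[[`, numeric(1), "n_var"),
    slope = vapply(curve$points, titration_slope_total, numeric(1)),
    n_frames = vapply(curve$points, `[[`, numeric(1), "n_frames_used"))
}

#' Hill curve value
#'
#' \eqn{n(pH) = 1/(1 + 10^{h (pH - pK_a)})}: mean occupancy of a site with
#' midpoint \code{pKa} and Hill coefficient \code{h}.
#'
#' @param pH Numeric vector.
#' @param pKa Midpoint pH.
#' @param h Hill coefficient.
#' @return Occupancy in (0, 1).
#' @export
hill_curve <- function(pH, pKa, h) 1 / (1 + 10^(h * (pH - pKa)))

#' Fit a Hill curve to mean occupancies
#'
#' Levenberg-Marquardt least squares of
#' \eqn{\bar n_i(pH) = 1/(1+10^{h(pH-pK_a)})}. Initial \code{pKa} is the
#' linearly interpolated half-occupancy pH (or the nearest sampled point),
#' initial \code{h} = 1; \code{h} is bounded to [0.05, 10] to avoid
#' degenerate fits on flat curves. The fit is flagged not-converged when
#' the solver fails or the fitted pKa falls more than 2 units outside the
#' sampled pH range (such extrapolated midpoints are indicative only).
#'
#' @param pH_values Numeric vector (>= 3 points).
#' @param mean_occupancies Numeric vector in [0, 1].
#' @param init Optional \code{c(pKa0, h0)} override.
#' @return Object of class \code{hill_fit}: list with \code{pKa}, \code{h},
#'   \code{rss}, \code{converged}.
#' @export
fit_hill <- function(pH_values, mean_occupancies, init = NULL) {
  if (length(pH_values) < 3) stop("Hill fit requires at least 3 points")
  stopifnot(length(pH_values) == length(mean_occupancies))
  if (any(mean_occupancies < -1e-9 | mean_occupancies > 1 + 1e-9))
    stop("mean occupancies must lie in [0, 1]")
  y <- pmin(pmax(mean_occupancies, 0), 1)
  x <- as.numeric(pH_values)
  if (diff(range(y)) < 1e-12) {
    return(structure(list(pKa = NA_real_, h = NA_real_,
                          rss = 0, converged = FALSE), class = "hill_fit"))
  }
  if (is.null(init)) {
    ord <- order(x)
    xo <- x[ord]; yo <- y[ord]
    cross <- which(diff(sign(yo - 0.5)) != 0)
    pKa0 <- if (length(cross)) {
      i <- cross[1]
      xo[i] + (0.5 - yo[i]) * (xo[i + 1] - xo[i]) / (yo[i + 1] - yo[i])
    } else xo[which.min(abs(yo - 0.5))]
    init <- c(pKa0, 1)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ 1 / (1 + 10^(h * (x - pKa))),
      start = list(pKa = init[1], h = init[2]),
      lower = c(-Inf, 0.05), upper = c(Inf, 10),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(pKa = NA_real_, h = NA_real_, rss = NA_real_,
                          converged = FALSE), class = "hill_fit"))
  }
  cf <- stats::coef(fit)
  pKa <- unname(cf[["pKa"]]); h <- unname(cf[["h"]])
  in_range <- pKa >= min(x) - 2 && pKa <= max(x) + 2
  structure(list(pKa = pKa, h = h,
                 rss = sum(stats::resid(fit)^2),
                 converged = isTRUE(in_range)),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("hill_fit: pKa=%.3f h=%.3f rss=%.3g converged=%s\n",
              x$pKa, x$h, x$rss, x$converged))
  invisible(x)
}

#' Fit Hill curves to every site of a titration curve
#'
#' @param curve A \code{titration_curve}.
#' @return Named list of \code{hill_fit} objects, one per site.
#' @export
fit_hill_sites <- function(curve) {
  pH <- curve$pH
  out <- lapply(curve$sites, function(s) {
    y <- vapply(curve$points, function(p) p$site_means[[s]], numeric(1))
    fit_hill(pH, y)
  })
  names(out) <- curve$sites
  out
}

#' Mean protein charge versus pH
#'
#' \eqn{Q(pH) = \sum_{acids} (\bar n_i - 1) + \sum_{bases} \bar n_i} in
#' protonic units, together with the fluctuation-derived charge slope
#' (acid and base site slopes have the same sign map as their occupancies).
#'
#' @param curve A \code{titration_curve}.
#' @param sites A \code{site_definitions} table covering all curve sites.
#' @return data.frame with columns pH, charge, slope.
#' @export
protein_charge_curve <- function(curve, sites) {
  kind <- sites$residue_kind[match(curve$sites, sites$label)]
  if (anyNA(kind))
    stop("missing residue_kind for site(s): ",
         paste(curve$sites[is.na(kind)], collapse = ", "))
  offset <- sum(kind == "acid")  # acids contribute (n_i - 1)
  ch <- vapply(curve$points, function(p) sum(p$site_means) - offset, numeric(1))
  sl <- vapply(curve$points, function(p) sum(titration_slope_site(p)),
               numeric(1))
  data.frame(pH = curve$pH, charge = ch, slope = sl)
}

#' Isoionic point from a charge curve
#'
#' pH at which the mean protein charge crosses zero, located on the
#' thermodynamically anchored Hermite spline of the charge curve (values =
#' mean charges, slopes = fluctuation-derived charge slopes) by root
#' bracketing on a dense grid plus \code{uniroot} refinement.
#'
#' @param charge_curve data.frame from \code{\link{protein_charge_curve}}.
#' @param digits Rounding for the reported pI (default 1 decimal; use
#'   \code{NA} for the unrounded root).
#' @return The isoionic pH.
#' @export
isoionic_point <- function(charge_curve, digits = 1) {
  s <- hermite_spline(charge_curve$pH, charge_curve$charge,
                      charge_curve$slope)
  f <- function(p) eval_spline(s, p)
  grid <- seq(min(charge_curve$pH), max(charge_curve$pH), length.out = 2001)
  v <- f(grid)
  sgn <- sign(v)
  cross <- which(sgn[-1] * sgn[-length(sgn)] <= 0 &
                   !(sgn[-1] == 0 & sgn[-length(sgn)] == 0))
  if (!length(cross)) {
    if (any(v == 0)) return(grid[which(v == 0)[1]])
    stop("charge curve does not change sign in the sampled pH range; ",
         "cannot bracket the isoionic point")
  }
  i <- cross[1]
  root <- if (v[i] == 0) grid[i] else
    stats::uniroot(f, c(grid[i], grid[i + 1]), tol = 1e-10)$root
  if (is.na(digits)) root else round(root, digits)
}

#' Bootstrap standard errors of occupancy statistics
#'
#' Two-level bootstrap tailored to autocorrelated CpHMD occupancy series:
#' replicates are resampled with replacement, then retained frames within
#' each chosen replicate are resampled as contiguous circular blocks
#' (moving-block bootstrap). The statistic is recomputed on each resample
#' and the standard deviation across resamples is returned. With a single
#' replicate the scheme degrades to block-only resampling (warning).
#'
#' @param trajs List of replicate \code{occupancy_trajectory} objects.
#' @param statistic Function taking a list of trajectories and returning a
#'   numeric vector (e.g. \code{function(ts) compute_titration_point(ts)$n_mean}).
#' @param B Number of bootstrap resamples (>= 50).
#' @param seed Integer RNG seed (mandatory).
#' @param block_ps Block length in ps (default 1000 = 1 ns, matching the
#'   >10 ns occupancy correlation times seen in CpHMD runs).
#' @return Named numeric vector of standard errors (same shape as the
#'   statistic), with attribute \code{"replicates"} = \code{B}.
#' @export
bootstrap_errors <- function(trajs, statistic, B = 200, seed, block_ps = 1000) {
  if (inherits(trajs, "occupancy_trajectory")) trajs <- list(trajs)
  if (B < 50) stop("B must be at least 50")
  if (missing(seed)) stop("a seed is required")
  if (length(trajs) == 1)
    warning("single replicate: falling back to block-only bootstrap")
  set.seed(seed)
  stats_mat <- vapply(seq_len(B), function(b) {
    picked <- trajs[sample.int(length(trajs), replace = TRUE)]
    res <- lapply(picked, resample_blocks, block_ps = block_ps)
    as.numeric(statistic(res))
  }, FUN.VALUE = as.numeric(statistic(trajs)))
  if (is.null(dim(stats_mat))) stats_mat <- matrix(stats_mat, nrow = 1)
  se <- apply(stats_mat, 1, stats::sd)
  names(se) <- names(statistic(trajs))
  attr(se, "replicates") <- B
  se
}

## Circular moving-block resample of the retained frames of one trajectory.
## Returns a trajectory whose retained frames are the resampled ones (times
## are re-indexed on a uniform grid; only moment statistics should be taken
## from resampled objects).
resample_blocks <- function(traj, block_ps) {
  idx <- which(traj$frame_mask)
  n <- length(idx)
  if (n == 0L) return(traj)
  dt <- if (n > 1) stats::median(diff(traj$times[idx])) else 1
  L <- max(1L, min(n, as.integer(round(block_ps / dt))))
  n_blocks <- ceiling(n / L)
  starts <- sample.int(n, n_blocks, replace = TRUE)
  pick <- unlist(lapply(starts, function(s) ((s - 1L + 0:(L - 1L)) %% n) + 1L))
  pick <- pick[seq_len(n)]
  occ <- traj$occupancies[idx[pick], , drop = FALSE]
  occupancy_trajectory(occ, seq_len(n) * dt, pH = traj$pH,
                       replicate_id = traj$replicate_id, form = traj$form,
                       sites = traj$sites)
}
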