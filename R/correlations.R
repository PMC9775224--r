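## Proton-occupancy coupling: Pearson matrices, networks, exchange kinetics.

#' Pairwise Pearson correlations of proton occupancies
#'
#' \eqn{\rho_{ij} = cov(n_i, n_j)/\sqrt{var(n_i) var(n_j)}} over the pooled
#' retained frames of all replicates at one (form, pH). Sites that never
#' titrate at that pH (zero variance) yield flagged-invalid entries rather
#' than zeros, so correlation networks cannot contain spurious null edges.
#' For dimers the matrix covers both chains jointly, so intrachain and
#' interchain pairs are treated on the same footing.
#'
#' @param trajs One \code{occupancy_trajectory} or a list of replicates.
#' @return Object of class \code{correlation_matrix}: list with
#'   \code{sites}, \code{rho} (symmetric, unit diagonal where valid),
#'   \code{valid} (logical matrix), \code{pH}, \code{form},
#'   \code{n_frames}.
#' @export
pearson_matrix <- function(trajs) {
  pt <- compute_titration_point(trajs)
  v <- diag(pt$site_cov)
  valid_site <- v > 0
  denom <- sqrt(outer(v, v))
  rho <- pt$site_cov / denom
  valid <- outer(valid_site, valid_site, `&`)
  rho[!valid] <- NA_real_
  diag(rho)[valid_site] <- 1
  dimnames(rho) <- list(pt$sites, pt$sites)
  dimnames(valid) <- dimnames(rho)
  structure(list(sites = pt$sites, rho = rho, valid = valid,
                 pH = pt$pH, form = pt$form,
                 n_frames = pt$n_frames_used),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  off <- abs(x$rho[upper.tri(x$rho)])
  cat(sprintf(
    "correlation_matrix: %d sites | form=%s pH=%.2f | max |rho| = %.3f\n",
    length(x$sites), x$form, x$pH,
    if (all(is.na(off))) NA else max(off, na.rm = TRUE)))
  invisible(x)
}

#' Correlation network edge list
#'
#' Undirected edges between site pairs with \eqn{|\rho| \ge} cutoff and
#' valid entries, sorted by \eqn{|\rho|} descending. Couplings as small as
#' |rho| = 0.15 can already reflect meaningful electrostatic interaction
#' networks, hence the permissive default.
#'
#' @param m A \code{correlation_matrix}.
#' @param cutoff Absolute-correlation threshold in (0, 1].
#' @return data.frame with columns \code{site_i}, \code{site_j},
#'   \code{rho}.
#' @export
correlation_network <- function(m, cutoff = 0.15) {
  stopifnot(cutoff > 0, cutoff <= 1)
  idx <- which(upper.tri(m$rho), arr.ind = TRUE)
  rho <- m$rho[idx]
  ok <- m$valid[idx] & !is.na(rho) & abs(rho) >= cutoff
  out <- data.frame(site_i = m$sites[idx[ok, 1]],
                    site_j = m$sites[idx[ok, 2]],
                    rho = rho[ok], stringsAsFactors = FALSE)
  out[order(-abs(out$rho)), , drop = FALSE]
}

#' Autocorrelation of a proton-occupancy series
#'
#' Normalized autocovariance (population normalization) of the binary
#' occupancy series of one site. Each replicate contributes its longest
#' contiguous retained stretch (masks from dissociation filtering would
#' otherwise splice distant times together); replicate ACFs are averaged
#' with frame-count weights.
#'
#' @param trajs One \code{occupancy_trajectory} or a list of replicates.
#' @param site Site label.
#' @param max_lag_ps Maximum lag in ps (default: half the stretch length).
#' @return Object of class \code{occupancy_acf}: list with \code{lag_ps},
#'   \code{acf}, \code{dt_ps}, \code{valid} (FALSE when the series never
#'   titrates).
#' @export
occupancy_acf <- function(trajs, site, max_lag_ps = NULL) {
  if (inherits(trajs, "occupancy_trajectory")) trajs <- list(trajs)
  stretches <- lapply(trajs, function(tr) {
    if (!site %in% tr$sites) stop("unknown site: ", site)
    r <- rle(tr$frame_mask)
    if (!any(r$values)) return(NULL)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    k <- which(r$values)[which.max(r$lengths[r$values])]
    idx <- starts[k]:ends[k]
    list(x = tr$occupancies[idx, site], dt = stats::median(diff(tr$times[idx])))
  })
  stretches <- Filter(Negate(is.null), stretches)
  if (!length(stretches)) stop("no retained frames")
  dt <- stretches[[1]]$dt
  if (is.null(max_lag_ps))
    max_lag_ps <- dt * floor(max(vapply(stretches, function(s)
      length(s$x), numeric(1))) / 2)
  max_lag <- max(1L, as.integer(floor(max_lag_ps / dt)))
  acfs <- lapply(stretches, function(s) {
    if (stats::var(s$x) == 0) return(NULL)
    lm <- min(max_lag, length(s$x) - 1L)
    a <- stats::acf(s$x, lag.max = lm, plot = FALSE, demean = TRUE)$acf[, 1, 1]
    list(a = a, w = length(s$x))
  })
  acfs <- Filter(Negate(is.null), acfs)
  if (!length(acfs)) {
    return(structure(list(lag_ps = 0, acf = NA_real_, dt_ps = dt,
                          valid = FALSE), class = "occupancy_acf"))
  }
  L <- max(vapply(acfs, function(z) length(z$a), integer(1)))
  num <- numeric(L); den <- numeric(L)
  for (z in acfs) {
    i <- seq_along(z$a)
    num[i] <- num[i] + z$w * z$a
    den[i] <- den[i] + z$w
  }
  structure(list(lag_ps = (seq_len(L) - 1L) * dt, acf = num / den,
                 dt_ps = dt, valid = TRUE),
            class = "occupancy_acf")
}

#' Occupancy correlation time
#'
#' Time of the first lag at which the autocorrelation function drops below
#' the threshold (first crossing, not sustained). If the ACF never crosses
#' within the available lags, the last lag time is returned with
#' \code{censored = TRUE}.
#'
#' @param acf An \code{occupancy_acf}.
#' @param threshold ACF threshold (default 0.1).
#' @return List with \code{tau_ps}, \code{censored}, \code{valid}.
#' @export
correlation_time <- function(acf, threshold = 0.1) {
  if (!isTRUE(acf$valid))
    return(list(tau_ps = NA_real_, censored = FALSE, valid = FALSE))
  below <- which(acf$acf < threshold)
  if (!length(below))
    return(list(tau_ps = max(acf$lag_ps), censored = TRUE, valid = TRUE))
  list(tau_ps = acf$lag_ps[below[1]], censored = FALSE, valid = TRUE)
}

#' Per-site coupling / kinetics / protonation-shift summary
#'
#' For every site and pH where both forms are present, joins: the maximum
#' absolute Pearson correlation over valid partners (within the site's own
#' form), the occupancy correlation time, the absolute monomer-to-dimer
#' protonation shift \eqn{|\bar n_i^{D,chain} - \bar n_i^M|} (dimer
#' per-chain mean), and the standard deviation of the signed correlations
#' (the dispersion summary; the signed mean is typically near zero by
#' cancellation).
#'
#' @param systems A \code{system_set} with both forms.
#' @param acf_threshold Correlation-time threshold (default 0.1).
#' @param form Which form's correlations/ACFs to summarize
#'   (default \code{"dimer"}).
#' @return data.frame with columns \code{site}, \code{pH},
#'   \code{max_abs_rho}, \code{sd_rho}, \code{tau_ps}, \code{tau_censored},
#'   \code{dprot}.
#' @export
site_summary_scatter <- function(systems, acf_threshold = 0.1,
                                 form = "dimer") {
  strip <- function(x) sub("^[^:]*:", "", x)
  rows <- list()
  for (p in systems$pH_values) {
    tm <- get_replicates(systems, "monomer", p)
    td <- get_replicates(systems, form, p)
    if (!length(tm) || !length(td)) {
      warning("pH ", p, ": missing form, row omitted")
      next
    }
    ptM <- compute_titration_point(tm)
    cm <- pearson_matrix(td)
    for (s in cm$sites) {
      partners <- setdiff(cm$sites, s)
      r <- cm$rho[s, partners]
      r <- r[cm$valid[s, partners]]
      max_rho <- if (length(r)) max(abs(r)) else NA_real_
      sd_rho <- if (length(r) > 1) stats::sd(r) else NA_real_
      a <- occupancy_acf(td, s)
      ct <- correlation_time(a, acf_threshold)
      mono_site <- strip(s)
      dprot <- if (mono_site %in% strip(ptM$sites)) {
        nm <- ptM$site_means[[which(strip(ptM$sites) == mono_site)[1]]]
        nd <- compute_titration_point(td)$site_means[[s]]
        abs(nd - nm)
      } else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        site = s, pH = p, max_abs_rho = max_rho, sd_rho = sd_rho,
        tau_ps = ct$tau_ps, tau_censored = isTRUE(ct$censored),
        dprot = dprot, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
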