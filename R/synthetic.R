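## Exactly solvable coupled-site titration models.
##
## The semi-grand partition function (binding polynomial) of a protein with
## M titratable sites, intrinsic pKa_i and pairwise couplings W_ij (kJ/mol,
## applied when both members of a pair are protonated) is
##   Xi(pH) = sum_{s in {0,1}^M} exp(-beta * sum_{i<j} W_ij s_i s_j)
##                               * prod_i 10^{-s_i (pH - pKa_i)}
## Everything the pipeline estimates from sampled occupancies (means,
## variances, covariances, linkage free energies) has an exact counterpart
## by direct state enumeration, which is what makes these models usable as
## oracles for every downstream stage.

#' Define a coupled-site titration model
#'
#' @param labels Site labels (unique).
#' @param pKa Intrinsic pKa per site.
#' @param kind \code{"acid"}/\code{"base"} per site (recycled).
#' @param W Symmetric coupling matrix in kJ/mol, zero diagonal; entry
#'   \code{W[i,j]} is added to the energy when sites i and j are both
#'   protonated. Default: no coupling.
#' @param temperature Temperature in K.
#' @param form \code{"monomer"} or \code{"dimer"} tag.
#' @param dG_assoc pH-independent association offset in kJ/mol (only
#'   meaningful for dimers; cancels in relative free energies).
#' @return Object of class \code{titration_model}.
#' @export
titration_model <- function(labels, pKa, kind = "acid", W = NULL,
                            temperature = 300,
                            form = c("monomer", "dimer"), dG_assoc = 0) {
  form <- match.arg(form)
  M <- length(labels)
  stopifnot(length(pKa) == M, M >= 1)
  if (M > 20) stop("models with more than 20 sites are not enumerable here")
  kind <- rep_len(kind, M)
  if (is.null(W)) W <- matrix(0, M, M)
  W <- as.matrix(W)
  if (!isTRUE(all.equal(W, t(W))) || any(diag(W) != 0))
    stop("W must be symmetric with zero diagonal")
  structure(list(labels = as.character(labels), pKa = as.numeric(pKa),
                 kind = kind, W = W, temperature = temperature,
                 form = form, dG_assoc = dG_assoc),
            class = "titration_model")
}

#' Build a dimer model from a monomer model
#'
#' Duplicates the monomer sites into chains A and B (labels prefixed
#' \code{"A:"}/\code{"B:"}), keeps the intrachain couplings, and adds an
#' interchain coupling block — the minimal way association perturbs
#' titration in a coupled-site model.
#'
#' @param monomer A \code{titration_model} with \code{form = "monomer"}.
#' @param W_inter M x M interchain coupling matrix in kJ/mol
#'   (\code{W_inter[i, j]} couples site i of chain A with site j of chain
#'   B); default zero.
#' @param dG_assoc pH-independent association offset (kJ/mol).
#' @param dpKa Optional per-site intrinsic-pKa shift applied to both chains
#'   upon dimerization.
#' @return A dimer \code{titration_model} with 2M sites.
#' @export
dimerize_model <- function(monomer, W_inter = NULL, dG_assoc = 0,
                           dpKa = 0) {
  M <- length(monomer$labels)
  if (is.null(W_inter)) W_inter <- matrix(0, M, M)
  W_inter <- as.matrix(W_inter)
  stopifnot(nrow(W_inter) == M, ncol(W_inter) == M)
  strip <- sub("^[^:]*:", "", monomer$labels)
  W <- rbind(cbind(monomer$W, W_inter),
             cbind(t(W_inter), monomer$W))
  titration_model(labels = c(paste0("A:", strip), paste0("B:", strip)),
                  pKa = rep(monomer$pKa + dpKa, 2),
                  kind = rep(monomer$kind, 2), W = W,
                  temperature = monomer$temperature, form = "dimer",
                  dG_assoc = dG_assoc)
}

## All 2^M microstates as a 0/1 matrix (states x sites).
enumerate_states <- function(M) {
  n <- 2L^M
  vapply(seq_len(M), function(i)
    as.integer(bitwAnd(seq_len(n) - 1L, bitwShiftL(1L, i - 1L)) > 0L),
    integer(n))
}

#' Exact titration thermodynamics by state enumeration
#'
#' Sums over all \eqn{2^M} protonation microstates with log-sum-exp
#' stabilization, returning per pH the log binding polynomial and every
#' moment the sampling pipeline estimates: mean and variance of the total
#' proton count, per-site means, covariances with the total, and the full
#' pairwise covariance matrix.
#'
#' @param model A \code{titration_model} (<= 20 sites).
#' @param pH_values Numeric vector of pH values.
#' @return Object of class \code{exact_titration}: list with \code{pH},
#'   \code{lnXi}, \code{n_mean}, \code{n_var}, \code{site_means} (matrix pH
#'   x sites), \code{site_cov_total} (matrix), \code{site_cov} (list of
#'   matrices), \code{model}.
#' @export
enumerate_exact <- function(model, pH_values) {
  M <- length(model$labels)
  S <- enumerate_states(M)                       # 2^M x M
  beta <- 1 / (protlink_constants[["R_kJ"]] * model$temperature)
  # pairwise coupling energy per state (kJ/mol), counted once per pair
  Epair <- rowSums((S %*% model$W) * S) / 2
  n_tot <- rowSums(S)
  lnXi <- numeric(length(pH_values))
  n_mean <- numeric(length(pH_values))
  n_var <- numeric(length(pH_values))
  site_means <- matrix(NA_real_, length(pH_values), M,
                       dimnames = list(NULL, model$labels))
  site_cov_total <- site_means
  site_cov <- vector("list", length(pH_values))
  for (q in seq_along(pH_values)) {
    lw <- -beta * Epair + log(10) * as.numeric(S %*% (model$pKa - pH_values[q]))
    mx <- max(lw)
    w <- exp(lw - mx)
    Z <- sum(w)
    p <- w / Z
    lnXi[q] <- mx + log(Z)
    mu <- as.numeric(crossprod(S, p))            # per-site means
    Sc <- sweep(S, 2, mu)
    C <- crossprod(Sc, Sc * p)                   # pairwise covariance
    site_means[q, ] <- mu
    site_cov[[q]] <- C
    site_cov_total[q, ] <- rowSums(C)
    n_mean[q] <- sum(mu)
    n_var[q] <- sum(C)
  }
  structure(list(pH = as.numeric(pH_values), lnXi = lnXi,
                 n_mean = n_mean, n_var = n_var,
                 site_means = site_means,
                 site_cov_total = site_cov_total,
                 site_cov = site_cov, model = model),
            class = "exact_titration")
}

#' Exact relative dimerization free energy (binding-polynomial oracle)
#'
#' \eqn{\Delta\Delta G(pH) = -RT\{[\ln\Xi_D - 2\ln\Xi_M](pH) -
#' [\ln\Xi_D - 2\ln\Xi_M](pH_{ref})\}} by direct enumeration. Any
#' pH-independent association offset cancels. This is the independent
#' reference the spline-linkage route must reproduce, and it pins the sign
#' convention of the linkage relation.
#'
#' @param model_M,model_D Monomer and dimer \code{titration_model}s (the
#'   dimer's sites must be two copies of the monomer's).
#' @param pH Numeric vector of evaluation pH values.
#' @param pH_ref Reference pH.
#' @param T Temperature (K); defaults to the monomer model's.
#' @return Numeric vector of exact relative free energies in kJ/mol.
#' @export
exact_ddG <- function(model_M, model_D, pH, pH_ref,
                      T = model_M$temperature) {
  if (length(model_D$labels) != 2 * length(model_M$labels))
    stop("dimer model must have twice the monomer's sites")
  RT <- protlink_constants[["R_kJ"]] * T
  all_pH <- c(pH, pH_ref)
  eM <- enumerate_exact(model_M, all_pH)
  eD <- enumerate_exact(model_D, all_pH)
  d <- eD$lnXi - 2 * eM$lnXi
  -RT * (d[seq_along(pH)] - d[length(all_pH)])
}

#' Convert an exact titration result to a titration curve
#'
#' Wraps exact enumeration moments in the same \code{titration_curve}
#' container the sampling pipeline produces, so the linkage machinery can
#' be driven with exact inputs (separating spline-interpolation error from
#' Monte Carlo noise).
#'
#' @param exact An \code{exact_titration}.
#' @return A \code{titration_curve}.
#' @export
exact_titration_curve <- function(exact) {
  pts <- lapply(seq_along(exact$pH), function(q) {
    structure(list(
      pH = exact$pH[q], form = exact$model$form,
      sites = exact$model$labels,
      n_mean = exact$n_mean[q], n_var = exact$n_var[q],
      site_means = stats::setNames(exact$site_means[q, ],
                                   exact$model$labels),
      site_cov_total = stats::setNames(exact$site_cov_total[q, ],
                                       exact$model$labels),
      site_cov = exact$site_cov[[q]],
      n_frames_used = Inf), class = "titration_point")
  })
  structure(list(form = exact$model$form, pH = exact$pH, points = pts,
                 sites = exact$model$labels),
            class = "titration_curve")
}

#' Metropolis sampling of occupancy trajectories
#'
#' Single-site-flip Metropolis chain on the microstate distribution of the
#' coupled-site model; its stationary distribution is exactly the binding
#' polynomial measure of \code{\link{enumerate_exact}}. Per-site attempt
#' weights allow designing slow-exchanging sites (long occupancy
#' correlation times).
#'
#' @param model A \code{titration_model}.
#' @param pH Simulation pH.
#' @param n_steps Total MC steps (>= 1000).
#' @param record_every Record the state every this many steps.
#' @param seed Integer seed (mandatory).
#' @param dt_ps Nominal time per recorded frame in ps (default 20).
#' @param attempt_weights Optional per-site relative flip-attempt rates.
#' @param replicate_id Replicate tag.
#' @param burn_in Steps discarded before recording (default
#'   \code{10 * record_every * n_sites}).
#' @return An \code{occupancy_trajectory}.
#' @export
sample_occupancies <- function(model, pH, n_steps, record_every = 10,
                               seed, dt_ps = 20, attempt_weights = NULL,
                               replicate_id = "rep1", burn_in = NULL) {
  if (missing(seed)) stop("a seed is required")
  if (n_steps < 1000) stop("n_steps must be at least 1000")
  M <- length(model$labels)
  if (is.null(attempt_weights)) attempt_weights <- rep(1, M)
  stopifnot(length(attempt_weights) == M, all(attempt_weights > 0))
  if (is.null(burn_in)) burn_in <- 10L * record_every * M
  beta <- 1 / (protlink_constants[["R_kJ"]] * model$temperature)
  set.seed(seed)
  init <- as.integer(stats::runif(M) < hill_curve(pH, model$pKa, 1))
  occ <- metropolis_occupancy(model$pKa, beta * model$W, pH,
                              as.integer(burn_in + n_steps),
                              as.integer(record_every),
                              cumsum(attempt_weights / sum(attempt_weights)),
                              init)
  skip <- burn_in %/% record_every
  occ <- occ[(skip + 1L):nrow(occ), , drop = FALSE]
  occupancy_trajectory(occ, seq_len(nrow(occ)) * dt_ps, pH = pH,
                       replicate_id = replicate_id, form = model$form,
                       sites = model$labels)
}

#' Generate synthetic ion clouds
#'
#' Draws iid ion positions per frame from a specified density: uniform in
#' a box, a Gaussian mixture, or a Boltzmann density
#' \eqn{\propto \exp(-z F \phi / RT)} over a supplied potential grid
#' (sampled voxel-wise with uniform jitter inside the voxel).
#'
#' @param spec List describing the density. One of:
#'   \code{list(type = "uniform", box = c(lx, ly, lz))} (Å, origin 0);
#'   \code{list(type = "gaussian", centers = matrix, sd = numeric,
#'   weights = numeric)};
#'   \code{list(type = "boltzmann", phi = potential_grid, z = charge,
#'   T = K)}.
#' @param N Ions per frame.
#' @param n_frames Number of frames.
#' @param seed Integer seed (mandatory).
#' @return List of \code{n_frames} N x 3 coordinate matrices (Å), with the
#'   spec attached as attribute \code{"spec"}.
#' @export
generate_ion_cloud <- function(spec, N, n_frames, seed) {
  if (missing(seed)) stop("a seed is required")
  set.seed(seed)
  draw <- switch(spec$type,
    uniform = function(n) {
      cbind(stats::runif(n, 0, spec$box[1]),
            stats::runif(n, 0, spec$box[2]),
            stats::runif(n, 0, spec$box[3]))
    },
    gaussian = function(n) {
      K <- nrow(spec$centers)
      w <- if (is.null(spec$weights)) rep(1 / K, K) else
        spec$weights / sum(spec$weights)
      sds <- rep_len(spec$sd, K)
      comp <- sample.int(K, n, replace = TRUE, prob = w)
      spec$centers[comp, , drop = FALSE] +
        matrix(stats::rnorm(3 * n, sd = sds[comp]), n, 3)
    },
    boltzmann = {
      phi <- spec$phi
      # phi in volts; R_kJ -> J/(mol K) needs *1000; fac = zF/(RT) in 1/V
      fac <- spec$z * protlink_constants[["faraday"]] /
        (protlink_constants[["R_kJ"]] * 1000 * spec$T)
      w <- exp(-fac * as.numeric(phi$values))
      if (!all(is.finite(w))) stop("non-normalizable boltzmann spec")
      w <- w / sum(w)
      dims <- phi$shape
      function(n) {
        vox <- sample.int(length(w), n, replace = TRUE, prob = w)
        ijk <- arrayInd(vox, dims) - 1L
        sweep(ijk + matrix(stats::runif(3 * n) - 0.5, n, 3), 2,
              phi$spacing, `*`) + rep(phi$origin, each = n)
      }
    },
    stop("unknown ion-cloud spec type: ", spec$type))
  frames <- lapply(seq_len(n_frames), function(i) draw(N))
  attr(frames, "spec") <- spec
  frames
}

## --- structural toy generators -------------------------------------------

#' Helix-like backbone chain template
#'
#' Deterministic N/CA/C backbone trace of \code{n_res} residues laid out
#' as two short helical segments joined by a straight linker — enough
#' secondary-structure-like geometry for superposition, SASA, dihedral and
#' PCA tests without any force field.
#'
#' @param n_res Number of residues (default 12).
#' @param chain Chain identifier.
#' @return List with \code{atoms} (data.frame) and \code{xyz}
#'   (matrix, nm).
#' @export
helix_chain_template <- function(n_res = 12, chain = "A") {
  radius <- 0.23; rise <- 0.15; twist <- 100 * pi / 180
  half <- ceiling(n_res / 2)
  ca <- t(vapply(seq_len(n_res), function(i) {
    seg <- if (i <= half) 1 else 2
    k <- if (seg == 1) i else i - half
    base <- if (seg == 1) c(0, 0, 0) else c(0.8, 0, half * rise + 0.2)
    ang <- k * twist
    base + c(radius * cos(ang), radius * sin(ang), k * rise)
  }, numeric(3)))
  atoms <- list(); xyz <- list()
  for (i in seq_len(n_res)) {
    # N and C offset along the local helix tangent
    tangent <- if (i < n_res) ca[min(i + 1, n_res), ] - ca[i, ] else
      ca[i, ] - ca[i - 1, ]
    tangent <- tangent / sqrt(sum(tangent^2))
    xyz[[length(xyz) + 1L]] <- ca[i, ] - 0.123 * tangent
    xyz[[length(xyz) + 1L]] <- ca[i, ]
    xyz[[length(xyz) + 1L]] <- ca[i, ] + 0.152 * tangent
    atoms[[length(atoms) + 1L]] <- data.frame(
      name = c("N", "CA", "C"), resid = "ALA", chain = chain,
      resno = i, stringsAsFactors = FALSE)
  }
  list(atoms = do.call(rbind, atoms), xyz = do.call(rbind, xyz))
}

## Rotation matrix about a unit axis by angle (radians), Rodrigues form.
rotation_about_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Generate a rigid-body synthetic dimer ensemble
#'
#' Chain A is a fixed helix-like template; chain B is the same template,
#' shifted by a base offset and transformed per frame by a programmed
#' rigid motion (rotation about a given axis through the chain-B centroid
#' plus a translation), with optional isotropic Gaussian coordinate noise.
#' The programmed angles/translations are returned so analyses can be
#' checked against them.
#'
#' @param n_frames Number of frames.
#' @param angles_deg Per-frame rotation angle(s) in degrees (recycled).
#' @param axis Rotation axis (length 3).
#' @param translations Per-frame translation(s): length-3 vector or
#'   \code{n_frames x 3} matrix (nm).
#' @param base_offset Chain-B placement offset from chain A (nm).
#' @param noise_sd Isotropic coordinate noise sd in nm (default 0).
#' @param n_res Residues per chain.
#' @param seed Integer seed (mandatory when \code{noise_sd > 0}).
#' @return A \code{conformation_ensemble} of the dimer, with the
#'   programmed motion in \code{provenance}.
#' @export
generate_dimer_ensemble <- function(n_frames, angles_deg = 0,
                                    axis = c(0, 0, 1),
                                    translations = c(0, 0, 0),
                                    base_offset = c(1.6, 0, 0),
                                    noise_sd = 0, n_res = 12, seed = NULL) {
  if (noise_sd > 0 && is.null(seed))
    stop("a seed is required when noise_sd > 0")
  if (!is.null(seed)) set.seed(seed)
  tplA <- helix_chain_template(n_res, "A")
  tplB <- helix_chain_template(n_res, "B")
  B0 <- sweep(tplB$xyz, 2, base_offset, `+`)
  ctrB <- colMeans(B0)
  angles <- rep_len(angles_deg, n_frames) * pi / 180
  if (is.null(dim(translations)))
    translations <- matrix(translations, n_frames, 3, byrow = TRUE)
  frames <- lapply(seq_len(n_frames), function(i) {
    Rm <- rotation_about_axis(axis, angles[i])
    B <- sweep(sweep(B0, 2, ctrB) %*% t(Rm), 2, ctrB + translations[i, ], `+`)
    xyz <- rbind(tplA$xyz, B)
    if (noise_sd > 0)
      xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = noise_sd),
                          nrow(xyz), 3)
    xyz
  })
  conformation_ensemble(rbind(tplA$atoms, tplB$atoms), frames,
                        provenance = list(angles_deg = angles * 180 / pi,
                                          translations = translations,
                                          axis = axis,
                                          noise_sd = noise_sd))
}
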