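## Structural analyses: superposition, RMSD, dissociation filtering,
## central structures, SASA / contact area, interface dihedrals,
## decoupled-fit PCA and free-energy landscapes. Coordinates are in nm.

#' Construct a conformational ensemble
#'
#' @param atoms data.frame with columns \code{name}, \code{resno},
#'   \code{chain} (and optionally \code{resid}, \code{mass}).
#' @param coords Array \code{n_frames x n_atoms x 3} in nm, or a list of
#'   \code{n_atoms x 3} matrices.
#' @param provenance Named list (form, pH, replicate ...).
#' @return Object of class \code{conformation_ensemble}.
#' @export
conformation_ensemble <- function(atoms, coords, provenance = list()) {
  if (is.list(coords) && !is.array(coords)) {
    coords <- aperm(simplify2array(coords), c(3, 1, 2))
  }
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3,
            dim(coords)[2] == nrow(atoms))
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  structure(list(atoms = atoms, coords = coords, provenance = provenance),
            class = "conformation_ensemble")
}

#' @export
print.conformation_ensemble <- function(x, ...) {
  cat(sprintf("conformation_ensemble: %d frames x %d atoms\n",
              dim(x$coords)[1], dim(x$coords)[2]))
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ensemble A \code{conformation_ensemble}.
#' @return Integer frame count.
#' @export
n_frames <- function(ensemble) dim(ensemble$coords)[1]

#' Extract one frame as a coordinate matrix
#' @param ensemble A \code{conformation_ensemble}.
#' @param i Frame index.
#' @return \code{n_atoms x 3} matrix (nm).
#' @export
get_frame <- function(ensemble, i) {
  m <- ensemble$coords[i, , , drop = FALSE]
  dim(m) <- dim(ensemble$coords)[2:3]
  m
}

#' Select atom indices
#'
#' Simple conjunctive selection over the ensemble's atom table.
#'
#' @param ensemble A \code{conformation_ensemble}.
#' @param chain Chain id(s), or NULL.
#' @param resno Residue numbers, or NULL.
#' @param name Atom names, or NULL.
#' @param backbone If TRUE, restrict to N/CA/C.
#' @return Integer vector of atom indices.
#' @export
select_atoms <- function(ensemble, chain = NULL, resno = NULL, name = NULL,
                         backbone = FALSE) {
  a <- ensemble$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  if (!is.null(name)) keep <- keep & a$name %in% name
  if (backbone) keep <- keep & a$name %in% c("N", "CA", "C")
  which(keep)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Optimal proper rotation and translation mapping \code{P} onto \code{Q}
#' in the least-squares sense; reflections are excluded by the usual
#' determinant correction.
#'
#' @param P,Q \code{n x 3} matched coordinate matrices.
#' @return List with \code{rotation} (3x3, to be applied as
#'   \code{x \%*\% rotation}), \code{translation} (length 3), and
#'   \code{rmsd} of the superposed pair.
#' @export
kabsch_transform <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  stopifnot(nrow(P) == nrow(Q), ncol(P) == 3, ncol(Q) == 3, nrow(P) >= 3)
  pc <- colMeans(P); qc <- colMeans(Q)
  Pc <- sweep(P, 2, pc); Qc <- sweep(Q, 2, qc)
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  trans <- qc - as.numeric(pc %*% R)
  fit <- sweep(Pc %*% R, 2, qc, `+`)
  list(rotation = R, translation = trans,
       rmsd = sqrt(mean(rowSums((fit - Q)^2))))
}

#' Superposition-minimized RMSD
#'
#' Minimum root-mean-square deviation between matched selections after
#' optimal rigid superposition.
#'
#' @param frame \code{n_atoms x 3} coordinate matrix (nm).
#' @param reference Matched reference matrix.
#' @param selection Optional atom indices used both for fitting and for
#'   the deviation (default: all).
#' @return RMSD in nm.
#' @export
rmsd <- function(frame, reference, selection = NULL) {
  if (!is.null(selection)) {
    frame <- frame[selection, , drop = FALSE]
    reference <- reference[selection, , drop = FALSE]
  }
  if (nrow(frame) < 3) stop("RMSD needs at least 3 atoms")
  kabsch_transform(frame, reference)$rmsd
}

#' Center-of-mass distance between two selections
#'
#' @param frame \code{n_atoms x 3} coordinate matrix (nm).
#' @param selection_A,selection_B Atom index vectors (non-empty).
#' @param masses Optional per-atom masses (full-length); default: equal.
#' @return Distance in nm.
#' @export
com_distance <- function(frame, selection_A, selection_B, masses = NULL) {
  if (!length(selection_A) || !length(selection_B))
    stop("empty selection")
  if (is.null(masses)) masses <- rep(1, nrow(frame))
  com <- function(sel) {
    w <- masses[sel] / sum(masses[sel])
    as.numeric(crossprod(frame[sel, , drop = FALSE], w))
  }
  sqrt(sum((com(selection_A) - com(selection_B))^2))
}

#' Dissociation frame filter for dimer ensembles
#'
#' Flags frames as dissociated when the COM distance between the two
#' partners exceeds \code{d_max} and/or the backbone RMSD to the reference
#' dimer (after optimal superposition) exceeds \code{rmsd_max}. Defaults
#' 3.3 nm and 1.2 nm. The returned mask feeds
#' \code{\link{apply_frame_mask}} so that dissociated frames are excluded
#' from all dimer statistics.
#'
#' @param ensemble A dimer \code{conformation_ensemble}.
#' @param reference \code{n_atoms x 3} reference coordinates (matched).
#' @param selection_A,selection_B Atom index vectors of the two partners.
#' @param rmsd_selection Atom indices for the RMSD (default: backbone).
#' @param d_max COM-distance threshold in nm (default 3.3).
#' @param rmsd_max RMSD threshold in nm (default 1.2).
#' @param masses Optional masses for the COM.
#' @return Logical vector, \code{TRUE} = frame retained (associated).
#' @export
dissociation_mask <- function(ensemble, reference, selection_A, selection_B,
                              rmsd_selection = NULL, d_max = 3.3,
                              rmsd_max = 1.2, masses = NULL) {
  if (nrow(reference) != dim(ensemble$coords)[2])
    stop("reference does not match ensemble atoms")
  if (is.null(rmsd_selection))
    rmsd_selection <- select_atoms(ensemble, backbone = TRUE)
  if (!length(rmsd_selection)) rmsd_selection <- seq_len(nrow(reference))
  vapply(seq_len(n_frames(ensemble)), function(i) {
    fr <- get_frame(ensemble, i)
    d <- com_distance(fr, selection_A, selection_B, masses)
    r <- rmsd(fr, reference, rmsd_selection)
    d <= d_max && r <= rmsd_max
  }, logical(1))
}

#' Central structure of an ensemble
#'
#' Index of the frame minimizing the mean squared superposition-minimized
#' RMSD to all other frames (ties broken by lowest index) — the ensemble
#' member most representative of the sampled conformations.
#'
#' @param ensemble A \code{conformation_ensemble}.
#' @param selection Optional atom indices for the RMSD.
#' @return Integer frame index.
#' @export
central_structure <- function(ensemble, selection = NULL) {
  nf <- n_frames(ensemble)
  if (nf == 1L) return(1L)
  frames <- lapply(seq_len(nf), function(i) {
    fr <- get_frame(ensemble, i)
    if (!is.null(selection)) fr <- fr[selection, , drop = FALSE]
    fr
  })
  msd <- numeric(nf)
  for (i in seq_len(nf - 1L)) for (j in (i + 1L):nf) {
    r2 <- kabsch_transform(frames[[i]], frames[[j]])$rmsd^2
    msd[i] <- msd[i] + r2
    msd[j] <- msd[j] + r2
  }
  which.min(msd / (nf - 1L))
}

## Deterministic golden-spiral point lattice on the unit sphere.
golden_spiral_points <- function(n) {
  i <- seq_len(n) - 0.5
  y <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - y^2))
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  cbind(r * cos(phi), y, r * sin(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Numerical SASA with a deterministic golden-spiral test-point lattice on
#' each atom's solvent-expanded sphere and a 0.14 nm rolling probe.
#'
#' @param frame \code{n_atoms x 3} coordinate matrix (nm).
#' @param radii Per-atom van der Waals radii in nm (positive).
#' @param probe Probe radius in nm (default 0.14).
#' @param n_sphere_points Test points per atom (default 960, >= 32).
#' @return List with \code{atom_area} (nm^2 per atom) and \code{total}.
#' @export
sasa <- function(frame, radii, probe = 0.14, n_sphere_points = 960) {
  frame <- as.matrix(frame)
  n <- nrow(frame)
  radii <- rep_len(radii, n)
  if (any(radii <= 0)) stop("radii must be positive")
  if (n_sphere_points < 32) stop("n_sphere_points must be at least 32")
  pts <- golden_spiral_points(n_sphere_points)
  R <- radii + probe
  maxR <- max(R)
  area <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(frame, 2, frame[i, ])^2)
    nb <- which(d2 < (R[i] + maxR)^2 & seq_len(n) != i)
    nb <- nb[sqrt(d2[nb]) < R[i] + R[nb]]
    test <- sweep(pts * R[i], 2, frame[i, ], `+`)
    acc <- rep(TRUE, n_sphere_points)
    for (j in nb) {
      dj2 <- rowSums(sweep(test, 2, frame[j, ])^2)
      acc <- acc & dj2 > R[j]^2
      if (!any(acc)) break
    }
    area[i] <- 4 * pi * R[i]^2 * sum(acc) / n_sphere_points
  }
  list(atom_area = area, total = sum(area))
}

#' Contact surface area between two partners
#'
#' Buried solvent-accessible area on association:
#' \eqn{SASA(A) + SASA(B) - SASA(A \cup B)}, returned whole
#' (\code{"full"}) or halved (\code{"half"}, the default, i.e. the
#' per-partner buried surface). The convention used is attached as an
#' attribute so downstream reports can state it.
#'
#' @param frame \code{n_atoms x 3} dimer coordinates (nm).
#' @param selection_A,selection_B Disjoint atom index sets.
#' @param radii Per-atom radii (full-length, nm).
#' @param probe Probe radius (nm).
#' @param convention \code{"half"} (default) or \code{"full"}.
#' @param n_sphere_points Test points per atom.
#' @return Contact area in nm^2 with attribute \code{"convention"}.
#' @export
contact_area <- function(frame, selection_A, selection_B, radii,
                         probe = 0.14, convention = c("half", "full"),
                         n_sphere_points = 960) {
  convention <- match.arg(convention)
  if (length(intersect(selection_A, selection_B)))
    stop("selections must be disjoint")
  radii <- rep_len(radii, nrow(frame))
  sA <- sasa(frame[selection_A, , drop = FALSE], radii[selection_A],
             probe, n_sphere_points)$total
  sB <- sasa(frame[selection_B, , drop = FALSE], radii[selection_B],
             probe, n_sphere_points)$total
  sel <- c(selection_A, selection_B)
  sAB <- sasa(frame[sel, , drop = FALSE], radii[sel],
              probe, n_sphere_points)$total
  buried <- sA + sB - sAB
  out <- if (convention == "half") buried / 2 else buried
  attr(out, "convention") <- convention
  out
}

#' Torsion angle of four points
#'
#' Standard signed dihedral of four centroids, in degrees in (-180, 180].
#'
#' @param p1,p2,p3,p4 Length-3 coordinates (or group centroids).
#' @return Angle in degrees.
#' @export
interface_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20)
    stop("collinear points: dihedral undefined")
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Decoupled-fit principal component analysis
#'
#' PCA of Cartesian coordinates in which the atoms used for superposition
#' and the atoms analysed are mutually exclusive: every frame is fitted on
#' the reference by the \code{fit_selection} only, the
#' \code{transform_selection} coordinates are then collected and
#' eigen-decomposed about their mean. The disjointness is what lets the
#' components capture relative (interchain or interdomain) motion rather
#' than internal noise of the analysed atoms.
#'
#' @param ensembles A \code{conformation_ensemble} or list thereof (frames
#'   pooled across all, e.g. across pH values and chain-role swaps).
#' @param fit_selection,transform_selection Disjoint atom index vectors.
#' @param reference \code{n_atoms x 3} reference coordinates.
#' @return Object of class \code{pca_model}: list with \code{mean},
#'   \code{components} (columns, orthonormal), \code{variance_fractions},
#'   \code{projections} (frames x components), \code{fit_selection},
#'   \code{transform_selection}, \code{reference}.
#' @export
pca_decoupled <- function(ensembles, fit_selection, transform_selection,
                          reference) {
  if (inherits(ensembles, "conformation_ensemble"))
    ensembles <- list(ensembles)
  if (length(intersect(fit_selection, transform_selection)))
    stop("fit and transform selections must be disjoint")
  ref_fit <- reference[fit_selection, , drop = FALSE]
  rows <- list()
  for (e in ensembles) {
    for (i in seq_len(n_frames(e))) {
      fr <- get_frame(e, i)
      k <- kabsch_transform(fr[fit_selection, , drop = FALSE], ref_fit)
      moved <- sweep(fr %*% k$rotation, 2, k$translation, `+`)
      rows[[length(rows) + 1L]] <-
        as.numeric(t(moved[transform_selection, , drop = FALSE]))
    }
  }
  X <- do.call(rbind, rows)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc)
  ncomp <- min(dim(Xc))
  lambda <- sv$d^2 / nrow(X)
  total <- sum(lambda)
  vf <- if (total > 0) lambda / total else rep(0, length(lambda))
  structure(list(mean = mu, components = sv$v,
                 variance_fractions = vf,
                 projections = Xc %*% sv$v,
                 fit_selection = fit_selection,
                 transform_selection = transform_selection,
                 reference = reference),
            class = "pca_model")
}

#' Project new frames onto a fitted PCA model
#'
#' @param model A \code{pca_model}.
#' @param ensembles Ensemble(s) to project (same atom layout).
#' @return Matrix of projections (frames x components).
#' @export
pca_project <- function(model, ensembles) {
  if (inherits(ensembles, "conformation_ensemble"))
    ensembles <- list(ensembles)
  ref_fit <- model$reference[model$fit_selection, , drop = FALSE]
  rows <- list()
  for (e in ensembles) {
    for (i in seq_len(n_frames(e))) {
      fr <- get_frame(e, i)
      k <- kabsch_transform(fr[model$fit_selection, , drop = FALSE], ref_fit)
      moved <- sweep(fr %*% k$rotation, 2, k$translation, `+`)
      rows[[length(rows) + 1L]] <-
        as.numeric(t(moved[model$transform_selection, , drop = FALSE]))
    }
  }
  X <- do.call(rbind, rows)
  sweep(X, 2, model$mean) %*% model$components
}

#' Free-energy landscape over two principal components
#'
#' 2-D Gaussian kernel density on a regular mesh with per-axis bandwidth
#' \eqn{\sigma (4N/3)^{-1/5}} (sigma = standard deviation of the N points
#' on that axis), converted to \eqn{F = -k_B T \ln(P / P_{max})}, so the
#' minimum is exactly 0 at the density maximum and F >= 0 everywhere.
#'
#' @param projections \code{N x >=2} matrix; the first two columns are
#'   used.
#' @param mesh Grid spacing in projection units.
#' @param T Temperature (K).
#' @param bandwidth Optional length-2 bandwidth override.
#' @param pad Margin around the data in bandwidth multiples (default 3).
#' @return Object of class \code{free_energy_landscape}: list with
#'   \code{x}, \code{y}, \code{P}, \code{F} (kJ/mol), \code{bandwidth},
#'   \code{temperature}.
#' @export
landscape <- function(projections, mesh, T = 300, bandwidth = NULL,
                      pad = 3) {
  pr <- as.matrix(projections)[, 1:2, drop = FALSE]
  N <- nrow(pr)
  if (N < 2) stop("at least 2 points required")
  sds <- apply(pr, 2, stats::sd)
  if (any(sds == 0)) stop("degenerate (all-identical) projections")
  if (is.null(bandwidth)) bandwidth <- sds * (4 * N / 3)^(-1 / 5)
  bandwidth <- rep_len(bandwidth, 2)
  gx <- seq(min(pr[, 1]) - pad * bandwidth[1],
            max(pr[, 1]) + pad * bandwidth[1], by = mesh)
  gy <- seq(min(pr[, 2]) - pad * bandwidth[2],
            max(pr[, 2]) + pad * bandwidth[2], by = mesh)
  P <- matrix(0, length(gx), length(gy))
  for (i in seq_len(N)) {
    P <- P + outer(stats::dnorm(gx, pr[i, 1], bandwidth[1]),
                   stats::dnorm(gy, pr[i, 2], bandwidth[2]))
  }
  P <- P / N
  kT <- protlink_constants[["R_kJ"]] * T
  Fmat <- -kT * log(P / max(P))
  structure(list(x = gx, y = gy, P = P, F = Fmat, bandwidth = bandwidth,
                 temperature = T),
            class = "free_energy_landscape")
}

#' 1-D Gaussian-kernel histogram
#'
#' Kernel density of a scalar observable (COM distances, contact areas,
#' dihedrals) with the \eqn{\sigma (4N/3)^{-1/5}} bandwidth rule and 1/N
#' normalization (the curve integrates to 1).
#'
#' @param x Numeric sample.
#' @param n_grid Output grid size (default 512).
#' @param bandwidth Optional override.
#' @return data.frame with columns \code{x}, \code{density}.
#' @export
kernel_histogram <- function(x, n_grid = 512, bandwidth = NULL) {
  x <- x[is.finite(x)]
  N <- length(x)
  if (N < 2) stop("at least 2 points required")
  s <- stats::sd(x)
  if (is.null(bandwidth)) bandwidth <- if (s > 0) s * (4 * N / 3)^(-1 / 5) else 1e-6
  g <- seq(min(x) - 3 * bandwidth, max(x) + 3 * bandwidth,
           length.out = n_grid)
  d <- vapply(g, function(gv) mean(stats::dnorm(gv, x, bandwidth)),
              numeric(1))
  data.frame(x = g, density = d)
}

#' Read a multi-model PDB file as an ensemble
#'
#' Wraps \code{bio3d::read.pdb(multi = TRUE)}; coordinates are converted
#' from Angstrom to nm.
#'
#' @param path File path.
#' @return A \code{conformation_ensemble}.
#' @export
read_ensemble_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  atoms <- data.frame(name = pdb$atom$elety,
                      resid = pdb$atom$resid,
                      chain = pdb$atom$chain,
                      resno = pdb$atom$resno,
                      stringsAsFactors = FALSE)
  frames <- lapply(seq_len(nrow(pdb$xyz)), function(m)
    matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE) / 10)
  conformation_ensemble(atoms, frames)
}

#' Write an ensemble as a multi-model PDB file
#'
#' @param ensemble A \code{conformation_ensemble} (nm; written in
#'   Angstrom).
#' @param path Output path.
#' @export
write_ensemble_pdb <- function(ensemble, path) {
  con <- file(path, "w")
  on.exit(close(con))
  a <- ensemble$atoms
  resid <- if (!is.null(a$resid)) a$resid else "GLY"
  for (m in seq_len(n_frames(ensemble))) {
    writeLines(sprintf("MODEL     %4d", m), con)
    fr <- get_frame(ensemble, m) * 10
    writeLines(sprintf(
      "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
      seq_len(nrow(a)), substr(a$name, 1, 4), substr(resid, 1, 3),
      a$chain, a$resno, fr[, 1], fr[, 2], fr[, 3]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
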