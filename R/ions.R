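## Ionic concentration fingerprints: Gaussian-kernel density grids from ion
## tracks, Boltzmann-relation concentrations from potential grids, and
## OpenDX scalar-grid import/export.

#' Construct a scalar grid
#'
#' Shared container for concentration and potential grids: a regular
#' orthogonal lattice with an origin (Å), per-axis spacing (Å) and a 3-D
#' value array.
#'
#' @param values 3-D numeric array.
#' @param origin Length-3 origin in Å.
#' @param spacing Per-axis spacing in Å (scalar recycled).
#' @param unit Value unit tag (e.g. \code{"mM"}, \code{"V"}).
#' @param meta Optional named list of metadata.
#' @return Object of class \code{scalar_grid}.
#' @export
scalar_grid <- function(values, origin = c(0, 0, 0), spacing = 1,
                        unit = "", meta = list()) {
  values <- as.array(values)
  stopifnot(length(dim(values)) == 3, length(origin) == 3)
  spacing <- rep_len(as.numeric(spacing), 3)
  structure(list(values = values, origin = as.numeric(origin),
                 spacing = spacing, shape = dim(values), unit = unit,
                 meta = meta),
            class = "scalar_grid")
}

#' @export
print.scalar_grid <- function(x, ...) {
  cat(sprintf("scalar_grid: %s | origin (%g, %g, %g) A | spacing (%g, %g, %g) A | range [%.4g, %.4g] %s\n",
              paste(x$shape, collapse = " x "),
              x$origin[1], x$origin[2], x$origin[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              min(x$values), max(x$values), x$unit))
  invisible(x)
}

## Grid axis coordinates.
grid_axes <- function(g) {
  lapply(1:3, function(d) g$origin[d] + (seq_len(g$shape[d]) - 1L) * g$spacing[d])
}

#' Gaussian-kernel ion concentration grid
#'
#' Estimates the per-species ion number density on a regular grid with an
#' isotropic 3-D Gaussian kernel (default bandwidth 2 Å, mesh 1 Å),
#' averaged over frames, and converts it to concentration in mM. The
#' kernel is separable, so each ion contributes an outer product of 1-D
#' Gaussians truncated at 4 standard deviations (mass loss below 0.1%).
#' The build checks number conservation: the grid must integrate back to
#' the per-frame ion count within 1% (a violation means the grid does not
#' cover the cloud and triggers a warning).
#'
#' @param ion_frames List of N x 3 coordinate matrices (Å), one per frame,
#'   or a single matrix.
#' @param origin,spacing,shape Grid geometry (Å); defaults: mesh 1 Å.
#' @param bandwidth Gaussian kernel standard deviation in Å (default 2).
#' @param species Species tag stored in the metadata.
#' @return A \code{scalar_grid} in mM with metadata \code{n_frames},
#'   \code{mean_n_ions}, \code{bandwidth}, \code{species},
#'   \code{recovered_ions}.
#' @export
kde_concentration <- function(ion_frames, origin, spacing = 1, shape,
                              bandwidth = 2, species = "ion") {
  if (is.matrix(ion_frames)) ion_frames <- list(ion_frames)
  stopifnot(length(ion_frames) >= 1, bandwidth > 0)
  spacing <- rep_len(as.numeric(spacing), 3)
  dens <- array(0, dim = shape)
  axes <- lapply(1:3, function(d) origin[d] + (seq_len(shape[d]) - 1L) * spacing[d])
  trunc <- 4 * bandwidth
  n_total <- 0L
  for (fr in ion_frames) {
    if (is.null(fr) || nrow(fr) == 0) next
    n_total <- n_total + nrow(fr)
    for (i in seq_len(nrow(fr))) {
      p <- fr[i, ]
      g1 <- lapply(1:3, function(d) {
        sel <- which(abs(axes[[d]] - p[d]) <= trunc)
        list(sel = sel,
             w = stats::dnorm(axes[[d]][sel], mean = p[d], sd = bandwidth))
      })
      if (any(vapply(g1, function(z) length(z$sel) == 0L, logical(1)))) next
      dens[g1[[1]]$sel, g1[[2]]$sel, g1[[3]]$sel] <-
        dens[g1[[1]]$sel, g1[[2]]$sel, g1[[3]]$sel] +
        outer(outer(g1[[1]]$w, g1[[2]]$w), g1[[3]]$w)
    }
  }
  n_frames <- length(ion_frames)
  dens <- dens / n_frames                      # mean number density per A^3
  voxel <- prod(spacing)
  mean_n_ions <- n_total / n_frames
  recovered <- sum(dens) * voxel
  if (mean_n_ions > 0 && abs(recovered - mean_n_ions) / mean_n_ions > 0.01)
    warning(sprintf(
      "grid recovers %.2f of %.2f ions (>1%% loss): enlarge the grid margin",
      recovered, mean_n_ions))
  # 1 A^-3 = 1e30 / N_A mM
  conc <- dens * 1e30 / protlink_constants[["avogadro"]]
  scalar_grid(conc, origin, spacing, unit = "mM",
              meta = list(n_frames = n_frames, mean_n_ions = mean_n_ions,
                          bandwidth = bandwidth, species = species,
                          recovered_ions = recovered))
}

#' Ion count recovered from a concentration grid
#'
#' Integrates a mM concentration grid back to a mean ion count — the
#' conservation check companion of \code{\link{kde_concentration}}.
#'
#' @param grid A \code{scalar_grid} in mM.
#' @return Mean number of ions in the grid volume.
#' @export
grid_ion_count <- function(grid) {
  stopifnot(grid$unit == "mM")
  sum(grid$values) * prod(grid$spacing) *
    protlink_constants[["avogadro"]] / 1e30
}

#' Boltzmann-relation ion concentrations from a potential grid
#'
#' \eqn{c_k(\vec r) = c_k^{bulk} \exp(-z_k F \phi(\vec r) / RT)}: the
#' mean-field concentration of an ion species in an electrostatic
#' potential, evaluated voxel-wise on a user-supplied grid (e.g. the
#' output of an external Poisson-Boltzmann solver).
#'
#' @param phi A \code{scalar_grid} of electrostatic potential in volts.
#' @param z Ion charge in protonic units (+1 Na+, -1 Cl-).
#' @param c_bulk Bulk concentration in mM.
#' @param T Temperature in K.
#' @param species Species tag.
#' @return A \code{scalar_grid} in mM with matching geometry.
#' @export
boltzmann_concentration <- function(phi, z, c_bulk, T = 300,
                                    species = "ion") {
  if (!all(is.finite(phi$values))) stop("non-finite potential values")
  stopifnot(T > 0, c_bulk >= 0)
  fac <- z * protlink_constants[["faraday"]] /
    (protlink_constants[["R_kJ"]] * 1000 * T)   # 1/V
  scalar_grid(c_bulk * exp(-fac * phi$values), phi$origin, phi$spacing,
              unit = "mM",
              meta = list(z = z, c_bulk = c_bulk, T = T, species = species))
}

#' Iso-concentration contour mask
#'
#' Logical mask of voxels at or above a concentration level; 200 mM is the
#' conventional level for whole-protein maps and 150 mM for interface
#' close-ups.
#'
#' @param grid A \code{scalar_grid} in mM.
#' @param level Concentration level in mM (> 0).
#' @return Logical array of the grid's shape.
#' @export
iso_contour_mask <- function(grid, level = 200) {
  stopifnot(level > 0)
  grid$values >= level
}

#' Rigid fit of trajectory frames onto a reference, applied to ion tracks
#'
#' For each frame, computes the least-squares rigid transform (proper
#' rotation + translation, Kabsch) of the protein selection onto the
#' reference and applies it to the frame's ion positions. Before fitting,
#' each ion is wrapped to its minimum-image position relative to the
#' protein selection's centroid (orthorhombic box), resolving the PBC
#' ambiguity of raw MD coordinates.
#'
#' @param protein_frames List of M x 3 protein-selection coordinate
#'   matrices (Å), one per frame.
#' @param ion_frames List of N x 3 ion coordinate matrices (Å), same
#'   length.
#' @param reference M x 3 reference coordinates of the same selection.
#' @param box Optional per-frame (or single) length-3 orthorhombic box
#'   vector (Å) for minimum-image wrapping; \code{NULL} disables wrapping.
#' @return List of transformed ion coordinate matrices.
#' @export
fit_frames_to_reference <- function(protein_frames, ion_frames, reference,
                                    box = NULL) {
  stopifnot(length(protein_frames) == length(ion_frames))
  ref <- as.matrix(reference)
  lapply(seq_along(protein_frames), function(i) {
    P <- as.matrix(protein_frames[[i]])
    if (nrow(P) != nrow(ref)) stop("selection mismatch in frame ", i)
    ions <- as.matrix(ion_frames[[i]])
    if (!is.null(box)) {
      b <- if (is.list(box)) box[[i]] else box
      ctr <- colMeans(P)
      d <- sweep(ions, 2, ctr)
      ions <- ions - sweep(round(sweep(d, 2, b, `/`)), 2, b, `*`)
    }
    k <- kabsch_transform(P, ref)
    sweep(ions %*% k$rotation, 2, k$translation, `+`)
  })
}

#' Average partial charges from mean protonation
#'
#' Builds the per-atom mean charge set used for mean-field electrostatics
#' on a representative structure: each titratable site's atoms get
#' \eqn{q = p\, q^{prot} + (1-p)\, q^{deprot}} with p the site's mean
#' occupancy; atoms outside any template keep their background charge.
#'
#' @param point A \code{titration_point} (mean occupancies per site).
#' @param charge_templates Named list (one per site) of data.frames with
#'   columns \code{atom}, \code{q_prot}, \code{q_deprot}.
#' @param background Optional named numeric vector of non-titratable atom
#'   charges.
#' @return Named numeric vector of mean per-atom charges.
#' @export
average_charge_assignment <- function(point, charge_templates,
                                      background = NULL) {
  missing_sites <- setdiff(point$sites, names(charge_templates))
  if (length(missing_sites))
    stop("missing charge template for site(s): ",
         paste(missing_sites, collapse = ", "))
  q <- if (is.null(background)) numeric(0) else background
  for (s in point$sites) {
    tpl <- charge_templates[[s]]
    p <- point$site_means[[s]]
    qi <- p * tpl$q_prot + (1 - p) * tpl$q_deprot
    names(qi) <- tpl$atom
    q <- c(q, qi)
  }
  q
}

#' Read an OpenDX scalar grid
#'
#' Parses the regular-grid OpenDX dialect written by common electrostatics
#' tools (gridpositions/gridconnections/array, three values per data
#' line, x fastest ordering per the DX convention: z varies fastest).
#'
#' @param path File path.
#' @param unit Unit tag to attach.
#' @return A \code{scalar_grid}.
#' @export
read_opendx <- function(path, unit = "") {
  lines <- readLines(path)
  gp <- grep("gridpositions counts", lines, value = TRUE)[1]
  if (is.na(gp)) stop("not an OpenDX regular grid: ", path)
  shape <- as.integer(utils::tail(strsplit(trimws(gp), "\\s+")[[1]], 3))
  org <- grep("^origin", lines, value = TRUE)[1]
  origin <- as.numeric(strsplit(trimws(org), "\\s+")[[1]][2:4])
  deltas <- grep("^delta", lines, value = TRUE)
  dmat <- t(vapply(deltas, function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]][2:4]), numeric(3)))
  spacing <- diag(dmat)
  data_start <- grep("class array", lines)[1] + 1L
  data_end <- length(lines)
  att <- grep("^(attribute|object \"|component)", lines)
  att <- att[att >= data_start]
  if (length(att)) data_end <- min(att) - 1L
  vals <- as.numeric(unlist(strsplit(trimws(lines[data_start:data_end]),
                                     "\\s+")))
  vals <- vals[!is.na(vals)]
  if (length(vals) != prod(shape))
    stop("OpenDX data length ", length(vals), " != grid size ", prod(shape))
  # DX order: last index (z) varies fastest; R arrays: first fastest
  arr <- aperm(array(vals, dim = rev(shape)), 3:1)
  scalar_grid(arr, origin, spacing, unit = unit)
}

#' Write an OpenDX scalar grid
#'
#' @param grid A \code{scalar_grid} (or logical mask array with geometry
#'   taken from \code{like}).
#' @param path Output path.
#' @param like Optional \code{scalar_grid} supplying geometry when
#'   \code{grid} is a bare array.
#' @export
write_opendx <- function(grid, path, like = NULL) {
  if (!inherits(grid, "scalar_grid")) {
    stopifnot(!is.null(like))
    grid <- scalar_grid(grid * 1.0, like$origin, like$spacing,
                        unit = like$unit)
  }
  n <- prod(grid$shape)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d",
            grid$shape[1], grid$shape[2], grid$shape[3]),
    sprintf("origin %.6g %.6g %.6g",
            grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.6g 0 0", grid$spacing[1]),
    sprintf("delta 0 %.6g 0", grid$spacing[2]),
    sprintf("delta 0 0 %.6g", grid$spacing[3]),
    sprintf("object 2 class gridconnections counts %d %d %d",
            grid$shape[1], grid$shape[2], grid$shape[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            n)), con)
  v <- as.numeric(aperm(grid$values, 3:1))   # z fastest, DX convention
  pad <- c(v, rep(NA_real_, (3 - length(v) %% 3) %% 3))
  m <- matrix(pad, ncol = 3, byrow = TRUE)
  rows <- apply(m, 1, function(r)
    paste(formatC(r[!is.na(r)], format = "e", digits = 8), collapse = " "))
  writeLines(rows, con)
  writeLines(c("attribute \"dep\" string \"positions\"",
               "object \"density\" class field",
               "component \"positions\" value 1",
               "component \"connections\" value 2",
               "component \"data\" value 3"), con)
  invisible(path)
}
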