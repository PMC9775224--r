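## Proton-occupancy trajectories: data model, readers/writers, frame masks.
##
## The on-disk dialect is deliberately minimal so that any CpHMD engine's
## per-step protonation log can be converted with a one-liner: UTF-8,
## tab-separated, '#' comments, header `time_ps<TAB><site1><TAB>...`,
## one row per frame, occupancies strictly in {0,1} (1 = proton bound).

#' Site definition table
#'
#' Builds the titratable-site metadata used by charge curves and free-energy
#' decompositions. A site's charge in protonic units is \code{occupancy - 1}
#' for acids (Asp, Glu, C-terminus, ...) and \code{occupancy} for bases
#' (His, N-terminus, ...).
#'
#' @param label Character vector of unique site labels, conventionally
#'   \code{"<chain>:<RESNAME><resnum>"}, e.g. \code{"A:ASP137"}, plus the
#'   \code{"A:NTER"} / \code{"A:CTER"} terminus forms.
#' @param residue_kind Character vector, each \code{"acid"} or \code{"base"}.
#' @return A \code{data.frame} of class \code{site_definitions} with columns
#'   \code{label}, \code{chain}, \code{residue_kind}.
#' @export
site_definitions <- function(label, residue_kind) {
  label <- as.character(label)
  residue_kind <- as.character(residue_kind)
  if (length(label) != length(residue_kind))
    stop("label and residue_kind must have equal length")
  if (anyDuplicated(label))
    stop("site labels must be unique: ",
         paste(unique(label[duplicated(label)]), collapse = ", "))
  if (!all(residue_kind %in% c("acid", "base")))
    stop("residue_kind must be 'acid' or 'base'")
  chain <- ifelse(grepl(":", label, fixed = TRUE),
                  sub(":.*$", "", label), NA_character_)
  out <- data.frame(label = label, chain = chain,
                    residue_kind = residue_kind,
                    stringsAsFactors = FALSE)
  class(out) <- c("site_definitions", "data.frame")
  out
}

#' Read a site-definition sidecar file
#'
#' Tab-separated, two columns \code{label} and \code{residue_kind}
#' (\code{acid}/\code{base}), '#' comments allowed.
#'
#' @param path File path.
#' @return A \code{site_definitions} data frame.
#' @export
read_site_definitions <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("label", "residue_kind") %in% names(tab)))
    stop("site-definition file must have columns 'label' and 'residue_kind'")
  site_definitions(tab$label, tab$residue_kind)
}

#' Write a site-definition sidecar file
#'
#' @param sites A \code{site_definitions} data frame.
#' @param path File path.
#' @export
write_site_definitions <- function(sites, path) {
  utils::write.table(sites[, c("label", "residue_kind")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a proton-occupancy trajectory
#'
#' The central container of the package: a binary occupancy matrix
#' (frames x sites) with frame times, pH/replicate/form metadata and a
#' logical frame mask. Frames are masked, never deleted, so the time axis
#' stays intact for autocorrelation analysis.
#'
#' @param occupancies Numeric or integer matrix, frames in rows, sites in
#'   columns, entries in \{0, 1\} (1 = proton bound). Column names are the
#'   site labels.
#' @param times Frame times in ps, strictly increasing, length =
#'   \code{nrow(occupancies)}.
#' @param pH pH at which the trajectory was run.
#' @param replicate_id Replicate identifier (text).
#' @param form \code{"monomer"} or \code{"dimer"}.
#' @param sites Optional site labels (default: column names).
#' @param frame_mask Optional logical vector; \code{TRUE} = frame retained.
#' @return An object of class \code{occupancy_trajectory}.
#' @export
occupancy_trajectory <- function(occupancies, times, pH,
                                 replicate_id = "rep1",
                                 form = c("monomer", "dimer"),
                                 sites = colnames(occupancies),
                                 frame_mask = NULL) {
  form <- match.arg(form)
  occupancies <- as.matrix(occupancies)
  storage.mode(occupancies) <- "integer"
  if (is.null(sites)) sites <- paste0("site", seq_len(ncol(occupancies)))
  sites <- as.character(sites)
  if (length(sites) != ncol(occupancies))
    stop("number of site labels does not match occupancy columns")
  if (anyDuplicated(sites)) stop("site labels must be unique")
  if (length(times) != nrow(occupancies))
    stop("length(times) does not match number of frames")
  if (nrow(occupancies) > 0L) {
    bad <- which(!(occupancies %in% c(0L, 1L)))
    if (length(bad))
      stop("non-binary occupancy entry at matrix position ", bad[1])
    if (any(diff(times) <= 0))
      stop("frame times must be strictly increasing")
  }
  if (!is.finite(pH)) stop("pH must be finite")
  if (is.null(frame_mask)) frame_mask <- rep(TRUE, nrow(occupancies))
  if (length(frame_mask) != nrow(occupancies))
    stop("frame_mask length does not match number of frames")
  colnames(occupancies) <- sites
  structure(list(
    sites = sites,
    times = as.numeric(times),
    occupancies = occupancies,
    pH = as.numeric(pH),
    replicate_id = as.character(replicate_id),
    form = form,
    frame_mask = as.logical(frame_mask)
  ), class = "occupancy_trajectory")
}

#' @export
print.occupancy_trajectory <- function(x, ...) {
  cat(sprintf(
    "occupancy_trajectory: %d frames x %d sites | form=%s pH=%.2f rep=%s | %d retained\n",
    nrow(x$occupancies), length(x$sites), x$form, x$pH, x$replicate_id,
    sum(x$frame_mask)))
  invisible(x)
}

#' Number of retained frames
#' @param traj An \code{occupancy_trajectory}.
#' @return Integer count of frames with \code{frame_mask == TRUE}.
#' @export
n_retained <- function(traj) sum(traj$frame_mask)

#' Retained occupancy rows of a trajectory
#' @param traj An \code{occupancy_trajectory}.
#' @return The occupancy matrix restricted to retained frames.
#' @export
retained_occupancies <- function(traj)
  traj$occupancies[traj$frame_mask, , drop = FALSE]

#' Read an occupancy table
#'
#' Parses the tab-separated occupancy dialect (see package vignette):
#' header \code{time_ps<TAB><site1><TAB>...}, one row per frame, entries in
#' \{0,1\}. Validation failures report the offending line number.
#'
#' @param path File path.
#' @param pH pH metadata for the trajectory.
#' @param replicate_id Replicate identifier.
#' @param form \code{"monomer"} or \code{"dimer"}.
#' @return An \code{occupancy_trajectory} with an all-true frame mask.
#' @export
read_occupancy_table <- function(path, pH, replicate_id = "rep1",
                                 form = c("monomer", "dimer")) {
  form <- match.arg(form)
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("empty occupancy table: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (header[1] != "time_ps")
    stop(sprintf("malformed header at line %d: first column must be 'time_ps'",
                 lineno[1]))
  sites <- header[-1]
  n_frames <- length(lines) - 1L
  times <- numeric(n_frames)
  occ <- matrix(0L, n_frames, length(sites))
  for (i in seq_len(n_frames)) {
    fields <- strsplit(lines[i + 1L], "\t", fixed = TRUE)[[1]]
    if (length(fields) != length(header))
      stop(sprintf("line %d: expected %d fields, found %d",
                   lineno[i + 1L], length(header), length(fields)))
    times[i] <- as.numeric(fields[1])
    vals <- fields[-1]
    if (!all(vals %in% c("0", "1")))
      stop(sprintf("line %d: non-binary occupancy entry '%s'",
                   lineno[i + 1L], vals[which(!(vals %in% c("0", "1")))[1]]))
    occ[i, ] <- as.integer(vals)
  }
  if (anyNA(times))
    stop(sprintf("line %d: unreadable time value",
                 lineno[1L + which(is.na(times))[1]]))
  if (n_frames > 1L && any(diff(times) <= 0))
    stop(sprintf("line %d: frame times not strictly increasing",
                 lineno[1L + which(diff(times) <= 0)[1] + 1L]))
  occupancy_trajectory(occ, times, pH = pH, replicate_id = replicate_id,
                       form = form, sites = sites)
}

#' Write an occupancy table
#'
#' Writes the trajectory in the tab-separated occupancy dialect. All frames
#' are written regardless of the frame mask (masks are analysis state, not
#' data); round trips through \code{\link{read_occupancy_table}} preserve
#' occupancies bit-exactly and times to full printed precision.
#'
#' @param traj An \code{occupancy_trajectory}.
#' @param path Output file path.
#' @export
write_occupancy_table <- function(traj, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("time_ps", traj$sites), collapse = "\t"), con)
  if (nrow(traj$occupancies) > 0L) {
    body <- paste(format(traj$times, digits = 15, trim = TRUE, scientific = FALSE),
                  apply(traj$occupancies, 1, paste, collapse = "\t"),
                  sep = "\t")
    writeLines(body, con)
  }
  invisible(path)
}

#' Mask equilibration frames
#'
#' Marks all frames earlier than \code{t_start} as not retained, the standard
#' way to restrict statistics to the equilibrated tail of a simulation
#' (e.g. the last 70 ns of a 100 ns run via \code{t_start = 30000}).
#' Frames are masked, not removed.
#'
#' @param traj An \code{occupancy_trajectory}.
#' @param t_start Time in ps; frames with \code{time < t_start} are masked.
#' @return The trajectory with an updated frame mask.
#' @export
discard_equilibration <- function(traj, t_start) {
  stopifnot(t_start >= 0)
  keep <- traj$times >= t_start
  if (!any(keep))
    warning("t_start beyond the final frame time: all frames masked")
  traj$frame_mask <- traj$frame_mask & keep
  traj
}

#' Combine a frame mask into a trajectory
#'
#' The new mask is AND-ed with the existing one, so masking is idempotent
#' and commutative. Typically used with \code{\link{dissociation_mask}}.
#'
#' @param traj An \code{occupancy_trajectory}.
#' @param mask Logical vector of length \code{n_frames}; \code{TRUE} = keep.
#' @return The trajectory with the combined mask.
#' @export
apply_frame_mask <- function(traj, mask) {
  if (length(mask) != nrow(traj$occupancies))
    stop("mask length does not match number of frames")
  traj$frame_mask <- traj$frame_mask & as.logical(mask)
  traj
}

#' Bundle trajectories into a system set
#'
#' Groups occupancy trajectories spanning form x pH x replicate, checking
#' that every (form, pH) cell has at least one replicate and that site lists
#' are consistent within each form.
#'
#' @param trajectories List of \code{occupancy_trajectory} objects.
#' @param temperature Simulation temperature in K (default 300).
#' @return An object of class \code{system_set} with elements
#'   \code{trajectories}, \code{pH_values} (sorted), \code{forms},
#'   \code{temperature}.
#' @export
system_set <- function(trajectories, temperature = 300) {
  stopifnot(length(trajectories) >= 1)
  ok <- vapply(trajectories, inherits, logical(1), "occupancy_trajectory")
  if (!all(ok)) stop("all elements must be occupancy_trajectory objects")
  forms <- unique(vapply(trajectories, `[[`, character(1), "form"))
  for (f in forms) {
    sl <- lapply(Filter(function(t) t$form == f, trajectories), `[[`, "sites")
    if (length(unique(lapply(sl, paste, collapse = "|"))) != 1)
      stop("inconsistent site lists among '", f, "' trajectories")
  }
  pHs <- sort(unique(vapply(trajectories, `[[`, numeric(1), "pH")))
  structure(list(trajectories = trajectories, pH_values = pHs,
                 forms = forms, temperature = temperature),
            class = "system_set")
}

#' Select trajectories from a system set
#'
#' @param systems A \code{system_set}.
#' @param form \code{"monomer"} or \code{"dimer"}.
#' @param pH pH value (matched with tolerance 1e-9).
#' @return List of matching \code{occupancy_trajectory} objects.
#' @export
get_replicates <- function(systems, form, pH) {
  Filter(function(t) t$form == form && abs(t$pH - pH) < 1e-9,
         systems$trajectories)
}
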