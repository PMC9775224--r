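## Stage orchestration: config handling and the run_* entry points used by
## the command-line wrapper (inst/cli/protlink.R) and by scripted analyses.
## Every stage is pure given (inputs, config, seed) and writes a manifest
## next to its outputs.

#' Default analysis configuration
#'
#' All thresholds default to the field's standard values: dissociation at
#' 3.3 nm COM distance / 1.2 nm RMSD, ACF threshold 0.1, correlation
#' cutoff 0.15, ion grid mesh 1 Angstrom with 2 Angstrom kernel bandwidth,
#' 0.14 nm SASA probe, reference pH = lowest sampled pH, kJ/mol units.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    temperature = 300,
    pH_ref = NULL,               # NULL -> lowest sampled pH
    units = "kJ",
    d_max_nm = 3.3,
    rmsd_max_nm = 1.2,
    acf_threshold = 0.1,
    correlation_cutoff = 0.15,
    grid_mesh_A = 1.0,
    kde_bandwidth_A = 2.0,
    sasa_probe_nm = 0.14,
    contact_area_convention = "half",
    bootstrap_B = 100,
    bootstrap_block_ps = 1000,
    seed = 1,
    equilibration_ps = 0,
    grid_step_pH = 0.01,
    occupancy_tables = list(),   # entries: list(path, form, pH, replicate)
    experimental_points = NULL
  )
}

#' Read and validate an analysis configuration (YAML)
#'
#' Unknown keys are rejected (typo safety); missing keys take defaults;
#' referenced occupancy tables must exist.
#'
#' @param path YAML file path.
#' @return Validated configuration list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- default_config()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  out <- defaults
  for (k in names(cfg)) out[[k]] <- cfg[[k]]   # no recursive merge
  base <- dirname(normalizePath(path))
  for (i in seq_along(out$occupancy_tables)) {
    e <- out$occupancy_tables[[i]]
    if (is.null(e$path) || is.null(e$form) || is.null(e$pH))
      stop("occupancy_tables entry ", i, " needs path, form and pH")
    p <- e$path
    if (!file.exists(p)) p <- file.path(base, e$path)
    if (!file.exists(p))
      stop("occupancy table not found: ", e$path)
    out$occupancy_tables[[i]]$path <- p
  }
  out
}

## Load all occupancy tables of a config into a system_set.
load_system_set <- function(config) {
  trajs <- lapply(config$occupancy_tables, function(e) {
    tr <- read_occupancy_table(e$path, pH = e$pH,
                               replicate_id = if (is.null(e$replicate))
                                 "rep1" else as.character(e$replicate),
                               form = e$form)
    if (config$equilibration_ps > 0)
      tr <- discard_equilibration(tr, config$equilibration_ps)
    tr
  })
  system_set(trajs, temperature = config$temperature)
}

## Write a small machine-readable run manifest next to stage outputs.
write_manifest <- function(out_dir, stage, config, extra = list()) {
  m <- c(list(stage = stage,
              package_version = as.character(utils::packageVersion("protlink")),
              seed = config$seed, temperature = config$temperature),
         extra)
  yaml::write_yaml(m, file.path(out_dir, paste0(stage, "_manifest.yaml")))
}

#' Titration stage
#'
#' Computes per-form titration tables (pH, mean protonation, variance,
#' fluctuation slope), per-site Hill fits with bootstrap errors, the
#' protein charge curve and, when the charge changes sign, the isoionic
#' point.
#'
#' @param config Configuration list (see \code{\link{default_config}}).
#' @param systems Optional pre-built \code{system_set} (otherwise loaded
#'   from the config paths).
#' @param sites Optional \code{site_definitions} for the charge curve.
#' @param out_dir Optional output directory for TSV files + manifest.
#' @return List with per-form \code{curves}, \code{tables},
#'   \code{hill_fits}, and (when sites given) \code{charge},
#'   \code{isoionic}.
#' @export
run_titrate <- function(config = default_config(), systems = NULL,
                        sites = NULL, out_dir = NULL) {
  if (is.null(systems)) systems <- load_system_set(config)
  if (length(unique(vapply(systems$trajectories, `[[`, numeric(1), "pH"))) < 2)
    message("note: a single pH value supports titration statistics only, ",
            "not free-energy integration")
  res <- list()
  for (f in systems$forms) {
    curve <- titration_curve(systems, f)
    hill <- fit_hill_sites(curve)
    res$curves[[f]] <- curve
    res$tables[[f]] <- titration_table(curve)
    res$hill_fits[[f]] <- hill
    if (!is.null(sites) && f == "monomer") {
      cc <- protein_charge_curve(curve, sites)
      res$charge <- cc
      res$isoionic <- tryCatch(isoionic_point(cc), error = function(e) NA)
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (f in names(res$tables)) {
      utils::write.table(res$tables[[f]],
                         file.path(out_dir, paste0("titration_", f, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      hf <- res$hill_fits[[f]]
      utils::write.table(
        data.frame(site = names(hf),
                   pKa = vapply(hf, `[[`, numeric(1), "pKa"),
                   h = vapply(hf, `[[`, numeric(1), "h"),
                   rss = vapply(hf, `[[`, numeric(1), "rss"),
                   converged = vapply(hf, `[[`, logical(1), "converged")),
        file.path(out_dir, paste0("hill_", f, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_manifest(out_dir, "titrate", config)
  }
  res
}

#' Free-energy stage
#'
#' Spline-linkage profile, per-site decomposition, the Hill-integral
#' alternative (when all fits converge), the bootstrap envelope, and
#' optional experimental anchoring; logs the maximum spline-vs-Hill
#' discrepancy.
#'
#' @inheritParams run_titrate
#' @param envelope Compute the bootstrap envelope (default TRUE).
#' @return List with \code{profile}, \code{decomposition},
#'   \code{hill_profile} (or NULL), \code{envelope} (or NULL),
#'   \code{anchored} (or NULL), \code{spline_vs_hill_max}.
#' @export
run_energy <- function(config = default_config(), systems = NULL,
                       out_dir = NULL, envelope = TRUE) {
  if (is.null(systems)) systems <- load_system_set(config)
  if (length(systems$pH_values) < 2)
    stop("free-energy integration requires >= 2 pH values")
  if (!all(c("monomer", "dimer") %in% systems$forms))
    stop("both monomer and dimer trajectories are required")
  cm <- titration_curve(systems, "monomer")
  cd <- titration_curve(systems, "dimer")
  pH_ref <- if (is.null(config$pH_ref)) min(cm$pH) else config$pH_ref
  units <- config$units
  prof <- ddG_profile(cm, cd, pH_ref = pH_ref, T = config$temperature,
                      grid_step = config$grid_step_pH, units = units)
  dec <- ddG_site_decomposition(cm, cd, pH_ref = pH_ref,
                                T = config$temperature,
                                grid_step = config$grid_step_pH,
                                units = units)
  hm <- fit_hill_sites(cm); hd <- fit_hill_sites(cd)
  hill_prof <- NULL; disc <- NA_real_
  if (all(vapply(c(hm, hd), `[[`, logical(1), "converged"))) {
    hill_prof <- ddG_profile_hill(hm, hd, range(cm$pH), pH_ref = pH_ref,
                                  T = config$temperature,
                                  grid_step = config$grid_step_pH,
                                  units = units)
    disc <- max(abs(hill_prof$ddG - prof$ddG))
    message(sprintf("spline vs Hill route: max |difference| = %.3f %s/mol",
                    disc, units))
  }
  env <- NULL
  if (envelope) {
    env <- profile_bootstrap_envelope(systems, pH_ref = pH_ref,
                                      T = config$temperature,
                                      B = config$bootstrap_B,
                                      seed = config$seed,
                                      grid_step = config$grid_step_pH,
                                      block_ps = config$bootstrap_block_ps,
                                      units = units)
  }
  anchored <- NULL
  if (!is.null(config$experimental_points)) {
    exp_pts <- read_experimental_points(config$experimental_points)
    anchored <- anchor_to_experiment(prof, exp_pts)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(env)) write_profile_tsv(env, file.path(out_dir, "ddG.tsv"))
    else write_profile_tsv(prof, file.path(out_dir, "ddG.tsv"))
    utils::write.table(
      data.frame(pH = dec$pH_grid, dec$per_site, check.names = FALSE),
      file.path(out_dir, "ddG_per_site.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    write_manifest(out_dir, "energy", config,
                   list(pH_ref = pH_ref, units = units,
                        spline_vs_hill_max = disc))
  }
  list(profile = prof, decomposition = dec, hill_profile = hill_prof,
       envelope = env, anchored = anchored, spline_vs_hill_max = disc)
}

#' Correlation stage
#'
#' Pearson matrices and edge lists per (form, pH); for dimers the edge
#' list is split into intrachain and interchain contacts; plus the
#' site-level summary (max |rho|, correlation time, protonation shift).
#'
#' @inheritParams run_titrate
#' @return List with \code{matrices} (named by form/pH), \code{networks},
#'   and \code{summary} (when both forms are present).
#' @export
run_correlate <- function(config = default_config(), systems = NULL,
                          out_dir = NULL) {
  if (is.null(systems)) systems <- load_system_set(config)
  matrices <- list(); networks <- list()
  for (f in systems$forms) for (p in systems$pH_values) {
    reps <- get_replicates(systems, f, p)
    if (!length(reps)) next
    key <- sprintf("%s_pH%g", f, p)
    m <- pearson_matrix(reps)
    net <- correlation_network(m, config$correlation_cutoff)
    if (f == "dimer" && nrow(net)) {
      chain <- function(x) sub(":.*$", "", x)
      net$interchain <- chain(net$site_i) != chain(net$site_j)
    }
    matrices[[key]] <- m
    networks[[key]] <- net
  }
  summ <- NULL
  if (all(c("monomer", "dimer") %in% systems$forms))
    summ <- site_summary_scatter(systems, config$acf_threshold)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (key in names(networks))
      utils::write.table(networks[[key]],
                         file.path(out_dir, paste0("edges_", key, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(summ))
      utils::write.table(summ, file.path(out_dir, "site_summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    write_manifest(out_dir, "correlate", config)
  }
  list(matrices = matrices, networks = networks, summary = summ)
}

#' Conformation stage for a dimer ensemble
#'
#' COM-distance and contact-area series with 1/N-normalized kernel
#' histograms, the dissociation mask at the configured thresholds, the
#' central structure, and a decoupled PCA of chain B after fitting
#' chain A (both chain-role assignments pooled) with its free-energy
#' landscape.
#'
#' @param config Configuration list.
#' @param ensemble A dimer \code{conformation_ensemble}.
#' @param reference Reference coordinates (default: frame 1).
#' @param radii Per-atom radii in nm for SASA (default 0.17).
#' @param out_dir Optional output directory.
#' @return List with \code{mask}, \code{com_nm}, \code{contact_nm2},
#'   \code{com_hist}, \code{contact_hist}, \code{central_index},
#'   \code{pca}, \code{landscape}.
#' @export
run_conform <- function(config = default_config(), ensemble,
                        reference = NULL, radii = 0.17, out_dir = NULL) {
  if (is.null(reference)) reference <- get_frame(ensemble, 1)
  selA <- select_atoms(ensemble, chain = "A")
  selB <- select_atoms(ensemble, chain = "B")
  mask <- dissociation_mask(ensemble, reference, selA, selB,
                            d_max = config$d_max_nm,
                            rmsd_max = config$rmsd_max_nm)
  keep <- which(mask)
  com <- vapply(keep, function(i)
    com_distance(get_frame(ensemble, i), selA, selB), numeric(1))
  radii <- rep_len(radii, dim(ensemble$coords)[2])
  ca <- vapply(keep, function(i)
    as.numeric(contact_area(get_frame(ensemble, i), selA, selB, radii,
                            probe = config$sasa_probe_nm,
                            convention = config$contact_area_convention,
                            n_sphere_points = 192)), numeric(1))
  kept <- conformation_ensemble(ensemble$atoms,
                                ensemble$coords[keep, , , drop = FALSE])
  cidx <- central_structure(kept, select_atoms(kept, backbone = TRUE))
  fitA <- select_atoms(kept, chain = "A", backbone = TRUE)
  trB <- select_atoms(kept, chain = "B", backbone = TRUE)
  pca <- pca_decoupled(kept, fitA, trB, reference)
  land <- if (nrow(pca$projections) >= 2 &&
              all(apply(pca$projections[, 1:2, drop = FALSE], 2,
                        stats::sd) > 0)) {
    landscape(pca$projections, mesh = 0.2, T = config$temperature)
  } else NULL
  out <- list(mask = mask, com_nm = com, contact_nm2 = ca,
              com_hist = if (length(com) > 1) kernel_histogram(com) else NULL,
              contact_hist = if (length(ca) > 1) kernel_histogram(ca) else NULL,
              central_index = keep[cidx], pca = pca, landscape = land)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(data.frame(frame = keep, com_nm = com,
                                  contact_nm2 = ca),
                       file.path(out_dir, "dimer_geometry.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_manifest(out_dir, "conform", config,
                   list(n_retained = length(keep),
                        central_frame = keep[cidx]))
  }
  out
}

#' Ion-density stage
#'
#' Kernel-density concentration grids per ion species at the configured
#' mesh and bandwidth, with optional OpenDX export and contour masks.
#'
#' @param config Configuration list.
#' @param ion_frames Named list (per species) of per-frame N x 3 ion
#'   coordinate matrices (Angstrom).
#' @param origin,shape Grid geometry.
#' @param contour_mM Contour level(s) for mask export (default 200).
#' @param out_dir Optional output directory (grids written as OpenDX).
#' @return Named list of \code{scalar_grid}s.
#' @export
run_ions <- function(config = default_config(), ion_frames, origin, shape,
                     contour_mM = 200, out_dir = NULL) {
  grids <- lapply(names(ion_frames), function(sp)
    kde_concentration(ion_frames[[sp]], origin = origin,
                      spacing = config$grid_mesh_A, shape = shape,
                      bandwidth = config$kde_bandwidth_A, species = sp))
  names(grids) <- names(ion_frames)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (sp in names(grids)) {
      write_opendx(grids[[sp]],
                   file.path(out_dir, paste0("conc_", sp, ".dx")))
      for (lev in contour_mM)
        write_opendx(iso_contour_mask(grids[[sp]], lev) * 1.0,
                     file.path(out_dir,
                               sprintf("contour_%s_%gmM.dx", sp, lev)),
                     like = grids[[sp]])
    }
    write_manifest(out_dir, "ions", config)
  }
  grids
}

#' Generate the shipped synthetic demonstration system
#'
#' A 4-site monomer (3 acids + 1 base, one intrachain coupling) and its
#' dimer with a repulsive interchain coupling on the interface acid —
#' qualitatively the situation where association perturbs an interface
#' carboxylate's titration. Occupancy trajectories are Metropolis-sampled
#' at pH 3..8 with 2 replicates per (form, pH).
#'
#' @param seed Integer seed.
#' @param n_steps MC steps per trajectory (default 2e5).
#' @param out_dir Optional directory; when given, occupancy tables, site
#'   definitions and a ready-to-run YAML config are written there.
#' @return List with \code{model_M}, \code{model_D}, \code{systems},
#'   \code{sites}.
#' @export
run_simulate <- function(seed = 1, n_steps = 2e5, out_dir = NULL) {
  mono <- titration_model(
    labels = c("ASP12", "GLU45", "HIS60", "ASP137"),
    pKa = c(4.0, 4.4, 6.5, 3.9),
    kind = c("acid", "acid", "base", "acid"),
    W = {
      W <- matrix(0, 4, 4)
      W[2, 3] <- W[3, 2] <- -4   # Glu-His attraction (opposite charges)
      W
    })
  Wi <- matrix(0, 4, 4)
  Wi[4, 4] <- 10                  # interface Asp137-Asp137' repulsion
  dim_model <- dimerize_model(mono, W_inter = Wi, dG_assoc = -25)
  pHs <- 3:8
  trajs <- list()
  sd0 <- seed
  for (p in pHs) for (r in 1:2) {
    sd0 <- sd0 + 1
    trajs[[length(trajs) + 1L]] <-
      sample_occupancies(mono, p, n_steps = n_steps, seed = sd0,
                         replicate_id = paste0("rep", r))
    sd0 <- sd0 + 1
    trajs[[length(trajs) + 1L]] <-
      sample_occupancies(dim_model, p, n_steps = n_steps, seed = sd0,
                         replicate_id = paste0("rep", r))
  }
  systems <- system_set(trajs)
  sites <- site_definitions(
    c(mono$labels, dim_model$labels),
    c(mono$kind, dim_model$kind))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    entries <- list()
    for (tr in trajs) {
      fn <- sprintf("occ_%s_pH%g_%s.tsv", tr$form, tr$pH, tr$replicate_id)
      write_occupancy_table(tr, file.path(out_dir, fn))
      entries[[length(entries) + 1L]] <-
        list(path = fn, form = tr$form, pH = tr$pH,
             replicate = tr$replicate_id)
    }
    write_site_definitions(sites, file.path(out_dir, "sites.tsv"))
    cfg <- default_config()
    cfg$occupancy_tables <- entries
    cfg$seed <- seed
    cfg$experimental_points <- NULL
    cfg <- cfg[!vapply(cfg, is.null, logical(1))]
    yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  }
  list(model_M = mono, model_D = dim_model, systems = systems,
       sites = sites)
}
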