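test_that("null linkage gives an identically zero profile", {
  mono <- make_mono3()
  dimer <- dimerize_model(mono)   # two non-interacting copies
  cm <- exact_titration_curve(enumerate_exact(mono, 3:8))
  cd <- exact_titration_curve(enumerate_exact(dimer, 3:8))
  prof <- ddG_profile(cm, cd, pH_ref = 3)
  expect_lt(max(abs(prof$ddG)), 1e-10)
  expect_equal(prof$ddG[1], 0)
})

test_that("spline linkage reproduces the binding-polynomial oracle", {
  for (pair in make_model_pairs()) {
    cm <- exact_titration_curve(enumerate_exact(pair$M, 3:8))
    cd <- exact_titration_curve(enumerate_exact(pair$D, 3:8))
    prof <- ddG_profile(cm, cd, pH_ref = 3)
    ex <- exact_ddG(pair$M, pair$D, prof$pH_grid, 3)
    expect_lt(max(abs(prof$ddG - ex)), 0.2)
    # the linkage derivative fixes the sign convention
    mid <- 5.5
    e <- exact_ddG(pair$M, pair$D, c(mid - 5e-5, mid + 5e-5), 3)
    slope_fd <- (e[2] - e[1]) / 1e-4
    eM <- enumerate_exact(pair$M, mid)
    eD <- enumerate_exact(pair$D, mid)
    expect_lt(abs(slope_fd - RT_ln10() * (eD$n_mean - 2 * eM$n_mean)), 1e-5)
  }
})

test_that("reference shift rigidly translates the profile", {
  pair <- make_model_pairs()[[2]]
  cm <- exact_titration_curve(enumerate_exact(pair$M, 3:8))
  cd <- exact_titration_curve(enumerate_exact(pair$D, 3:8))
  p3 <- ddG_profile(cm, cd, pH_ref = 3)
  p6 <- ddG_profile(cm, cd, pH_ref = 6)
  d <- p3$ddG - p6$ddG
  expect_lt(diff(range(d)), 1e-10)
  expect_equal(p6$ddG[which.min(abs(p6$pH_grid - 6))], 0, tolerance = 1e-12)
})

test_that("per-site decomposition is additive and localizes couplings", {
  pair <- make_model_pairs()[[3]]
  cm <- exact_titration_curve(enumerate_exact(pair$M, 3:8))
  cd <- exact_titration_curve(enumerate_exact(pair$D, 3:8))
  prof <- ddG_profile(cm, cd, pH_ref = 3)
  dec <- ddG_site_decomposition(cm, cd, pH_ref = 3)
  expect_lt(max(abs(dec$total - prof$ddG)), 1e-9)
  # a site titrating identically in both forms contributes nothing
  mono1 <- titration_model(c("ASP1", "GLU2"), c(4, 5), "acid")
  Wi <- matrix(0, 2, 2); Wi[1, 1] <- 10
  dim1 <- dimerize_model(mono1, W_inter = Wi)
  cm1 <- exact_titration_curve(enumerate_exact(mono1, 3:8))
  cd1 <- exact_titration_curve(enumerate_exact(dim1, 3:8))
  dec1 <- ddG_site_decomposition(cm1, cd1, pH_ref = 3)
  expect_lt(max(abs(dec1$per_site[, "GLU2"])), 1e-9)
  # ... and the coupled site carries essentially all of the effect
  nz <- abs(dec1$per_site[, "ASP1"])
  tot <- abs(dec1$total)
  big <- tot > 0.05
  expect_true(all(nz[big] / tot[big] >= 0.95))
})

test_that("Hill antiderivative differentiates back to the Hill curve", {
  set.seed(21)
  for (i in 1:5) {
    pKa <- runif(1, 3, 8); h <- runif(1, 0.3, 3)
    x <- runif(100, 2, 9)
    eps <- 1e-5
    num <- (hill_antiderivative(x + eps, pKa, h) -
              hill_antiderivative(x - eps, pKa, h)) / (2 * eps)
    expect_lt(max(abs(num - hill_curve(x, pKa, h))), 1e-9)
  }
  # logistic symmetry: integral over [pKa-2, pKa+2] with h=1 equals 2
  expect_equal(hill_antiderivative(7, 5, 1) - hill_antiderivative(3, 5, 1),
               2, tolerance = 1e-12)
})

test_that("Hill and spline routes agree when sites are exactly Hill", {
  pH <- 3:8
  pars_M <- list(c(4.2, 1), c(5.1, 1), c(6.3, 1))
  pars_D <- list(c(3.8, 1), c(5.1, 1), c(6.8, 1),
                 c(3.8, 1), c(5.1, 1), c(6.8, 1))
  mk_curve <- function(pars, form) {
    sites <- paste0(if (form == "dimer") rep(c("A:", "B:"),
                                             each = length(pars) / 2) else "",
                    "S", seq_along(pars))
    if (form == "dimer") sites <- paste0(rep(c("A:", "B:"),
                                             each = length(pars) / 2),
                                         "S", rep(seq_len(length(pars) / 2), 2))
    pts <- lapply(pH, function(p) {
      mu <- vapply(pars, function(q) hill_curve(p, q[1], q[2]), numeric(1))
      names(mu) <- sites
      # independent Hill sites: var_i = -dn/dpH / ln10 per the single-site identity
      v <- vapply(pars, function(q)
        log(10) * q[2] * hill_curve(p, q[1], q[2]) *
          (1 - hill_curve(p, q[1], q[2])) / log(10), numeric(1))
      names(v) <- sites
      structure(list(pH = p, form = form, sites = sites,
                     n_mean = sum(mu), n_var = sum(v), site_means = mu,
                     site_cov_total = v,
                     site_cov = diag(v), n_frames_used = Inf),
                class = "titration_point")
    })
    structure(list(form = form, pH = pH, points = pts, sites = sites),
              class = "titration_curve")
  }
  cm <- mk_curve(pars_M, "monomer")
  cd <- mk_curve(pars_D, "dimer")
  spl <- ddG_profile(cm, cd, pH_ref = 3)
  fitsM <- lapply(pars_M, function(q)
    structure(list(pKa = q[1], h = q[2], rss = 0, converged = TRUE),
              class = "hill_fit"))
  names(fitsM) <- cm$sites
  fitsD <- lapply(pars_D, function(q)
    structure(list(pKa = q[1], h = q[2], rss = 0, converged = TRUE),
              class = "hill_fit"))
  names(fitsD) <- cd$sites
  hil <- ddG_profile_hill(fitsM, fitsD, c(3, 8), pH_ref = 3)
  expect_lt(max(abs(spl$ddG - hil$ddG)), 0.1)
  # a non-converged fit is refused by name
  fitsM[[1]]$converged <- FALSE
  expect_error(ddG_profile_hill(fitsM, fitsD, c(3, 8)), names(fitsM)[1])
})

test_that("experimental anchoring recovers a known vertical offset", {
  pair <- make_model_pairs()[[2]]
  cm <- exact_titration_curve(enumerate_exact(pair$M, 3:8))
  cd <- exact_titration_curve(enumerate_exact(pair$D, 3:8))
  prof <- ddG_profile(cm, cd, pH_ref = 3)
  at <- function(p) prof$ddG[which.min(abs(prof$pH_grid - p))]
  exp_pts <- data.frame(pH = c(4, 5.5, 7),
                        dG = vapply(c(4, 5.5, 7), at, numeric(1)) + 7.3,
                        is_upper_bound = 0L)
  fit <- anchor_to_experiment(prof, exp_pts)
  expect_lt(abs(fit$offset - 7.3), 1e-9)
  # upper-bound points are excluded from the fit
  exp2 <- rbind(exp_pts,
                data.frame(pH = 6, dG = -100, is_upper_bound = 1L))
  fit2 <- anchor_to_experiment(prof, exp2)
  expect_equal(fit2$offset, fit$offset)
  expect_equal(unname(fit2$bound_residual_sign), -1)
  # a single point is matched exactly
  one <- anchor_to_experiment(prof, exp_pts[2, ])
  expect_lt(abs(one$dG[which.min(abs(one$pH_grid - 5.5))] -
                  exp_pts$dG[2]), 1e-9)
  expect_error(anchor_to_experiment(prof,
                                    data.frame(pH = 5, dG = 1,
                                               is_upper_bound = 1L)),
               "usable")
})

test_that("bootstrap envelope collapses on constant data and covers", {
  # zero-variance occupancies -> zero-width envelope
  pHs <- c(3, 5, 8)
  trajs <- list()
  for (p in pHs) {
    occ_m <- matrix(as.integer(p < 5), 50, 1, dimnames = list(NULL, "S1"))
    occ_d <- matrix(as.integer(p < 5), 50, 2,
                    dimnames = list(NULL, c("A:S1", "B:S1")))
    trajs <- c(trajs,
               list(make_traj(occ_m, pH = p),
                    make_traj(occ_d, pH = p, form = "dimer")))
  }
  env <- profile_bootstrap_envelope(system_set(trajs), B = 50, seed = 2)
  expect_lt(max(env$upper - env$lower), 1e-12)
})
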