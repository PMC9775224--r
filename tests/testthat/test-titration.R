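test_that("titration point reproduces Bernoulli identities", {
  # deterministic single-site series with mean exactly 0.25
  occ <- matrix(c(rep(1L, 5), rep(0L, 15)), 20, 1,
                dimnames = list(NULL, "s1"))
  pt <- compute_titration_point(make_traj(occ))
  p <- 0.25
  expect_equal(pt$n_mean, p)
  expect_equal(pt$n_var, p * (1 - p))
  expect_equal(unname(pt$site_cov_total), p * (1 - p))
})

test_that("fully protonated frames give n = n_sites with zero variance", {
  pt <- compute_titration_point(make_traj(matrix(1L, 10, 4)))
  expect_equal(pt$n_mean, 4)
  expect_equal(pt$n_var, 0)
  expect_equal(titration_slope_total(pt), 0)
})

test_that("additivity identities hold to machine precision", {
  set.seed(42)
  trajs <- lapply(1:3, function(r)
    make_traj(matrix(rbinom(500 * 5, 1, runif(1, 0.2, 0.8)), 500, 5),
              rep_id = paste0("r", r)))
  pt <- compute_titration_point(trajs)
  expect_equal(pt$n_mean, sum(pt$site_means))
  expect_equal(pt$n_var, sum(pt$site_cov_total), tolerance = 1e-13)
  expect_equal(titration_slope_total(pt),
               sum(titration_slope_site(pt)), tolerance = 1e-13)
  expect_error(titration_slope_site(pt, "nope"), "unknown site")
})

test_that("sampled moments match exact enumeration within 3 MC SE", {
  mono <- make_mono3()
  tr <- sample_occupancies(mono, 5, n_steps = 1e6, record_every = 10,
                           seed = 314)
  pt <- compute_titration_point(tr)
  ex <- enumerate_exact(mono, 5)
  n_eff <- nrow(retained_occupancies(tr)) / 50  # crude autocorr discount
  for (i in 1:3) {
    se <- sqrt(ex$site_means[1, i] * (1 - ex$site_means[1, i]) / n_eff)
    expect_lt(abs(pt$site_means[[i]] - ex$site_means[1, i]), 3 * se + 1e-4)
  }
  expect_lt(abs(pt$n_var - ex$n_var), 0.05)
})

test_that("fluctuation slope matches the exact curve derivative", {
  mono <- make_mono3()
  for (p in c(3.5, 5, 7)) {
    e <- enumerate_exact(mono, c(p - 5e-5, p, p + 5e-5))
    fd_tot <- (e$n_mean[3] - e$n_mean[1]) / 1e-4
    expect_lt(abs(-log(10) * e$n_var[2] - fd_tot), 1e-6)
    fd_site <- (e$site_means[3, ] - e$site_means[1, ]) / 1e-4
    expect_lt(max(abs(-log(10) * e$site_cov_total[2, ] - fd_site)), 1e-6)
  }
  # single site at its midpoint: slope = -ln(10)/4
  m1 <- titration_model("s", 5)
  e1 <- enumerate_exact(m1, 5)
  expect_equal(-log(10) * e1$n_var, -log(10) / 4, tolerance = 1e-12)
})

test_that("Hill fit recovers noiseless parameters and shifts with pH", {
  pH <- 3:8
  for (truth in list(c(4.5, 1.0), c(5.5, 0.6))) {
    y <- hill_curve(pH, truth[1], truth[2])
    f <- fit_hill(pH, y)
    expect_true(f$converged)
    expect_lt(abs(f$pKa - truth[1]), 1e-6)
    expect_lt(abs(f$h - truth[2]), 1e-6)
  }
  # pH-shift covariance: shifting the axis shifts pKa by the same amount
  y <- hill_curve(pH, 4.7, 1.3)
  f0 <- fit_hill(pH, y)
  f1 <- fit_hill(pH + 0.8, y)
  expect_equal(f1$pKa - f0$pKa, 0.8, tolerance = 1e-6)
  expect_equal(f1$h, f0$h, tolerance = 1e-6)
})

test_that("Hill fit flags degenerate and inadequate inputs", {
  expect_error(fit_hill(c(4, 5), c(0.2, 0.8)), "3 points")
  flat <- fit_hill(3:8, rep(0.5, 6))
  expect_false(flat$converged)
  # non-Hill exact curve still fits with positive residual
  mono <- make_mono3()
  e <- enumerate_exact(mono, 3:8)
  f <- fit_hill(3:8, e$site_means[, "GLU9"])
  expect_true(f$converged)
  expect_gt(f$rss, 0)
})

test_that("charge curve and isoionic point follow the charge map", {
  # all bases fully protonated -> +n; all acids deprotonated -> -n
  base_curve <- exact_titration_curve(
    enumerate_exact(titration_model(c("b1", "b2"), c(20, 20), "base"), 5))
  sd_b <- site_definitions(c("b1", "b2"), c("base", "base"))
  expect_equal(protein_charge_curve(base_curve, sd_b)$charge, 2,
               tolerance = 1e-9)
  acid_curve <- exact_titration_curve(
    enumerate_exact(titration_model(c("a1", "a2"), c(-10, -10)), 5))
  sd_a <- site_definitions(c("a1", "a2"), c("acid", "acid"))
  expect_equal(protein_charge_curve(acid_curve, sd_a)$charge, -2,
               tolerance = 1e-9)
  # acid pKa 4 + base pKa 6, independent -> pI = 5 by symmetry
  m <- titration_model(c("a", "b"), c(4, 6), c("acid", "base"))
  cc <- protein_charge_curve(exact_titration_curve(enumerate_exact(m, 3:8)),
                             site_definitions(c("a", "b"),
                                              c("acid", "base")))
  expect_equal(isoionic_point(cc, digits = NA), 5, tolerance = 1e-3)
  # all-acid system never crosses zero
  cc_a <- protein_charge_curve(
    exact_titration_curve(enumerate_exact(
      titration_model(c("a1", "a2"), c(4, 5)), 3:8)),
    site_definitions(c("a1", "a2"), c("acid", "acid")))
  expect_error(isoionic_point(cc_a), "sign")
})

test_that("isoionic point matches the exact charge root on a 4-site model", {
  m <- titration_model(c("a1", "a2", "b1", "b2"), c(3.9, 4.8, 6.1, 7.2),
                       c("acid", "acid", "base", "base"),
                       W = {
                         W <- matrix(0, 4, 4)
                         W[1, 3] <- W[3, 1] <- -4
                         W
                       })
  sd4 <- site_definitions(m$labels, m$kind)
  cc <- protein_charge_curve(exact_titration_curve(enumerate_exact(m, 3:8)),
                             sd4)
  pI <- isoionic_point(cc, digits = NA)
  charge_exact <- function(p) {
    e <- enumerate_exact(m, p)
    sum(e$site_means[1, ]) - 2
  }
  root <- uniroot(charge_exact, c(3, 8), tol = 1e-10)$root
  expect_lt(abs(pI - root), 1e-3)
})

test_that("bootstrap SE matches the analytic iid value and is stable", {
  set.seed(99)
  n <- 1e4
  trajs <- lapply(1:2, function(r)
    make_traj(matrix(rbinom(n, 1, 0.5), n, 1, dimnames = list(NULL, "s")),
              dt = 1, rep_id = paste0("r", r)))
  stat <- function(ts) compute_titration_point(ts)$n_mean
  se <- bootstrap_errors(trajs, stat, B = 200, seed = 5, block_ps = 1)
  analytic <- sqrt(0.25 / (2 * n))
  expect_lt(abs(se - analytic) / analytic, 0.15)
  se2 <- bootstrap_errors(trajs, stat, B = 800, seed = 6, block_ps = 1)
  expect_lt(abs(se2 - se) / se, 0.10)
  # constant occupancy -> exactly zero SE
  const <- make_traj(matrix(1L, 100, 1))
  expect_warning(se0 <- bootstrap_errors(list(const), stat, B = 50,
                                         seed = 1), "single replicate")
  expect_equal(as.numeric(se0), 0)
  expect_error(bootstrap_errors(trajs, stat, B = 10, seed = 1), "at least 50")
})
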