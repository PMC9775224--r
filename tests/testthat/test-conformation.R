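test_that("COM distance does the arithmetic and is rigid-invariant", {
  fr <- rbind(c(0, 0, 0), c(3, 0, 0), c(6, 0, 0))
  expect_equal(com_distance(fr, 1:2, 3), 4.5)
  expect_equal(com_distance(fr, 1:3, 1:3), 0)
  expect_error(com_distance(fr, integer(0), 3), "empty")
  # rigid motion leaves it unchanged
  R <- protlink:::rotation_about_axis(c(1, 2, 0.5), 1.1)
  fr2 <- sweep(fr %*% t(R), 2, c(4, -2, 7), `+`)
  expect_lt(abs(com_distance(fr2, 1:2, 3) - 4.5), 1e-12)
})

test_that("Kabsch RMSD vanishes for rotated copies and matches brute force", {
  set.seed(20)
  P <- matrix(rnorm(12), 4, 3)
  R <- protlink:::rotation_about_axis(c(0.3, 1, -0.2), 0.8)
  Q <- sweep(P %*% t(R), 2, c(1, 2, 3), `+`)
  expect_lt(rmsd(Q, P), 1e-10)
  expect_lt(rmsd(P, P), 1e-14)
  # brute-force rotation-grid minimum (coarse scan + local refinement)
  P2 <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 1), 4, 3, byrow = TRUE)
  Q2 <- P2 + matrix(c(0.05, -0.03, 0.02, 0, 0.04, -0.02,
                      -0.03, 0, 0.05, 0.02, -0.04, 0), 4, 3, byrow = TRUE)
  cP <- sweep(P2, 2, colMeans(P2)); cQ <- sweep(Q2, 2, colMeans(Q2))
  euler_rmsd <- function(a, b, cc) {
    Rb <- protlink:::rotation_about_axis(c(1, 0, 0), a) %*%
      protlink:::rotation_about_axis(c(0, 1, 0), b) %*%
      protlink:::rotation_about_axis(c(0, 0, 1), cc)
    sqrt(mean(rowSums((cP %*% t(Rb) - cQ)^2)))
  }
  scan <- function(ctr, half, step) {
    best <- c(Inf, 0, 0, 0)
    for (a in seq(ctr[1] - half, ctr[1] + half, step))
      for (b in seq(ctr[2] - half, ctr[2] + half, step))
        for (cc in seq(ctr[3] - half, ctr[3] + half, step)) {
          v <- euler_rmsd(a, b, cc)
          if (v < best[1]) best <- c(v, a, b, cc)
        }
    best
  }
  coarse <- scan(c(0, 0, 0), 0.3, 0.02)
  fine <- scan(coarse[2:4], 0.02, 0.001)
  expect_lt(abs(rmsd(P2, Q2) - fine[1]), 1e-4)
  expect_lte(rmsd(P2, Q2), fine[1] + 1e-12)  # Kabsch is the true optimum
})

test_that("dissociation filter excludes exactly the programmed frames", {
  ens <- generate_dimer_ensemble(
    n_frames = 6,
    translations = rbind(c(0, 0, 0), c(0.5, 0, 0), c(5, 0, 0),
                         c(0, 0, 0), c(2.5, 0, 0), c(8, 0, 0)))
  ref <- get_frame(ens, 1)
  selA <- select_atoms(ens, chain = "A")
  selB <- select_atoms(ens, chain = "B")
  mask <- dissociation_mask(ens, ref, selA, selB)
  base_com <- com_distance(ref, selA, selB)
  expected <- vapply(1:6, function(i) {
    com_distance(get_frame(ens, i), selA, selB) <= 3.3 &&
      rmsd(get_frame(ens, i), ref) <= 1.2
  }, logical(1))
  expect_identical(mask, expected)
  expect_true(mask[1])           # reference copy retained
  expect_false(mask[6])          # +8 nm shift excluded
  # idempotence through apply_frame_mask on a matching occupancy track
  occ <- make_traj(matrix(1L, 6, 1), form = "dimer")
  o1 <- apply_frame_mask(occ, mask)
  o2 <- apply_frame_mask(o1, mask)
  expect_identical(o1$frame_mask, o2$frame_mask)
})

test_that("central structure minimizes mean pairwise squared RMSD", {
  set.seed(22)
  base <- matrix(rnorm(30), 10, 3)
  frames <- lapply(1:8, function(i) base + matrix(rnorm(30, sd = 0.05),
                                                  10, 3))
  frames[[5]] <- base + matrix(rnorm(30, sd = 1), 10, 3)  # shape outlier
  atoms <- data.frame(name = "CA", resno = 1:10, chain = "A")
  ens <- conformation_ensemble(atoms, frames)
  ci <- central_structure(ens)
  expect_true(ci != 5)
  # brute-force check
  msd <- numeric(8)
  for (i in 1:8) for (j in setdiff(1:8, i))
    msd[i] <- msd[i] + rmsd(frames[[i]], frames[[j]])^2
  expect_equal(ci, which.min(msd))
  # identical frames -> first index
  same <- conformation_ensemble(atoms, lapply(1:5, function(i) base))
  expect_equal(central_structure(same), 1L)
})

test_that("SASA matches sphere closed forms", {
  one <- sasa(matrix(0, 1, 3), radii = 0.2)
  expect_lt(abs(one$total - 4 * pi * 0.34^2) / (4 * pi * 0.34^2), 0.005)
  # far-separated atoms are additive
  two_far <- sasa(rbind(c(0, 0, 0), c(5, 0, 0)), radii = c(0.2, 0.15))
  iso <- 4 * pi * (0.34^2 + 0.29^2)
  expect_lt(abs(two_far$total - iso) / iso, 0.005)
  # overlapping equal spheres: accessible area = 2*(4 pi R^2 - cap), cap
  # area of each buried cap = 2 pi R h with h = R - d/2
  R <- 0.3; d <- 0.35
  two <- sasa(rbind(c(0, 0, 0), c(d, 0, 0)), radii = R - 0.14)
  h <- R - d / 2
  analytic <- 2 * (4 * pi * R^2 - 2 * pi * R * h)
  expect_lt(abs(two$total - analytic) / analytic, 0.01)
  expect_error(sasa(matrix(0, 1, 3), 0.2, n_sphere_points = 16), "32")
})

test_that("SASA is converged in the point count", {
  set.seed(23)
  fr <- matrix(rnorm(150, sd = 0.4), 50, 3)
  a1 <- sasa(fr, 0.17, n_sphere_points = 960)$total
  a2 <- sasa(fr, 0.17, n_sphere_points = 1920)$total
  expect_lt(abs(a1 - a2) / a2, 0.005)
})

test_that("contact area matches the two-sphere buried form and symmetry", {
  R <- 0.3; d <- 0.35
  fr <- rbind(c(0, 0, 0), c(d, 0, 0))
  ca <- contact_area(fr, 1, 2, radii = R - 0.14, convention = "full")
  h <- R - d / 2
  analytic <- 2 * 2 * pi * R * h          # both buried caps
  expect_lt(abs(as.numeric(ca) - analytic) / analytic, 0.01)
  ca_sym <- contact_area(fr, 2, 1, radii = R - 0.14, convention = "full")
  expect_equal(as.numeric(ca), as.numeric(ca_sym))
  expect_equal(as.numeric(contact_area(fr, 1, 2, radii = R - 0.14)),
               as.numeric(ca) / 2)        # half convention default
  # distant partners bury nothing
  far <- rbind(c(0, 0, 0), c(3, 0, 0))
  expect_equal(as.numeric(contact_area(far, 1, 2, radii = 0.16)), 0)
  expect_error(contact_area(fr, 1:2, 2, radii = 0.16), "disjoint")
})

test_that("interface dihedral hits the textbook configurations", {
  expect_equal(interface_dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                                  c(1, -1, 0)), 180)
  expect_equal(interface_dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                                  c(1, 1, 0)), 0)
  a <- interface_dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 0.5, 0.7))
  b <- interface_dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                          c(1, 0.5, -0.7))
  expect_equal(a, -b)
  expect_error(interface_dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                                  c(3, 0, 0)), "collinear")
})

test_that("programmed dihedral sweeps are tracked within 2 degrees", {
  angles <- seq(0, 90, by = 15)
  ens <- generate_dimer_ensemble(n_frames = length(angles),
                                 angles_deg = angles, axis = c(1, 0, 0))
  selA <- select_atoms(ens, chain = "A")
  selB <- select_atoms(ens, chain = "B")
  # centroid-based dihedral across the interface: ends of A, ends of B
  d0 <- NULL
  meas <- vapply(seq_along(angles), function(i) {
    fr <- get_frame(ens, i)
    interface_dihedral(colMeans(fr[selA[1:6], ]),
                       colMeans(fr[selA, ]),
                       colMeans(fr[selB, ]),
                       colMeans(fr[selB[1:6], ]))
  }, numeric(1))
  drift <- meas - meas[1]
  expect_lt(max(abs(abs(drift) - angles)), 2)
})

test_that("decoupled PCA ignores rigid motion and finds programmed modes", {
  angles <- seq(0, 60, length.out = 30)
  ens <- generate_dimer_ensemble(n_frames = 30, angles_deg = angles,
                                 axis = c(0, 0, 1))
  ref <- get_frame(ens, 1)
  fitA <- select_atoms(ens, chain = "A", backbone = TRUE)
  trB <- select_atoms(ens, chain = "B", backbone = TRUE)
  pca <- pca_decoupled(ens, fitA, trB, ref)
  expect_gte(pca$variance_fractions[1], 0.90)
  expect_true(all(diff(pca$projections[, 1]) > 0) ||
                all(diff(pca$projections[, 1]) < 0))
  # orthonormal components; full reconstruction
  G <- crossprod(pca$components)
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-10)
  # whole-system rigid motion leaves projections unchanged
  R <- protlink:::rotation_about_axis(c(1, 1, 0), 0.7)
  moved <- lapply(seq_len(30), function(i)
    sweep(get_frame(ens, i) %*% t(R), 2, c(2, -1, 3), `+`))
  ens2 <- conformation_ensemble(ens$atoms, moved)
  p2 <- pca_project(pca, ens2)
  expect_lt(max(abs(p2 - pca$projections)), 1e-8)
  # identical frames -> zero variance everywhere
  still <- generate_dimer_ensemble(n_frames = 5)
  pca0 <- pca_decoupled(still, fitA, trB, get_frame(still, 1))
  expect_lt(max(pca0$variance_fractions), 1e-12)
  expect_error(pca_decoupled(ens, fitA, fitA, ref), "disjoint")
})

test_that("landscape zero is at the density maximum, k_BT at P_max/e", {
  set.seed(25)
  pr <- cbind(rnorm(400), rnorm(400))
  L <- landscape(pr, mesh = 0.1, T = 300)
  expect_equal(min(L$F), 0)
  expect_true(all(L$F >= 0))
  imax <- which(L$P == max(L$P), arr.ind = TRUE)[1, ]
  expect_equal(L$F[imax[1], imax[2]], 0)
  kT <- 8.314462618e-3 * 300
  target <- max(L$P) / exp(1)
  idx <- which(abs(L$P - target) / target < 0.02)
  expect_true(all(abs(L$F[idx] - kT) < 0.05 * kT + 0.02))
  # symmetric two-cluster mixture -> two equal basins
  pr2 <- rbind(cbind(rnorm(2000, -6, 0.5), rnorm(2000, 0, 0.5)),
               cbind(rnorm(2000, 6, 0.5), rnorm(2000, 0, 0.5)))
  L2 <- landscape(pr2, mesh = 0.2, T = 300)
  left <- min(L2$F[L2$x < 0, ])
  right <- min(L2$F[L2$x > 0, ])
  expect_lt(abs(left - right), 0.1 * kT)
})

test_that("multi-model PDB ensembles round-trip", {
  ens <- generate_dimer_ensemble(n_frames = 3, angles_deg = c(0, 20, 40))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble_pdb(ens, path)
  back <- read_ensemble_pdb(path)
  expect_equal(dim(back$coords), dim(ens$coords))
  expect_lt(max(abs(back$coords - ens$coords)), 1e-3)  # PDB 0.001 A grid
  expect_equal(back$atoms$chain, ens$atoms$chain)
})
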