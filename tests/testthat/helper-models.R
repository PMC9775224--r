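# Shared synthetic model constructors for the test suite.

# Coupled 3-site monomer: two acids attract/repel a base; pKa spread over
# the 3-8 window so every site titrates somewhere in range.
make_mono3 <- function() {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 6
  W[2, 3] <- W[3, 2] <- -3
  titration_model(c("ASP2", "GLU9", "HIS5"), c(4.1, 4.6, 6.4),
                  c("acid", "acid", "base"), W)
}

# Dimer of mono3 with an interface repulsion on site 1.
make_dimer3 <- function(mono = make_mono3()) {
  Wi <- matrix(0, 3, 3)
  Wi[1, 1] <- 8
  Wi[1, 2] <- Wi[2, 1] <- 2
  dimerize_model(mono, W_inter = Wi, dG_assoc = -20)
}

# Three model pairs of growing size and mixed couplings for the linkage
# equivalence checks (4-10 sites in the dimer).
make_model_pairs <- function() {
  p1 <- list(M = titration_model(c("ASP3", "HIS7"), c(4.0, 6.2),
                                 c("acid", "base"),
                                 matrix(c(0, -2, -2, 0), 2, 2)))
  Wi1 <- matrix(c(6, 0, 0, -3), 2, 2)
  p1$D <- dimerize_model(p1$M, W_inter = Wi1, dG_assoc = -15)

  p2 <- list(M = make_mono3())
  p2$D <- make_dimer3(p2$M)

  W3 <- matrix(0, 5, 5)
  W3[1, 4] <- W3[4, 1] <- 4
  W3[2, 5] <- W3[5, 2] <- -5
  W3[3, 4] <- W3[4, 3] <- 2
  p3 <- list(M = titration_model(
    c("ASP1", "GLU2", "HIS3", "ASP4", "CTER"),
    c(3.8, 4.5, 6.6, 4.2, 3.4),
    c("acid", "acid", "base", "acid", "acid"), W3))
  Wi3 <- matrix(0, 5, 5)
  Wi3[4, 4] <- 9
  Wi3[1, 2] <- Wi3[2, 1] <- -2
  p3$D <- dimerize_model(p3$M, W_inter = Wi3, dG_assoc = -30)

  list(p1, p2, p3)
}

# Small deterministic occupancy trajectory from explicit entries.
make_traj <- function(occ, dt = 20, pH = 7, form = "monomer",
                      rep_id = "rep1") {
  occ <- as.matrix(occ)
  occupancy_trajectory(occ, seq_len(nrow(occ)) * dt, pH = pH,
                       replicate_id = rep_id, form = form)
}
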