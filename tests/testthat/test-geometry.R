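test_that("Kabsch superposition recovers rigid motions exactly", {
  set.seed(1)
  P <- matrix(rnorm(30), 10)
  sp <- kabsch_superpose(P, P)
  expect_equal(sp$rmsd, 0, tolerance = 1e-12)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-9)

  # 90 degree rotation about z plus translation is exactly recoverable
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  Q <- sweep(P %*% Rz, 2, c(5, 0, 0), "+")
  sp <- kabsch_superpose(P, Q)
  expect_lt(sp$rmsd, 1e-9)
  expect_lt(max(abs(apply_superposition(P, sp) - Q)), 1e-9)
  # proper orthonormal rotation
  expect_equal(crossprod(sp$rotation), diag(3), tolerance = 1e-9)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
})

test_that("Kabsch RMSD never exceeds the unsuperposed RMSD", {
  set.seed(7)
  for (i in 1:20) {
    P <- matrix(rnorm(24), 8)
    Q <- matrix(rnorm(24), 8)
    raw <- sqrt(mean(rowSums((P - Q)^2)))
    expect_lte(kabsch_superpose(P, Q)$rmsd, raw + 1e-12)
  }
})

test_that("degenerate superposition inputs are hard errors", {
  expect_error(kabsch_superpose(matrix(rnorm(6), 2), matrix(rnorm(6), 2)),
               "3 points")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("ensemble alignment undoes rigid motion and is idempotent", {
  s <- tiny_structure(12, ss = "helix")
  ens <- rigid_motion_ensemble(s, n = 6, seed = 3)
  aligned <- align_ensemble(ens, s)
  for (f in seq_len(n_frames(aligned)))
    expect_lt(max(abs(frame_coords(aligned, f) - s$coords)), 1e-9)
  again <- align_ensemble(aligned, s)
  expect_lt(max(abs(again$xyz - aligned$xyz)), 1e-9)
  expect_equal(aligned$label, ens$label)
  expect_equal(aligned$equilibration_frame, ens$equilibration_frame)
})

test_that("alignment never increases the per-frame RMSD to the reference", {
  s <- tiny_structure(10)
  g <- gnm_build(s, 12)
  ens <- sample_gnm_ensemble(g, s, 20, scale = 0.3, seed = 5)
  set.seed(6)
  for (f in seq_len(n_frames(ens)))
    ens <- set_frame_coords(ens, f,
      sweep(frame_coords(ens, f) %*% euler_rotation(runif(3, 0, 2)),
            2, runif(3, -5, 5), "+"))
  pre <- rmsd_series(ens, s, superpose = FALSE)
  post <- rmsd_series(align_ensemble(ens, s), s, superpose = FALSE)
  expect_true(all(post <= pre + 1e-12))
})

test_that("rmsd_series matches closed forms", {
  s <- tiny_structure(10, ss = "helix")
  xyz <- rbind(as.vector(t(s$coords)),
               as.vector(t(sweep(s$coords, 2, c(3, -2, 7), "+"))))
  ens <- trajectory_ensemble("t", s, xyz)
  expect_equal(rmsd_series(ens, s), c(0, 0), tolerance = 1e-9)

  # one CA of 10 displaced by 1 A -> RMSD = 1/sqrt(10) without refit
  coords <- s$coords
  ca_row <- which(s$layout$atom == "CA")[4]
  coords[ca_row, 1] <- coords[ca_row, 1] + 1
  ens1 <- trajectory_ensemble("t", s, matrix(as.vector(t(coords)), 1))
  expect_equal(rmsd_series(ens1, s, superpose = FALSE), 1 / sqrt(10),
               tolerance = 1e-12)
})

test_that("average structure honors symmetry and identical frames", {
  s <- tiny_structure(8, ss = "helix")
  xyz <- matrix(rep(as.vector(t(s$coords)), 4), nrow = 4, byrow = TRUE)
  ens <- trajectory_ensemble("t", s, xyz)
  avg <- average_structure(ens, s)
  expect_lt(max(abs(avg$coords - s$coords)), 1e-9)

  # two frames symmetric about the reference average back to the reference
  d <- matrix(rnorm(3 * nrow(s$layout), sd = 0.01), ncol = 3)
  up <- s$coords + d; dn <- s$coords - d
  ens2 <- trajectory_ensemble("t", s,
                              rbind(as.vector(t(up)), as.vector(t(dn))))
  avg2 <- average_structure(ens2, s)
  expect_lt(kabsch_superpose(ca_coords(avg2), ca_coords(s))$rmsd, 1e-3)
})

test_that("iterative average recovers the generating center of a sample", {
  s <- tiny_structure(20, ss = "helix")
  g <- gnm_build(s, 10)
  ens <- sample_gnm_ensemble(g, s, 2000, scale = 0.25, seed = 8)
  avg <- average_structure(ens, s, iterate = TRUE)
  expect_lt(kabsch_superpose(ca_coords(avg), ca_coords(s))$rmsd, 0.1)
})

test_that("equilibration detection follows the RMSD trend", {
  expect_equal(as.integer(detect_equilibration(rep(1.5, 50), 10)), 1L)
  expect_error(detect_equilibration(rep(1, 50), 1), "window")
  expect_error(detect_equilibration(rep(1, 10), 8), "too short")

  # saturating exponential: compare against a direct lm-based scan
  tau <- 20; n <- 600; window <- 100
  series <- 2 * (1 - exp(-(seq_len(n) - 1) / tau))
  idx <- detect_equilibration(series, window, slope_tol = 1e-3,
                              sd_tol = 0.05)
  oracle <- NA
  for (i in seq_len(n - window + 1)) {
    y <- series[i:(i + window - 1)]
    fit <- stats::lm(y ~ seq_along(y))
    if (abs(coef(fit)[2]) <= 1e-3 && sd(y) <= 0.05) { oracle <- i; break }
  }
  expect_equal(as.integer(idx), oracle)
  # for these parameters the analytic first-passage index sits near 2.8*tau
  expect_gte(idx, 2.5 * tau)
  expect_lte(idx, 6 * tau)

  # monotone ramp never equilibrates: last index plus a warning
  ramp <- seq(0, 10, length.out = 100)
  expect_warning(idx2 <- detect_equilibration(ramp, 20), "last frame")
  expect_equal(as.integer(idx2), 100L)
  expect_false(attr(idx2, "converged"))
})

test_that("RMSF matches closed forms and is rigid-motion invariant", {
  s <- tiny_structure(10, ss = "helix")
  xyz <- matrix(rep(as.vector(t(s$coords)), 5), nrow = 5, byrow = TRUE)
  static <- trajectory_ensemble("t", s, xyz)
  expect_equal(unname(rmsf(static)), rep(0, 10))

  # sinusoidal oscillation of one residue: RMSF = a / sqrt(2)
  a <- 1.7; F <- 1000
  phase <- 2 * pi * (seq_len(F) - 1) / F
  xyz <- matrix(rep(as.vector(t(s$coords)), F), nrow = F, byrow = TRUE)
  ca_row <- which(s$layout$atom == "CA")[5]
  xyz[, 3 * ca_row - 2] <- xyz[, 3 * ca_row - 2] + a * sin(phase)
  osc <- trajectory_ensemble("t", s, xyz)
  prof <- rmsf(osc)
  expect_equal(unname(prof[5]), a / sqrt(2), tolerance = 0.01)
  expect_lt(max(prof[-5]), 1e-9)

  # applying one global rigid motion to all frames, then aligning,
  # leaves the RMSF unchanged
  g <- gnm_build(s, 10)
  ens <- sample_gnm_ensemble(g, s, 200, scale = 0.2, seed = 9)
  base_prof <- rmsf(align_ensemble(ens, s))
  rot <- euler_rotation(c(0.4, 1.1, -0.7))
  moved <- ens
  for (f in seq_len(n_frames(moved)))
    moved <- set_frame_coords(moved, f,
      sweep(frame_coords(moved, f) %*% rot, 2, c(4, -2, 9), "+"))
  expect_equal(rmsf(align_ensemble(moved, s)), base_prof,
               tolerance = 1e-9)
})

test_that("mean squared RMSF equals mean squared deviation from the mean", {
  s <- tiny_structure(15)
  g <- gnm_build(s, 12)
  ens <- align_ensemble(sample_gnm_ensemble(g, s, 50, scale = 0.3,
                                            seed = 10), s)
  prof <- rmsf(ens)
  mean_struct <- s
  rows <- seq_len(nrow(s$layout))
  mean_struct$coords <- matrix(colMeans(ens$xyz), ncol = 3, byrow = TRUE)
  dev <- rmsd_series(ens, mean_struct, superpose = FALSE)
  expect_equal(mean(prof^2), mean(dev^2), tolerance = 1e-9)
})

test_that("torsions match the builder's inputs and the bio3d oracle", {
  s <- tiny_structure(20, ss = "helix")
  phi <- torsion_series(s, "phi")
  psi <- torsion_series(s, "psi")
  expect_true(all(abs(phi$values - (-57)) < 0.1))
  expect_true(all(abs(psi$values - (-47)) < 0.1))
  expect_equal(ncol(phi$values), 19)  # undefined at the first residue
  expect_equal(ncol(psi$values), 19)  # undefined at the last residue

  # pseudo-dihedrals of the ideal helix: constant, equal to bio3d's value
  pd <- torsion_series(s, "pseudo_dihedral")
  expect_equal(ncol(pd$values), 17)
  expect_lt(diff(range(pd$values)), 1e-6)
  ca_rows_idx <- which(s$layout$atom == "CA")[1:4]
  oracle <- bio3d::torsion.xyz(as.vector(t(s$coords[ca_rows_idx, ])))
  expect_equal(pd$values[1, 1], unname(oracle), tolerance = 1e-6)

  # four coplanar CA atoms in cis arrangement: pseudo-dihedral 0
  coords <- matrix(0, nrow = 12, ncol = 3)
  zig <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  layout <- data.frame(residue_id = rep(1:4, each = 3),
                       atom = rep(c("N", "CA", "C"), 4))
  coords[which(layout$atom == "CA"), ] <- zig
  coords[which(layout$atom == "N"), ] <- zig + 10
  coords[which(layout$atom == "C"), ] <- zig - 10
  flat <- backbone_structure(1:4, rep("ALA", 4), "A", coords, layout)
  pd0 <- torsion_series(flat, "pseudo_dihedral")
  expect_equal(abs(pd0$values[1, 1]), 0, tolerance = 1e-9)
})

test_that("torsions are invariant to global rigid motion", {
  s <- tiny_structure(10, seed = 2)
  rot <- euler_rotation(c(1.2, 0.5, 2.2))
  moved <- s
  moved$coords <- sweep(s$coords %*% rot, 2, c(-3, 8, 1), "+")
  for (kind in c("phi", "psi", "pseudo_dihedral")) {
    expect_equal(torsion_series(moved, kind)$values,
                 torsion_series(s, kind)$values, tolerance = 1e-9)
  }
})

test_that("missing backbone atoms for a torsion kind are reported", {
  s <- tiny_structure(6, ss = "helix")
  ca_only_rows <- which(s$layout$atom == "CA")
  ca_struct <- backbone_structure(
    s$residue_ids, s$residue_names, "A",
    s$coords[ca_only_rows, ], s$layout[ca_only_rows, ])
  expect_error(torsion_series(ca_struct, "phi"), "missing backbone atoms")
  expect_silent(torsion_series(ca_struct, "pseudo_dihedral"))
})
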