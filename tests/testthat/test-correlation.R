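test_that("perfectly coupled and anti-coupled residues reach +1 / -1", {
  s <- tiny_structure(6, ss = "helix")
  F <- 40
  set.seed(3)
  xyz <- matrix(rep(as.vector(t(s$coords)), F), nrow = F, byrow = TRUE)
  ca <- which(s$layout$atom == "CA")
  d <- matrix(rnorm(F * 3), F)          # shared fluctuation signal
  noise <- array(rnorm(F * 3 * 6, sd = 0.3), dim = c(F, 6, 3))
  for (r in 1:6) {
    cols <- (3 * ca[r] - 2):(3 * ca[r])
    xyz[, cols] <- xyz[, cols] + noise[, r, ]
  }
  # residue 2 copies residue 1's fluctuations; residue 5 mirrors them
  cols1 <- (3 * ca[1] - 2):(3 * ca[1])
  xyz[, cols1] <- matrix(rep(s$coords[ca[1], ], each = F), F) + d
  cols2 <- (3 * ca[2] - 2):(3 * ca[2])
  xyz[, cols2] <- matrix(rep(s$coords[ca[2], ], each = F), F) + d
  cols5 <- (3 * ca[5] - 2):(3 * ca[5])
  xyz[, cols5] <- matrix(rep(s$coords[ca[5], ], each = F), F) - d
  ens <- trajectory_ensemble("t", s, xyz)
  map <- cartesian_cross_correlation(ens)
  expect_equal(map$matrix[1, 2], 1, tolerance = 1e-9)
  expect_equal(map$matrix[1, 5], -1, tolerance = 1e-9)
})

test_that("zero-variance residues are rejected by name", {
  s <- tiny_structure(5)
  F <- 10
  set.seed(4)
  xyz <- matrix(rep(as.vector(t(s$coords)), F), nrow = F, byrow = TRUE)
  ca <- which(s$layout$atom == "CA")
  for (r in c(1, 2, 4, 5)) {
    cols <- (3 * ca[r] - 2):(3 * ca[r])
    xyz[, cols] <- xyz[, cols] + matrix(rnorm(F * 3, sd = 0.2), F)
  }
  ens <- trajectory_ensemble("t", s, xyz)  # residue 3 is frozen
  expect_error(cartesian_cross_correlation(ens), "residue 3")
})

test_that("empirical maps converge to the analytic network correlations", {
  s <- tiny_structure(30, ss = "helix")
  g <- gnm_build(s, 8)
  truth <- gnm_correlation(g)$matrix
  err <- vapply(c(500, 8000), function(F) {
    ens <- sample_gnm_ensemble(g, s, F, scale = 0.09, seed = 11)
    max(abs(cartesian_cross_correlation(ens)$matrix - truth))
  }, numeric(1))
  expect_lt(err[2], err[1])        # monotone sampling error
  expect_lt(err[2], 0.05)
})

test_that("every returned map is symmetric, unit-diagonal and bounded", {
  s <- tiny_structure(8)
  g <- gnm_build(s, 12)
  set.seed(12)
  for (i in 1:5) {
    ens <- sample_gnm_ensemble(g, s, 30, scale = runif(1, 0.05, 1),
                               seed = i)
    for (map in list(cartesian_cross_correlation(ens),
                     angular_cross_correlation(
                       torsion_series(ens, "pseudo_dihedral")))) {
      m <- map$matrix
      expect_lt(max(abs(m - t(m))), 1e-12)
      expect_equal(unname(diag(m)), rep(1, nrow(m)))
      expect_true(all(m >= -1 & m <= 1))
    }
  }
})

test_that("duplicating all frames leaves maps unchanged", {
  s <- tiny_structure(10)
  g <- gnm_build(s, 12)
  ens <- sample_gnm_ensemble(g, s, 25, scale = 0.2, seed = 13)
  doubled <- trajectory_ensemble("t", s, rbind(ens$xyz, ens$xyz))
  expect_equal(cartesian_cross_correlation(doubled)$matrix,
               cartesian_cross_correlation(ens)$matrix, tolerance = 1e-12)
  expect_equal(
    angular_cross_correlation(torsion_series(doubled, "phi"))$matrix,
    angular_cross_correlation(torsion_series(ens, "phi"))$matrix,
    tolerance = 1e-12)
})

test_that("the Cartesian map is invariant to one global rigid motion", {
  s <- tiny_structure(12)
  g <- gnm_build(s, 12)
  ens <- sample_gnm_ensemble(g, s, 60, scale = 0.2, seed = 14)
  base <- cartesian_cross_correlation(align_ensemble(ens, s))$matrix
  rot <- euler_rotation(c(0.3, 0.9, -1.4))
  moved <- ens
  for (f in seq_len(n_frames(moved)))
    moved <- set_frame_coords(moved, f,
      sweep(frame_coords(moved, f) %*% rot, 2, c(12, -4, 3), "+"))
  expect_equal(cartesian_cross_correlation(align_ensemble(moved, s))$matrix,
               base, tolerance = 1e-9)
})

test_that("angular correlations handle offsets, noise and the 180 seam", {
  F <- 10000
  set.seed(15)
  base <- 40 * sin(seq_len(F) / 50) + rnorm(F, sd = 5)
  # constant offset: perfect correlation
  series <- structure(list(kind = "pseudo_dihedral",
                           torsion_labels = 1:2,
                           values = cbind(base, base + 23)),
                      class = "angle_series")
  map <- angular_cross_correlation(series)
  expect_equal(map$matrix[1, 2], 1, tolerance = 1e-9)

  # two independent uniform series: |C| below 3/sqrt(F)
  u <- stats::runif(F, -180, 180); v <- stats::runif(F, -180, 180)
  series$values <- cbind(u, v)
  map <- angular_cross_correlation(series)
  expect_lt(abs(map$matrix[1, 2]), 3 / sqrt(F))

  # oscillation across the seam vs a phase-locked copy
  seam <- ifelse(sin(seq_len(F) / 10) > 0, 175, -175) +
    rnorm(F, sd = 1)
  seam <- ((seam + 180) %% 360) - 180
  series$values <- cbind(seam, seam)
  map <- angular_cross_correlation(series)
  expect_equal(map$matrix[1, 2], 1, tolerance = 1e-9)
  # without unwrapping the same signal decorrelates from its wrapped self
  shifted <- ((seam + 5 + 180) %% 360) - 180
  series$values <- cbind(seam, shifted)
  expect_gt(angular_cross_correlation(series)$matrix[1, 2], 0.99)
})

test_that("region coupling summarizes map blocks and sees planted springs", {
  id_map <- allodyn:::new_correlation_map(diag(10), 1:10, "cartesian",
                                          "t", 10)
  rc <- region_coupling(id_map, 1:4, 6:9)
  expect_equal(rc$score, 0)
  expect_equal(rc$n_pairs, 16)
  ones <- allodyn:::new_correlation_map(matrix(1, 10, 10), 1:10,
                                        "cartesian", "t", 10)
  expect_equal(region_coupling(ones, "1-4", "6-9")$score, 1)
  expect_error(region_coupling(id_map, 1:5, 5:8), "disjoint")
  expect_error(region_coupling(id_map, 100:110, 1:4), "no labels")

  # a spring bridging two regions strengthens their analytic coupling
  s <- tiny_structure(30, ss = "helix")
  g0 <- gnm_build(s, 8)
  g1 <- gnm_add_contacts(g0, rbind(c(5, 25), c(6, 26), c(7, 24)))
  rc0 <- region_coupling(gnm_correlation(g0), "4-8", "23-27")
  rc1 <- region_coupling(gnm_correlation(g1), "4-8", "23-27")
  expect_gt(rc1$score, rc0$score)
  # and the sampled maps reproduce the ordering
  e0 <- sample_gnm_ensemble(g0, s, 5000, scale = 0.09, seed = 16)
  e1 <- sample_gnm_ensemble(g1, s, 5000, scale = 0.09, seed = 17)
  expect_gt(
    region_coupling(cartesian_cross_correlation(e1), "4-8", "23-27")$score,
    region_coupling(cartesian_cross_correlation(e0), "4-8", "23-27")$score)
})

test_that("difference maps localize a planted coupling perturbation", {
  m <- kix_allosteric_models(seed = 1)
  wt <- gnm_correlation(m$wt)
  mut <- gnm_correlation(m$mutant)
  expect_equal(difference_map(wt, wt)$values,
               matrix(0, length(wt$labels), length(wt$labels)))
  d_ab <- difference_map(wt, mut)
  d_ba <- difference_map(mut, wt)
  expect_equal(d_ab$values, -d_ba$values)

  # top |difference| entries concentrate in the perturbed region pair
  vals <- abs(d_ab$values)
  vals[lower.tri(vals, diag = TRUE)] <- 0
  ord <- order(vals, decreasing = TRUE)[1:20]
  rows <- wt$labels[(ord - 1) %% nrow(vals) + 1]
  cols <- wt$labels[(ord - 1) %/% nrow(vals) + 1]
  loop <- expand_residue_ranges(m$loop_region)
  a3 <- expand_residue_ranges(m$alpha3_region)
  in_pair <- (rows %in% loop & cols %in% a3) |
             (rows %in% a3 & cols %in% loop)
  expect_gte(sum(in_pair), 10)

  # kind/label mismatches are hard errors
  ps <- angular_cross_correlation(
    torsion_series(sample_gnm_ensemble(m$wt, m$structure, 10, 0.1, 1),
                   "pseudo_dihedral"))
  expect_error(difference_map(wt, ps), "kind")
})
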