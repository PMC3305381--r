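# Fixtures and independent oracles shared across the suite. Everything is
# generated in code; no binary data.

# small all-loop (or custom ss) chain starting at residue 1
tiny_structure <- function(n = 3, ss = NULL, seed = 1) {
  segments <- if (!is.null(ss)) list(list(from = 1, to = n, ss = ss))
              else list()
  build_backbone(topology_spec(n, segments = segments, offset = 1L),
                 seed = seed)
}

# hand-written 3-residue backbone PDB text (N/CA/C per residue)
tiny_pdb_lines <- function() {
  c("ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00",
    "ATOM      4  N   GLY A   2       3.320   1.540   0.000  1.00  0.00",
    "ATOM      5  CA  GLY A   2       4.120   2.750   0.150  1.00  0.00",
    "ATOM      6  C   GLY A   2       5.600   2.480   0.300  1.00  0.00",
    "ATOM      7  N   SER A   3       6.420   3.510   0.400  1.00  0.00",
    "ATOM      8  CA  SER A   3       7.870   3.350   0.520  1.00  0.00",
    "ATOM      9  C   SER A   3       8.520   4.720   0.610  1.00  0.00",
    "TER", "END")
}

# ensemble of rigid-motion copies of a structure (known ground truth)
rigid_motion_ensemble <- function(structure, n = 5, seed = 1, label = "rm") {
  rot_z <- function(a) matrix(c(cos(a), sin(a), 0,
                                -sin(a), cos(a), 0,
                                0, 0, 1), 3, 3)
  set.seed(seed)
  xyz <- t(vapply(seq_len(n), function(f) {
    R <- rot_z(runif(1, 0, 2 * pi))
    t_vec <- runif(3, -10, 10)
    as.vector(t(sweep(structure$coords %*% R, 2, t_vec, "+")))
  }, numeric(3 * nrow(structure$layout))))
  trajectory_ensemble(label, structure, xyz)
}

# Euler-angle rotation matrix (z-y-z convention)
euler_rotation <- function(p) {
  ca <- cos(p[1]); sa <- sin(p[1])
  cb <- cos(p[2]); sb <- sin(p[2])
  cc <- cos(p[3]); sc <- sin(p[3])
  rz1 <- matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, byrow = TRUE)
  ry <- matrix(c(cb, 0, sb, 0, 1, 0, -sb, 0, cb), 3, byrow = TRUE)
  rz2 <- matrix(c(cc, -sc, 0, sc, cc, 0, 0, 0, 1), 3, byrow = TRUE)
  rz1 %*% ry %*% rz2
}

# brute-force minimum RMSD oracle: dense rotation grid refined by
# Nelder-Mead, independent of the Kabsch implementation
brute_force_min_rmsd <- function(P, Q) {
  Pc <- scale(P, scale = FALSE)
  Qc <- scale(Q, scale = FALSE)
  f <- function(p)
    sqrt(mean(rowSums((Pc %*% t(euler_rotation(p)) - Qc)^2)))
  grid <- expand.grid(a = seq(0, 2 * pi, length.out = 19)[-19],
                      b = seq(0, pi, length.out = 10),
                      c = seq(0, 2 * pi, length.out = 19)[-19])
  vals <- apply(grid, 1, f)
  best <- as.numeric(grid[which.min(vals), ])
  stats::optim(best, f, method = "Nelder-Mead",
               control = list(reltol = 1e-15, maxit = 5000))$value
}

# partition equality up to cluster relabeling
same_partition <- function(a, b) {
  tab <- table(a, b)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

# planted conformer mixture over well-separated centers; returns
# ensembles plus the planted per-frame center index
planted_mixture <- function(n_centers = 3, weights, n_frames = 300,
                            noise = 0.5, separation = 9, seed = 1) {
  base <- tiny_structure(30, ss = "helix")
  centers <- make_conformer_centers(base, n_centers,
                                    rmsd_from_base = separation,
                                    seed = seed)
  make_mixture_ensembles(centers, weights, n_frames, noise = noise,
                         seed = seed + 1)
}
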