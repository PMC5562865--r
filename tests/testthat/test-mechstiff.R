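test_that("dimer algebra: 5 zero modes and k_eff equal to gamma", {
  m <- build_anm(rbind(c(0, 0, 0), c(5, 0, 0)), cutoff = 15, gamma = 2.5)
  expect_identical(m$n_zero, 5L)
  expect_identical(sum(m$eigenvalues > 1e-8 * max(m$eigenvalues)), 1L)
  expect_equal(effective_stiffness(m, 1, 2), 2.5, tolerance = 1e-10)
})

test_that("three collinear beads give series springs end to end", {
  m <- build_anm(rbind(c(0, 0, 0), c(6, 0, 0), c(12, 0, 0)), cutoff = 10, gamma = 1)
  # bending/rotation null space inflates the zero-mode count for a 1-D chain
  expect_identical(m$n_zero, 7L)
  expect_equal(effective_stiffness(m, 1, 3), 0.5, tolerance = 1e-10)
  expect_equal(effective_stiffness(m, 1, 2), 1, tolerance = 1e-10)
})

test_that("a connected 3-D cloud has exactly 6 zero modes and H annihilates translations", {
  xyz <- bead_cloud(100, sd = 8, seed = 21)
  m <- build_anm(xyz, cutoff = 18)
  expect_identical(m$n_zero, 6L)
  # uniform translation lies in the null space: reconstruct H from the
  # eigendecomposition and apply it
  tr <- rep(c(1, 0, 0), 100)
  Hv <- m$eigenvectors %*% (m$eigenvalues * crossprod(m$eigenvectors, tr))
  expect_lt(max(abs(Hv)), 1e-10)
})

test_that("build_anm rejects degenerate inputs", {
  xyz <- bead_cloud(20, sd = 3, seed = 2)
  expect_error(build_anm(xyz[1, , drop = FALSE]), "at least 2")
  expect_error(build_anm(cbind(xyz, 1)), "n x 3")
  bad <- xyz; bad[5, 2] <- NA
  expect_error(build_anm(bad), "finite")
  # two distant clusters: disconnected graph reported with component count
  far <- rbind(xyz, xyz + 500)
  expect_error(build_anm(far, cutoff = 15), "disconnected")
})

test_that("mode-sum stiffness equals the full-Hessian pseudo-inverse oracle", {
  xyz <- bead_cloud(50, sd = 6, seed = 11)
  m <- build_anm(xyz, cutoff = 15, gamma = 1.7)
  set.seed(31)
  for (q in 1:12) {
    i <- sample(50, 1); j <- sample(setdiff(1:50, i), 1)
    ko <- pinv_stiffness(xyz, cutoff = 15, gamma = 1.7, i, j)
    expect_equal(effective_stiffness(m, i, j), ko, tolerance = 1e-6)
  }
  expect_error(effective_stiffness(m, 3, 3), "distinct")
})

test_that("stiffness is invariant under rigid rotation and translation", {
  xyz <- bead_cloud(40, sd = 5, seed = 13)
  m0 <- build_anm(xyz, cutoff = 15)
  set.seed(14)
  R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  m1 <- build_anm(xyz %*% R + 77, cutoff = 15)
  for (pr in list(c(1, 2), c(5, 30), c(12, 39))) {
    k0 <- effective_stiffness(m0, pr[1], pr[2])
    k1 <- effective_stiffness(m1, pr[1], pr[2])
    expect_lt(abs(k1 - k0) / k0, 1e-8)
  }
})

test_that("raising the cutoff never softens any pair", {
  # Rayleigh monotonicity: adding springs adds a positive-semidefinite term
  # to the Hessian, so no pairwise stiffness can fall. This requires a
  # mechanism-free network (exactly 6 zero modes) at both cutoffs: an
  # internal floppy mode is excluded from the compliance sum while zero but
  # re-enters as a large compliance once extra contacts barely stiffen it.
  xyz <- bead_cloud(40, sd = 4, seed = 18)
  m15 <- build_anm(xyz, cutoff = 15)
  m18 <- build_anm(xyz, cutoff = 18)
  expect_identical(c(m15$n_zero, m18$n_zero), c(6L, 6L))
  expect_true(all(effective_stiffness_matrix(m18) >=
                    effective_stiffness_matrix(m15) - 1e-9, na.rm = TRUE))
})

test_that("stiffness profile bins per domain and honors the protection mask", {
  # three domains: a dense cluster, a looser cluster, a sparse chain
  set.seed(41)
  dense <- matrix(rnorm(60, sd = 2.0), 20, 3)
  loose <- matrix(rnorm(60, sd = 5.0), 20, 3) + matrix(rep(c(25, 0, 0), each = 20), 20)
  chain <- cbind(seq(50, 50 + 19 * 6, by = 6), 0, 0)
  xyz <- rbind(dense, loose, chain)
  m <- build_anm(xyz, cutoff = 16)
  labels <- rep(c("D1", "D2", "D3"), each = 20)
  pr <- stiffness_profile(m, labels, thresholds = c(2, 4))
  expect_equal(rowSums(pr$bins[, c("frac_soft", "frac_mid", "frac_stiff")]),
               rep(1, 3), tolerance = 1e-12)
  # the densest domain carries the largest stiff fraction
  expect_gte(pr$bins$frac_stiff[1], pr$bins$frac_stiff[2])
  expect_gte(pr$bins$frac_stiff[1], pr$bins$frac_stiff[3])
  # per-residue scalars are positive
  expect_true(all(pr$per_residue > 0))

  # masking: a fully masked domain is flagged, not silently zeroed
  mask <- labels == "D2"
  pr2 <- stiffness_profile(m, labels, protected_mask = mask, thresholds = c(2, 4))
  expect_true(pr2$bins$all_masked[pr2$bins$domain == "D2"])
  expect_true(is.na(pr2$bins$frac_soft[pr2$bins$domain == "D2"]))
  expect_error(stiffness_profile(m, labels[-1]), "length")
})

test_that("uniform toy structure lands in a single stiffness bin", {
  # symmetric tetrahedron: identical environments, identical per-residue k
  xyz <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) * 4
  m <- build_anm(xyz, cutoff = 15)
  pr <- stiffness_profile(m, rep("T", 4), thresholds = c(12, 15))
  fr <- unlist(pr$bins[1, c("frac_soft", "frac_mid", "frac_stiff")])
  expect_equal(unname(sort(fr, decreasing = TRUE)[1]), 1)
})

test_that("C-alpha PDB reading extracts coordinates and rejects insertion codes", {
  xyz <- bead_cloud(12, sd = 4, seed = 3)
  tmp <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(tmp, xyz)
  got <- read_calpha_pdb(tmp)
  expect_equal(nrow(got$coords), 12)
  expect_equal(got$coords, round(xyz, 3), tolerance = 1e-6, ignore_attr = TRUE)
  m <- build_anm(got$coords, cutoff = 15)
  expect_identical(m$n_zero, 6L)
  # insertion code rejection
  lines <- readLines(tmp)
  lines[3] <- sub("ALA A   3", "ALA A   2A", lines[3])
  writeLines(lines, tmp)
  expect_error(read_calpha_pdb(tmp), "insertion")
})
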