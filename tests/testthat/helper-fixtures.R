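# Shared fixtures and independent oracles, built in code.

# small two-domain architecture for fast simulator tests
toy_arch <- function(l_aa = 0.38) {
  d <- data.frame(
    name = c("IgC2_1", "FnIII_1"),
    dclass = c("IgC2", "FnIII"),
    n_res = c(96, 95),
    n_protected = c(55, 0),
    linker_after = c(4, 0),
    d_fold = c(4.5, 4.5),
    stringsAsFactors = FALSE)
  structure(list(domains = d, l_aa = l_aa), class = "protein_architecture")
}

# hand-scripted event sequence (bypasses random draws)
manual_script <- function(dL, F_rupt, class = rep("FnIII", length(dL)),
                          L0 = 60, detach_force = 250) {
  ev <- data.frame(type = rep("rupture", length(dL)), class = class,
                   domain = if (length(dL)) paste0(class, "_", seq_along(dL)) else character(0),
                   dL = dL, F_rupt = F_rupt,
                   hump = rep(FALSE, length(dL)), hump_dl = rep(NA_real_, length(dL)),
                   hump_F = rep(NA_real_, length(dL)),
                   partial = rep(FALSE, length(dL)), stringsAsFactors = FALSE)
  structure(ev, class = c("unfolding_script", "data.frame"),
            L0 = L0, detach_force = detach_force, seed = 0L)
}

# independent inversion oracle: plain scalar bisection, written separately
# from the package implementation
bisect_extension <- function(Fq, p, tol = 1e-9) {
  lo <- 0; hi <- p$Lc * (1 - 1e-9)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (wlc_force(mid, p) < Fq) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# brute-force stiffness oracle: pseudo-inverse of the full Hessian built
# independently of the package's assembly code
pinv_stiffness <- function(coords, cutoff, gamma, i, j) {
  n <- nrow(coords)
  H <- matrix(0, 3 * n, 3 * n)
  dm <- as.matrix(stats::dist(coords))
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    if (dm[a, b] > cutoff) next
    r <- coords[b, ] - coords[a, ]
    blk <- -gamma * tcrossprod(r) / sum(r * r)
    ia <- (3 * a - 2):(3 * a); ib <- (3 * b - 2):(3 * b)
    H[ia, ib] <- blk; H[ib, ia] <- blk
    H[ia, ia] <- H[ia, ia] - blk; H[ib, ib] <- H[ib, ib] - blk
  }
  Hp <- MASS::ginv(H)
  rh <- (coords[j, ] - coords[i, ]); rh <- rh / sqrt(sum(rh^2))
  e <- rep(0, 3 * n)
  e[(3 * i - 2):(3 * i)] <- -rh
  e[(3 * j - 2):(3 * j)] <- rh
  1 / drop(t(e) %*% Hp %*% e)
}

# compact connected bead cloud
bead_cloud <- function(n = 50, sd = 6, seed = 11) {
  set.seed(seed)
  matrix(stats::rnorm(3 * n, sd = sd), n, 3)
}

# minimal C-alpha PDB text for io tests
write_toy_pdb <- function(path, coords, chain = "A") {
  lines <- vapply(seq_len(nrow(coords)), function(i)
    sprintf("ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            i, chain, i, coords[i, 1], coords[i, 2], coords[i, 3]), character(1))
  writeLines(c(lines, "END"), path)
  path
}
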