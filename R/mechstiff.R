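# Anisotropic network model and mechanical stiffness: effective spring
# constants between residue pairs from C-alpha coordinates, and per-domain
# stiffness-bin summaries.

#' Build an anisotropic network model from C-alpha coordinates
#'
#' Standard ANM construction: residues within `cutoff` of each other are
#' connected by uniform springs of force constant `gamma`; the off-diagonal
#' 3x3 super-element of the Hessian for a contacting pair (i, j) is
#' `-gamma (r_ij r_ij^T) / |r_ij|^2` and diagonal super-elements are minus
#' the sum of the off-diagonals in their row. The model stores the full
#' eigendecomposition; a connected three-dimensional structure has exactly
#' six numerically zero modes (rigid translations and rotations).
#'
#' @param coords Numeric `n x 3` matrix of C-alpha positions (Angstrom).
#' @param cutoff Contact cutoff (Angstrom, default 15 - the conventional
#'   C-alpha ANM choice).
#' @param gamma Uniform spring constant (arbitrary units, default 1).
#' @param zero_tol Relative tolerance (vs the largest eigenvalue) below which
#'   a mode counts as zero.
#' @return An `anm_model`: list with `coords`, `cutoff`, `gamma`,
#'   `eigenvalues` (ascending), `eigenvectors` (columns matching), `n_zero`,
#'   `n`.
#' @export
build_anm <- function(coords, cutoff = 15, gamma = 1, zero_tol = 1e-8) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("'coords' must be an n x 3 matrix")
  n <- nrow(coords)
  if (n < 2L) stop("at least 2 residues are required to build an ANM")
  if (any(!is.finite(coords))) stop("coordinates must be finite")
  dmat <- as.matrix(stats::dist(coords))
  adj <- dmat <= cutoff & upper.tri(dmat)

  # connectivity of the contact graph
  comp <- integer(n); comp[1] <- 1L; queue <- 1L; lab <- 1L
  neigh <- dmat <= cutoff; diag(neigh) <- FALSE
  while (any(comp == 0L)) {
    if (!length(queue)) {
      lab <- lab + 1L
      queue <- which(comp == 0L)[1]
      comp[queue] <- lab
    }
    v <- queue[1]; queue <- queue[-1]
    nb <- which(neigh[v, ] & comp == 0L)
    comp[nb] <- comp[v]
    queue <- c(queue, nb)
  }
  if (max(comp) > 1L) {
    sizes <- table(comp)
    stop(sprintf("contact graph is disconnected at cutoff %g A: %d components (sizes %s)",
                 cutoff, max(comp), paste(sizes, collapse = ", ")))
  }

  H <- matrix(0, 3 * n, 3 * n)
  pr <- which(adj, arr.ind = TRUE)
  for (q in seq_len(nrow(pr))) {
    i <- pr[q, 1]; j <- pr[q, 2]
    r <- coords[j, ] - coords[i, ]
    blk <- -gamma * tcrossprod(r) / sum(r * r)
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    H[ii, jj] <- blk
    H[jj, ii] <- blk
    H[ii, ii] <- H[ii, ii] - blk
    H[jj, jj] <- H[jj, jj] - blk
  }
  eg <- eigen(H, symmetric = TRUE)
  vals <- rev(eg$values)
  vecs <- eg$vectors[, rev(seq_len(3 * n)), drop = FALSE]
  n_zero <- sum(abs(vals) < zero_tol * max(abs(vals)))
  structure(list(coords = coords, cutoff = cutoff, gamma = gamma,
                 eigenvalues = vals, eigenvectors = vecs,
                 n_zero = n_zero, n = n, zero_tol = zero_tol),
            class = "anm_model")
}

#' @export
print.anm_model <- function(x, ...) {
  cat(sprintf("ANM model: %d residues, cutoff %g A, gamma %g (%d zero modes)\n",
              x$n, x$cutoff, x$gamma, x$n_zero))
  invisible(x)
}

#' Effective spring constant between two residues
#'
#' Mechanical-stiffness measure of the effective resistance of the network to
#' pulling residues `i` and `j` apart: the compliance along the i-j direction
#' summed over the non-zero normal modes,
#' \deqn{C_{ij} = \sum_{k} \lambda_k^{-1} [ (u_{k,j} - u_{k,i}) \cdot \hat r_{ij} ]^2,}
#' and the effective spring constant is its inverse, `k_eff = 1 / C_ij`. The
#' measure is symmetric in (i, j) and invariant under rigid rotation and
#' translation of the coordinates.
#'
#' @param model An `anm_model`.
#' @param i,j Residue indices (1-based, `i != j`).
#' @return Effective spring constant (same arbitrary units as `gamma`).
#' @export
effective_stiffness <- function(model, i, j) {
  stopifnot(inherits(model, "anm_model"))
  if (i == j) stop("effective stiffness requires two distinct residues")
  n <- model$n
  if (i < 1 || j < 1 || i > n || j > n) stop("residue index out of range")
  rij <- model$coords[j, ] - model$coords[i, ]
  rhat <- rij / sqrt(sum(rij^2))
  keep <- which(abs(model$eigenvalues) >= model$zero_tol * max(abs(model$eigenvalues)))
  V <- model$eigenvectors
  di <- (3 * i - 2):(3 * i); dj <- (3 * j - 2):(3 * j)
  proj <- crossprod(V[dj, keep, drop = FALSE] - V[di, keep, drop = FALSE], rhat)
  C <- sum(proj^2 / model$eigenvalues[keep])
  1 / C
}

#' All-pairs effective stiffness matrix
#'
#' @param model An `anm_model`.
#' @return Symmetric `n x n` matrix of effective spring constants (diagonal
#'   `NA`).
#' @export
effective_stiffness_matrix <- function(model) {
  stopifnot(inherits(model, "anm_model"))
  n <- model$n
  keep <- which(abs(model$eigenvalues) >= model$zero_tol * max(abs(model$eigenvalues)))
  lam <- model$eigenvalues[keep]
  # reshape eigenvectors to per-residue 3-vectors: Vd[[d]] is n x K
  V <- model$eigenvectors[, keep, drop = FALSE]
  K <- length(keep)
  Vx <- V[seq(1, 3 * n, by = 3), , drop = FALSE]
  Vy <- V[seq(2, 3 * n, by = 3), , drop = FALSE]
  Vz <- V[seq(3, 3 * n, by = 3), , drop = FALSE]
  out <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    d <- sweep(model$coords, 2, model$coords[i, ])
    nr <- sqrt(rowSums(d^2)); nr[i] <- 1
    rh <- d / nr
    S <- (Vx - matrix(Vx[i, ], n, K, byrow = TRUE)) * rh[, 1] +
         (Vy - matrix(Vy[i, ], n, K, byrow = TRUE)) * rh[, 2] +
         (Vz - matrix(Vz[i, ], n, K, byrow = TRUE)) * rh[, 3]
    C <- as.numeric((S * S) %*% (1 / lam))
    C[i] <- NA
    out[i, ] <- 1 / C
  }
  (out + t(out)) / 2
}

#' Per-residue stiffness profile and per-domain bins
#'
#' Summarises the pairwise effective spring constants into a per-residue
#' scalar (mean over all partners) and, per domain, the fractions of
#' residues falling into three stiffness ranges: `k < thresholds[1]` (soft),
#' `thresholds[1] <= k < thresholds[2]` (moderate) and `k >= thresholds[2]`
#' (stiff). Residues flagged in `protected_mask` (e.g. the disulfide-clamped
#' part of IgC2 domains, which never extends under force) are excluded from
#' their domain's bin counts; a domain whose residues are all masked is
#' flagged rather than silently reported as zeros.
#'
#' @param model An `anm_model`.
#' @param labels Character/factor vector of length `n`: domain label per
#'   residue.
#' @param protected_mask Logical vector of length `n` (default all FALSE).
#' @param thresholds Two ascending bin thresholds (default `c(12, 15)` in the
#'   model's arbitrary units; note these depend on `gamma` and the averaging
#'   convention).
#' @return A `stiffness_profile`: list with `per_residue` (numeric vector),
#'   `bins` (data.frame: domain, frac_soft, frac_mid, frac_stiff,
#'   n_residues, all_masked), `thresholds`.
#' @export
stiffness_profile <- function(model, labels, protected_mask = NULL,
                              thresholds = c(12, 15)) {
  stopifnot(inherits(model, "anm_model"))
  n <- model$n
  if (length(labels) != n)
    stop("'labels' length must equal the number of residues in the model")
  if (is.null(protected_mask)) protected_mask <- rep(FALSE, n)
  if (length(protected_mask) != n)
    stop("'protected_mask' length must equal the number of residues in the model")
  if (length(thresholds) != 2 || diff(thresholds) <= 0)
    stop("'thresholds' must be two ascending values")
  km <- effective_stiffness_matrix(model)
  per_res <- rowMeans(km, na.rm = TRUE)
  doms <- unique(as.character(labels))
  bins <- data.frame(domain = doms, frac_soft = NA_real_, frac_mid = NA_real_,
                     frac_stiff = NA_real_, n_residues = 0L, all_masked = FALSE,
                     stringsAsFactors = FALSE)
  for (q in seq_along(doms)) {
    idx <- which(as.character(labels) == doms[q] & !protected_mask)
    bins$n_residues[q] <- length(idx)
    if (!length(idx)) { bins$all_masked[q] <- TRUE; next }
    k <- per_res[idx]
    bins$frac_soft[q] <- mean(k < thresholds[1])
    bins$frac_mid[q] <- mean(k >= thresholds[1] & k < thresholds[2])
    bins$frac_stiff[q] <- mean(k >= thresholds[2])
  }
  structure(list(per_residue = per_res, bins = bins, thresholds = thresholds,
                 units = sprintf("a.u. (gamma = %g; per-residue scalar = mean pairwise k_eff)",
                                 model$gamma)),
            class = "stiffness_profile")
}

#' @export
print.stiffness_profile <- function(x, ...) {
  cat(sprintf("Stiffness profile (%s); bin thresholds %g / %g\n",
              x$units, x$thresholds[1], x$thresholds[2]))
  print(x$bins, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Read C-alpha coordinates from a PDB file
#'
#' Extracts C-alpha atoms (optionally one chain). Insertion codes are
#' rejected: renumber the structure first.
#'
#' @param path PDB file path.
#' @param chain Optional single chain identifier.
#' @return List with `coords` (n x 3 matrix, Angstrom), `resno`, `chain`.
#' @export
read_calpha_pdb <- function(path, chain = NULL) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- bio3d::read.pdb(path)
  sel <- bio3d::atom.select(pdb, "calpha", chain = chain, verbose = FALSE)
  at <- pdb$atom[sel$atom, , drop = FALSE]
  if (nrow(at) == 0) stop("no C-alpha atoms found", if (!is.null(chain)) paste0(" in chain ", chain))
  ins <- at$insert
  if (any(!is.na(ins) & nzchar(ins)))
    stop("PDB contains insertion codes; renumber residues before stiffness analysis")
  list(coords = as.matrix(at[, c("x", "y", "z")]), resno = at$resno, chain = at$chain)
}
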