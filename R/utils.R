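# Small internal helpers.

# Evaluate expr under a local, seeded RNG stream, restoring the caller's
# RNG state afterwards so package functions never perturb user randomness.
with_local_seed <- function(seed, expr) {
  if (is.null(seed) || !is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("a single integer 'seed' is required (reproducibility is mandatory)")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Draw one value from a (possibly truncated) univariate Gaussian mixture.
# Truncation is rejection-sampled within [lower, upper] and additionally
# within mean +/- 3 sd of the drawn component.
draw_mixture <- function(n, means, sds, weights, lower = -Inf, upper = Inf,
                         trunc_3sd = TRUE) {
  k <- length(means)
  stopifnot(length(sds) == k, length(weights) == k)
  comp <- sample.int(k, n, replace = TRUE, prob = weights)
  out <- numeric(n)
  for (i in seq_len(n)) {
    m <- means[comp[i]]; s <- sds[comp[i]]
    lo <- max(lower, if (trunc_3sd) m - 3 * s else -Inf)
    hi <- min(upper, if (trunc_3sd) m + 3 * s else Inf)
    if (lo >= hi) { out[i] <- hi; next }
    # inverse-CDF sampling on the truncated support
    plo <- stats::pnorm(lo, m, s); phi <- stats::pnorm(hi, m, s)
    out[i] <- stats::qnorm(plo + stats::runif(1) * (phi - plo), m, s)
  }
  out
}
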