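# Population-level statistics: Gaussian-mixture decomposition of increment
# and force histograms, domain-class assignment, and detectors for
# characteristic spectral features.

#' Fit a Gaussian mixture to a population of measurements
#'
#' Two routes are provided. The default `"em"` is maximum-likelihood EM
#' (via mclust, unequal variances): for the strongly overlapping components
#' typical of unfolding-length and rupture-force populations it is the
#' unbiased estimator and is therefore used for all population summaries.
#' Method `"histls"` mirrors the histogram-Gaussian decompositions
#' traditional in smAFM population analysis: the values are binned (1 nm
#' bins suit contour-length increments, 10 pN bins suit rupture forces) and
#' `k` Gaussian components are fit to the bin counts by least squares
#' (Levenberg-Marquardt) from several deterministic starts (quantile- and
#' histogram-mode-based), keeping the best sum of squared residuals. The two
#' routes agree on well-separated mixtures; least squares on binned counts
#' acquires a visible bias when components overlap, which is why it is not
#' the default.
#'
#' @param values Numeric measurements (at least `10 k`).
#' @param k Number of components (>= 1).
#' @param method `"em"` (default) or `"histls"`.
#' @param bin_width Histogram bin width; default 1 (appropriate for nm-scale
#'   increments; pass 10 for pN-scale forces).
#' @param n_starts Number of deterministic restarts (histls).
#' @param equal_var Constrain all components to a common variance (EM route
#'   only). Appropriate when the underlying components are known to share
#'   their width, as the three increment components do (printed sds
#'   3.3/3.3/3.7 nm); it prevents the spare component from turning into a
#'   broad outlier-absorber. Default `FALSE`.
#' @param background Optional two-element range. When given, the EM route
#'   fits `k` shared-width Gaussians plus a uniform background component
#'   supported on this range, with a free background weight. This is the
#'   robust-mixture treatment for a known contamination class: compound
#'   increments from undetected cascaded ruptures are sums of two
#'   single-domain releases, so they live above ~15 nm and below the
#'   analysis window, precisely between the population modes where they
#'   would otherwise drag component means. The fitted background weight is
#'   returned as `bg_weight`.
#' @return A `mixture_fit`: list with `k`, `means`, `sds`, `weights` (sorted
#'   by ascending mean), `method`, `gof` (SSR for histls, log-likelihood for
#'   EM), `degenerate` flag, `n`.
#' @importFrom mclust Mclust mclustBIC
#' @export
fit_gaussian_mixture <- function(values, k, method = c("em", "histls"),
                                 bin_width = 1, n_starts = 5L,
                                 equal_var = FALSE, background = NULL) {
  method <- match.arg(method)
  values <- values[is.finite(values)]
  if (k < 1) stop("'k' must be at least 1")
  if (length(values) < 10 * k)
    stop(sprintf("insufficient data: %d values for k = %d components (need >= %d)",
                 length(values), k, 10 * k))

  if (method == "em" && !is.null(background)) {
    if (length(background) != 2 || diff(background) <= 0)
      stop("'background' must be an increasing two-element range")
    f <- em_with_background(values, k, background)
    return(structure(list(k = k, means = f$mu, sds = rep(f$sg, k),
                          weights = f$w / sum(f$w), method = "em",
                          gof = f$loglik, degenerate = f$sg < bin_width / 4,
                          n = length(values), bg_weight = f$wb,
                          bg_range = background), class = "mixture_fit"))
  }

  if (method == "em") {
    mc <- mclust::Mclust(values, G = k, modelNames = if (equal_var) "E" else "V",
                         verbose = FALSE)
    if (is.null(mc)) stop("EM mixture fit failed")
    mu <- as.numeric(mc$parameters$mean)
    sd_ <- sqrt(as.numeric(mc$parameters$variance$sigmasq))
    if (length(sd_) == 1L) sd_ <- rep(sd_, k)
    w <- as.numeric(mc$parameters$pro)
    o <- order(mu)
    return(structure(list(k = k, means = mu[o], sds = sd_[o], weights = w[o],
                          method = "em", gof = mc$loglik,
                          degenerate = any(sd_ < bin_width / 4),
                          n = length(values)), class = "mixture_fit"))
  }

  rng <- range(values)
  brk <- seq(floor(rng[1] / bin_width) * bin_width,
             ceiling(rng[2] / bin_width) * bin_width + bin_width, by = bin_width)
  h <- graphics::hist(values, breaks = brk, plot = FALSE)
  ctr <- h$mids; cnt <- h$counts
  N <- length(values)

  model_counts <- function(par) {
    mu <- par[1:k]; sg <- exp(par[(k + 1):(2 * k)]); A <- exp(par[(2 * k + 1):(3 * k)])
    pred <- rep(0, length(ctr))
    for (j in seq_len(k)) pred <- pred + A[j] * bin_width * stats::dnorm(ctr, mu[j], sg[j])
    pred
  }
  resid_fun <- function(par) cnt - model_counts(par)

  # deterministic starting points: quantile-based means, histogram-mode-based
  # means (top-k separated local maxima of the smoothed counts), and
  # perturbations of both
  qs <- stats::quantile(values, probs = (seq_len(k) - 0.5) / k, names = FALSE)
  spread <- stats::sd(values) / sqrt(k)
  sm <- as.numeric(stats::filter(cnt, rep(1 / 3, 3), sides = 2))
  sm[is.na(sm)] <- cnt[is.na(sm)]
  is_max <- which(sm >= c(-Inf, sm[-length(sm)]) & sm >= c(sm[-1], -Inf) & sm > 0)
  is_max <- is_max[order(sm[is_max], decreasing = TRUE)]
  modes <- numeric(0)
  for (i in is_max) {   # greedy pick, keeping modes >= 3 bins apart
    if (all(abs(ctr[i] - modes) >= 3 * bin_width)) modes <- c(modes, ctr[i])
    if (length(modes) == k) break
  }
  ms <- if (length(modes) == k) sort(modes) else qs

  starts <- list(
    list(mu = qs, sg = rep(max(spread, bin_width), k)),
    list(mu = ms, sg = rep(max(spread / 2, bin_width), k)),
    list(mu = ms, sg = rep(max(spread, bin_width), k)))
  extra <- max(0L, n_starts - length(starts))
  for (st in seq_len(extra)) {
    shift <- (st - (extra + 1) / 2) / max(1, extra)
    starts[[length(starts) + 1L]] <-
      list(mu = qs + shift * spread * rep_len(c(1, -1), k),
           sg = rep(max(spread, bin_width / 2), k) * (1 + 0.3 * shift))
  }

  best <- NULL
  for (stt in starts) {
    par0 <- c(stt$mu, log(stt$sg), log(rep(N / k, k)))
    fit <- tryCatch(
      minpack.lm::nls.lm(par0, fn = resid_fun,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(resid_fun(fit$par)^2)
    if (is.null(best) || ssr < best$ssr) best <- list(par = fit$par, ssr = ssr)
  }
  if (is.null(best)) stop("histogram least-squares mixture fit failed to converge")
  mu <- best$par[1:k]; sg <- exp(best$par[(k + 1):(2 * k)])
  A <- exp(best$par[(2 * k + 1):(3 * k)])
  w <- A / sum(A)
  o <- order(mu)
  structure(list(k = k, means = mu[o], sds = sg[o], weights = w[o],
                 method = "histls", gof = best$ssr,
                 degenerate = any(sg < bin_width / 4), n = N,
                 bin_width = bin_width), class = "mixture_fit")
}

# EM for k shared-width Gaussians plus a uniform background on bg; quantile
# initialisation keeps the fit fully deterministic
em_with_background <- function(x, k, bg, max_iter = 500L, tol = 1e-8) {
  mu <- stats::quantile(x, (seq_len(k) - 0.5) / k, names = FALSE)
  sg <- stats::sd(x) / k
  w <- rep(0.9 / k, k)
  wb <- 0.1
  ub <- 1 / diff(bg)
  inb <- x >= bg[1] & x <= bg[2]
  ll <- -Inf
  for (it in seq_len(max_iter)) {
    d <- vapply(seq_len(k), function(j) w[j] * stats::dnorm(x, mu[j], sg),
                numeric(length(x)))
    d <- matrix(d, nrow = length(x))
    db <- wb * ub * inb
    tot <- rowSums(d) + db + 1e-300
    r <- d / tot
    nk <- colSums(r)
    mu_new <- colSums(r * x) / pmax(nk, 1e-12)
    sg_new <- sqrt(sum(vapply(seq_len(k), function(j)
      sum(r[, j] * (x - mu_new[j])^2), numeric(1))) / sum(nk))
    w <- nk / length(x)
    wb <- sum(db / tot) / length(x)
    mu <- mu_new
    sg <- max(sg_new, 1e-3)
    ll_new <- sum(log(tot))
    if (is.finite(ll) && abs(ll_new - ll) < tol) { ll <- ll_new; break }
    ll <- ll_new
  }
  o <- order(mu)
  list(mu = mu[o], sg = sg, w = w[o], wb = wb, loglik = ll)
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("Gaussian mixture (%s, k = %d, n = %d):\n", x$method, x$k, x$n))
  for (j in seq_len(x$k))
    cat(sprintf("  component %d: mean %.2f, sd %.2f, weight %.3f\n",
                j, x$means[j], x$sds[j], x$weights[j]))
  if (isTRUE(x$degenerate)) cat("  [degenerate component flagged]\n")
  invisible(x)
}

#' Posterior responsibilities under a mixture fit
#' @param x Values.
#' @param mix A `mixture_fit`.
#' @return Matrix `length(x) x k` of posterior component probabilities.
#' @export
mixture_posterior <- function(x, mix) {
  stopifnot(inherits(mix, "mixture_fit"))
  num <- sapply(seq_len(mix$k), function(j)
    mix$weights[j] * stats::dnorm(x, mix$means[j], mix$sds[j]))
  num <- matrix(num, nrow = length(x))
  sweep(num, 1, pmax(rowSums(num), .Machine$double.xmin), "/")
}

#' Assign domain classes to events from the increment mixture
#'
#' Events are labeled by maximum posterior responsibility under a
#' 3-component contour-length-increment mixture: the two lower-mean
#' components correspond to disulfide-clamped IgC2 segments, the
#' largest-mean component to fully unfolding FnIII modules. Posterior ties
#' break toward the larger-mean component (FnIII). A hard cut at `hard_cut`
#' nm is available as a fallback.
#'
#' @param events Events data.frame (needs a `dL` column), e.g. from
#'   [analyze_dataset()].
#' @param dl_mixture A 3-component `mixture_fit` of the increments.
#' @param hard_cut If non-`NULL`, label by `dL >= hard_cut` instead of the
#'   posterior.
#' @return The events data.frame with `label` filled in (`IgC2`, `FnIII`, or
#'   `unassigned` for missing increments).
#' @export
classify_events <- function(events, dl_mixture, hard_cut = NULL) {
  if (!is.null(hard_cut)) {
    events$label <- ifelse(is.na(events$dL), "unassigned",
                           ifelse(events$dL >= hard_cut, "FnIII", "IgC2"))
    return(events)
  }
  stopifnot(inherits(dl_mixture, "mixture_fit"))
  if (dl_mixture$k < 2) stop("classification needs a mixture with at least 2 components")
  ok <- !is.na(events$dL)
  events$label <- "unassigned"
  if (any(ok)) {
    post <- mixture_posterior(events$dL[ok], dl_mixture)
    fn_comp <- dl_mixture$k           # components sorted by mean; largest = FnIII
    p_fn <- post[, fn_comp]
    p_ig <- rowSums(post[, -fn_comp, drop = FALSE])
    events$label[ok] <- ifelse(p_fn >= p_ig, "FnIII", "IgC2")  # tie -> FnIII
  }
  events
}

#' Canonical population analysis of an event table
#'
#' The standard population summary chain: restrict increments to a physical
#' analysis window (default 3-45 nm, the range spanned by real unfolding
#' increments; values outside are compound or spurious segmentation
#' artifacts), fit the 3-component increment mixture (EM, equal variances -
#' the increment components share their width - plus a uniform background on
#' 15-45 nm absorbing compound increments from cascaded ruptures), label
#' every event by posterior responsibility, and fit 2-component
#' rupture-force mixtures per domain class (EM, free variances).
#'
#' @param events Combined events data.frame (needs `dL` and `Fmax`), e.g.
#'   from [analyze_dataset()].
#' @param dl_range Analysis window for increments (nm).
#' @param k_dl Components of the increment mixture (default 3).
#' @param k_f Components of each force mixture (default 2).
#' @param method Passed to [fit_gaussian_mixture()].
#' @return List with `dl_fit`, `events` (labeled, windowed), `f_igc2_fit`,
#'   `f_fniii_fit` (either may be `NULL` when a class has too few events).
#' @export
population_analysis <- function(events, dl_range = c(3, 45), k_dl = 3, k_f = 2,
                                method = "em") {
  ev <- events[!is.na(events$dL) & events$dL >= dl_range[1] & events$dL <= dl_range[2], ]
  dl_fit <- fit_gaussian_mixture(ev$dL, k = k_dl, method = method,
                                 bin_width = 1, equal_var = TRUE,
                                 background = if (method == "em") c(15, dl_range[2]) else NULL)
  ev <- classify_events(ev, dl_fit)
  fit_class <- function(lab) {
    x <- ev$Fmax[ev$label == lab & !is.na(ev$Fmax)]
    if (length(x) < 10 * k_f) return(NULL)
    fit_gaussian_mixture(x, k = k_f, method = method, bin_width = 10)
  }
  list(dl_fit = dl_fit, events = ev,
       f_igc2_fit = fit_class("IgC2"), f_fniii_fit = fit_class("FnIII"))
}

#' Detect two-stage (intermediate "hump") FnIII unfolding
#'
#' Scans consecutive event pairs of an analyzed curve for the signature of an
#' FnIII module unfolding through an intermediate: a first partial increment
#' of 11-18 nm whose completion brings the summed increment to a full FnIII
#' length, with the intermediate rupturing at a distinctly lower force than
#' the completion (`Fmax_1 < force_ratio * Fmax_2`). Matching pairs are
#' reported (location = partial increment) and can be merged into single
#' FnIII events with [merge_hump_events()].
#'
#' Note an inherent specificity limit: the disulfide-clamped IgC2 increments
#' around 17.4 +/- 3.3 nm overlap the intermediate window, so a pair of
#' consecutive IgC2 events can mimic the signature; the force-ratio
#' requirement suppresses but cannot eliminate such mimics. Treat reports on
#' curves rich in IgC2 events as candidates.
#'
#' @param analysis A `curve_analysis` (events need increments; labels not
#'   required).
#' @param hump_range Partial-increment window (nm), default `c(11, 18)`.
#' @param full_range Window for the summed increment (nm), default
#'   `c(26, 36)` (a full FnIII length).
#' @param force_ratio Maximum intermediate/completion force ratio (default
#'   0.85).
#' @return Data frame of feature reports (`feature = "hump"`, `event_index`,
#'   `location` = partial increment in nm, `magnitude` = merged increment).
#' @export
detect_intermediate_hump <- function(analysis, hump_range = c(11, 18),
                                     full_range = c(26, 36),
                                     force_ratio = 0.85) {
  stopifnot(inherits(analysis, "curve_analysis"))
  ev <- analysis$events
  out <- data.frame(curve = character(0), feature = character(0),
                    event_index = integer(0), location = numeric(0),
                    magnitude = numeric(0))
  if (nrow(ev) < 2) return(out)
  for (i in seq_len(nrow(ev) - 1L)) {
    d1 <- ev$dL[i]; d2 <- ev$dL[i + 1L]
    if (is.na(d1) || is.na(d2)) next
    if (d1 >= hump_range[1] && d1 <= hump_range[2] &&
        (d1 + d2) >= full_range[1] && (d1 + d2) <= full_range[2] &&
        ev$Fmax[i] < force_ratio * ev$Fmax[i + 1L]) {
      out[nrow(out) + 1L, ] <- list(as.character(analysis$curve_id), "hump",
                                    ev$index[i], d1, d1 + d2)
    }
  }
  out
}

#' Merge detected hump pairs into single FnIII events
#'
#' @param analysis A `curve_analysis`.
#' @param reports Output of [detect_intermediate_hump()].
#' @return The analysis with each reported pair collapsed into one event
#'   (`dL` = summed increment, `Fmax` = completion force, `hump = TRUE`).
#' @export
merge_hump_events <- function(analysis, reports) {
  ev <- analysis$events
  ev$hump <- FALSE
  drop <- integer(0)
  for (r in seq_len(nrow(reports))) {
    i <- match(reports$event_index[r], ev$index)
    if (is.na(i) || i >= nrow(ev)) next
    ev$dL[i] <- reports$magnitude[r]
    ev$Fmax[i] <- ev$Fmax[i + 1L]
    ev$hump[i] <- TRUE
    ev$label[i] <- "FnIII"
    drop <- c(drop, i + 1L)
  }
  if (length(drop)) ev <- ev[-drop, , drop = FALSE]
  ev$index <- seq_len(nrow(ev))
  rownames(ev) <- NULL
  analysis$events <- ev
  analysis$n_peaks <- nrow(ev) + 1L
  analysis
}

#' Detect long low-force plateaus
#'
#' Finds contiguous regions where the (median-smoothed) force stays within a
#' `+/- band` pN band around a level in `level_range` over a separation span
#' of at least `min_span` nm, with an additional flatness requirement (the
#' least-squares slope of force vs separation must not exceed `max_slope`
#' pN/nm, which excludes slowly rising WLC branches that merely pass through
#' the force band). Such plateaus are the signature of weak interdomain
#' contacts - the bent "horseshoe" arrangement of the N-terminal IgC2
#' modules - peeling open at near-constant force. A validity flag records
#' whether the plateau precedes every FnIII-labeled event, the position the
#' horseshoe interpretation requires.
#'
#' @param curve The preprocessed `force_curve`.
#' @param analysis The matching `curve_analysis` (labels used for the
#'   position flag when present).
#' @param min_span Minimum separation span (nm, default 30).
#' @param band Half-width of the force band (pN, default 10).
#' @param level_range Allowed plateau levels (pN, default `c(10, 40)`).
#' @param max_slope Maximum absolute slope (pN/nm, default 0.2: a true
#'   shelf rises at ~0.1 pN/nm, while worm-like-chain branches drifting
#'   through the force band rise several times faster).
#' @param smooth_k Median-smoothing window (samples).
#' @param peak_margin Interior detected peaks whose force exceeds the window
#'   level by more than `band + peak_margin` (pN) reject/restart the window;
#'   smaller excursions are treated as noise on the shelf. Default 5.
#' @param fn_dl_max FnIII-labeled events with increments above this (nm,
#'   default 38) are ignored by the position check: a genuine single FnIII
#'   increment never exceeds ~38 nm, so larger ones are compound increments -
#'   typically the event whose measured increment swallowed the plateau span
#'   itself.
#' @return Data frame of reports: `feature = "plateau"`, `location` (start
#'   separation, nm), `span` (nm), `magnitude` (mean force, pN),
#'   `valid_position`.
#' @export
detect_long_plateau <- function(curve, analysis = NULL, min_span = 30, band = 10,
                                level_range = c(10, 40), max_slope = 0.2,
                                smooth_k = 21, fn_dl_max = 38,
                                peak_margin = 5) {
  stopifnot(inherits(curve, "force_curve"))
  Fs <- as.numeric(stats::runmed(curve$force, smooth_k))
  s <- curve$separation
  inband <- Fs >= level_range[1] - band & Fs <= level_range[2] + band
  out <- data.frame(curve = character(0), feature = character(0),
                    location = numeric(0), span = numeric(0),
                    magnitude = numeric(0), valid_position = logical(0))
  if (!any(inband)) return(out)
  r <- rle(inband)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  first_fn_sep <- Inf
  if (!is.null(analysis) && nrow(analysis$events)) {
    fn <- analysis$events$sep_peak[analysis$events$label == "FnIII" &
                                     !is.na(analysis$events$dL) &
                                     analysis$events$dL <= fn_dl_max]
    if (length(fn)) first_fn_sep <- min(fn)
  }
  peak_seps <- if (!is.null(analysis) && nrow(analysis$events))
    analysis$events$sep_peak else numeric(0)
  peak_force <- if (!is.null(analysis) && nrow(analysis$events))
    analysis$events$Fmax else numeric(0)
  for (g in which(r$values)) {
    a <- starts[g]; b <- ends[g]
    # within the run, grow maximal windows whose force range stays <= 2*band
    i <- a
    while (i <= b) {
      j <- i; cmax <- Fs[i]; cmin <- Fs[i]
      while (j < b) {
        nmax <- max(cmax, Fs[j + 1L]); nmin <- min(cmin, Fs[j + 1L])
        if (nmax - nmin > 2 * band) break
        j <- j + 1L; cmax <- nmax; cmin <- nmin
      }
      span <- s[j] - s[i]
      if (span >= min_span) {
        lev <- mean(curve$force[i:j])
        slope <- stats::coef(stats::lm.fit(cbind(1, s[i:j]), Fs[i:j]))[2]
        # a true plateau contains no saw-tooth: when the window swallows a
        # detected rupture peak that actually breaks the force band (it grew
        # from the preceding tooth's flank), restart it just past that peak
        # instead of reporting; peaks whose force sits inside the band are
        # noise excursions on the shelf, not teeth
        inside <- peak_seps > s[i] + 1 & peak_seps < s[j] - 1 &
          peak_force > lev + band + peak_margin
        interior <- peak_seps[inside]
        if (length(interior)) {
          nxt <- which(s > max(interior) + 0.5)[1]
          i <- if (is.na(nxt)) j + 1L else max(i + 1L, nxt)
          next
        }
        if (lev >= level_range[1] && lev <= level_range[2] && abs(slope) <= max_slope) {
          out[nrow(out) + 1L, ] <- list(
            as.character(curve$meta$id %||% NA), "plateau",
            s[i], span, lev, s[j] <= first_fn_sep)
          i <- j + 1L
        } else {
          # failed level/flatness: the window may have grown from a low
          # pre-plateau stretch into the shelf, so advance gradually rather
          # than skipping everything it covered
          i <- i + max(1L, (j - i + 1L) %/% 4L)
        }
      } else {
        i <- i + max(1L, (j - i + 1L) %/% 4L)
      }
    }
  }
  out
}

#' Detect partial first-FnIII unfolding events
#'
#' Flags classified events whose increment falls in the partial-FnIII window
#' (23.1-24.4 nm, optionally padded by `tol` to absorb fit noise), that occur
#' after every IgC2-labeled event of the curve, and that are followed by at
#' most `max_following` FnIII-labeled events - the placement signature of a
#' partially unfolding first FnIII module.
#'
#' @param analysis A `curve_analysis` with labeled events (see
#'   [classify_events()]).
#' @param window Increment window (nm), default `c(23.1, 24.4)`.
#' @param tol Symmetric widening of the window (nm, default 0.6) absorbing
#'   WLC-fit scatter.
#' @param max_following Maximum FnIII events allowed after the flagged one.
#' @return Data frame of reports: `feature = "partial_fniii"`,
#'   `event_index`, `location` (= increment, nm), `n_following_fniii`.
#' @export
detect_partial_fniii <- function(analysis, window = c(23.1, 24.4), tol = 0.6,
                                 max_following = 3L) {
  stopifnot(inherits(analysis, "curve_analysis"))
  ev <- analysis$events
  out <- data.frame(curve = character(0), feature = character(0),
                    event_index = integer(0), location = numeric(0),
                    n_following_fniii = integer(0))
  if (!nrow(ev)) return(out)
  lo <- window[1] - tol; hi <- window[2] + tol
  for (i in seq_len(nrow(ev))) {
    d <- ev$dL[i]
    if (is.na(d) || d < lo || d > hi) next
    after <- if (i < nrow(ev)) ev$label[(i + 1L):nrow(ev)] else character(0)
    if (any(after == "IgC2")) next
    nf <- sum(after == "FnIII")
    if (nf > max_following) next
    out[nrow(out) + 1L, ] <- list(as.character(analysis$curve_id), "partial_fniii",
                                  ev$index[i], d, nf)
  }
  out
}
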