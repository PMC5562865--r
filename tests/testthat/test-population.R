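test_that("EM mixture fitting recovers known component parameters", {
  set.seed(2)
  v <- c(rnorm(900, 9.5, 3.3), rnorm(900, 17.4, 3.3), rnorm(1200, 30.6, 3.7))
  m <- fit_gaussian_mixture(v, 3)
  expect_equal(m$means, c(9.5, 17.4, 30.6), tolerance = 0.5 / 9.5)
  expect_true(all(diff(m$means) > 0))
  expect_equal(sum(m$weights), 1, tolerance = 1e-8)
  # single component: moments
  set.seed(4)
  x <- rnorm(500, 50, 8)
  m1 <- fit_gaussian_mixture(x, 1)
  expect_equal(m1$means, mean(x), tolerance = 0.02 * 50)
  expect_equal(m1$sds, sd(x), tolerance = 0.02 * 8 / 0.02 * 0.02 * 8)
  expect_error(fit_gaussian_mixture(rnorm(5), 3), "insufficient")
})

test_that("histogram-LS agrees with EM on well-separated mixtures", {
  set.seed(6)
  v <- c(rnorm(1500, 10, 1.5), rnorm(1500, 30, 2))
  ls <- fit_gaussian_mixture(v, 2, method = "histls", bin_width = 1)
  em <- fit_gaussian_mixture(v, 2, method = "em")
  expect_lt(max(abs(ls$means - em$means)), 0.5)
  expect_equal(ls$means, c(10, 30), tolerance = 0.05)
  expect_false(ls$degenerate)
})

test_that("posterior classification assigns the published component labels", {
  mix <- structure(list(k = 3, means = c(9.5, 17.4, 30.6),
                        sds = c(3.3, 3.3, 3.7), weights = c(0.3, 0.3, 0.4),
                        method = "em", gof = 0, degenerate = FALSE, n = 1000),
                   class = "mixture_fit")
  ev <- data.frame(dL = c(30.6, 9.5, 17.4, NA), Fmax = c(100, 60, 70, 80),
                   label = "unassigned")
  out <- classify_events(ev, mix)
  expect_identical(out$label, c("FnIII", "IgC2", "IgC2", "unassigned"))
  # a value with equal posterior mass breaks toward FnIII: construct the
  # crossing point of components 2 and 3 numerically
  f <- function(x) 0.3 * dnorm(x, 17.4, 3.3) + 0.3 * dnorm(x, 9.5, 3.3) -
    0.4 * dnorm(x, 30.6, 3.7)
  xc <- uniroot(f, c(20, 30))$root
  out2 <- classify_events(data.frame(dL = xc, Fmax = 1, label = ""), mix)
  expect_identical(out2$label, "FnIII")
  # hard-cut fallback
  out3 <- classify_events(data.frame(dL = c(20, 28), Fmax = 1, label = ""),
                          dl_mixture = NULL, hard_cut = 24)
  expect_identical(out3$label, c("IgC2", "FnIII"))
  expect_error(classify_events(ev, structure(list(k = 1), class = "mixture_fit")),
               "2 components")
})

test_that("hump detector merges scripted two-stage events", {
  # hand-built analysis: a 13 + 17 nm pair completing at higher force
  an <- structure(list(events = data.frame(
    index = 1:3, peak_idx = c(100, 200, 300), sep_peak = c(50, 65, 100),
    Fmax = c(60, 60 / 0.7, 120), Lc = c(60, 73, 90), dL = c(13, 17, 30),
    label = "unassigned"), n_peaks = 3L, detachment_force = 250,
    passes_quality = TRUE, strong_attachment = FALSE, curve_id = "h1"),
    class = "curve_analysis")
  rep <- detect_intermediate_hump(an)
  expect_identical(nrow(rep), 1L)
  expect_equal(rep$location, 13)
  expect_equal(rep$magnitude, 30)
  merged <- merge_hump_events(an, rep)
  expect_identical(nrow(merged$events), 2L)
  expect_true(merged$events$hump[1])
  expect_equal(merged$events$dL[1], 30)
  expect_identical(merged$events$label[1], "FnIII")
  # an intermediate at 11 nm is still caught (inclusive lower bound)
  an$events$dL <- c(11, 19, 30)
  expect_identical(nrow(detect_intermediate_hump(an)), 1L)
  # no report when the completion force is not distinctly higher
  an$events$Fmax <- c(100, 101, 120)
  expect_identical(nrow(detect_intermediate_hump(an)), 0L)
})

test_that("hump round trip on simulated two-stage events", {
  arch <- cntn4_architecture()
  em <- event_model(p_hump = 1, p_partial = 0, p_horseshoe = 0)
  ds <- synthesize_dataset(15, arch, em, sim_config(), seed = 5, pickup = "full")
  an <- analyze_dataset(ds$curves)
  n_merged <- 0
  for (a in an$analyses) {
    rep <- detect_intermediate_hump(a)
    if (!nrow(rep)) next
    m <- merge_hump_events(a, rep)
    ok <- m$events$hump & m$events$dL >= 26 & m$events$dL <= 36
    n_merged <- n_merged + sum(ok)
  }
  # two-stage events whose intermediate tooth survives as a separate peak are
  # recovered as single full-length FnIII events
  expect_gte(n_merged, 10)
})

test_that("plateau detector recovers simulated horseshoe shelves", {
  arch <- cntn4_architecture()
  em <- event_model(p_horseshoe = 1, p_hump = 0, p_partial = 0)
  ds <- synthesize_dataset(25, arch, em, sim_config(), seed = 2, pickup = "full")
  an <- analyze_dataset(ds$curves)
  found <- list()
  for (i in seq_along(ds$curves)) {
    a <- an$analyses[[i]]
    a$events <- classify_events(a$events, hard_cut = 24, dl_mixture = NULL)
    rep <- detect_long_plateau(preprocess(ds$curves[[i]]), a)
    if (nrow(rep)) found[[length(found) + 1L]] <- rep
  }
  pl <- do.call(rbind, found)
  n_scripted <- sum(ds$truth$type == "plateau")
  expect_gte(nrow(pl), 0.5 * n_scripted)
  # the reported mean runs slightly above the 20 pN entry force: the shelf
  # carries a small upward tilt
  expect_equal(mean(pl$magnitude), 20, tolerance = 4 / 20)
  expect_true(all(pl$span >= 30))
  # detected plateaus lie before the true FnIII rupture positions, up to the
  # detector's ~1% false-window rate
  before <- vapply(seq_len(nrow(pl)), function(q) {
    tr <- ds$truth[ds$truth$curve == pl$curve[q], ]
    fnx <- tr$x_rupt[tr$class == "FnIII"]
    !length(fnx) || pl$location[q] < min(fnx)
  }, logical(1))
  expect_gte(mean(before), 0.9)
})

test_that("a shelf placed after FnIII events is reported with an invalid position", {
  cfg <- sim_config(noise_sd = 3)
  # hand-built script: two FnIII teeth, then a plateau (the second release
  # is large enough that the force relaxes below the shelf level, so the
  # shelf renders); the first FnIII tooth has a clean increment before the
  # plateau and must invalidate the position flag
  ev <- data.frame(type = c("rupture", "rupture", "plateau"),
                   class = c("FnIII", "FnIII", "horseshoe"),
                   domain = c("FnIII_1", "FnIII_2", "IgC2_1-4"),
                   dL = c(30, 50, 40),
                   F_rupt = c(80, 110, 20), hump = FALSE, hump_dl = NA_real_,
                   hump_F = NA_real_, partial = FALSE)
  scr <- structure(ev, class = c("unfolding_script", "data.frame"),
                   L0 = 60, detach_force = 200, seed = 1L)
  cur <- synthesize_curve(scr, cfg, seed = 9)
  a <- analyze_curve(cur)
  a$events <- classify_events(a$events, hard_cut = 24, dl_mixture = NULL)
  rep <- detect_long_plateau(preprocess(cur), a)
  expect_gte(nrow(rep), 1)
  expect_false(any(rep$valid_position))
})

test_that("partial-FnIII detector applies window and ordering rules", {
  mk <- function(dL, label) structure(list(
    events = data.frame(index = seq_along(dL), peak_idx = seq_along(dL),
                        sep_peak = cumsum(dL) + 50, Fmax = 80, Lc = cumsum(dL) + 60,
                        dL = dL, label = label),
    n_peaks = length(dL), detachment_force = 250, passes_quality = TRUE,
    strong_attachment = FALSE, curve_id = "p1"), class = "curve_analysis")
  # canonical placement: flagged once, with the count of following FnIII
  a <- mk(c(10, 17, 23.7, 30, 31, 30), c("IgC2", "IgC2", "IgC2", "FnIII", "FnIII", "FnIII"))
  rep <- detect_partial_fniii(a)
  expect_identical(nrow(rep), 1L)
  expect_identical(rep$n_following_fniii, 3L)
  # an IgC2 event after the candidate kills the flag
  b <- mk(c(23.5, 10, 30), c("IgC2", "IgC2", "FnIII"))
  expect_identical(nrow(detect_partial_fniii(b)), 0L)
  # a full FnIII increment is not a partial event
  d <- mk(c(10, 17, 30.6, 30), c("IgC2", "IgC2", "FnIII", "FnIII"))
  expect_identical(nrow(detect_partial_fniii(d)), 0L)
  # more than three following FnIII events kills the flag
  e <- mk(c(23.7, 30, 30, 30, 30), c("IgC2", rep("FnIII", 4)))
  expect_identical(nrow(detect_partial_fniii(e)), 0L)
})

test_that("partial-FnIII round trip flags simulated events", {
  arch <- cntn4_architecture()
  em <- event_model(p_partial = 1, p_hump = 0, p_horseshoe = 0)
  ds <- synthesize_dataset(30, arch, em, sim_config(), seed = 6, pickup = "full")
  an <- analyze_dataset(ds$curves)
  n_one <- 0
  for (a in an$analyses) {
    a$events <- classify_events(a$events, hard_cut = 24, dl_mixture = NULL)
    if (nrow(detect_partial_fniii(a)) >= 1) n_one <- n_one + 1
  }
  # cascades can swallow the partial tooth; at least half the curves retain a
  # detectable, correctly placed partial event
  expect_gte(n_one, 15)
})

test_that("detectors stay quiet on feature-free curves", {
  arch <- cntn4_architecture()
  em0 <- event_model(p_hump = 0, p_partial = 0, p_horseshoe = 0)
  ds <- synthesize_dataset(60, arch, em0, sim_config(), seed = 7)
  an <- analyze_dataset(ds$curves)
  n_plat <- 0; n_part <- 0; n_hump <- 0
  for (i in seq_along(ds$curves)) {
    a <- an$analyses[[i]]
    a$events <- classify_events(a$events, hard_cut = 24, dl_mixture = NULL)
    n_plat <- n_plat + (nrow(detect_long_plateau(preprocess(ds$curves[[i]]), a)) > 0)
    n_part <- n_part + (nrow(detect_partial_fniii(a)) > 0)
    n_hump <- n_hump + (nrow(detect_intermediate_hump(a)) > 0)
  }
  expect_lte(n_plat, 0.05 * 60)   # >= 95% empty (merge-induced flat valleys)
  expect_lte(n_part, 0.15 * 60)   # >= 85% empty (increment-merge mimics)
  # consecutive IgC2 pairs overlap the intermediate window, which bounds the
  # hump detector's specificity
  expect_lte(n_hump, 0.20 * 60)
})

test_that("population_analysis labels events with high accuracy", {
  arch <- cntn4_architecture()
  em0 <- event_model(p_hump = 0, p_partial = 0, p_horseshoe = 0)
  ds <- synthesize_dataset(120, arch, em0, sim_config(), seed = 23)
  an <- analyze_dataset(ds$curves)
  pa <- population_analysis(an$events)
  # evaluate label accuracy on curves where every event was recovered
  n_ok <- 0; n_tot <- 0
  for (a in an$analyses) {
    tr <- ds$truth[ds$truth$curve == a$curve_id, ]
    ev <- pa$events[pa$events$curve == a$curve_id, ]
    if (nrow(ev) != nrow(tr)) next
    keep <- !is.na(ev$dL)
    n_tot <- n_tot + sum(keep)
    n_ok <- n_ok + sum(ev$label[keep] == tr$class[keep])
  }
  expect_gt(n_tot, 250)
  expect_gte(n_ok / n_tot, 0.95)
})
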