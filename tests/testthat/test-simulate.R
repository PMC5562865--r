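test_that("draw_event_sequence yields one event per domain when features are off", {
  arch <- cntn4_architecture()
  em0 <- event_model(p_hump = 0, p_partial = 0, p_horseshoe = 0)
  scr <- draw_event_sequence(arch, em0, seed = 12)
  expect_identical(nrow(scr), 10L)
  expect_true(all(scr$type == "rupture"))
  expect_setequal(scr$domain, arch$domains$name)
  expect_true(all(scr$dL > 0))
  expect_error(draw_event_sequence(arch, em0), "seed")
})

test_that("partial-FnIII events are placed after IgC2 and before other FnIII", {
  arch <- cntn4_architecture()
  em <- event_model(p_partial = 1, p_hump = 0, p_horseshoe = 0)
  for (s in 1:10) {
    scr <- draw_event_sequence(arch, em, seed = s)
    i <- which(scr$partial)
    expect_length(i, 1)
    expect_true(scr$dL[i] >= 23.1 && scr$dL[i] <= 24.4)
    expect_true(all(which(scr$class == "IgC2") < i))
    expect_lte(sum(scr$class == "FnIII") - 1L, 3L)  # at most 3 full FnIII follow
    expect_true(all(which(scr$class == "FnIII" & !scr$partial) > i))
  }
})

test_that("horseshoe plateaus precede every FnIII event", {
  arch <- cntn4_architecture()
  em <- event_model(p_horseshoe = 1, p_hump = 0, p_partial = 0)
  for (s in 1:15) {
    scr <- draw_event_sequence(arch, em, seed = s)
    i <- which(scr$type == "plateau")
    expect_length(i, 1)
    # the weak contacts give way at the first crossing of the shelf force,
    # ahead of every unfolding tooth
    expect_identical(i, 1L)
    expect_true(all(which(scr$class == "FnIII") > i))
    expect_true(scr$dL[i] >= 35 && scr$dL[i] <= 45)
  }
})

test_that("scripted class-conditional draws follow the event model", {
  arch <- cntn4_architecture()
  em <- event_model(p_hump = 0, p_partial = 0, p_horseshoe = 0)
  # Monte-Carlo oracle: empirical FnIII mean over many scripts approaches
  # the configured 30.6 nm (draws truncated at +/-3 sd, clamp 38.8 nm)
  dls <- unlist(lapply(1:300, function(s) {
    scr <- draw_event_sequence(arch, em, seed = 1000 + s)
    scr$dL[scr$class == "FnIII"]
  }))
  se <- sd(dls) / sqrt(length(dls))
  expect_lt(abs(mean(dls) - 30.6), 2 * se + 0.15)  # 0.15 = truncation shift bound
  # IgC2 draws never exceed the architecture's unprotected contour at 0.40 nm/aa
  igs <- unlist(lapply(1:100, function(s) {
    scr <- draw_event_sequence(arch, em, seed = 2000 + s)
    scr$dL[scr$class == "IgC2"]
  }))
  expect_true(all(igs <= max(unprotected_contour(arch, l_aa = 0.40)) + 1e-9))
})

test_that("synthesized curves are deterministic and well-formed", {
  arch <- toy_arch()
  em <- event_model()
  cfg <- sim_config()
  scr <- draw_event_sequence(arch, em, seed = 31)
  c1 <- synthesize_curve(scr, cfg, seed = 32)
  c2 <- synthesize_curve(scr, cfg, seed = 32)
  expect_identical(c1$separation, c2$separation)
  expect_identical(c1$force, c2$force)
  expect_true(all(diff(c1$separation) > 0))
  c3 <- synthesize_curve(scr, cfg, seed = 33)
  expect_false(identical(c1$force, c3$force))
})

test_that("noiseless branches equal the WLC through cantilever compliance", {
  cfg <- sim_config(noise_sd = 0)
  scr <- manual_script(dL = 30, F_rupt = 120, L0 = 60)
  cur <- synthesize_curve(scr, cfg, seed = 1)
  # samples on the first branch must satisfy F = wlc(x; L0) exactly
  p <- wlc_params(Lp = 0.4, Lc = 60)
  first <- cur$separation < 55 & cur$force > 1 & cur$force < 119
  resid <- cur$force[first] - wlc_force(cur$separation[first], p)
  expect_lt(max(abs(resid)), 1e-3)
})

test_that("an empty script gives a detachment-only curve", {
  scr <- manual_script(numeric(0), numeric(0), character(0),
                       L0 = 30, detach_force = 60)
  cur <- synthesize_curve(scr, sim_config(noise_sd = 0), seed = 2)
  expect_true(all(diff(cur$separation) > 0))
  expect_lt(max(cur$force), 60 + 1e-6)
  an <- suppressWarnings(analyze_curve(cur))
  expect_identical(an$n_peaks, 0L)
})

test_that("single-event round trip recovers the scripted increment", {
  cfg <- sim_config(noise_sd = 0)
  scr <- manual_script(dL = 30, F_rupt = 150, L0 = 60)
  cur <- synthesize_curve(scr, cfg, seed = 3)
  an <- analyze_curve(cur)
  expect_identical(an$n_peaks, 1L)
  expect_equal(an$events$dL[1], 30, tolerance = 0.1 / 30)
})

test_that("contour length is conserved through a full unfolding cascade", {
  cfg <- sim_config(noise_sd = 0)
  dls <- c(12, 18, 30, 28)
  scr <- manual_script(dL = dls, F_rupt = c(60, 90, 120, 150), L0 = 60,
                       detach_force = 300)
  cur <- synthesize_curve(scr, cfg, seed = 4)
  an <- analyze_curve(cur)
  # final branch contour length = L0 + sum(dL), via its fitted Lc
  last_ev <- an$events[nrow(an$events), ]
  expect_equal(last_ev$Lc + last_ev$dL, 60 + sum(dls),
               tolerance = 0.005)
})

test_that("dataset generation is reproducible and junk curves fail selection", {
  arch <- cntn4_architecture()
  em <- event_model()
  cfg <- sim_config()
  d1 <- synthesize_dataset(6, arch, em, cfg, seed = 11)
  d2 <- synthesize_dataset(6, arch, em, cfg, seed = 11)
  expect_identical(d1$curves[[3]]$force, d2$curves[[3]]$force)
  expect_identical(d1$truth, d2$truth)

  dj <- synthesize_dataset(40, arch, em, cfg, seed = 13, junk_fraction = 0.5)
  an <- analyze_dataset(dj$curves)
  fl <- filter_curves(an$analyses)
  n_sel <- length(fl$selected_idx)
  # binomial expectation: ~half the curves engage 0-3 domains and fail the
  # >= 4 peak filter
  expect_gt(n_sel, 40 * 0.5 - 3 * sqrt(40 * 0.25))
  expect_lt(n_sel, 40 * 0.5 + 3 * sqrt(40 * 0.25))
})

test_that("Bell-mode rupture forces increase with pulling speed", {
  arch <- toy_arch()
  fmean <- sapply(c(0.1, 1.0), function(v) {
    cfg <- sim_config(v = v, noise_sd = 0, rupture_mode = "bell")
    f <- c()
    for (s in 1:60) {
      scr <- manual_script(dL = 30, F_rupt = NA, L0 = 50, detach_force = 800)
      cur <- synthesize_curve(scr, cfg, seed = 600 + s)
      tr <- attr(cur, "truth")
      f <- c(f, tr$F_achieved)
    }
    mean(f)
  })
  expect_gt(fmean[2], fmean[1])
})
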