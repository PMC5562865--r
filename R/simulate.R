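# Synthetic smAFM data: quasi-static constant-velocity pulling of a
# multidomain chain through a Hookean cantilever.

#' Event model for synthetic unfolding curves
#'
#' Class-conditional distributions and feature probabilities that drive the
#' curve generator. The defaults are the population parameters measured for
#' CNTN4: contour-length increments of IgC2 events drawn from a two-component
#' Gaussian mixture (9.5 +/- 3.3 nm and 17.4 +/- 3.3 nm, reflecting the two
#' sizes of disulfide-free IgC2 segments) and FnIII events from a single
#' Gaussian (30.6 +/- 3.7 nm); rupture forces per class from two-component
#' mixtures (IgC2: 61.0 +/- 12.9 and 95.0 +/- 26.4 pN; FnIII: 79.4 +/- 21.5
#' and 145.0 +/- 48.6 pN). Component weights within a class are not published
#' and default to equal.
#'
#' Optional spectral features: with probability `p_hump` an FnIII event
#' unfolds through a 13-18 nm intermediate (two-stage rupture); with
#' probability `p_partial` the first FnIII module contributes a 23.1-24.4 nm
#' partial-unfolding event placed after all IgC2 events; with probability
#' `p_horseshoe` a near-constant-force plateau (opening of the bent
#' "horseshoe" arrangement of the first IgC2 modules, ~20 pN over 35-45 nm)
#' is inserted before any FnIII event. The default feature rates are low
#' (0.03): each two-stage or compound feature injects increments between the
#' population modes, and the measured increment histogram this generator
#' emulates is cleanly described by the three printed Gaussians, which bounds
#' how often such features can appear as separate saw-teeth. Feature-specific
#' analyses enable them explicitly (probability 1).
#'
#' @param dl_igc2,dl_fniii Lists with `means`, `sds`, `weights` for the
#'   increment mixtures (nm).
#' @param f_igc2,f_fniii Same for rupture forces (pN).
#' @param p_hump,p_partial,p_horseshoe Feature probabilities in `[0, 1]`.
#' @param hump_range Intermediate-stage length range (nm).
#' @param hump_force_frac Range of the intermediate rupture force as a
#'   fraction of the event's full rupture force.
#' @param partial_range Partial-FnIII increment range (nm).
#' @param horseshoe_force Plateau force (pN).
#' @param plateau_range Plateau span range (nm).
#' @param truncate Truncate class-conditional draws at +/- 3 sd and at the
#'   physical clamp limit implied by the architecture (default TRUE).
#' @return An object of class `event_model`.
#' @export
event_model <- function(dl_igc2 = list(means = c(9.5, 17.4), sds = c(3.3, 3.3),
                                       weights = c(0.5, 0.5)),
                        dl_fniii = list(means = 30.6, sds = 3.7, weights = 1),
                        f_igc2 = list(means = c(61, 95), sds = c(12.9, 26.4),
                                      weights = c(0.5, 0.5)),
                        f_fniii = list(means = c(79.4, 145), sds = c(21.5, 48.6),
                                       weights = c(0.5, 0.5)),
                        p_hump = 0.03, p_partial = 0.03, p_horseshoe = 0.03,
                        hump_range = c(13, 18), hump_force_frac = c(0.5, 0.8),
                        partial_range = c(23.1, 24.4),
                        horseshoe_force = 20, plateau_range = c(35, 45),
                        truncate = TRUE) {
  chk <- function(m, what) {
    if (any(m$sds <= 0)) stop(what, ": component sds must be positive")
    if (any(m$weights <= 0) || abs(sum(m$weights) - 1) > 1e-8)
      stop(what, ": weights must be positive and sum to 1")
    if (length(m$means) != length(m$sds) || length(m$means) != length(m$weights))
      stop(what, ": means, sds, weights must have equal length")
  }
  chk(dl_igc2, "dl_igc2"); chk(dl_fniii, "dl_fniii")
  chk(f_igc2, "f_igc2"); chk(f_fniii, "f_fniii")
  for (p in c(p_hump, p_partial, p_horseshoe))
    if (p < 0 || p > 1) stop("feature probabilities must lie in [0, 1]")
  structure(list(dl_igc2 = dl_igc2, dl_fniii = dl_fniii,
                 f_igc2 = f_igc2, f_fniii = f_fniii,
                 p_hump = p_hump, p_partial = p_partial,
                 p_horseshoe = p_horseshoe,
                 hump_range = hump_range, hump_force_frac = hump_force_frac,
                 partial_range = partial_range,
                 horseshoe_force = horseshoe_force,
                 plateau_range = plateau_range,
                 truncate = truncate), class = "event_model")
}

#' Simulator acquisition configuration
#'
#' Instrument-side parameters of the synthetic experiment. Defaults follow
#' the acquisition conditions of the emulated experiment: pulling speed
#' 0.5 um/s and cantilever spring constant 0.02 N/m (= 20 pN/nm), giving a
#' nominal loading rate `k_c * v` of 1e4 pN/s.
#'
#' @param v Pulling speed (um/s).
#' @param k_c Cantilever spring constant (N/m).
#' @param rate Samples per nm of piezo travel (default 10).
#' @param noise_sd Gaussian force noise (pN, default 5).
#' @param rupture_mode `"phenomenological"` (ruptures occur at the scripted
#'   force drawn from the measured mixtures) or `"bell"` (stochastic
#'   Bell-Evans kinetics, `k(F) = k0 exp(F dx / kBT)`).
#' @param k0 Zero-force unfolding rate (1/s), Bell mode.
#' @param dx Distance to the transition state (nm), Bell mode.
#' @param T Temperature (K).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(v = 0.5, k_c = 0.02, rate = 10, noise_sd = 5,
                       rupture_mode = c("phenomenological", "bell"),
                       k0 = 1e-4, dx = 0.4, T = 300) {
  rupture_mode <- match.arg(rupture_mode)
  if (v <= 0 || k_c <= 0 || rate <= 0 || noise_sd < 0)
    stop("'v', 'k_c', 'rate' must be positive and 'noise_sd' non-negative")
  structure(list(v_nm_s = v * 1000, k_pN_nm = k_c * 1000, rate = rate,
                 noise_sd = noise_sd, rupture_mode = rupture_mode,
                 k0 = k0, dx = dx, T = T, kBT = .KB * T),
            class = "sim_config")
}

#' Draw a scripted unfolding event sequence
#'
#' Samples, for each domain of the architecture, an unfolding event
#' (class-conditional contour-length increment and rupture force) and an
#' event order, plus optional spectral features. The order is a random
#' interleaving biased by rupture force (`order = "force_biased"`, default):
#' event rank is the drawn rupture force plus Gaussian jitter, so weak
#' ruptures tend to occur early, reproducing the predominantly
#' short-before-long saw-tooth sequences seen experimentally while still
#' allowing non-sequential interleavings. `order = "random"` gives a uniform
#' shuffle.
#'
#' Placement rules for features: a partial first-FnIII event replaces that
#' module's full event and is placed after every IgC2 event (so at most three
#' full FnIII events follow it); a horseshoe plateau is inserted among the
#' IgC2 events, before any FnIII event, and only when IgC2 modules are
#' engaged.
#'
#' @param arch A `protein_architecture` (possibly a sub-span of the full
#'   molecule when the tip picked up part of the chain).
#' @param em An [event_model()].
#' @param seed Integer seed (required; reproducibility is mandatory).
#' @param order `"force_biased"` or `"random"`.
#' @param order_sd Jitter (pN) of the force-biased ranking.
#' @param detach_force Final detachment force (pN); default draws
#'   `N(60 + 18 n_domains, 35)` floored at 30, so fully stretched molecules
#'   detach under high stress.
#' @return An object of class `unfolding_script`: data.frame of scripted
#'   events (`type`, `class`, `domain`, `dL`, `F_rupt`, hump fields) with
#'   attributes `L0` (initial folded contour length, nm) and `detach_force`.
#' @export
draw_event_sequence <- function(arch, em, seed, order = c("force_biased", "random"),
                                order_sd = 20, detach_force = NULL) {
  stopifnot(inherits(arch, "protein_architecture"), inherits(em, "event_model"))
  if (missing(seed)) stop("a 'seed' is required (reproducibility is mandatory)")
  order <- match.arg(order)
  with_local_seed(seed, {
    d <- arch$domains
    n <- nrow(d)
    is_ig <- d$dclass == "IgC2"
    # physical ceiling on increments: largest unprotected contour in the
    # class, at the upper end of the per-residue gain (0.40 nm/aa)
    clamp_ig <- if (any(is_ig)) max((d$n_res - d$n_protected)[is_ig]) * 0.40 else Inf
    clamp_fn <- if (any(!is_ig)) max(d$n_res[!is_ig]) * 0.40 else Inf

    dL <- numeric(n); Fr <- numeric(n)
    for (i in seq_len(n)) {
      if (is_ig[i]) {
        dL[i] <- draw_mixture(1, em$dl_igc2$means, em$dl_igc2$sds, em$dl_igc2$weights,
                              lower = 1, upper = if (em$truncate) clamp_ig else Inf,
                              trunc_3sd = em$truncate)
        Fr[i] <- draw_mixture(1, em$f_igc2$means, em$f_igc2$sds, em$f_igc2$weights,
                              lower = 5, trunc_3sd = em$truncate)
      } else {
        dL[i] <- draw_mixture(1, em$dl_fniii$means, em$dl_fniii$sds, em$dl_fniii$weights,
                              lower = 1, upper = if (em$truncate) clamp_fn else Inf,
                              trunc_3sd = em$truncate)
        Fr[i] <- draw_mixture(1, em$f_fniii$means, em$f_fniii$sds, em$f_fniii$weights,
                              lower = 5, trunc_3sd = em$truncate)
      }
    }

    ev <- data.frame(type = "rupture", class = d$dclass, domain = d$name,
                     dL = dL, F_rupt = Fr,
                     hump = FALSE, hump_dl = NA_real_, hump_F = NA_real_,
                     partial = FALSE, stringsAsFactors = FALSE)

    # partial unfolding of the first FnIII module
    has_fn1 <- "FnIII_1" %in% d$name
    do_partial <- has_fn1 && any(is_ig) && stats::runif(1) < em$p_partial
    if (do_partial) {
      i1 <- which(d$name == "FnIII_1")
      ev$dL[i1] <- stats::runif(1, em$partial_range[1], em$partial_range[2])
      ev$partial[i1] <- TRUE
    }

    # unfolding intermediates in full FnIII events
    for (i in which(!is_ig & !ev$partial)) {
      if (stats::runif(1) < em$p_hump) {
        hd <- stats::runif(1, em$hump_range[1], em$hump_range[2])
        if (hd < ev$dL[i] - 5) {
          ev$hump[i] <- TRUE
          ev$hump_dl[i] <- hd
          ev$hump_F[i] <- ev$F_rupt[i] *
            stats::runif(1, em$hump_force_frac[1], em$hump_force_frac[2])
        }
      }
    }

    # ordering
    key <- if (order == "force_biased") ev$F_rupt + stats::rnorm(n, 0, order_sd)
           else stats::runif(n)
    if (do_partial) {
      ig_idx <- which(is_ig); fn_idx <- which(!is_ig & !ev$partial)
      ord <- c(ig_idx[order(key[ig_idx])], which(ev$partial),
               fn_idx[order(key[fn_idx])])
    } else {
      ord <- order(key)
    }
    ev <- ev[ord, , drop = FALSE]

    # horseshoe-opening plateau: the ~20 pN interdomain contacts are far
    # weaker than any domain's rupture force, so under quasi-static loading
    # the horseshoe peels open at the first crossing of the shelf force,
    # before any unfolding tooth (and therefore before every FnIII event)
    n_ig <- sum(is_ig)
    if (n_ig > 0 && stats::runif(1) < em$p_horseshoe) {
      plat <- data.frame(type = "plateau", class = "horseshoe", domain = "IgC2_1-4",
                         dL = stats::runif(1, em$plateau_range[1], em$plateau_range[2]),
                         F_rupt = em$horseshoe_force,
                         hump = FALSE, hump_dl = NA_real_, hump_F = NA_real_,
                         partial = FALSE, stringsAsFactors = FALSE)
      ev <- rbind(plat, ev)
    }
    rownames(ev) <- NULL

    if (is.null(detach_force))
      detach_force <- max(30, stats::rnorm(1, 60 + 18 * n, 35))
    structure(ev, class = c("unfolding_script", "data.frame"),
              L0 = folded_contour_length(arch), detach_force = detach_force,
              seed = seed)
  })
}

# Solve the quasi-static force balance F = k (z - x) = wlc(x; Lc) for a
# vector of piezo positions z at fixed contour length, by vectorised
# bisection on x in [0, Lc).
solve_balance <- function(z, Lc, k, Lp, T) {
  if (length(z) == 0L) return(list(x = numeric(0), F = numeric(0)))
  p <- wlc_params(Lp = Lp, Lc = Lc, T = T)
  lo <- rep(0, length(z))
  hi <- pmin(z, Lc * (1 - 1e-9))
  hi[hi < 0] <- 0
  for (it in seq_len(60L)) {
    mid <- 0.5 * (lo + hi)
    g <- k * (z - mid) - wlc_force(mid, p)   # decreasing in x
    pos <- g > 0
    lo[pos] <- mid[pos]
    hi[!pos] <- mid[!pos]
  }
  x <- 0.5 * (lo + hi)
  list(x = x, F = k * (z - x))
}

#' Synthesize one force-extension curve from a script
#'
#' Quasi-static constant-velocity pulling: at every piezo position `z` the
#' tip-sample separation `x` solves the force balance
#' `F = k_c (z - x) = F_WLC(x; Lc)` for the current contour length. When the
#' force reaches the scripted rupture force (phenomenological mode) or a
#' Bell-Evans survival draw fires (kinetic mode), the contour length grows by
#' the scripted increment. Intermediate ("hump") events rupture in two
#' stages; a horseshoe plateau is rendered as a constant-force shelf with a
#' slight upward tilt during which contour length is released continuously.
#' After the final detachment the force falls to baseline. Gaussian noise is
#' added to the force channel only, so separations remain strictly
#' increasing.
#'
#' @param script An [draw_event_sequence()] script.
#' @param cfg A [sim_config()].
#' @param seed Integer seed for noise (and Bell draws).
#' @param Lp Persistence length of the unfolded chain (nm).
#' @return A `force_curve`: list with `separation` (nm), `force` (pN), and
#'   `meta`; attribute `truth` records per-event rupture positions.
#' @export
synthesize_curve <- function(script, cfg, seed, Lp = 0.4) {
  stopifnot(inherits(script, "unfolding_script"), inherits(cfg, "sim_config"))
  if (missing(seed)) stop("a 'seed' is required (reproducibility is mandatory)")
  with_local_seed(seed, {
    dz <- 1 / cfg$rate
    k <- cfg$k_pN_nm
    Lc <- attr(script, "L0")
    detachF <- attr(script, "detach_force")
    z_now <- 0
    xs <- list(); fs <- list()
    truth <- data.frame(event = integer(0), type = character(0),
                        class = character(0), domain = character(0),
                        dL = numeric(0), F_target = numeric(0),
                        F_achieved = numeric(0), x_rupt = numeric(0),
                        stringsAsFactors = FALSE)

    # expand humps into sub-events
    sub <- list()
    for (i in seq_len(nrow(script))) {
      e <- script[i, ]
      if (e$type == "rupture" && isTRUE(e$hump)) {
        s1 <- e; s1$dL <- e$hump_dl; s1$F_rupt <- e$hump_F; s1$type <- "rupture"
        s2 <- e; s2$dL <- e$dL - e$hump_dl
        sub[[length(sub) + 1L]] <- transform(s1, parent = i, stage = 1L)
        sub[[length(sub) + 1L]] <- transform(s2, parent = i, stage = 2L)
      } else {
        sub[[length(sub) + 1L]] <- transform(e, parent = i, stage = 0L)
      }
    }
    sub <- if (length(sub)) do.call(rbind, sub) else NULL

    run_branch <- function(F_stop) {
      # returns z position at which the branch ends (force reaches F_stop,
      # or Bell rupture), appending samples along the way
      if (F_stop >= 0) {
        # deterministic threshold (phenomenological ruptures, plateau entry,
        # detachment): the branch end solves directly for z at the target force
        x_r <- wlc_extension(F_stop, wlc_params(Lp = Lp, Lc = Lc, T = cfg$T))
        z_r <- x_r + F_stop / k
        if (z_r >= z_now + dz) {
          zg <- seq(z_now + dz, z_r, by = dz)
          if (length(zg)) {
            sol <- solve_balance(zg, Lc, k, Lp, cfg$T)
            xs[[length(xs) + 1L]] <<- sol$x
            fs[[length(fs) + 1L]] <<- sol$F
            z_now <<- zg[length(zg)]
          }
        }
        list(F_ach = F_stop, x_r = x_r)
      } else {
        # Bell-Evans kinetics: integrate the hazard along the ramp until an
        # Exp(1) threshold is crossed (force capped at 1200 pN)
        E <- stats::rexp(1)
        cum <- 0
        dt <- dz / cfg$v_nm_s
        repeat {
          zg <- seq(z_now + dz, z_now + 500 * dz, by = dz)
          sol <- solve_balance(zg, Lc, k, Lp, cfg$T)
          haz <- cfg$k0 * exp(sol$F * cfg$dx / cfg$kBT) * dt
          ch <- cum + cumsum(haz)
          idx <- which(ch >= E | sol$F >= 1200)[1]
          if (is.na(idx)) {
            xs[[length(xs) + 1L]] <<- sol$x
            fs[[length(fs) + 1L]] <<- sol$F
            z_now <<- zg[length(zg)]
            cum <- ch[length(ch)]
          } else {
            xs[[length(xs) + 1L]] <<- sol$x[seq_len(idx)]
            fs[[length(fs) + 1L]] <<- sol$F[seq_len(idx)]
            z_now <<- zg[idx]
            return(list(F_ach = sol$F[idx], x_r = sol$x[idx]))
          }
        }
      }
    }

    ei <- 0L
    if (!is.null(sub) && nrow(sub) > 0) for (i in seq_len(nrow(sub))) {
      e <- sub[i, ]
      if (e$type == "plateau") {
        # ride up to the plateau force, then a constant-force shelf with a
        # slight tilt ("not completely flat") spanning e$dL of extension.
        # Contour is released keeping the extension ratio x/Lc constant, so
        # the force stays at the shelf level and the post-plateau branch
        # resumes continuously (releasing only the spanned length would
        # leave the chain taut and snap the separation backwards).
        rb <- run_branch(min(e$F_rupt, detachF))
        span <- e$dL
        st <- solve_balance(z_now, Lc, k, Lp, cfg$T)   # actual entry state
        x_entry <- st$x
        if (st$F > e$F_rupt + 2) {
          # the chain is already above the shelf force (the preceding
          # rupture left it taut): the weak contacts give way at once and
          # the release is instantaneous, with no visible shelf
          Lc <- Lc * (x_entry + span) / x_entry
          ei <- ei + 1L
          truth[nrow(truth) + 1L, ] <- list(ei, "plateau_instant", e$class,
                                            e$domain, span, e$F_rupt, st$F,
                                            x_entry)
        } else {
          zg <- seq(z_now + dz, z_now + span, by = dz)
          tilt <- 0.08  # pN per nm
          fshelf <- e$F_rupt + tilt * (zg - z_now)
          xs[[length(xs) + 1L]] <- zg - fshelf / k
          fs[[length(fs) + 1L]] <- fshelf
          z_now <- zg[length(zg)]
          Lc <- Lc * (x_entry + span) / x_entry
          ei <- ei + 1L
          truth[nrow(truth) + 1L, ] <- list(ei, "plateau", e$class, e$domain,
                                            span, e$F_rupt, e$F_rupt, x_entry)
        }
      } else {
        F_stop <- if (cfg$rupture_mode == "bell") -1 else e$F_rupt
        rb <- run_branch(F_stop)
        Lc <- Lc + e$dL
        ei <- ei + 1L
        truth[nrow(truth) + 1L, ] <- list(ei, if (e$stage == 1L) "hump_stage" else "rupture",
                                          e$class, e$domain, e$dL, e$F_rupt,
                                          rb$F_ach, rb$x_r)
      }
    }

    # final branch up to detachment, then force falls to baseline
    run_branch(detachF)
    n_sofar <- sum(lengths(xs))
    n_tail <- max(200L, ceiling(0.12 * n_sofar))
    zg <- seq(z_now + dz, z_now + n_tail * dz, by = dz)
    xs[[length(xs) + 1L]] <- zg           # zero deflection
    fs[[length(fs) + 1L]] <- rep(0, length(zg))

    separation <- unlist(xs, use.names = FALSE)
    force <- unlist(fs, use.names = FALSE)
    if (any(diff(separation) <= 0))
      stop(sprintf("simulation error: non-increasing separation near z = %.2f nm",
                   separation[which(diff(separation) <= 0)[1]]))
    if (cfg$noise_sd > 0)
      force <- force + stats::rnorm(length(force), 0, cfg$noise_sd)

    curve <- structure(list(
      separation = separation, force = force,
      meta = list(v_nm_s = cfg$v_nm_s, k_c_pN_nm = cfg$k_pN_nm,
                  rate = cfg$rate, noise_sd = cfg$noise_sd, seed = seed,
                  id = paste0("sim_seed", seed),
                  L0 = attr(script, "L0"),
                  detach_force = detachF)),
      class = "force_curve")
    attr(curve, "truth") <- truth
    curve
  })
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf("Force curve '%s': %d samples, separation %.1f-%.1f nm, force up to %.0f pN\n",
              x$meta$id %||% "?", length(x$force), min(x$separation),
              max(x$separation), max(x$force)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Synthesize a dataset of curves with ground truth
#'
#' Batch generation of saw-tooth curves. By default each curve engages a
#' random contiguous span of 4-10 domains of the architecture (the tip picks
#' the molecule up at random points along the chain, so most traces sample
#' part of it), emulating the experimental spread of 4-10 clear unfolding
#' peaks per selected trace. A configurable `junk_fraction` of curves engage
#' only 0-3 domains (non-specific or weak attachments) and fail the
#' downstream >= 4-peak selection.
#'
#' @param n_curves Number of curves (>= 1).
#' @param arch A `protein_architecture`.
#' @param em An [event_model()].
#' @param cfg A [sim_config()].
#' @param seed Integer master seed; per-curve seeds are derived from it.
#' @param junk_fraction Fraction of junk curves (default 0).
#' @param pickup `"span"` (random contiguous 4-10 domain span, default) or
#'   `"full"` (whole molecule every time).
#' @param dir Optional output directory; when given, curves and the truth
#'   table are written as TSV.
#' @return List with `curves` (list of `force_curve`), `truth` (data.frame
#'   keyed by curve id) and `scripts`.
#' @export
synthesize_dataset <- function(n_curves, arch, em, cfg, seed,
                               junk_fraction = 0,
                               pickup = c("span", "full"), dir = NULL) {
  stopifnot(n_curves >= 1)
  pickup <- match.arg(pickup)
  if (missing(seed)) stop("a 'seed' is required (reproducibility is mandatory)")
  plan <- with_local_seed(seed, {
    data.frame(
      seed1 = sample.int(.Machine$integer.max - 1L, n_curves),
      seed2 = sample.int(.Machine$integer.max - 1L, n_curves),
      junk = stats::runif(n_curves) < junk_fraction,
      start = sample.int(nrow(arch$domains), n_curves, replace = TRUE),
      len = sample(4:min(10, nrow(arch$domains)), n_curves, replace = TRUE),
      junk_len = sample(0:3, n_curves, replace = TRUE))
  })
  curves <- vector("list", n_curves)
  scripts <- vector("list", n_curves)
  truth_list <- vector("list", n_curves)
  for (i in seq_len(n_curves)) {
    nd <- nrow(arch$domains)
    if (plan$junk[i]) {
      len <- plan$junk_len[i]
      st <- min(plan$start[i], nd)
      idx <- if (len == 0) integer(0) else seq(st, min(nd, st + len - 1L))
    } else if (pickup == "full") {
      idx <- seq_len(nd)
    } else {
      len <- plan$len[i]
      st <- min(plan$start[i], max(1L, nd - len + 1L))
      idx <- seq(st, min(nd, st + len - 1L))
    }
    sub <- arch
    sub$domains <- arch$domains[idx, , drop = FALSE]
    id <- sprintf("curve_%04d", i)
    if (length(idx) == 0) {
      # no molecular attachment at all: bare baseline trace
      scr <- structure(data.frame(type = character(0), class = character(0),
                                  domain = character(0), dL = numeric(0),
                                  F_rupt = numeric(0), hump = logical(0),
                                  hump_dl = numeric(0), hump_F = numeric(0),
                                  partial = logical(0)),
                       class = c("unfolding_script", "data.frame"),
                       L0 = 20, detach_force = 15, seed = plan$seed1[i])
    } else {
      scr <- draw_event_sequence(sub, em, seed = plan$seed1[i])
    }
    cur <- synthesize_curve(scr, cfg, seed = plan$seed2[i])
    cur$meta$id <- id
    tr <- attr(cur, "truth")
    if (nrow(tr)) tr <- cbind(curve = id, tr, stringsAsFactors = FALSE)
    else tr <- cbind(curve = character(0), tr)
    curves[[i]] <- cur
    scripts[[i]] <- scr
    truth_list[[i]] <- tr
  }
  truth <- do.call(rbind, truth_list)
  rownames(truth) <- NULL
  out <- list(curves = curves, truth = truth, scripts = scripts)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (cur in curves)
      write_curve_file(cur, file.path(dir, paste0(cur$meta$id, ".tsv")))
    utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  out
}
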