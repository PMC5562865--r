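# Inference chain from raw retraction curve to per-event (dL, Fmax):
# baseline correction, rupture detection, branch segmentation, per-branch WLC
# fitting, increment computation, curve-selection filters.

#' Baseline-correct (and optionally smooth) a raw curve
#'
#' Subtracts the force baseline estimated as the median of the final 10% of
#' samples (the contact-free region after detachment). Separations are never
#' touched. Optional moving-median smoothing of the force channel.
#'
#' @param raw A `force_curve` with at least 50 samples.
#' @param smooth Odd moving-median window in samples; 0 (default) disables.
#' @return A corrected `force_curve`.
#' @export
preprocess <- function(raw, smooth = 0) {
  stopifnot(inherits(raw, "force_curve"))
  n <- length(raw$force)
  if (n < 50L) stop("curve too short to preprocess (need >= 50 samples, got ", n, ")")
  tail_idx <- seq.int(floor(n * 0.9) + 1L, n)
  baseline <- stats::median(raw$force[tail_idx])
  out <- raw
  out$force <- raw$force - baseline
  if (smooth > 1) {
    w <- as.integer(smooth); if (w %% 2L == 0L) w <- w + 1L
    out$force <- as.numeric(stats::runmed(out$force, w))
  }
  out$meta$baseline <- baseline
  out
}

#' Detect rupture peaks in a saw-tooth curve
#'
#' A sample is a rupture peak when it is a local maximum of the (lightly
#' median-smoothed) force, its force is at least `min_peak_force`, and the
#' force falls by at least `min_drop` within `window_nm` of piezo travel
#' after it. Lookahead windows are measured in piezo travel (reconstructed
#' from the median sampling step) rather than tip-sample separation, because
#' the separation axis is not uniform: it compresses on steep rising
#' branches and jumps by `dF/k_c` when the cantilever relaxes through a
#' rupture. Candidate clusters closer than `dedup_nm` of travel collapse to
#' the strongest member.
#'
#' @param curve A preprocessed `force_curve`.
#' @param min_drop Minimum force drop (pN, default 10: at the default
#'   5 pN force noise the median-smoothed detection statistic has a standard
#'   deviation near 2.3 pN, so 10 pN is still a >4-sigma drop and produces
#'   no false peaks on featureless noise traces in the test suite; stricter
#'   thresholds censor small-increment events - whose post-rupture force
#'   relaxation shrinks as the contour length grows - and that censoring is
#'   class-asymmetric).
#' @param min_peak_force Minimum pre-drop force (pN, default 30).
#' @param window_nm Piezo-travel window within which the drop must occur (nm).
#' @param local_nm Half-width of the local-maximum neighbourhood (nm of
#'   travel).
#' @param dedup_nm Minimum travel between reported peaks (nm).
#' @return Strictly increasing integer sample indices (possibly empty).
#' @export
detect_ruptures <- function(curve, min_drop = 10, min_peak_force = 30,
                            window_nm = 2, local_nm = 0.5, dedup_nm = 2) {
  stopifnot(inherits(curve, "force_curve"))
  Fs <- as.numeric(stats::runmed(curve$force, 5))
  s <- curve$separation
  n <- length(Fs)
  if (n < 3L) return(integer(0))
  step <- stats::median(diff(s))          # nominal piezo step per sample
  m <- max(3L, ceiling(window_nm / step)) # drop lookahead, samples
  w <- max(2L, ceiling(local_nm / step))  # local-max half-width, samples
  md <- max(3L, ceiling(dedup_nm / step)) # dedup radius, samples
  cand <- which(Fs >= min_peak_force)
  cand <- cand[cand < n]
  if (!length(cand)) return(integer(0))
  keep <- logical(length(cand))
  for (ci in seq_along(cand)) {
    i <- cand[ci]
    lo <- max(1L, i - w); hi <- min(n, i + w)
    if (Fs[i] < max(Fs[lo:hi])) next
    jr <- min(n, i + m)
    if (min(Fs[(i + 1L):jr]) <= Fs[i] - min_drop) keep[ci] <- TRUE
  }
  pk <- cand[keep]
  if (!length(pk)) return(integer(0))
  # collapse clusters of near-coincident candidates to the strongest
  out <- integer(0)
  grp_start <- 1L
  for (gi in seq_along(pk)) {
    if (gi == length(pk) || pk[gi + 1L] - pk[gi] > md) {
      grp <- pk[grp_start:gi]
      out <- c(out, grp[which.max(Fs[grp])])
      grp_start <- gi + 1L
    }
  }
  sort(out)
}

#' Extract unfolding events from detected peaks
#'
#' Fits a WLC branch (persistence length fixed by default) to the rising
#' stretch before every detected peak: samples from the preceding valley
#' (+10 pN) to the peak. Each event's rupture force is the WLC model force at
#' the peak separation; its contour-length increment `dL` is the forward
#' difference of successive branch contour lengths,
#' `dL_i = Lc_(i+1) - Lc_i`, which pairs the increment released by a rupture
#' with the force at which that same rupture occurred. The last detected peak
#' is taken as the tip-detachment event: it supplies the final branch (and
#' hence the last increment) and the detachment force, but is not itself an
#' unfolding event.
#'
#' Branches with fewer than `min_branch_pts` usable points, failed fits, or
#' non-increasing contour lengths yield `NA` increments and a warning.
#'
#' @param curve A preprocessed `force_curve`.
#' @param peaks Indices from [detect_ruptures()].
#' @param Lp Persistence length (nm), fixed during fitting.
#' @param T Temperature (K).
#' @param min_branch_pts Minimum samples per fittable branch (default 5).
#' @return A `curve_analysis`: list with `events` (data.frame: `index`,
#'   `peak_idx`, `sep_peak`, `Fmax`, `Lc`, `dL`, `label`), `n_peaks`,
#'   `detachment_force`, `passes_quality`, `strong_attachment`.
#' @export
extract_events <- function(curve, peaks, Lp = 0.4, T = 300, min_branch_pts = 5L) {
  stopifnot(inherits(curve, "force_curve"))
  s <- curve$separation; f <- curve$force
  Fs <- as.numeric(stats::runmed(f, 5))
  M <- length(peaks)
  empty <- data.frame(index = integer(0), peak_idx = integer(0),
                      sep_peak = numeric(0), Fmax = numeric(0),
                      Lc = numeric(0), dL = numeric(0),
                      label = character(0), stringsAsFactors = FALSE)
  if (M == 0L)
    return(structure(list(events = empty, n_peaks = 0L,
                          detachment_force = NA_real_, passes_quality = FALSE,
                          strong_attachment = FALSE, curve_id = curve$meta$id %||% NA),
                     class = "curve_analysis"))

  Lc <- rep(NA_real_, M); Fm <- rep(NA_real_, M)
  prev_end <- 1L
  for (b in seq_len(M)) {
    p <- peaks[b]
    vr <- prev_end:p
    valley <- vr[which.min(Fs[vr])]
    thr <- Fs[valley] + 10
    idx <- valley:p
    idx <- idx[Fs[idx] >= thr]
    # keep the contiguous run ending at the peak
    if (length(idx)) {
      brk <- which(diff(idx) > 1L)
      if (length(brk)) idx <- idx[(max(brk) + 1L):length(idx)]
    }
    if (length(idx) >= min_branch_pts && sum(f[idx] > 10) >= min_branch_pts) {
      ft <- tryCatch(fit_wlc_segment(s[idx], f[idx], Lp_mode = "fixed", Lp = Lp, T = T),
                     error = function(e) NULL)
      if (!is.null(ft) && ft$converged) {
        Lc[b] <- ft$params$Lc
        Fm[b] <- wlc_force(min(s[p], ft$params$Lc * (1 - 1e-9)), ft$params)
      }
    }
    if (is.na(Fm[b])) Fm[b] <- Fs[p]
    prev_end <- p + 1L
  }

  if (any(is.na(Lc)))
    warning(sprintf("curve %s: %d of %d branches could not be WLC-fitted",
                    curve$meta$id %||% "?", sum(is.na(Lc)), M))

  # collapse duplicate detections of one rupture: two peaks whose branch
  # contour lengths differ by less than min_dl bracket a stub branch, not a
  # real unfolding step; keep the first (full) branch and the stronger force
  min_dl <- 1.5
  repeat {
    if (length(peaks) < 2L) break
    dup <- which(!is.na(Lc[-1]) & !is.na(Lc[-length(Lc)]) &
                   (Lc[-1] - Lc[-length(Lc)]) < min_dl)
    if (!length(dup)) break
    i <- dup[1]
    Fm[i] <- max(Fm[i], Fm[i + 1L], na.rm = TRUE)
    peaks <- peaks[-(i + 1L)]
    Lc <- Lc[-(i + 1L)]
    Fm <- Fm[-(i + 1L)]
  }
  M <- length(peaks)

  if (M >= 2L) {
    ev_idx <- seq_len(M - 1L)
    dL <- Lc[ev_idx + 1L] - Lc[ev_idx]
    bad <- which(!is.na(dL) & dL <= 0)
    if (length(bad)) {
      warning(sprintf("curve %s: %d non-increasing contour-length increment(s) set to NA",
                      curve$meta$id %||% "?", length(bad)))
      dL[bad] <- NA_real_
    }
    events <- data.frame(index = ev_idx, peak_idx = peaks[ev_idx],
                         sep_peak = s[peaks[ev_idx]], Fmax = Fm[ev_idx],
                         Lc = Lc[ev_idx], dL = dL,
                         label = "unassigned", stringsAsFactors = FALSE)
  } else {
    events <- empty
  }
  n_peaks <- M - 1L
  detach <- Fm[M]
  structure(list(events = events, n_peaks = n_peaks,
                 detachment_force = detach,
                 passes_quality = n_peaks >= 4L,
                 strong_attachment = (n_peaks >= 7L && n_peaks <= 10L && isTRUE(detach >= 150)),
                 curve_id = curve$meta$id %||% NA),
            class = "curve_analysis")
}

#' @export
print.curve_analysis <- function(x, ...) {
  cat(sprintf("Curve analysis '%s': %d unfolding peaks, detachment %.0f pN%s%s\n",
              x$curve_id, x$n_peaks, x$detachment_force,
              if (isTRUE(x$passes_quality)) ", passes quality" else "",
              if (isTRUE(x$strong_attachment)) ", strong attachment" else ""))
  if (nrow(x$events)) print(x$events, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Analyze one curve end to end
#'
#' [preprocess()] then [detect_ruptures()] then [extract_events()] with
#' shared defaults.
#'
#' @param curve Raw `force_curve`.
#' @param ... Passed to the stages (`smooth`, `min_drop`, `min_peak_force`,
#'   `Lp`, `T`).
#' @return A `curve_analysis`.
#' @export
analyze_curve <- function(curve, smooth = 0, min_drop = 10, min_peak_force = 30,
                          Lp = 0.4, T = 300) {
  cu <- preprocess(curve, smooth = smooth)
  pk <- detect_ruptures(cu, min_drop = min_drop, min_peak_force = min_peak_force)
  extract_events(cu, pk, Lp = Lp, T = T)
}

#' Analyze a set of curves
#'
#' @param curves List of raw `force_curve` objects.
#' @inheritParams analyze_curve
#' @return List with `analyses` (list of `curve_analysis`) and `events`
#'   (combined data.frame with a `curve` id column).
#' @export
analyze_dataset <- function(curves, smooth = 0, min_drop = 10,
                            min_peak_force = 30, Lp = 0.4, T = 300) {
  analyses <- lapply(curves, function(cu)
    suppressWarnings(analyze_curve(cu, smooth = smooth, min_drop = min_drop,
                                   min_peak_force = min_peak_force, Lp = Lp, T = T)))
  ev <- do.call(rbind, lapply(analyses, function(a) {
    if (nrow(a$events) == 0) return(NULL)
    cbind(curve = a$curve_id, a$events, stringsAsFactors = FALSE)
  }))
  if (is.null(ev))
    ev <- data.frame(curve = character(0), index = integer(0), peak_idx = integer(0),
                     sep_peak = numeric(0), Fmax = numeric(0), Lc = numeric(0),
                     dL = numeric(0), label = character(0))
  rownames(ev) <- NULL
  list(analyses = analyses, events = ev)
}

#' Curve-selection filters
#'
#' Mirrors the experimental data curation: `selected` keeps curves showing at
#' least `min_peaks` clear unfolding maxima (default 4); `strong` further
#' keeps curves with 7-10 peaks and a high final detachment force, the
#' signature of a molecule stretched between its termini.
#'
#' @param analyses List of `curve_analysis` objects.
#' @param min_peaks Selection threshold (default 4).
#' @param strong_range Peak-count range of the strong-attachment subset.
#' @param strong_detach Detachment-force threshold (pN, default 150).
#' @return List with `selected` and `strong` (lists of `curve_analysis`,
#'   flags updated) and index vectors `selected_idx`, `strong_idx`.
#' @export
filter_curves <- function(analyses, min_peaks = 4L, strong_range = c(7L, 10L),
                          strong_detach = 150) {
  np <- vapply(analyses, function(a) as.numeric(a$n_peaks), numeric(1))
  det <- vapply(analyses, function(a) as.numeric(a$detachment_force), numeric(1))
  sel <- which(np >= min_peaks)
  str <- which(np >= strong_range[1] & np <= strong_range[2] &
                 !is.na(det) & det >= strong_detach)
  str <- intersect(str, sel)
  upd <- lapply(seq_along(analyses), function(i) {
    a <- analyses[[i]]
    a$passes_quality <- i %in% sel
    a$strong_attachment <- i %in% str
    a
  })
  list(selected = upd[sel], strong = upd[str],
       selected_idx = sel, strong_idx = str, analyses = upd)
}
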