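#' Detect hoof-on / hoof-off events from calibrated limb IMU signals
#'
#' Stand-in detector: hoof-on is the time of the peak of the merged
#' acceleration magnitude above `on_threshold` (impact transient) within each
#' supra-threshold cluster; hoof-off is the first upcross of the sagittal
#' angular rate above `off_threshold` after the stance settles (start of the
#' swing wave). Alternation is enforced by post-filtering: ons without a
#' following off before the next on are dropped.
#'
#' @param t timestamps, s.
#' @param limb_gyro n x 3 bias-compensated angular rate, dps.
#' @param limb_accel n x 3 merged calibrated acceleration, g (or a
#'   `merged_acceleration`).
#' @param on_threshold impact magnitude threshold, g.
#' @param off_threshold swing angular-rate threshold, dps.
#' @param min_stance minimum delay after hoof-on before searching for the
#'   swing onset, s.
#' @return list with `on` and `off` vectors, strictly alternating.
#' @export
detect_limb_events <- function(t, limb_gyro, limb_accel, on_threshold = 4,
                               off_threshold = 50, min_stance = 0.15) {
  if (inherits(limb_accel, "merged_acceleration")) limb_accel <- limb_accel$accel
  mag <- sqrt(rowSums(as.matrix(limb_accel)^2))
  hot <- which(mag > on_threshold)
  if (length(hot) == 0) stopf("no impact transients found: fewer than 2 strides detectable")
  # cluster supra-threshold samples separated by > 50 ms
  brk <- c(0, which(diff(t[hot]) > 0.05), length(hot))
  ons <- vapply(seq_len(length(brk) - 1), function(i) {
    idx <- hot[(brk[i] + 1):brk[i + 1]]
    t[idx[which.max(mag[idx])]]
  }, numeric(1))
  gy <- as.matrix(limb_gyro)[, 2]
  up <- which(gy[-1] >= off_threshold & gy[-length(gy)] < off_threshold)
  t_up <- t[up + 1]
  offs <- numeric(0); kept_ons <- numeric(0)
  for (i in seq_along(ons)) {
    lim <- if (i < length(ons)) ons[i + 1] else Inf
    cand <- t_up[t_up >= ons[i] + min_stance & t_up < lim]
    if (length(cand)) {
      kept_ons <- c(kept_ons, ons[i])
      offs <- c(offs, cand[1])
    }
  }
  if (length(kept_ons) < 3 || length(offs) < 2) {
    stopf("fewer than 2 strides detectable")
  }
  list(on = kept_ons, off = offs)
}

#' Build the hoof-event table of a processed trial
#'
#' @param trial a `trial_recording` processed with [process_trial()].
#' @param source `"detector"` (run [detect_limb_events()] on each limb node)
#'   or `"truth"` (use the simulator's ground-truth events).
#' @param ... passed to [detect_limb_events()].
#' @return list of class `hoof_event_table`: per limb `on`/`off` vectors plus
#'   a `source` attribute.
#' @export
detect_hoof_events <- function(trial, source = c("detector", "truth"), ...) {
  source <- match.arg(source)
  ev <- if (source == "truth") {
    trial$events
  } else {
    assert_that(!is.null(trial$proc), "trial must be processed first")
    stats::setNames(lapply(grf_limbs(), function(limb) {
      detect_limb_events(trial$proc$t, trial$proc$nodes[[limb]]$gyro,
                         trial$proc$nodes[[limb]]$acc, ...)
    }), grf_limbs())
  }
  for (limb in grf_limbs()) {
    e <- ev[[limb]]
    m <- min(length(e$on), length(e$off))
    assert_that(all(diff(c(rbind(e$on[seq_len(m)], e$off[seq_len(m)]))) > 0),
                "events must strictly alternate for limb %s", limb)
  }
  structure(ev, class = "hoof_event_table", source = source)
}

# internal: complete stance intervals of one limb within [start, end]
complete_stances <- function(events, start, end, tol = 1e-9) {
  m <- min(length(events$on), length(events$off))
  on <- events$on[seq_len(m)]; off <- events$off[seq_len(m)]
  keep <- on >= start - tol & off <= end + tol
  data.frame(on = on[keep], off = off[keep])
}

# internal: does the limb have a complete swing followed by a complete stance
# inside [start, end]? (the walk completeness rule)
has_swing_stance_pair <- function(ev, start, end, tol = 1e-9) {
  m <- min(length(ev$on), length(ev$off))
  on <- ev$on[seq_len(m)]; off <- ev$off[seq_len(m)]
  for (j in seq_len(m - 1)) {
    if (off[j] >= start - tol && on[j + 1] <= end + tol &&
        off[j + 1] <= end + tol) {
      return(TRUE)  # swing (off_j, on_{j+1}) then stance (on_{j+1}, off_{j+1})
    }
  }
  FALSE
}

# internal: window validity; trot = exactly one complete stance per limb
# (the swing is the wrapped complement of the single-stride window), walk =
# a complete swing-then-stance pair per limb
window_valid <- function(events, start, end, gait) {
  all(vapply(grf_limbs(), function(limb) {
    if (gait == "trot") {
      nrow(complete_stances(events[[limb]], start, end)) == 1
    } else {
      has_swing_stance_pair(events[[limb]], start, end)
    }
  }, logical(1)))
}

new_stride_window <- function(events, start, end, gait) {
  stances <- stats::setNames(lapply(grf_limbs(), function(limb) {
    complete_stances(events[[limb]], start, end)
  }), grf_limbs())
  # stance of interest: the latest complete stance of each limb
  soi <- stats::setNames(lapply(stances, function(tab) {
    tab[which.max(tab$on), , drop = FALSE]
  }), grf_limbs())
  structure(list(start = start, end = end, gait = gait, stances = stances,
                 stance_of_interest = soi),
            class = "stride_window")
}

#' Cut walk stride windows
#'
#' Each window runs from a left-hind hoof-off to the earliest subsequent
#' right-front hoof-off such that the window contains, for every limb, one
#' full swing phase followed by its complete stance phase (the limb's stance
#' of interest); candidate windows failing that completeness check are
#' dropped, not repaired. Windows are half-open `[start, end)`; a stance
#' ending exactly at the boundary belongs to the window.
#'
#' @param events a `hoof_event_table` (or compatible per-limb list).
#' @param max_span maximum window span in units of the median stride duration.
#' @param verbose message the number of dropped candidates (always recorded
#'   in the `n_dropped` attribute; trailing hoof-offs near the end of a
#'   recording routinely lack a completing window and are counted too).
#' @return list of `stride_window` objects (possibly empty).
#' @export
window_walk <- function(events, max_span = 2.5, verbose = FALSE) {
  lh_off <- events$LH$off
  if (length(lh_off) < 2) return(list())
  Tmed <- stats::median(diff(events$LH$on))
  out <- list()
  dropped <- 0L
  for (start in lh_off) {
    ends <- events$RF$off[events$RF$off > start &
                            events$RF$off <= start + max_span * Tmed]
    found <- FALSE
    for (end in ends) {
      if (window_valid(events, start, end, "walk")) {
        out[[length(out) + 1]] <- new_stride_window(events, start, end, "walk")
        found <- TRUE
        break
      }
    }
    if (!found) dropped <- dropped + 1L
  }
  if (dropped > 0 && verbose) {
    message(sprintf(
      "window_walk: dropped %d candidate window(s) without a complete swing-stance pair for every limb",
      dropped))
  }
  attr(out, "n_dropped") <- dropped
  out
}

#' Cut trot stride windows
#'
#' Each window runs from a left-hind hoof-off to the next left-hind hoof-off
#' (exactly one stride, so consecutive windows tile the trial), validated to
#' contain one complete stance per limb; diagonal-pair onset synchrony is
#' inherited from the events.
#'
#' @inheritParams window_walk
#' @return list of `stride_window` objects (possibly empty).
#' @export
window_trot <- function(events, verbose = FALSE) {
  lh_off <- events$LH$off
  if (length(lh_off) < 2) return(list())
  out <- list()
  dropped <- 0L
  for (i in seq_len(length(lh_off) - 1)) {
    start <- lh_off[i]; end <- lh_off[i + 1]
    if (window_valid(events, start, end, "trot")) {
      out[[length(out) + 1]] <- new_stride_window(events, start, end, "trot")
    } else {
      dropped <- dropped + 1L
    }
  }
  if (dropped > 0 && verbose) {
    message(sprintf(
      "window_trot: dropped %d stride(s) without exactly one complete stance per limb",
      dropped))
  }
  attr(out, "n_dropped") <- dropped
  out
}

#' Segment a processed trial into stride windows
#'
#' @param trial processed `trial_recording`.
#' @param events optional pre-computed event table; defaults to the detector.
#' @param ... passed to [detect_hoof_events()].
#' @return list of `stride_window`s, each annotated with the trial's horse id,
#'   gait and speed.
#' @export
segment_trial <- function(trial, events = NULL, ...) {
  events <- events %||% detect_hoof_events(trial, ...)
  wins <- if (trial$gait_params$gait == "walk") window_walk(events)
          else window_trot(events)
  lapply(wins, function(w) {
    w$horse_id <- trial$horse$horse_id
    w$speed <- trial$gait_params$speed
    w
  })
}
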