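#' Detect stance and swing onsets from the pendulum-angle trace
#'
#' The limb behaves as a pendulum about the hip: touch-down occurs at
#' maximal protraction (local maximum of the anterior-positive pendulum
#' angle) and lift-off at maximal retraction (local minimum). The trace is
#' smoothed with a centered moving average, local extrema are located, and
#' extrema closer together than `min_half_cycle_ms` are suppressed keeping
#' the more extreme value; alternation (exactly one swing onset between two
#' stance onsets) is then enforced.
#'
#' @param angles tibble from [compute_angles()] (needs `frame` and
#'   `pendulum_deg`).
#' @param fps frame rate (frames per second).
#' @param smooth_window centered moving-average width in frames (odd;
#'   default 5).
#' @param min_half_cycle_ms shortest admissible interval between successive
#'   extrema, in milliseconds (default 60, about half the shortest swing
#'   durations seen in treadmill locomotion at this scale).
#' @return tibble with columns `frame` and
#'   `event` (`"stance_onset"`/`"swing_onset"`), ordered by frame.
#' @export
detect_transitions <- function(angles, fps, smooth_window = 5,
                               min_half_cycle_ms = 60) {
  y <- angles$pendulum_deg
  n <- length(y)
  if (n < 3 * smooth_window || n < 10) {
    abort("Pendulum series too short for transition detection.",
          class = "gaitloop_error_insufficient_data")
  }
  if (fps <= 0) abort("`fps` must be positive.", class = "gaitloop_error_value")
  # centered moving average; edges fall back to the raw trace
  if (smooth_window > 1) {
    k <- rep(1 / smooth_window, smooth_window)
    ys <- as.numeric(stats::filter(y, k, sides = 2))
    ys[is.na(ys)] <- y[is.na(ys)]
  } else {
    ys <- y
  }
  d <- diff(ys)
  sgn <- sign(d)
  # carry the last nonzero slope sign through plateaus
  nz <- sgn != 0
  if (!any(nz)) {
    abort("Pendulum trace is constant; no gait events.",
          class = "gaitloop_error_insufficient_data")
  }
  idx <- cumsum(nz)
  idx[idx == 0] <- 1
  sgn_f <- sgn[nz][idx]
  turns <- which(diff(sgn_f) != 0) + 1
  type <- ifelse(sgn_f[turns - 1] > 0, "stance_onset", "swing_onset")
  ev <- tibble::tibble(pos = turns, type = type, val = ys[turns])
  min_gap <- max(1L, round(min_half_cycle_ms / 1000 * fps))
  med <- stats::median(ys)
  # suppress extrema packed tighter than the minimum half-cycle, keeping the
  # one deviating most from the trace median
  repeat {
    if (nrow(ev) < 2) break
    gaps <- diff(ev$pos)
    j <- which(gaps < min_gap)
    if (length(j) == 0) break
    j <- j[1]
    drop <- if (abs(ev$val[j] - med) < abs(ev$val[j + 1] - med)) j else j + 1
    ev <- ev[-drop, ]
  }
  # enforce alternation: of consecutive same-type extrema keep the more extreme
  repeat {
    if (nrow(ev) < 2) break
    same <- which(ev$type[-1] == ev$type[-nrow(ev)])
    if (length(same) == 0) break
    j <- same[1]
    keep_first <- if (ev$type[j] == "stance_onset") {
      ev$val[j] >= ev$val[j + 1]
    } else {
      ev$val[j] <= ev$val[j + 1]
    }
    ev <- ev[-(if (keep_first) j + 1 else j), ]
  }
  if (sum(ev$type == "stance_onset") < 1 || nrow(ev) < 2) {
    abort("Too few gait events detected.",
          class = "gaitloop_error_insufficient_data")
  }
  # refine each extremum on the raw trace: smoothing biases the extrema of
  # an asymmetric wave toward its slow flank, the raw argmax/argmin in a
  # window around the smoothed extremum is unbiased
  w <- max(2L, smooth_window %/% 2L + 1L)
  ev$pos <- purrr::map2_int(ev$pos, ev$type, function(p, ty) {
    lo <- max(1L, p - w)
    hi <- min(n, p + w)
    win <- y[lo:hi]
    lo - 1L + if (ty == "stance_onset") which.max(win) else which.min(win)
  })
  ev <- ev[order(ev$pos), ]
  ev <- ev[!duplicated(ev$pos), ]
  ev <- ev[c(TRUE, ev$type[-1] != ev$type[-nrow(ev)]), ]
  tibble::tibble(frame = angles$frame[ev$pos], event = ev$type)
}

#' Label every frame stance, swing or abnormal
#'
#' Frames in `[stance_onset, swing_onset)` are stance; frames in
#' `[swing_onset, next stance_onset)` are swing; frames before the first or
#' after the last detected transition are abnormal, and any frame whose
#' likelihood gate failed (`valid = FALSE`) is abnormal regardless of phase.
#' Frames are also assigned a `cycle_id` (stance onset to next stance
#' onset); frames outside any complete cycle get `NA`.
#'
#' @param angles tibble from [compute_angles()].
#' @param transitions tibble from [detect_transitions()].
#' @return tibble with columns `frame`, `label` (factor
#'   stance/swing/abnormal), `cycle_id`.
#' @export
label_frames <- function(angles, transitions) {
  fr <- angles$frame
  lab <- rep("abnormal", length(fr))
  ev <- transitions[order(transitions$frame), ]
  for (i in seq_len(nrow(ev) - 1)) {
    lo <- ev$frame[i]
    hi <- ev$frame[i + 1]
    phase <- if (ev$event[i] == "stance_onset") "stance" else "swing"
    lab[fr >= lo & fr < hi] <- phase
  }
  lab[!angles$valid] <- "abnormal"
  st <- ev$frame[ev$event == "stance_onset"]
  cyc <- rep(NA_integer_, length(fr))
  if (length(st) >= 2) {
    for (k in seq_len(length(st) - 1)) {
      cyc[fr >= st[k] & fr < st[k + 1]] <- k
    }
  }
  tibble::tibble(frame = fr,
                 label = factor(lab, levels = c("stance", "swing",
                                                "abnormal")),
                 cycle_id = cyc)
}

#' Segment labeled frames into gait cycles
#'
#' One cycle per consecutive stance-onset pair (stance precedes swing within
#' a cycle). Durations are frame counts times `1000 / fps`. A cycle fails QC
#' (`qc_pass = FALSE`) if any frame inside it is labeled abnormal — e.g. a
#' landmark likelihood dropped below the gate.
#'
#' @param labels tibble from [label_frames()].
#' @param transitions tibble from [detect_transitions()].
#' @param fps frame rate (frames per second).
#' @return tibble with one row per cycle: `cycle_id`, `stance_onset`,
#'   `swing_onset`, `end`, `stance_ms`, `swing_ms`, `cycle_ms`, `qc_pass`.
#' @export
segment_cycles <- function(labels, transitions, fps) {
  ev <- transitions[order(transitions$frame), ]
  st <- ev$frame[ev$event == "stance_onset"]
  sw <- ev$frame[ev$event == "swing_onset"]
  if (length(st) < 2) {
    abort("Need at least two stance onsets to segment cycles.",
          class = "gaitloop_error_insufficient_data")
  }
  out <- purrr::map_dfr(seq_len(length(st) - 1), function(k) {
    s0 <- st[k]
    s1 <- st[k + 1]
    mid <- sw[sw > s0 & sw < s1]
    if (length(mid) != 1) return(NULL)
    inside <- labels$frame >= s0 & labels$frame < s1
    tibble::tibble(
      cycle_id = k,
      stance_onset = s0, swing_onset = mid, end = s1,
      stance_ms = (mid - s0) * 1000 / fps,
      swing_ms = (s1 - mid) * 1000 / fps,
      cycle_ms = (s1 - s0) * 1000 / fps,
      qc_pass = !any(labels$label[inside] == "abnormal")
    )
  })
  out
}

#' Label a session end to end
#'
#' Convenience wrapper chaining [compute_angles()], [detect_transitions()],
#' [label_frames()] and [segment_cycles()].
#'
#' @param session a `gait_session`.
#' @param likelihood_threshold likelihood gate (default 0.8).
#' @param ... passed to [detect_transitions()].
#' @return list with tibbles `angles`, `transitions`, `labels`, `cycles`.
#' @export
label_session <- function(session, likelihood_threshold = 0.8, ...) {
  fps <- session_fps(session)
  angles <- compute_angles(session, likelihood_threshold)
  transitions <- detect_transitions(angles, fps, ...)
  labels <- label_frames(angles, transitions)
  cycles <- segment_cycles(labels, transitions, fps)
  list(angles = angles, transitions = transitions, labels = labels,
       cycles = cycles)
}
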