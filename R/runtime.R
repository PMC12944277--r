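#' Streaming closed-loop simulation
#'
#' Replays a session through the full closed loop, frame by frame with no
#' lookahead: joint angles are computed, encoded as 21-byte ASCII serial
#' frames, decoded on the receiving side (two-decimal wire precision;
#' malformed or out-of-range frames are logged as drops and the previous
#' state persists), classified by the MLP, debounced by the phase machine,
#' and both stimulation channels are scheduled from the resulting state
#' timeline. Transition detection from the pendulum angle is deliberately
#' not used here — at runtime the classifier alone drives the state, as in
#' deployment; pendulum-based labeling is the offline training-set path.
#'
#' @param session a `gait_session` (or a `gait_sim`, whose session is
#'   used).
#' @param model a trained `gait_mlp`.
#' @param config a [stim_config()].
#' @param debounce_frames phase-machine debounce (default 2).
#' @param baud serial line rate for the analytic latency budget (default
#'   115200).
#' @return list: `ticks` (per-frame tibble: frame, decoded angles,
#'   posteriors, state, lines, dropped flag, n_pulses started that frame),
#'   `trains` (stance/swing `stim_train`s), `summary` (one-row tibble with
#'   phase counts, drop count and the analytic serial latency in ms).
#' @export
run_stream <- function(session, model, config = stim_config(),
                       debounce_frames = 2, baud = 115200) {
  if (inherits(session, "gait_sim")) session <- session$session
  fps <- session_fps(session)
  angles <- compute_angles(session)
  n <- nrow(angles)
  # serial codec round trip, one frame at a time; out-of-range or
  # non-finite angles become dropped frames rather than errors
  dec <- matrix(NA_real_, n, 3)
  dropped <- logical(n)
  for (i in seq_len(n)) {
    a <- c(angles$hip_deg[i], angles$knee_deg[i], angles$ankle_deg[i])
    ok <- tryCatch({
      dec[i, ] <- decode_angle_frame(encode_angle_frame(a[1], a[2], a[3]))
      TRUE
    }, error = function(e) FALSE)
    dropped[i] <- !ok
  }
  post <- matrix(NA_real_, n, 3)
  keep <- which(!dropped)
  if (length(keep) > 0) {
    pr <- predict(model, matrix(dec[keep, ], ncol = 3))
    post[keep, ] <- as.matrix(pr[, c("p_stance", "p_swing", "p_abnormal")])
  }
  state <- phase_state_init()
  st <- character(n)
  stance_line <- logical(n)
  swing_line <- logical(n)
  for (i in seq_len(n)) {
    if (!dropped[i]) {
      state <- update_state(state, post[i, ], debounce_frames)
    }
    st[i] <- state$current
    stance_line[i] <- state$stance_line
    swing_line[i] <- state$swing_line
  }
  timeline <- tibble::tibble(state = factor(st, levels = PHASE_LEVELS))
  trains <- list(
    stance = schedule_train(timeline, fps, config, "stance"),
    swing = schedule_train(timeline, fps, config, "swing")
  )
  frame_t <- (seq_len(n) - 1) / fps
  pulse_count <- function(tr) {
    findInterval(tr$onset_s, c(frame_t, n / fps))
  }
  n_pulses <- tabulate(c(pulse_count(trains$stance),
                         pulse_count(trains$swing)), nbins = n)
  ticks <- tibble::tibble(
    frame = angles$frame,
    hip_deg = dec[, 1], knee_deg = dec[, 2], ankle_deg = dec[, 3],
    p_stance = post[, 1], p_swing = post[, 2], p_abnormal = post[, 3],
    state = factor(st, levels = PHASE_LEVELS),
    stance_line = stance_line, swing_line = swing_line,
    dropped = dropped, n_pulses = n_pulses
  )
  serial_ms <- serial_transmission_time(21, baud)
  summary <- tibble::tibble(
    n_frames = n,
    n_dropped = sum(dropped),
    n_stance = sum(st == "stance"),
    n_swing = sum(st == "swing"),
    n_abnormal = sum(st == "abnormal"),
    n_pulses_stance = nrow(trains$stance),
    n_pulses_swing = nrow(trains$swing),
    serial_latency_ms = serial_ms
  )
  list(ticks = ticks, trains = trains, summary = summary)
}
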