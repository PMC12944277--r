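#' Stimulation configuration
#'
#' Parameters of the charge-balanced biphasic pulse generator: each pulse
#' is a negative phase followed by a positive phase of equal width
#' (`phase_width_us` each, default 200 us), repeated at `frequency_hz`
#' (default 100 Hz) while the triggering gait phase persists. Amplitude is
#' expressed in 12-bit DAC quantization levels (4096 levels, 0-4095).
#' Waveforms are synthesized on a discrete grid (`sample_rate_hz`, default
#' 1 MHz so a 200 us phase is exactly 200 samples).
#'
#' @param phase_width_us width of each pulse phase in microseconds.
#' @param frequency_hz pulse repetition rate in Hz.
#' @param amplitude_level DAC amplitude, integer in 0-4095.
#' @param sample_rate_hz synthesis grid rate in Hz.
#' @param burst_mode `"phase_locked"` (pulses continue at `frequency_hz`
#'   for the duration of the detected phase) or `"fixed_duration"`.
#' @param burst_duration_s burst length for `"fixed_duration"` mode.
#' @param onset_delay_us delay from phase onset to the first pulse.
#' @return a `stim_config` list.
#' @export
stim_config <- function(phase_width_us = 200, frequency_hz = 100,
                        amplitude_level = 1000, sample_rate_hz = 1e6,
                        burst_mode = c("phase_locked", "fixed_duration"),
                        burst_duration_s = 0.1, onset_delay_us = 0) {
  burst_mode <- match.arg(burst_mode)
  if (amplitude_level < 0 || amplitude_level > 4095) {
    abort("`amplitude_level` must be in 0-4095 (4096 DAC levels).",
          class = "gaitloop_error_range")
  }
  if (2 * phase_width_us * 1e-6 > 1 / frequency_hz) {
    abort("Pulse (2 x phase_width) does not fit in one period.",
          class = "gaitloop_error_config")
  }
  if (phase_width_us <= 0 || frequency_hz <= 0 || sample_rate_hz <= 0) {
    abort("Widths, frequency and sample rate must be positive.",
          class = "gaitloop_error_value")
  }
  structure(list(phase_width_us = phase_width_us,
                 frequency_hz = frequency_hz,
                 amplitude_level = amplitude_level,
                 sample_rate_hz = sample_rate_hz,
                 burst_mode = burst_mode,
                 burst_duration_s = burst_duration_s,
                 onset_delay_us = onset_delay_us),
            class = "stim_config")
}

#' Synthesize one biphasic pulse
#'
#' Negative phase then positive phase, each `phase_width_us` long, at
#' `amplitude_level`, on the synthesis grid, followed by zeros up to one
#' pulse period. The sample sum is exactly zero (charge balance).
#'
#' @param config a [stim_config()].
#' @return integer-valued numeric vector of one period of samples.
#' @export
synth_pulse <- function(config) {
  n_phase <- round(config$phase_width_us * 1e-6 * config$sample_rate_hz)
  n_period <- round(config$sample_rate_hz / config$frequency_hz)
  a <- config$amplitude_level
  c(rep(-a, n_phase), rep(a, n_phase), rep(0, n_period - 2 * n_phase))
}

#' Debounced three-state gait-phase machine
#'
#' Maps per-frame softmax posteriors to a stance/swing/abnormal state with
#' reciprocal indicator lines. The candidate state is the posterior argmax;
#' a stance/swing switch requires the candidate to persist
#' `debounce_frames` consecutive frames, while an abnormal candidate
#' switches immediately (safety: stimulation must stop without delay) and
#' drives both lines LOW. The stance and swing lines are never
#' simultaneously HIGH.
#'
#' @param posteriors tibble with `p_stance`, `p_swing`, `p_abnormal` (one
#'   row per frame, e.g. from [predict.gait_mlp()]).
#' @param debounce_frames consecutive frames required to confirm a
#'   stance/swing switch (default 2).
#' @param init initial state (default `"abnormal"`).
#' @return tibble with one row per frame: `frame_pos`, `state`,
#'   `stance_line`, `swing_line`.
#' @export
phase_machine <- function(posteriors, debounce_frames = 2,
                          init = "abnormal") {
  P <- as.matrix(posteriors[, c("p_stance", "p_swing", "p_abnormal")])
  n <- nrow(P)
  cand_all <- PHASE_LEVELS[max.col(P)]
  state <- character(n)
  cur <- init
  pend <- NA_character_
  count <- 0L
  for (i in seq_len(n)) {
    cand <- cand_all[i]
    if (cand == cur) {
      pend <- NA_character_
      count <- 0L
    } else if (cand == "abnormal") {
      cur <- "abnormal"
      pend <- NA_character_
      count <- 0L
    } else {
      if (identical(cand, pend)) count <- count + 1L else {
        pend <- cand
        count <- 1L
      }
      if (count >= debounce_frames) {
        cur <- cand
        pend <- NA_character_
        count <- 0L
      }
    }
    state[i] <- cur
  }
  tibble::tibble(frame_pos = seq_len(n),
                 state = factor(state, levels = PHASE_LEVELS),
                 stance_line = state == "stance",
                 swing_line = state == "swing")
}

#' Single-step state update of the phase machine
#'
#' Stateful form of [phase_machine()] for streaming use.
#'
#' @param state list with `current`, `pending`, `count` (use
#'   `phase_state_init()` to create).
#' @param posterior numeric vector `c(p_stance, p_swing, p_abnormal)`.
#' @param debounce_frames as in [phase_machine()].
#' @return updated state list, with `stance_line`/`swing_line` reflecting
#'   `current`.
#' @export
update_state <- function(state, posterior, debounce_frames = 2) {
  cand <- PHASE_LEVELS[which.max(posterior)]
  if (cand == state$current) {
    state$pending <- NA_character_
    state$count <- 0L
  } else if (cand == "abnormal") {
    state$current <- "abnormal"
    state$pending <- NA_character_
    state$count <- 0L
  } else {
    if (identical(cand, state$pending)) {
      state$count <- state$count + 1L
    } else {
      state$pending <- cand
      state$count <- 1L
    }
    if (state$count >= debounce_frames) {
      state$current <- cand
      state$pending <- NA_character_
      state$count <- 0L
    }
  }
  state$stance_line <- state$current == "stance"
  state$swing_line <- state$current == "swing"
  state
}

#' @rdname update_state
#' @param current initial phase.
#' @export
phase_state_init <- function(current = "abnormal") {
  list(current = current, pending = NA_character_, count = 0L,
       stance_line = current == "stance", swing_line = current == "swing")
}

#' Schedule a phase-triggered pulse train for one channel
#'
#' From a per-frame state timeline, emits pulse onsets on the channel's
#' phase (stance -> DAC1, swing -> DAC2): the first pulse at phase onset
#' plus `onset_delay_us`, then one pulse every `1/frequency_hz` while the
#' phase persists (`phase_locked`) or for a fixed burst
#' (`fixed_duration`). A pulse, once started, always completes; no new
#' pulse starts at or after the phase end.
#'
#' @param timeline tibble with `state` per frame (from [phase_machine()]).
#' @param fps frame rate of the timeline.
#' @param config a [stim_config()].
#' @param channel `"stance"` or `"swing"`.
#' @return a `stim_train`: tibble of pulse `onset_s` with the channel and
#'   config attached as attributes.
#' @export
schedule_train <- function(timeline, fps, config, channel = c("stance",
                                                              "swing")) {
  channel <- match.arg(channel)
  st <- as.character(timeline$state)
  n <- length(st)
  active <- st == channel
  starts <- which(active & !dplyr::lag(active, default = FALSE))
  ends <- which(active & !dplyr::lead(active, default = FALSE))
  period <- 1 / config$frequency_hz
  onsets <- numeric(0)
  for (i in seq_along(starts)) {
    t0 <- (starts[i] - 1) / fps + config$onset_delay_us * 1e-6
    t_end <- ends[i] / fps  # segment end (exclusive edge of last frame)
    if (config$burst_mode == "fixed_duration") {
      t_end <- min(t_end, t0 + config$burst_duration_s)
    }
    if (t0 >= t_end) next
    k <- ceiling((t_end - t0) / period - 1e-9)
    onsets <- c(onsets, t0 + period * seq(0, k - 1))
  }
  structure(tibble::tibble(onset_s = onsets),
            class = c("stim_train", "tbl_df", "tbl", "data.frame"),
            channel = channel, config = config)
}

#' Materialize a pulse train as a sampled waveform
#'
#' @param train a `stim_train` from [schedule_train()].
#' @param t_start,t_end window to synthesize, in seconds.
#' @return tibble with `time_s` and `level` (signed DAC levels) on the
#'   synthesis grid.
#' @export
stim_waveform <- function(train, t_start = 0,
                          t_end = max(c(train$onset_s, 0)) + 0.01) {
  config <- attr(train, "config")
  sr <- config$sample_rate_hz
  n <- round((t_end - t_start) * sr)
  n_phase <- round(config$phase_width_us * 1e-6 * sr)
  level <- numeric(n)
  a <- config$amplitude_level
  for (t0 in train$onset_s) {
    i0 <- round((t0 - t_start) * sr)
    neg <- seq(i0 + 1, i0 + n_phase)
    pos <- seq(i0 + n_phase + 1, i0 + 2 * n_phase)
    neg <- neg[neg >= 1 & neg <= n]
    pos <- pos[pos >= 1 & pos <= n]
    level[neg] <- level[neg] - a
    level[pos] <- level[pos] + a
  }
  tibble::tibble(time_s = t_start + (seq_len(n) - 1) / sr, level = level)
}
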