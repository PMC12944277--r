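#' Stance duty factor
#'
#' Stance duration as a percentage of cycle duration.
#'
#' @param stance_ms stance duration (ms), strictly between 0 and `cycle_ms`.
#' @param cycle_ms cycle duration (ms).
#' @return percentage in (0, 100). Vectorized.
#' @export
duty_factor <- function(stance_ms, cycle_ms) {
  if (any(stance_ms <= 0) || any(cycle_ms <= stance_ms)) {
    abort("Require 0 < stance_ms < cycle_ms.", class = "gaitloop_error_range")
  }
  100 * stance_ms / cycle_ms
}

#' Range of motion of a joint-angle trace
#'
#' @param trace numeric vector of joint angles (degrees) over one cycle.
#' @return tibble with `min_deg`, `max_deg`, `rom_deg` (= max - min).
#' @export
joint_rom <- function(trace) {
  if (length(trace) == 0 || all(is.na(trace))) {
    abort("Empty joint-angle trace.", class = "gaitloop_error_value")
  }
  tibble::tibble(min_deg = min(trace, na.rm = TRUE),
                 max_deg = max(trace, na.rm = TRUE),
                 rom_deg = max(trace, na.rm = TRUE) - min(trace, na.rm = TRUE))
}

#' Resample a within-cycle trace onto the normalized 0-100% grid
#'
#' Linear resampling onto 101 points (0, 1, ..., 100% of the cycle).
#'
#' @param trace numeric vector covering one cycle from stance onset to the
#'   next stance onset (at least 4 frames).
#' @return numeric vector of length 101.
#' @export
normalize_cycle <- function(trace) {
  n <- length(trace)
  if (n < 4) {
    abort("Cycle too short to normalize (need >= 4 frames).",
          class = "gaitloop_error_insufficient_data")
  }
  approx(x = seq(0, 100, length.out = n), y = trace, xout = 0:100)$y
}

#' Averaged normalized gait cycle per joint
#'
#' Resamples each QC-passing cycle of each joint trace onto the 0-100% grid
#' and averages pointwise across cycles.
#'
#' @param angles tibble from [compute_angles()].
#' @param cycles tibble from [segment_cycles()].
#' @param joints angle columns to normalize.
#' @return tibble with columns `pct` (0-100), `joint`, `mean_deg`,
#'   `n_cycles`.
#' @export
normalize_cycles <- function(angles, cycles,
                             joints = c("hip_deg", "knee_deg", "ankle_deg")) {
  use <- cycles[cycles$qc_pass, ]
  if (nrow(use) == 0) {
    abort("No QC-passing cycles to normalize.",
          class = "gaitloop_error_insufficient_data")
  }
  purrr::map_dfr(joints, function(j) {
    traces <- purrr::map(seq_len(nrow(use)), function(k) {
      sel <- angles$frame >= use$stance_onset[k] & angles$frame <= use$end[k]
      tr <- angles[[j]][sel]
      if (length(tr) < 4) NULL else normalize_cycle(tr)
    })
    traces <- purrr::compact(traces)
    m <- do.call(rbind, traces)
    tibble::tibble(pct = 0:100, joint = j, mean_deg = colMeans(m),
                   n_cycles = length(traces))
  })
}

#' Percent change of a test value relative to a reference
#'
#' `100 * (reference - test) / reference`; positive when the test value is
#' reduced relative to the reference. Stored at full precision; round for
#' display.
#'
#' @param reference reference value (> 0).
#' @param test test value.
#' @return percent change (full precision).
#' @export
percent_change <- function(reference, test) {
  if (any(reference <= 0)) {
    abort("`reference` must be positive.", class = "gaitloop_error_range")
  }
  100 * (reference - test) / reference
}

#' Welch's unpaired t-test from group summary statistics
#'
#' Computes the Welch statistic `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)`,
#' Welch-Satterthwaite degrees of freedom, and the two-sided p-value from
#' the t distribution — the appropriate test when each animal is one
#' independent biological replicate and only group means/SDs are in hand.
#'
#' @param mean1,sd1,n1 summary statistics of group 1 (n1 >= 2, sd1 >= 0).
#' @param mean2,sd2,n2 summary statistics of group 2.
#' @return one-row tibble: `estimate` (mean1 - mean2), `statistic` (t),
#'   `df`, `p.value` (two-sided).
#' @export
welch_t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) {
    abort("Each group needs n >= 2.", class = "gaitloop_error_value")
  }
  if (sd1 < 0 || sd2 < 0) {
    abort("SDs must be nonnegative.", class = "gaitloop_error_value")
  }
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  se2 <- v1 + v2
  if (se2 == 0) {
    if (mean1 == mean2) {
      abort("Degenerate test: zero variance and equal means.",
            class = "gaitloop_error_degenerate")
    }
    abort("Degenerate test: zero variance in both groups.",
          class = "gaitloop_error_degenerate")
  }
  t <- (mean1 - mean2) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  tibble::tibble(estimate = mean1 - mean2, statistic = t, df = df,
                 p.value = 2 * pt(-abs(t), df))
}

#' Per-animal gait summary over QC-passing cycles
#'
#' Spatiotemporal and kinematic summaries for one animal: mean cycle,
#' stance and swing durations, stance duty factor (computed per cycle, then
#' averaged — the mean-of-ratios convention), and per-joint min/max/ROM
#' (per cycle, then averaged). Only QC-passing cycles contribute.
#'
#' @param angles tibble from [compute_angles()].
#' @param cycles tibble from [segment_cycles()].
#' @param animal_id animal label.
#' @param duty_method `"mean_of_ratios"` (default: per-cycle duty factors
#'   averaged) or `"ratio_of_means"`.
#' @return one-row tibble of summaries.
#' @export
animal_summary <- function(angles, cycles, animal_id = "animal",
                           duty_method = c("mean_of_ratios",
                                           "ratio_of_means")) {
  duty_method <- match.arg(duty_method)
  use <- cycles[cycles$qc_pass, ]
  if (nrow(use) == 0) {
    abort("No QC-passing cycles for this animal.",
          class = "gaitloop_error_insufficient_data")
  }
  duty <- if (duty_method == "mean_of_ratios") {
    mean(duty_factor(use$stance_ms, use$cycle_ms))
  } else {
    duty_factor(mean(use$stance_ms), mean(use$cycle_ms))
  }
  per_joint <- purrr::imap(
    c(hip = "hip_deg", knee = "knee_deg", ankle = "ankle_deg"),
    function(j, nm) {
      roms <- purrr::map_dfr(seq_len(nrow(use)), function(k) {
        sel <- angles$frame >= use$stance_onset[k] &
          angles$frame < use$end[k]
        joint_rom(angles[[j]][sel])
      })
      out <- tibble::tibble(mean(roms$min_deg), mean(roms$max_deg),
                            mean(roms$rom_deg), .name_repair = "minimal")
      names(out) <- paste0(nm, c("_min_deg", "_max_deg", "_rom_deg"))
      out
    })
  per_joint <- dplyr::bind_cols(per_joint)
  dplyr::bind_cols(
    tibble::tibble(animal_id = animal_id,
                   n_cycles_used = nrow(use),
                   cycle_ms = mean(use$cycle_ms),
                   stance_ms = mean(use$stance_ms),
                   swing_ms = mean(use$swing_ms),
                   duty_factor_pct = duty),
    per_joint
  )
}

#' Group-level statistics across animals
#'
#' Mean and SD of each metric over animal means (each animal is one
#' independent replicate; cycles are never pooled across animals, avoiding
#' pseudoreplication).
#'
#' @param summaries tibble of rows from [animal_summary()].
#' @param group group label attached to the output.
#' @return tibble with columns `group`, `metric`, `mean`, `sd`, `n`.
#' @export
aggregate_group <- function(summaries, group = "group") {
  if (nrow(summaries) == 0) {
    abort("Need at least one animal.", class = "gaitloop_error_value")
  }
  summaries %>%
    dplyr::select(-dplyr::any_of("animal_id")) %>%
    tidyr::pivot_longer(dplyr::everything(), names_to = "metric") %>%
    dplyr::group_by(.data$metric) %>%
    dplyr::summarise(mean = mean(.data$value),
                     sd = if (dplyr::n() > 1) stats::sd(.data$value) else 0,
                     n = dplyr::n(), .groups = "drop") %>%
    tibble::add_column(group = group, .before = 1)
}

#' Stick-diagram segments for plotting hindlimb posture
#'
#' For each selected frame, the four segments connecting iliac crest, hip,
#' knee, ankle and MTP, with the frame's phase attached (stance drawn black,
#' swing red by convention). Abnormal frames are omitted.
#'
#' @param session a `gait_session`.
#' @param labels tibble from [label_frames()].
#' @param every keep every `every`-th frame (default 1 = all).
#' @return tibble with columns `frame`, `segment`, `x`, `y`, `xend`, `yend`,
#'   `phase`, `color`.
#' @export
stick_diagram <- function(session, labels, every = 1) {
  keep <- labels$frame[labels$label != "abnormal"]
  keep <- keep[seq(1, length(keep), by = every)]
  s <- as.data.frame(session)
  s <- s[s$frame %in% keep, ]
  lab <- labels$label[match(s$frame, labels$frame)]
  chain <- GAIT_LANDMARKS
  purrr::map_dfr(seq_len(4), function(i) {
    tibble::tibble(frame = s$frame, segment = i,
                   x = s[[paste0(chain[i], "_x")]],
                   y = s[[paste0(chain[i], "_y")]],
                   xend = s[[paste0(chain[i + 1], "_x")]],
                   yend = s[[paste0(chain[i + 1], "_y")]],
                   phase = as.character(lab),
                   color = ifelse(lab == "stance", "black", "red"))
  }) %>% dplyr::arrange(.data$frame, .data$segment)
}
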