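#' Joint-angle templates over the normalized gait cycle
#'
#' A template is a set of keypoints `(phase, value)` on the 0-1 normalized
#' cycle (0 = stance onset), interpolated with cosine easing: between
#' consecutive keypoints the curve follows a half-cosine, so it is C1,
#' periodic, and attains its extrema exactly at the keypoints (no
#' overshoot, unlike cubic splines). Stance occupies `[0, duty)` of the
#' template axis, swing the remainder.
#'
#' The built-in sham ankle template is calibrated to stance-onset 88.48,
#' maximum 118.30 (end of stance, peak plantarflexion before toe-off) and
#' minimum 74.37 degrees (mid-swing, maximal dorsiflexion); the SCI ankle
#' to 73.67 / 76.42 / 42.32 degrees (ankle depression). The sham hip rises
#' in early stance then falls; the SCI hip shows the reversed early-stance
#' trajectory (initial decrease). Hip and knee keypoint values are package
#' calibrations consistent with those shapes.
#'
#' @param group `"sham"` or `"sci"`.
#' @return named list of keypoint tibbles (`hip`, `knee`, `ankle`) plus the
#'   template duty fraction.
#' @export
gait_templates <- function(group = c("sham", "sci")) {
  group <- match.arg(group)
  kp <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    tibble::tibble(phase = m[, 1], value = m[, 2])
  }
  if (group == "sham") {
    duty <- 298.72 / 438.87
    list(
      hip = kp(0, 95, 0.22, 112, 0.75, 83),
      knee = kp(0, 110, 0.25, 88, 0.80, 125),
      ankle = kp(0, 88.48, duty, 118.30, (duty + 1) / 2, 74.37),
      duty = duty
    )
  } else {
    duty <- 200.15 / 295.36
    list(
      hip = kp(0, 98, 0.20, 86, 0.65, 108),
      knee = kp(0, 105, 0.30, 82, 0.78, 115),
      ankle = kp(0, 73.67, duty, 76.42, (duty + 1) / 2, 42.32),
      duty = duty
    )
  }
}

#' Evaluate a keypoint template at normalized phases
#'
#' @param keypoints tibble with `phase` (in \[0, 1)) and `value`.
#' @param phase numeric vector of query phases (wrapped into \[0, 1)).
#' @return interpolated values (cosine-eased, periodic).
#' @export
template_eval <- function(keypoints, phase) {
  kp <- keypoints[order(keypoints$phase), ]
  px <- c(kp$phase, kp$phase[1] + 1)
  pv <- c(kp$value, kp$value[1])
  p <- phase %% 1
  p <- ifelse(p < px[1], p + 1, p)
  i <- findInterval(p, px, rightmost.closed = TRUE)
  s <- (p - px[i]) / (px[i + 1] - px[i])
  pv[i] + (pv[i + 1] - pv[i]) * (1 - cos(pi * s)) / 2
}

#' Synthetic gait generator configuration
#'
#' Defines a virtual treadmill session. Per-cycle stance duration and duty
#' factor are drawn from truncated normal distributions (truncation at
#' mean +/- 3 SD and at physical bounds), with cycle duration derived as
#' `stance / duty` and swing as the remainder — so the generator's stance
#' and duty-factor means are recovered directly by the analysis pipeline.
#' Group defaults reproduce the sham/SCI treadmill statistics this package
#' is calibrated against (sham: stance 298.72 +/- 30.76 ms, duty 67.14%;
#' SCI: stance 200.15 +/- 30.50 ms, duty 67.66%).
#'
#' @param group `"sham"` or `"sci"` (selects duration and template
#'   defaults).
#' @param fps frame rate (default 156).
#' @param duration_s session length in seconds (default 180).
#' @param stance_ms length-2 `c(mean, sd)` of per-cycle stance duration.
#' @param duty_pct length-2 `c(mean, sd)` of per-cycle duty factor; the
#'   default per-cycle SD (2%) reflects cycle-to-cycle variability of the
#'   stance fraction.
#' @param templates joint templates (see [gait_templates()]).
#' @param noise_deg SD of additive per-frame joint-angle jitter (degrees,
#'   default 1.5).
#' @param pendulum_amp_deg half-range of the limb-axis pendulum sweep
#'   (default 20).
#' @param segment_lengths_mm named lengths crest-hip, hip-knee, knee-ankle,
#'   ankle-MTP (plausible adult-mouse values; they set landmark geometry
#'   only — joint angles are scale-invariant).
#' @param px_per_mm pixel scale of the virtual camera (default 5).
#' @param bouts_per_min rate of abnormal (irregular-behavior) bouts
#'   (default 2).
#' @param bout_duration_s mean abnormal bout length in seconds (default 1).
#' @param direction +1 travel toward +x, -1 toward -x.
#' @param seed RNG seed.
#' @return a `gait_gen_config` list.
#' @export
gait_gen_config <- function(group = c("sham", "sci"), fps = 156,
                            duration_s = 180,
                            stance_ms = NULL, duty_pct = NULL,
                            templates = NULL, noise_deg = 1.5,
                            pendulum_amp_deg = 20,
                            segment_lengths_mm = c(crest = 8, thigh = 15,
                                                   shank = 16, foot = 9),
                            px_per_mm = 5, bouts_per_min = 2,
                            bout_duration_s = 1, direction = 1, seed = 1) {
  group <- match.arg(group)
  if (is.null(stance_ms)) {
    stance_ms <- if (group == "sham") c(298.72, 30.76) else c(200.15, 30.50)
  }
  if (is.null(duty_pct)) {
    duty_pct <- if (group == "sham") c(67.14, 2.0) else c(67.66, 2.0)
  }
  if (is.null(templates)) templates <- gait_templates(group)
  frame_ms <- 1000 / fps
  if (stance_ms[1] - 3 * stance_ms[2] <= 2 * frame_ms) {
    abort("Stance distribution reaches below 2 frame periods.",
          class = "gaitloop_error_config")
  }
  if (duty_pct[1] <= 0 || duty_pct[1] >= 100) {
    abort("Mean duty factor must lie in (0, 100)%.",
          class = "gaitloop_error_config")
  }
  if (any(stance_ms < 0) || any(duty_pct[2] < 0)) {
    abort("SDs must be nonnegative.", class = "gaitloop_error_config")
  }
  structure(list(group = group, fps = fps, duration_s = duration_s,
                 stance_ms = stance_ms, duty_pct = duty_pct,
                 templates = templates, noise_deg = noise_deg,
                 pendulum_amp_deg = pendulum_amp_deg,
                 segment_lengths_mm = segment_lengths_mm,
                 px_per_mm = px_per_mm, bouts_per_min = bouts_per_min,
                 bout_duration_s = bout_duration_s, direction = direction,
                 seed = seed),
            class = "gait_gen_config")
}

rtruncnorm1 <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd == 0) return(rep(mean, n))
  lo <- max(lo, mean - 3 * sd)
  hi <- min(hi, mean + 3 * sd)
  out <- numeric(0)
  guard <- 0
  while (length(out) < n) {
    draw <- rnorm(2 * (n - length(out)) + 10, mean, sd)
    out <- c(out, draw[draw > lo & draw < hi])
    guard <- guard + 1
    if (guard > 1000) {
      abort("Infeasible truncation bounds.", class = "gaitloop_error_config")
    }
  }
  out[seq_len(n)]
}

#' Draw per-cycle stance and swing durations
#'
#' Truncated-normal per-cycle draws of stance duration and duty factor
#' (jointly defining cycle and swing), reproducible under the config seed.
#'
#' @param config a [gait_gen_config()].
#' @param n_cycles number of cycles; default: enough to cover
#'   `config$duration_s`.
#' @return tibble with `cycle_id`, `stance_ms`, `swing_ms`, `cycle_ms`,
#'   `duty_pct`, `start_ms`.
#' @export
sample_cycles <- function(config, n_cycles = NULL) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  if (is.null(n_cycles)) {
    exp_cycle <- config$stance_ms[1] / (config$duty_pct[1] / 100)
    n_cycles <- ceiling(config$duration_s * 1000 / exp_cycle)
    n_cycles <- n_cycles + max(5, ceiling(0.05 * n_cycles))
  }
  frame_ms <- 1000 / config$fps
  stance <- rtruncnorm1(n_cycles, config$stance_ms[1], config$stance_ms[2],
                        lo = 2 * frame_ms)
  duty <- rtruncnorm1(n_cycles, config$duty_pct[1], config$duty_pct[2],
                      lo = 5, hi = 95)
  cycle <- stance / (duty / 100)
  tibble::tibble(cycle_id = seq_len(n_cycles), stance_ms = stance,
                 swing_ms = cycle - stance, cycle_ms = cycle,
                 duty_pct = duty,
                 start_ms = cumsum(dplyr::lag(cycle, default = 0)))
}

#' Render per-frame joint-angle traces from a cycle plan
#'
#' Each frame is located within its cycle, mapped to the template's
#' normalized phase axis by a piecewise-linear time warp (the frame's
#' stance fraction maps onto the template's stance span and likewise for
#' swing), and the joint templates are evaluated there, with optional
#' additive Gaussian jitter. The target pendulum angle follows a
#' half-cosine per half-cycle, so its maximum falls exactly at stance
#' onset (touch-down) and its minimum at swing onset (lift-off).
#'
#' @param cycles tibble from [sample_cycles()].
#' @param config a [gait_gen_config()].
#' @return tibble of ground truth per frame: `frame`, `time_s`, `cycle_id`,
#'   `phase` (normalized 0-1), `label`, `hip_deg`, `knee_deg`, `ankle_deg`,
#'   `pendulum_deg`.
#' @export
render_angles <- function(cycles, config) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 1L)
  fps <- config$fps
  n_frames <- round(config$duration_s * fps)
  t_ms <- (seq_len(n_frames) - 1) * 1000 / fps
  total <- sum(cycles$cycle_ms)
  if (t_ms[n_frames] >= total) {
    abort("Cycle plan shorter than requested duration.",
          class = "gaitloop_error_config")
  }
  edges <- c(cycles$start_ms, total)
  ci <- findInterval(t_ms, edges)
  tau <- t_ms - cycles$start_ms[ci]
  f <- tau / cycles$cycle_ms[ci]
  duty <- cycles$duty_pct[ci] / 100
  stance <- f < duty
  df0 <- config$templates$duty
  phase <- ifelse(stance, f / duty * df0,
                  df0 + (f - duty) / (1 - duty) * (1 - df0))
  noise <- function(n) if (config$noise_deg > 0)
    rnorm(n, 0, config$noise_deg) else rep(0, n)
  A <- config$pendulum_amp_deg
  pend <- ifelse(stance, A * cos(pi * f / duty),
                 -A * cos(pi * (f - duty) / (1 - duty)))
  clamp <- function(x) pmin(179, pmax(1, x))
  tibble::tibble(
    frame = seq_len(n_frames) - 1L,
    time_s = t_ms / 1000,
    cycle_id = cycles$cycle_id[ci],
    phase = phase,
    label = factor(ifelse(stance, "stance", "swing"),
                   levels = PHASE_LEVELS),
    hip_deg = clamp(template_eval(config$templates$hip, phase) +
                      noise(n_frames)),
    knee_deg = clamp(template_eval(config$templates$knee, phase) +
                       noise(n_frames)),
    ankle_deg = clamp(template_eval(config$templates$ankle, phase) +
                        noise(n_frames)),
    pendulum_deg = pend
  )
}

#' Emit landmark coordinates by forward kinematics
#'
#' Builds the five-landmark limb chain from per-frame joint angles: the
#' chain is first constructed in a canonical pose (interior angles equal to
#' the requested hip/knee/ankle angles by construction), then rigidly
#' rotated about the hip so the hip-to-MTP axis matches the requested
#' pendulum angle — rigid rotation preserves interior angles, so
#' [compute_angles()] recovers the inputs exactly (up to floating point).
#' The hip anchor oscillates slowly to mimic trunk motion; translation
#' affects no angle.
#'
#' @param truth tibble with `frame`, `time_s`, `hip_deg`, `knee_deg`,
#'   `ankle_deg`, `pendulum_deg` (e.g. from [render_angles()]).
#' @param config a [gait_gen_config()].
#' @param likelihood per-frame landmark likelihood, length 1 or
#'   `nrow(truth)` (default: high-confidence draws in \[0.9, 1\]).
#' @return a `gait_session` in pixel units.
#' @export
emit_landmarks <- function(truth, config, likelihood = NULL) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 2L)
  n <- nrow(truth)
  if (any(truth$hip_deg <= 0 | truth$hip_deg >= 180 |
          truth$knee_deg <= 0 | truth$knee_deg >= 180 |
          truth$ankle_deg <= 0 | truth$ankle_deg >= 180)) {
    abort("Joint angles must lie strictly inside (0, 180).",
          class = "gaitloop_error_value")
  }
  L <- config$segment_lengths_mm * config$px_per_mm
  if (any(L <= 0)) {
    abort("Segment lengths must be positive.",
          class = "gaitloop_error_config")
  }
  d2r <- pi / 180
  u <- function(theta_deg) cbind(sin(theta_deg * d2r), cos(theta_deg * d2r))
  theta_thigh <- 30
  th1 <- theta_thigh - truth$hip_deg
  th_shank <- theta_thigh + 180 + truth$knee_deg
  th_foot <- th_shank + 180 - truth$ankle_deg
  P2 <- matrix(0, n, 2)
  P1 <- L[["crest"]] * u(th1)
  P3 <- L[["thigh"]] * u(rep(theta_thigh, n))
  P4 <- P3 + L[["shank"]] * u(th_shank)
  P5 <- P4 + L[["foot"]] * u(th_foot)
  psi_raw <- atan2(P5[, 1], P5[, 2]) / d2r
  delta <- (truth$pendulum_deg - psi_raw) * d2r
  rot <- function(P) cbind(P[, 1] * cos(delta) + P[, 2] * sin(delta),
                           P[, 2] * cos(delta) - P[, 1] * sin(delta))
  P1 <- rot(P1); P3 <- rot(P3); P4 <- rot(P4); P5 <- rot(P5)
  # trunk sway: slow anchor oscillation, irrelevant to all angles
  ax <- 600 + 4 * sin(2 * pi * 0.4 * truth$time_s)
  ay <- 300 + 2 * sin(2 * pi * 0.9 * truth$time_s)
  place <- function(P) cbind(P[, 1] + ax, P[, 2] + ay)
  P1 <- place(P1); P2 <- place(P2); P3 <- place(P3)
  P4 <- place(P4); P5 <- place(P5)
  if (config$direction < 0) {
    flip <- function(P) {
      P[, 1] <- 2 * ax - P[, 1]
      P
    }
    P1 <- flip(P1); P2 <- flip(P2); P3 <- flip(P3)
    P4 <- flip(P4); P5 <- flip(P5)
  }
  if (is.null(likelihood)) likelihood <- runif(n, 0.9, 1)
  lik <- rep(likelihood, length.out = n)
  pts <- list(iliac_crest = P1, hip = P2, knee = P3, ankle = P4, mtp = P5)
  frames <- tibble::tibble(frame = truth$frame)
  for (lm in GAIT_LANDMARKS) {
    frames[[paste0(lm, "_x")]] <- pts[[lm]][, 1]
    frames[[paste0(lm, "_y")]] <- pts[[lm]][, 2]
    frames[[paste0(lm, "_likelihood")]] <- lik
  }
  gait_session(frames, fps = config$fps, group = config$group,
               subject = paste0("synthetic-", config$group),
               direction = config$direction)
}

#' Inject abnormal (irregular-behavior) bouts
#'
#' Emulates bouts of twisting, corner-dwelling or reversed running: during
#' each bout the limb collapses to a crouched, atypical configuration
#' (joint angles redrawn far from the locomotor manifold), landmark
#' coordinates are jittered, at least one landmark likelihood drops below
#' 0.8, and the ground-truth label becomes abnormal.
#'
#' @param sim a `gait_sim` from [simulate_session()].
#' @param bouts optional tibble with `start_s` and `duration_s`; by default
#'   bouts are drawn from the config rate (`bouts_per_min`,
#'   `bout_duration_s`).
#' @return the modified `gait_sim`.
#' @export
inject_abnormal <- function(sim, bouts = NULL) {
  config <- sim$config
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 3L)
  if (is.null(bouts)) {
    n_bouts <- round(config$bouts_per_min * config$duration_s / 60)
    if (n_bouts == 0) return(sim)
    bouts <- tibble::tibble(
      start_s = sort(runif(n_bouts, 0, config$duration_s -
                             2 * config$bout_duration_s)),
      duration_s = runif(n_bouts, 0.5, 1.5) * config$bout_duration_s
    )
  }
  truth <- sim$truth
  fps <- config$fps
  mark <- rep(FALSE, nrow(truth))
  for (i in seq_len(nrow(bouts))) {
    i0 <- floor(bouts$start_s[i] * fps)
    n_fr <- round(bouts$duration_s[i] * fps)
    mark[truth$frame >= i0 & truth$frame < i0 + n_fr] <- TRUE
  }
  if (!any(mark)) return(sim)
  n_ab <- sum(mark)
  ab_truth <- truth[mark, ]
  ab_truth$hip_deg <- runif(n_ab, 15, 55)
  ab_truth$knee_deg <- runif(n_ab, 15, 55)
  ab_truth$ankle_deg <- runif(n_ab, 15, 55)
  ab_truth$pendulum_deg <- runif(n_ab, -60, 60)
  ab_cfg <- config
  ab_cfg$seed <- config$seed + 4L
  ab_session <- emit_landmarks(ab_truth, ab_cfg,
                               likelihood = runif(n_ab, 0.2, 0.79))
  jitter_cols <- as.vector(t(outer(GAIT_LANDMARKS, c("_x", "_y"), paste0)))
  for (col in jitter_cols) {
    ab_session[[col]] <- ab_session[[col]] + rnorm(n_ab, 0, 3)
  }
  session <- sim$session
  for (col in setdiff(session_columns(), "frame")) {
    session[[col]][mark] <- ab_session[[col]]
  }
  truth$label[mark] <- "abnormal"
  truth$hip_deg[mark] <- ab_truth$hip_deg
  truth$knee_deg[mark] <- ab_truth$knee_deg
  truth$ankle_deg[mark] <- ab_truth$ankle_deg
  truth$pendulum_deg[mark] <- ab_truth$pendulum_deg
  sim$session <- session
  sim$truth <- truth
  sim$bouts <- bouts
  sim
}

#' Simulate a complete synthetic treadmill session
#'
#' Chains [sample_cycles()], [render_angles()], [emit_landmarks()] and
#' [inject_abnormal()], returning the emitted session together with its
#' ground truth — per-frame true labels and angles, and the per-cycle true
#' durations — so every pipeline stage can be scored against the
#' generator.
#'
#' @param config a [gait_gen_config()].
#' @param abnormal inject abnormal bouts per the config rate (default
#'   TRUE).
#' @return a `gait_sim` list: `session` (a `gait_session`), `truth`
#'   (per-frame tibble), `cycles` (per-cycle tibble), `config`.
#' @export
simulate_session <- function(config, abnormal = TRUE) {
  cycles <- sample_cycles(config)
  truth <- render_angles(cycles, config)
  session <- emit_landmarks(truth, config)
  sim <- structure(list(session = session, truth = truth, cycles = cycles,
                        config = config),
                   class = "gait_sim")
  if (abnormal && config$bouts_per_min > 0) sim <- inject_abnormal(sim)
  sim
}

#' @export
print.gait_sim <- function(x, ...) {
  cat(sprintf(
    "<gait_sim> %s, %g s @ %g fps, %d frames, %d cycles, seed %d\n",
    x$config$group, x$config$duration_s, x$config$fps, nrow(x$truth),
    nrow(x$cycles), x$config$seed))
  invisible(x)
}

#' Simulate a group of virtual animals
#'
#' @param config a [gait_gen_config()]; animal `i` uses `config$seed + 100
#'   * i`.
#' @param n_animals number of virtual animals (default 3).
#' @param ... passed to [simulate_session()].
#' @return named list of `gait_sim` objects.
#' @export
simulate_group <- function(config, n_animals = 3, ...) {
  sims <- purrr::map(seq_len(n_animals), function(i) {
    cfg <- config
    cfg$seed <- config$seed + 100L * i
    simulate_session(cfg, ...)
  })
  names(sims) <- paste0(config$group, "_", seq_len(n_animals))
  sims
}
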