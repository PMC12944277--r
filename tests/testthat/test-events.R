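sine_angles <- function(n_cycles = 20, period = 100, amp = 20,
                        phase = 25) {
  n <- n_cycles * period
  tibble::tibble(frame = 0:(n - 1),
                 pendulum_deg = amp * cos(2 * pi * ((0:(n - 1)) - phase) /
                                            period),
                 valid = TRUE)
}

test_that("a pure sinusoid yields evenly spaced alternating extrema", {
  ang <- sine_angles(20, 100)
  tr <- detect_transitions(ang, fps = 156)
  st <- tr$frame[tr$event == "stance_onset"]
  sw <- tr$frame[tr$event == "swing_onset"]
  expect_identical(length(st), 20L)
  expect_identical(length(sw), 20L)
  expect_true(all(diff(st) == 100))
  expect_true(all(diff(sw) == 100))
  # alternation: exactly one swing onset between consecutive stance onsets
  expect_true(all(diff(match(tr$event, c("stance_onset",
                                         "swing_onset"))) != 0))
})

test_that("an asymmetric 2:1 pendulum wave recovers the stance fraction", {
  # stance 2/3 of a 99-frame cycle: slow descending half-cosine then fast
  # ascending half-cosine, extrema exactly at the phase boundaries
  period <- 99
  stance_len <- 66
  f <- (0:(30 * period - 1)) %% period
  y <- ifelse(f < stance_len, 20 * cos(pi * f / stance_len),
              -20 * cos(pi * (f - stance_len) / (period - stance_len)))
  ang <- tibble::tibble(frame = seq_along(y) - 1L, pendulum_deg = y,
                        valid = TRUE)
  tr <- detect_transitions(ang, fps = 156)
  lab <- label_frames(ang, tr)
  cyc <- segment_cycles(lab, tr, fps = 156)
  stance_frames <- cyc$stance_ms / 1000 * 156
  expect_true(all(abs(stance_frames - stance_len) <= 1))
})

test_that("a one-frame spike does not create spurious transitions", {
  ang <- sine_angles(10, 100)
  spiked <- ang
  spiked$pendulum_deg[550] <- spiked$pendulum_deg[550] + 30
  tr0 <- detect_transitions(ang, fps = 156)
  tr1 <- detect_transitions(spiked, fps = 156)
  expect_identical(nrow(tr1), nrow(tr0))
  expect_true(all(table(tr1$event) == c(10, 10)))
})

test_that("too-short or flat series raise insufficient-data errors", {
  short <- tibble::tibble(frame = 0:5, pendulum_deg = rnorm(6),
                          valid = TRUE)
  expect_error(detect_transitions(short, fps = 156),
               class = "gaitloop_error_insufficient_data")
  flat <- tibble::tibble(frame = 0:199, pendulum_deg = 0, valid = TRUE)
  expect_error(detect_transitions(flat, fps = 156),
               class = "gaitloop_error_insufficient_data")
})

test_that("labels partition frames and respect the likelihood override", {
  ang <- sine_angles(10, 100)
  tr <- detect_transitions(ang, fps = 156)
  lab <- label_frames(ang, tr)
  counts <- table(lab$label)
  expect_identical(sum(counts), nrow(ang))

  # stance phase spans descending half of the wave (max -> min), so with a
  # symmetric sinusoid stance and swing counts are near-equal
  expect_lt(abs(counts[["stance"]] - counts[["swing"]]), 110)

  # frames before the first and after the last transition are abnormal
  first_t <- min(tr$frame)
  last_t <- max(tr$frame)
  expect_true(all(lab$label[lab$frame < first_t] == "abnormal"))
  expect_true(all(lab$label[lab$frame > last_t] == "abnormal"))

  # one gated frame becomes abnormal without touching its neighbors
  ang2 <- ang
  ang2$valid[500] <- FALSE
  lab2 <- label_frames(ang2, tr)
  expect_identical(as.character(lab2$label[500]), "abnormal")
  changed <- which(as.character(lab2$label) != as.character(lab$label))
  expect_identical(changed, 500L)
})

test_that("the natural stance:swing imbalance survives labeling", {
  sim <- quick_sim("sham", duration_s = 20, seed = 21, bouts_per_min = 0)
  lab <- label_session(sim$session)
  counts <- table(lab$labels$label)
  ratio <- counts[["stance"]] / counts[["swing"]]
  # duty ~67% implies stance:swing about 2:1
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.6)
})

test_that("dropouts only ever convert labels to abnormal", {
  sim <- quick_sim("sham", duration_s = 15, seed = 31, bouts_per_min = 0)
  lab0 <- label_session(sim$session)
  s2 <- sim$session
  set.seed(1)
  hit <- sample(nrow(s2), 50)
  s2$knee_likelihood[hit] <- 0.5
  ang2 <- compute_angles(s2)
  lab2 <- label_frames(ang2, lab0$transitions)
  a <- as.character(lab0$labels$label)
  b <- as.character(lab2$label)
  expect_true(all(b[b != a] == "abnormal"))
})

test_that("cycle segmentation gets the frame arithmetic right", {
  n <- 220
  lab <- tibble::tibble(frame = 0:(n - 1),
                        label = factor("stance", levels = phase_levels),
                        cycle_id = NA)
  tr <- tibble::tibble(frame = c(0L, 67L, 100L, 167L, 200L),
                       event = c("stance_onset", "swing_onset",
                                 "stance_onset", "swing_onset",
                                 "stance_onset"))
  cyc <- segment_cycles(lab, tr, fps = 156)
  expect_identical(nrow(cyc), 2L)
  expect_equal(cyc$stance_ms[1], 67 / 156 * 1000, tolerance = 1e-9)
  expect_equal(cyc$swing_ms[1], 33 / 156 * 1000, tolerance = 1e-9)
  expect_equal(cyc$cycle_ms[1], 100 / 156 * 1000, tolerance = 1e-9)
  expect_equal(cyc$cycle_ms, cyc$stance_ms + cyc$swing_ms)
  expect_true(all(cyc$stance_onset < cyc$swing_onset &
                    cyc$swing_onset < cyc$end))

  # a low-likelihood frame inside a cycle fails that cycle's QC
  lab2 <- lab
  lab2$label[51] <- "abnormal"
  cyc2 <- segment_cycles(lab2, tr, fps = 156)
  expect_false(cyc2$qc_pass[1])
  expect_true(cyc2$qc_pass[2])

  expect_error(segment_cycles(lab, tr[1:2, ], fps = 156),
               class = "gaitloop_error_insufficient_data")
})

test_that("a clean n-cycle session segments into n-1 passing cycles", {
  sim <- quick_sim("sham", duration_s = 20, seed = 41, bouts_per_min = 0)
  lab <- label_session(sim$session)
  st <- sum(lab$transitions$event == "stance_onset")
  expect_identical(nrow(lab$cycles), st - 1L)
  expect_true(all(lab$cycles$qc_pass))
})
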