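test_that("cycle sampling honors its configured distributions", {
  cfg0 <- gait_gen_config("sham", stance_ms = c(298.72, 0),
                          duty_pct = c(67.14, 0), seed = 1)
  cyc <- sample_cycles(cfg0, n_cycles = 20)
  expect_true(all(cyc$stance_ms == 298.72))
  expect_true(all(abs(cyc$duty_pct - 67.14) < 1e-12))
  expect_equal(cyc$cycle_ms, cyc$stance_ms + cyc$swing_ms)

  cfg <- gait_gen_config("sham", seed = 2)
  big <- sample_cycles(cfg, n_cycles = 10000)
  expect_lt(abs(mean(big$stance_ms) - 298.72) / 298.72, 0.01)
  expect_lt(abs(mean(big$duty_pct) - 67.14) / 67.14, 0.01)
  # truncation: no draw beyond 3 sd
  expect_true(all(abs(big$stance_ms - 298.72) < 3 * 30.76))

  # infeasible configuration: stance distribution touching zero
  expect_error(gait_gen_config("sham", stance_ms = c(10, 10)),
               class = "gaitloop_error_config")
})

test_that("angle templates hit their calibration keypoints exactly", {
  tpl <- gait_templates("sham")
  expect_equal(template_eval(tpl$ankle, 0), 88.48)
  expect_equal(template_eval(tpl$ankle, tpl$duty), 118.30)
  expect_equal(template_eval(tpl$ankle, (tpl$duty + 1) / 2), 74.37)
  # cosine easing never overshoots the keypoint range
  grid <- template_eval(tpl$ankle, seq(0, 1, by = 1e-3))
  expect_lte(max(grid), 118.30)
  expect_gte(min(grid), 74.37)

  sci <- gait_templates("sci")
  expect_equal(template_eval(sci$ankle, sci$duty), 76.42)
  expect_equal(template_eval(sci$ankle, (sci$duty + 1) / 2), 42.32)
})

test_that("rendered traces follow the templates and group phenotypes", {
  cfg <- gait_gen_config("sham", duration_s = 10, seed = 3, noise_deg = 0)
  cyc <- sample_cycles(cfg)
  tr <- render_angles(cyc, cfg)
  expect_lt(abs(max(tr$ankle_deg) - 118.30), 0.5)
  expect_lt(abs(min(tr$ankle_deg) - 74.37), 0.5)
  # sham hip rises in early stance
  c1 <- tr[tr$cycle_id == 2, ]
  early <- c1$hip_deg[c1$phase < 0.1]
  expect_gt(utils::tail(early, 1), early[1])

  sci <- gait_gen_config("sci", duration_s = 10, seed = 3, noise_deg = 0)
  trs <- render_angles(sample_cycles(sci), sci)
  expect_lt(abs(min(trs$ankle_deg) - 42.32), 0.5)
  # SCI reversal: hip initially decreases during early stance
  s1 <- trs[trs$cycle_id == 2, ]
  early_s <- s1$hip_deg[s1$phase < 0.1]
  expect_lt(utils::tail(early_s, 1), early_s[1])

  # pendulum extrema sit at the phase boundaries
  expect_equal(max(tr$pendulum_deg[tr$phase < 0.02]),
               max(tr$pendulum_deg), tolerance = 1e-6)
})

test_that("landmark emission inverts exactly and respects symmetry", {
  cfg <- gait_gen_config("sham", duration_s = 5, seed = 4, noise_deg = 0)
  truth <- render_angles(sample_cycles(cfg), cfg)
  sess <- emit_landmarks(truth, cfg, likelihood = 1)
  ang <- compute_angles(sess)
  expect_lt(max(abs(ang$hip_deg - truth$hip_deg)), 1e-6)
  expect_lt(max(abs(ang$knee_deg - truth$knee_deg)), 1e-6)
  expect_lt(max(abs(ang$ankle_deg - truth$ankle_deg)), 1e-6)
  expect_lt(max(abs(ang$pendulum_deg - truth$pendulum_deg)), 1e-6)

  # doubling segment lengths changes no recovered angle
  cfg2 <- cfg
  cfg2$segment_lengths_mm <- cfg$segment_lengths_mm * 2
  ang2 <- compute_angles(emit_landmarks(truth, cfg2, likelihood = 1))
  expect_lt(max(abs(ang2$hip_deg - ang$hip_deg)), 1e-9)

  # reversing travel direction flips the recovered pendulum sign
  cfg3 <- cfg
  cfg3$direction <- -1
  sess3 <- emit_landmarks(truth, cfg3, likelihood = 1)
  ang3 <- compute_angles(sess3)
  expect_lt(max(abs(ang3$pendulum_deg - truth$pendulum_deg)), 1e-6)
  # same landmarks read with the wrong direction flag give the mirror
  attr(sess3, "direction") <- 1
  ang3m <- compute_angles(sess3)
  expect_lt(max(abs(ang3m$pendulum_deg + truth$pendulum_deg)), 1e-6)

  expect_error(emit_landmarks(dplyr::mutate(truth, hip_deg = 0), cfg),
               class = "gaitloop_error_value")
})

test_that("abnormal bouts mark ground truth and likelihoods consistently", {
  cfg <- gait_gen_config("sham", duration_s = 15, seed = 5,
                         bouts_per_min = 0)
  sim0 <- simulate_session(cfg)
  expect_false(any(sim0$truth$label == "abnormal"))

  bout <- tibble::tibble(start_s = 5, duration_s = 1)
  sim1 <- inject_abnormal(sim0, bouts = bout)
  expect_identical(sum(sim1$truth$label == "abnormal"), 156L)
  ab <- sim1$truth$label == "abnormal"
  lik <- compute_angles(sim1$session)$min_likelihood
  expect_true(all(lik[ab] < 0.8))
  expect_true(all(lik[!ab] >= 0.8))

  # downstream labeling marks at least those frames abnormal
  lab <- label_session(sim1$session)
  expect_true(all(lab$labels$label[ab] == "abnormal"))
})

test_that("the pipeline recovers generator parameters on a sham group", {
  cfg <- gait_gen_config("sham", duration_s = 30, seed = 6,
                         bouts_per_min = 0)
  sims <- simulate_group(cfg, n_animals = 3)
  sums <- purrr::imap_dfr(sims, function(s, id) {
    lab <- label_session(s$session)
    animal_summary(lab$angles, lab$cycles, id)
  })
  g <- aggregate_group(sums, "sham")
  frame_ms <- 1000 / 156
  expect_lt(abs(g$mean[g$metric == "stance_ms"] - 298.72), 2 * frame_ms)
  expect_lt(abs(g$mean[g$metric == "duty_factor_pct"] - 67.14), 1)
  true_cycle <- mean(purrr::map_dbl(sims,
                                    function(s) mean(s$cycles$cycle_ms)))
  expect_lt(abs(g$mean[g$metric == "cycle_ms"] - true_cycle), 2 * frame_ms)
})

test_that("a classifier trained on synthetic gait generalizes", {
  m <- fixture_model()
  d <- fixture_dataset()
  val <- d[d$split == "val", ]
  p <- predict(m, val)
  expect_gte(mean(p$label == val$label), 0.90)
  ab <- val$label == "abnormal"
  expect_gte(mean(p$label[ab] == "abnormal"), 0.99)
})
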