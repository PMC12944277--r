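# shared fixtures, built in code at test time

phase_levels <- c("stance", "swing", "abnormal")

# a tiny session with geometrically sensible landmarks
toy_session <- function(n = 3, likelihood = 0.95) {
  frames <- tibble::tibble(
    frame = seq_len(n) - 1L,
    iliac_crest_x = 90 + seq_len(n), iliac_crest_y = 80,
    iliac_crest_likelihood = likelihood,
    hip_x = 100 + seq_len(n), hip_y = 100, hip_likelihood = likelihood,
    knee_x = 110 + seq_len(n), knee_y = 130, knee_likelihood = likelihood,
    ankle_x = 95 + seq_len(n), ankle_y = 160, ankle_likelihood = likelihood,
    mtp_x = 105 + seq_len(n), mtp_y = 180, mtp_likelihood = likelihood
  )
  gait_session(frames)
}

# quick synthetic session wrapper
quick_sim <- function(group = "sham", duration_s = 20, seed = 1, ...) {
  simulate_session(gait_gen_config(group, duration_s = duration_s,
                                   seed = seed, ...))
}

# one small trained classifier, cached for the whole test run
.fixture_env <- new.env(parent = emptyenv())

fixture_model <- function() {
  if (is.null(.fixture_env$model)) {
    sims <- list(
      sham = quick_sim("sham", duration_s = 25, seed = 301),
      sci = quick_sim("sci", duration_s = 25, seed = 302)
    )
    d <- build_dataset(purrr::map(sims, function(s) {
      dplyr::mutate(s$truth[, c("hip_deg", "knee_deg", "ankle_deg")],
                    label = s$truth$label)
    }))
    d <- split_dataset(d, seed = 1)
    .fixture_env$model <- mlp_train(d, epochs_max = 50, seed = 3)
    .fixture_env$dataset <- d
  }
  .fixture_env$model
}

fixture_dataset <- function() {
  fixture_model()
  .fixture_env$dataset
}

# independent loop-arithmetic forward pass (oracle for the vectorized one)
oracle_forward <- function(model, x) {
  if (!is.null(model$scaling)) {
    x <- (x - model$scaling$center) / model$scaling$scale
  }
  a <- x
  L <- length(model$weights)
  for (l in seq_len(L)) {
    W <- model$weights[[l]]$W
    b <- model$weights[[l]]$b
    z <- numeric(ncol(W))
    for (j in seq_len(ncol(W))) {
      acc <- b[j]
      for (i in seq_len(nrow(W))) acc <- acc + a[i] * W[i, j]
      z[j] <- acc
    }
    a <- if (l < L) pmax(z, 0) else z
  }
  e <- exp(a - max(a))
  e / sum(e)
}
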