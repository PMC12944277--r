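cluster_data <- function(n_per = 1500, seed = 1) {
  set.seed(seed)
  mk <- function(m, lab) {
    tibble::tibble(hip_deg = rnorm(n_per, m[1], 3),
                   knee_deg = rnorm(n_per, m[2], 3),
                   ankle_deg = rnorm(n_per, m[3], 3),
                   label = factor(lab, levels = phase_levels))
  }
  dplyr::bind_rows(mk(c(100, 110, 100), "stance"),
                   mk(c(60, 70, 60), "swing"),
                   mk(c(30, 30, 30), "abnormal"))
}

test_that("dataset building keeps every frame and the class proportions", {
  sim <- quick_sim("sham", duration_s = 10, seed = 81)
  lab <- label_session(sim$session)
  src <- dplyr::mutate(lab$angles[, c("hip_deg", "knee_deg", "ankle_deg")],
                       label = lab$labels$label)
  d <- build_dataset(list(a = src))
  expect_identical(nrow(d), nrow(sim$session))
  expect_identical(table(d$label), table(src$label))

  d10 <- build_dataset(list(x = src[1:10, ]))
  expect_identical(nrow(d10), 10L)
  expect_equal(d10$hip_deg, src$hip_deg[1:10])

  bad <- src
  bad$label[5] <- NA
  expect_error(build_dataset(list(b = bad)), class = "gaitloop_error_value")
})

test_that("the 80/20 split is disjoint, exhaustive and reproducible", {
  d <- cluster_data(500)
  s1 <- split_dataset(d, seed = 9)
  s2 <- split_dataset(d, seed = 9)
  expect_identical(s1$split, s2$split)
  expect_identical(sum(s1$split == "train"),
                   as.integer(floor(nrow(d) * 0.8)))
  expect_identical(sum(s1$split %in% c("train", "val")), nrow(d))
  # class priors preserved exactly over the union (no resampling)
  expect_identical(table(s1$label), table(d$label))
})

test_that("parameter counts match brute-force enumeration", {
  expect_identical(n_parameters(mlp_new(3, c(32, 32), 3)), 1283L)
  expect_identical(n_parameters(mlp_new(3, integer(0), 3)), 12L)
  set.seed(3)
  for (k in 1:20) {
    d_in <- sample(1:8, 1)
    h <- sample(1:40, sample(0:3, 1))
    d_out <- sample(2:6, 1)
    m <- mlp_new(d_in, h, d_out)
    # enumeration oracle: walk the layer size chain
    sizes <- c(d_in, h, d_out)
    want <- 0L
    for (l in seq_len(length(sizes) - 1)) {
      want <- want + sizes[l] * sizes[l + 1] + sizes[l + 1]
    }
    expect_identical(n_parameters(m), as.integer(want))
  }
})

test_that("forward pass matches an independent matrix-arithmetic oracle", {
  set.seed(17)
  for (k in 1:10) {
    m <- mlp_new(seed = k)
    if (k %% 2 == 0) {
      m$scaling <- list(center = runif(3, 50, 100), scale = runif(3, 5, 20))
    }
    x <- runif(3, 0, 180)
    got <- predict(m, matrix(x, 1))
    want <- oracle_forward(m, x)
    expect_equal(c(got$p_stance, got$p_swing, got$p_abnormal), want,
                 tolerance = 1e-9)
  }
})

test_that("posteriors are a probability simplex; zero weights are uniform", {
  m <- mlp_new(seed = 2)
  x <- matrix(runif(300, 0, 180), ncol = 3)
  p <- predict(m, x)
  expect_equal(p$p_stance + p$p_swing + p$p_abnormal, rep(1, 100),
               tolerance = 1e-9)
  m0 <- m
  for (l in seq_along(m0$weights)) {
    m0$weights[[l]]$W[] <- 0
    m0$weights[[l]]$b[] <- 0
  }
  p0 <- predict(m0, matrix(c(90, 90, 90), 1))
  expect_equal(unlist(p0[1, 1:3], use.names = FALSE), rep(1 / 3, 3))
  expect_error(predict(m, matrix(c(NA, 1, 1), 1)),
               class = "gaitloop_error_value")
})

test_that("training separates well-separated clusters", {
  d <- split_dataset(cluster_data(800, seed = 5), seed = 5)
  m <- mlp_train(d, epochs_max = 50, seed = 7)
  expect_gte(glance(m)$val_accuracy, 0.99)
  expect_lte(nrow(m$history), 300)
  # checkpoint contract: returned weights attain the best validation loss
  val <- d[d$split == "val", ]
  p <- predict(m, val)
  idx <- cbind(seq_len(nrow(val)), as.integer(val$label))
  loss <- -mean(log(pmax(as.matrix(p[, 1:3])[idx], 1e-12)))
  expect_equal(loss, min(m$history$val_loss), tolerance = 1e-9)
})

test_that("label-shuffled training stays at the class prior (no leakage)", {
  d <- cluster_data(600, seed = 6)
  set.seed(8)
  d$label <- sample(d$label)
  d <- split_dataset(d, seed = 8)
  m <- mlp_train(d, epochs_max = 25, seed = 9)
  prior <- max(table(d$label)) / nrow(d)
  acc <- glance(m)$val_accuracy
  expect_lt(abs(acc - prior), 0.05)
})

test_that("training is reproducible under a fixed seed", {
  d <- split_dataset(cluster_data(300, seed = 10), seed = 10)
  m1 <- mlp_train(d, epochs_max = 5, seed = 11)
  m2 <- mlp_train(d, epochs_max = 5, seed = 11)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$history, m2$history)
})

test_that("model serialization round-trips bit-exactly", {
  m <- fixture_model()
  path <- withr::local_tempfile(fileext = ".json")
  save_mlp(m, path)
  m2 <- load_mlp(path)
  expect_identical(m2$weights, m$weights)
  expect_identical(m2$sizes, m$sizes)
  expect_equal(m2$scaling, m$scaling)
  expect_identical(n_parameters(m2), 1283L)

  x <- tibble::tibble(hip_deg = runif(100, 0, 180),
                      knee_deg = runif(100, 0, 180),
                      ankle_deg = runif(100, 0, 180))
  expect_equal(predict(m2, x), predict(m, x), tolerance = 1e-12)

  # truncated file is rejected, not misread
  raw <- readLines(path)
  trunc <- withr::local_tempfile(fileext = ".json")
  writeLines(substr(paste(raw, collapse = ""), 1, 200), trunc)
  expect_error(load_mlp(trunc), class = "gaitloop_error_format")
  notmodel <- withr::local_tempfile(fileext = ".json")
  writeLines('{"format": "other"}', notmodel)
  expect_error(load_mlp(notmodel), class = "gaitloop_error_format")
})

test_that("tidy and glance describe the architecture", {
  m <- mlp_new()
  td <- tidy(m)
  expect_identical(nrow(td), 3L)
  expect_identical(sum(td$n_weights + td$n_biases), 1283L)
  expect_identical(td$activation, c("relu", "relu", "softmax"))
  g <- glance(m)
  expect_identical(g$n_parameters, 1283L)
  expect_true(is.na(g$epochs_trained))
})
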