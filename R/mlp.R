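PHASE_LEVELS <- c("stance", "swing", "abnormal")

#' Assemble a labeled joint-angle dataset from labeled sessions
#'
#' Pairs each frame's three joint angles with its phase label, one row per
#' frame, preserving source order and the natural class proportions (the
#' stance phase is inherently longer than the swing phase; no rebalancing
#' or resampling is performed).
#'
#' @param sessions named list; each element a tibble with columns
#'   `hip_deg`, `knee_deg`, `ankle_deg` and `label`
#'   (stance/swing/abnormal) — e.g. [compute_angles()] joined with
#'   [label_frames()] output.
#' @return tibble with columns `session`, `hip_deg`, `knee_deg`,
#'   `ankle_deg`, `label`.
#' @export
build_dataset <- function(sessions) {
  if (is.null(names(sessions)) || any(!nzchar(names(sessions)))) {
    names(sessions) <- paste0("session", seq_along(sessions))
  }
  purrr::imap_dfr(sessions, function(s, id) {
    if (anyNA(s$label)) {
      abort(paste0("Session \"", id, "\" contains unlabeled frames."),
            class = "gaitloop_error_value")
    }
    lab <- as.character(s$label)
    if (!all(lab %in% PHASE_LEVELS)) {
      abort("Labels must be stance/swing/abnormal.",
            class = "gaitloop_error_value")
    }
    tibble::tibble(session = id, hip_deg = s$hip_deg, knee_deg = s$knee_deg,
                   ankle_deg = s$ankle_deg,
                   label = factor(lab, levels = PHASE_LEVELS))
  })
}

#' Add a random train/validation split
#'
#' Shuffles rows into disjoint, exhaustive train/validation masks.
#'
#' @param data tibble from [build_dataset()].
#' @param train_frac fraction of rows assigned to training (default 0.8).
#' @param seed RNG seed for the shuffle.
#' @return `data` with a `split` column (`"train"`/`"val"`).
#' @export
split_dataset <- function(data, train_frac = 0.8, seed = 1) {
  n <- nrow(data)
  n_train <- floor(n * train_frac)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  idx <- sample.int(n)
  split <- rep("val", n)
  split[idx[seq_len(n_train)]] <- "train"
  dplyr::mutate(data, split = split)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Initialize the lightweight gait-phase MLP
#'
#' Feed-forward network with ReLU hidden layers and a softmax output; the
#' default 3-32-32-3 architecture (three joint angles in, three phase
#' probabilities out) has 1283 trainable parameters.
#'
#' @param input number of input features (default 3).
#' @param hidden integer vector of hidden-layer widths (default c(32, 32)).
#' @param output number of classes (default 3).
#' @param seed RNG seed for He-normal weight initialization.
#' @return a `gait_mlp` object.
#' @export
mlp_new <- function(input = 3, hidden = c(32, 32), output = 3, seed = 1) {
  sizes <- as.integer(c(input, hidden, output))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  weights <- purrr::map(seq_len(length(sizes) - 1), function(l) {
    fan_in <- sizes[l]
    list(W = matrix(rnorm(fan_in * sizes[l + 1], sd = sqrt(2 / fan_in)),
                    fan_in, sizes[l + 1]),
         b = rep(0, sizes[l + 1]))
  })
  structure(list(sizes = sizes, weights = weights, scaling = NULL,
                 levels = PHASE_LEVELS, history = NULL,
                 config = list(seed = seed)),
            class = "gait_mlp")
}

#' Number of trainable parameters of an MLP
#'
#' Sum over layers of `fan_in * fan_out + fan_out` (weights plus biases).
#'
#' @param model a `gait_mlp`.
#' @return integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(purrr::map_int(model$weights,
                     function(l) length(l$W) + length(l$b)))
}

mlp_forward <- function(weights, X) {
  act <- list()
  pre <- list()
  A <- X
  L <- length(weights)
  for (l in seq_len(L)) {
    Z <- sweep(A %*% weights[[l]]$W, 2, weights[[l]]$b, "+")
    pre[[l]] <- Z
    A <- if (l < L) pmax(Z, 0) else Z
    act[[l]] <- A
  }
  # row-stabilized softmax
  Z <- act[[L]]
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  P <- E / rowSums(E)
  list(P = P, act = act, pre = pre)
}

mlp_loss_acc <- function(weights, X, y_idx) {
  P <- mlp_forward(weights, X)$P
  p_true <- P[cbind(seq_len(nrow(P)), y_idx)]
  list(loss = -mean(log(pmax(p_true, 1e-12))),
       acc = mean(max.col(P) == y_idx))
}

#' Train the gait-phase MLP
#'
#' Minimizes categorical cross-entropy with the Adam optimizer
#' (mini-batches, default size 128), for up to `epochs_max` epochs with
#' early stopping on validation loss and checkpointing: the returned model
#' carries the weights of the best validation epoch. Inputs are z-scored
#' per feature using training-split statistics stored with the model
#' (disable with `scale_inputs = FALSE` to train on raw degrees).
#'
#' @param data tibble with `hip_deg`, `knee_deg`, `ankle_deg`, `label` and a
#'   `split` column (see [split_dataset()]); if `split` is absent an 80/20
#'   split is drawn with `seed`.
#' @param epochs_max maximum epochs (default 300).
#' @param batch_size mini-batch size (default 128).
#' @param seed RNG seed (initialization and batch shuffling).
#' @param learning_rate,beta1,beta2 Adam hyperparameters (defaults 1e-3,
#'   0.9, 0.999).
#' @param patience early-stopping patience in epochs (default 25).
#' @param scale_inputs z-score inputs on training statistics (default TRUE).
#' @param hidden hidden-layer widths (default c(32, 32)).
#' @return a trained `gait_mlp` with a `history` tibble (`epoch`,
#'   `train_loss`, `train_acc`, `val_loss`, `val_acc`).
#' @export
mlp_train <- function(data, epochs_max = 300, batch_size = 128, seed = 1,
                      learning_rate = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      patience = 25, scale_inputs = TRUE,
                      hidden = c(32, 32)) {
  if (!"split" %in% names(data)) data <- split_dataset(data, seed = seed)
  if (!any(data$split == "train") || !any(data$split == "val")) {
    abort("Both train and val splits must be non-empty.",
          class = "gaitloop_error_value")
  }
  X_all <- as.matrix(data[, c("hip_deg", "knee_deg", "ankle_deg")])
  dimnames(X_all) <- NULL
  y_all <- as.integer(factor(as.character(data$label),
                             levels = PHASE_LEVELS))
  tr <- data$split == "train"
  scaling <- NULL
  if (scale_inputs) {
    ctr <- colMeans(X_all[tr, , drop = FALSE])
    scl <- apply(X_all[tr, , drop = FALSE], 2, stats::sd)
    scl[scl == 0] <- 1
    scaling <- list(center = unname(ctr), scale = unname(scl))
    X_all <- sweep(sweep(X_all, 2, ctr), 2, scl, "/")
  }
  Xtr <- X_all[tr, , drop = FALSE]
  ytr <- y_all[tr]
  Xva <- X_all[!tr, , drop = FALSE]
  yva <- y_all[!tr]

  model <- mlp_new(input = 3, hidden = hidden, output = 3, seed = seed)
  W <- model$weights
  L <- length(W)
  adam <- purrr::map(W, function(l) {
    list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
  })
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed + 1L)

  n_tr <- nrow(Xtr)
  Ytr <- matrix(0, n_tr, 3)
  Ytr[cbind(seq_len(n_tr), ytr)] <- 1
  t_step <- 0
  best_val <- Inf
  best_W <- W
  best_epoch <- 0
  hist <- vector("list", epochs_max)
  for (epoch in seq_len(epochs_max)) {
    ord <- sample.int(n_tr)
    for (start in seq(1, n_tr, by = batch_size)) {
      ix <- ord[start:min(start + batch_size - 1, n_tr)]
      X <- Xtr[ix, , drop = FALSE]
      Y <- Ytr[ix, , drop = FALSE]
      fw <- mlp_forward(W, X)
      m <- length(ix)
      delta <- (fw$P - Y) / m
      grads <- vector("list", L)
      for (l in rev(seq_len(L))) {
        A_prev <- if (l == 1) X else fw$act[[l - 1]]
        grads[[l]] <- list(W = crossprod(A_prev, delta),
                           b = colSums(delta))
        if (l > 1) {
          delta <- (delta %*% t(W[[l]]$W)) * (fw$pre[[l - 1]] > 0)
        }
      }
      t_step <- t_step + 1
      bc1 <- 1 - beta1^t_step
      bc2 <- 1 - beta2^t_step
      for (l in seq_len(L)) {
        a <- adam[[l]]
        a$mW <- beta1 * a$mW + (1 - beta1) * grads[[l]]$W
        a$vW <- beta2 * a$vW + (1 - beta2) * grads[[l]]$W^2
        a$mb <- beta1 * a$mb + (1 - beta1) * grads[[l]]$b
        a$vb <- beta2 * a$vb + (1 - beta2) * grads[[l]]$b^2
        W[[l]]$W <- W[[l]]$W -
          learning_rate * (a$mW / bc1) / (sqrt(a$vW / bc2) + 1e-8)
        W[[l]]$b <- W[[l]]$b -
          learning_rate * (a$mb / bc1) / (sqrt(a$vb / bc2) + 1e-8)
        adam[[l]] <- a
      }
    }
    m_tr <- mlp_loss_acc(W, Xtr, ytr)
    m_va <- mlp_loss_acc(W, Xva, yva)
    hist[[epoch]] <- tibble::tibble(epoch = epoch,
                                    train_loss = m_tr$loss,
                                    train_acc = m_tr$acc,
                                    val_loss = m_va$loss,
                                    val_acc = m_va$acc)
    if (m_va$loss < best_val) {
      best_val <- m_va$loss
      best_W <- W
      best_epoch <- epoch
    } else if (epoch - best_epoch >= patience) {
      break
    }
  }
  model$weights <- best_W
  model$scaling <- scaling
  model$history <- dplyr::bind_rows(purrr::compact(hist))
  model$config <- list(seed = seed, epochs_max = epochs_max,
                       batch_size = batch_size,
                       learning_rate = learning_rate, beta1 = beta1,
                       beta2 = beta2, patience = patience,
                       best_epoch = best_epoch,
                       scale_inputs = scale_inputs)
  model
}

#' Predict gait-phase posteriors
#'
#' Deterministic forward pass; softmax probabilities over stance, swing and
#' abnormal plus the argmax label.
#'
#' @param object a `gait_mlp`.
#' @param newdata tibble or matrix with columns/order `hip_deg`, `knee_deg`,
#'   `ankle_deg`.
#' @param ... unused.
#' @return tibble with `p_stance`, `p_swing`, `p_abnormal`, `label`.
#' @export
predict.gait_mlp <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else {
    as.matrix(newdata[, c("hip_deg", "knee_deg", "ankle_deg")])
  }
  if (anyNA(X) || any(!is.finite(X))) {
    abort("Non-finite angles in classifier input.",
          class = "gaitloop_error_value")
  }
  if (!is.null(object$scaling)) {
    X <- sweep(sweep(X, 2, object$scaling$center), 2,
               object$scaling$scale, "/")
  }
  P <- mlp_forward(object$weights, X)$P
  tibble::tibble(p_stance = P[, 1], p_swing = P[, 2], p_abnormal = P[, 3],
                 label = factor(object$levels[max.col(P)],
                                levels = object$levels))
}

#' @export
print.gait_mlp <- function(x, ...) {
  cat(sprintf("<gait_mlp> %s | %d parameters%s\n",
              paste(x$sizes, collapse = "-"), n_parameters(x),
              if (is.null(x$history)) " (untrained)" else
                sprintf(" | trained %d epochs (best %d)",
                        max(x$history$epoch), x$config$best_epoch)))
  invisible(x)
}

#' Save / load a gait-phase MLP
#'
#' Self-describing JSON container recording layer sizes, weights at full
#' double precision, input scaling, class levels and the training
#' configuration. Load reproduces weights bit-exactly.
#'
#' @param model a `gait_mlp`.
#' @param path file path (.json).
#' @return `save_mlp()` returns `path` invisibly; `load_mlp()` the model.
#' @export
save_mlp <- function(model, path) {
  payload <- list(
    format = "gaitloop-mlp", version = 1L,
    sizes = model$sizes, levels = model$levels,
    scaling = model$scaling,
    config = model$config,
    weights = purrr::map(model$weights,
                         function(l) list(W = l$W, b = l$b)),
    history = model$history
  )
  # 17 significant digits round-trip IEEE doubles exactly
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname save_mlp
#' @export
load_mlp <- function(path) {
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e) {
                        abort(paste0("Cannot parse model file: ", path),
                              class = "gaitloop_error_format")
                      })
  if (is.null(payload$format) || payload$format != "gaitloop-mlp") {
    abort("Not a gaitloop MLP model file.", class = "gaitloop_error_format")
  }
  sizes <- as.integer(payload$sizes)
  weights <- purrr::map(seq_len(length(sizes) - 1), function(l) {
    W <- payload$weights$W[[l]]
    list(W = matrix(as.numeric(W), sizes[l], sizes[l + 1]),
         b = as.numeric(payload$weights$b[[l]]))
  })
  scaling <- payload$scaling
  if (!is.null(scaling)) {
    scaling <- list(center = as.numeric(scaling$center),
                    scale = as.numeric(scaling$scale))
  }
  structure(list(sizes = sizes, weights = weights, scaling = scaling,
                 levels = as.character(payload$levels),
                 history = if (is.null(payload$history)) NULL else
                   tibble::as_tibble(payload$history),
                 config = payload$config),
            class = "gait_mlp")
}

#' Tidy the layer structure of a gait-phase MLP
#'
#' @param x a `gait_mlp`.
#' @param ... unused.
#' @return tibble with one row per layer: sizes and parameter counts.
#' @export
tidy.gait_mlp <- function(x, ...) {
  L <- length(x$weights)
  tibble::tibble(layer = seq_len(L),
                 fan_in = x$sizes[seq_len(L)],
                 fan_out = x$sizes[-1],
                 n_weights = purrr::map_int(x$weights,
                                            function(l) length(l$W)),
                 n_biases = purrr::map_int(x$weights,
                                           function(l) length(l$b)),
                 activation = c(rep("relu", L - 1), "softmax"))
}

#' One-row summary of a gait-phase MLP fit
#'
#' @param x a `gait_mlp`.
#' @param ... unused.
#' @return one-row tibble: parameter count, epochs trained, best epoch,
#'   best validation loss/accuracy (NA if untrained).
#' @export
glance.gait_mlp <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    n_parameters = n_parameters(x),
    epochs_trained = if (is.null(h)) NA_integer_ else max(h$epoch),
    best_epoch = if (is.null(h)) NA_integer_ else x$config$best_epoch,
    val_loss = if (is.null(h)) NA_real_ else min(h$val_loss),
    val_accuracy = if (is.null(h)) NA_real_ else
      h$val_acc[which.min(h$val_loss)]
  )
}

#' Plot training curves of a gait-phase MLP
#'
#' @param object a trained `gait_mlp`.
#' @param ... unused.
#' @return a ggplot of loss and accuracy per epoch.
#' @export
autoplot.gait_mlp <- function(object, ...) {
  if (is.null(object$history)) {
    abort("Model has no training history.", class = "gaitloop_error_value")
  }
  h <- object$history %>%
    tidyr::pivot_longer(-"epoch", names_to = c("split", "metric"),
                        names_sep = "_")
  ggplot2::ggplot(h, ggplot2::aes(.data$epoch, .data$value,
                                  color = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, color = NULL) +
    ggplot2::theme_minimal()
}
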