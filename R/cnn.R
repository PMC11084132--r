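#' Configuration for the breathprint CNN
#'
#' The classifier is a small three-layer convolutional network mapping a
#' 14 x 16 x 16 breathprint image to a lung-cancer probability: three
#' conv(3x3, same padding) + ReLU + max-pool(2x2) stages, a flattened
#' feature vector (optionally with dropout), and a single sigmoid output
#' unit. It is trained by minimising binary cross-entropy with Adam; when
#' a validation set is supplied, epochs are selected by validation AUC
#' (cross-entropy as tie-break), early stopping applies, and predictions
#' average the three best epoch checkpoints.
#'
#' @param conv_channels Three positive integers: filters per conv layer.
#' @param kernel_size Positive odd kernel size (must not exceed the
#'   smallest feature map, 4 x 4 at the third layer).
#' @param dropout_rate Dropout probability in `[0, 1)` applied to the
#'   pooled features during training.
#' @param learning_rate Adam step size for full training.
#' @param epochs Maximum training epochs.
#' @param batch_size Minibatch size.
#' @param patience Early-stopping patience (epochs without validation-loss
#'   improvement); ignored when no validation set is given.
#' @param seed Integer seed controlling initialisation, shuffling, dropout.
#' @param finetune List of fine-tuning settings: `n_samples` (target-site
#'   samples used, default 10), `learning_rate`, `epochs`, `frozen_layers`
#'   (subset of `"conv1"`, `"conv2"`, `"conv3"` kept bit-identical) and
#'   `l2_anchor`, the ridge penalty tying the tuned parameters to the
#'   source-model weights (a few target samples cannot support an
#'   unconstrained refit).
#' @return An object of class `cnn_config`.
#' @export
cnn_config <- function(conv_channels = c(8L, 16L, 32L),
                       kernel_size = 3L,
                       dropout_rate = 0,
                       learning_rate = 1e-3,
                       epochs = 60L,
                       batch_size = 32L,
                       patience = 10L,
                       seed = 1L,
                       finetune = list(n_samples = 10L,
                                       learning_rate = 1e-3,
                                       epochs = 30L,
                                       l2_anchor = 8,
                                       frozen_layers = c("conv1", "conv2",
                                                         "conv3"))) {
  if (length(conv_channels) != 3L || any(conv_channels < 1)) {
    invalid_argument("`conv_channels` must be three positive integers.")
  }
  check_scalar_number(kernel_size, "kernel_size")
  if (kernel_size < 1 || kernel_size %% 2 != 1) {
    invalid_argument("`kernel_size` must be a positive odd integer.")
  }
  if (kernel_size > 4) {
    invalid_argument("kernel larger than the smallest feature map (4 x 4).")
  }
  check_scalar_number(dropout_rate, "dropout_rate")
  if (dropout_rate < 0 || dropout_rate >= 1) {
    invalid_argument("`dropout_rate` must be in [0, 1).")
  }
  check_scalar_number(learning_rate, "learning_rate")
  if (learning_rate <= 0) invalid_argument("`learning_rate` must be > 0.")
  if (epochs < 0) invalid_argument("`epochs` must be >= 0.")
  if (batch_size < 1) invalid_argument("`batch_size` must be >= 1.")
  ft_default <- list(n_samples = 10L, learning_rate = 1e-3, epochs = 30L,
                     l2_anchor = 8,
                     frozen_layers = c("conv1", "conv2", "conv3"))
  finetune <- utils::modifyList(ft_default, finetune)
  if (!all(finetune$frozen_layers %in% c("conv1", "conv2", "conv3"))) {
    invalid_argument("`frozen_layers` must be a subset of conv1..conv3.")
  }
  structure(
    list(conv_channels = as.integer(conv_channels),
         kernel_size = as.integer(kernel_size),
         dropout_rate = dropout_rate,
         learning_rate = learning_rate,
         epochs = as.integer(epochs),
         batch_size = as.integer(batch_size),
         patience = as.integer(patience),
         seed = as.integer(seed),
         finetune = finetune),
    class = "cnn_config"
  )
}

# ---- low-level layers (channel-first arrays: C x H x W x N) --------------

conv_forward <- function(X, W, b) {
  d <- dim(X); Cin <- d[1]; H <- d[2]; Wd <- d[3]; N <- d[4]
  k <- dim(W)[1]; p <- (k - 1L) %/% 2L; Cout <- dim(W)[4]
  Xp <- array(0, c(Cin, H + 2L * p, Wd + 2L * p, N))
  Xp[, p + seq_len(H), p + seq_len(Wd), ] <- X
  M <- H * Wd * N
  out <- matrix(0, Cout, M)
  for (ki in seq_len(k)) {
    for (kj in seq_len(k)) {
      Xs <- Xp[, ki:(ki + H - 1L), kj:(kj + Wd - 1L), , drop = FALSE]
      dim(Xs) <- c(Cin, M)
      out <- out + crossprod(matrix(W[ki, kj, , ], Cin, Cout), Xs)
    }
  }
  out <- out + b
  dim(out) <- c(Cout, H, Wd, N)
  list(out = out, Xp = Xp, H = H, Wd = Wd, pad = p)
}

conv_backward <- function(dY, cache, W, need_dx = TRUE) {
  H <- cache$H; Wd <- cache$Wd; p <- cache$pad
  Xp <- cache$Xp
  d <- dim(dY); Cout <- d[1]; N <- d[4]
  Cin <- dim(Xp)[1]; k <- dim(W)[1]
  M <- H * Wd * N
  dYm <- dY; dim(dYm) <- c(Cout, M)
  dW <- array(0, dim(W))
  dXp <- if (need_dx) array(0, dim(Xp)) else NULL
  for (ki in seq_len(k)) {
    for (kj in seq_len(k)) {
      Xs <- Xp[, ki:(ki + H - 1L), kj:(kj + Wd - 1L), , drop = FALSE]
      dim(Xs) <- c(Cin, M)
      dW[ki, kj, , ] <- tcrossprod(Xs, dYm)
      if (need_dx) {
        dXs <- matrix(W[ki, kj, , ], Cin, dim(W)[4]) %*% dYm
        dim(dXs) <- c(Cin, H, Wd, N)
        dXp[, ki:(ki + H - 1L), kj:(kj + Wd - 1L), ] <-
          dXp[, ki:(ki + H - 1L), kj:(kj + Wd - 1L), ] + dXs
      }
    }
  }
  dX <- if (need_dx) dXp[, p + seq_len(H), p + seq_len(Wd), , drop = FALSE]
  list(dX = dX, dW = dW, db = rowSums(dYm))
}

pool_forward <- function(X) {
  d <- dim(X); C <- d[1]; H <- d[2]; Wd <- d[3]; N <- d[4]
  oh <- seq(1L, H, 2L); ev_h <- oh + 1L
  ow <- seq(1L, Wd, 2L); ev_w <- ow + 1L
  x11 <- X[, oh, ow, , drop = FALSE]
  x12 <- X[, oh, ev_w, , drop = FALSE]
  x21 <- X[, ev_h, ow, , drop = FALSE]
  x22 <- X[, ev_h, ev_w, , drop = FALSE]
  m <- pmax(x11, x12, x21, x22)
  m11 <- x11 == m
  m12 <- (x12 == m) & !m11
  m21 <- (x21 == m) & !m11 & !m12
  m22 <- !m11 & !m12 & !m21
  list(out = m, masks = list(m11, m12, m21, m22), in_dim = d)
}

pool_backward <- function(dY, cache) {
  d <- cache$in_dim
  dX <- array(0, d)
  oh <- seq(1L, d[2], 2L); ev_h <- oh + 1L
  ow <- seq(1L, d[3], 2L); ev_w <- ow + 1L
  dX[, oh, ow, ] <- dY * cache$masks[[1]]
  dX[, oh, ev_w, ] <- dY * cache$masks[[2]]
  dX[, ev_h, ow, ] <- dY * cache$masks[[3]]
  dX[, ev_h, ev_w, ] <- dY * cache$masks[[4]]
  dX
}

flatten_forward <- function(X) {
  d <- dim(X)
  out <- X
  dim(out) <- c(d[1] * d[2] * d[3], d[4])
  out
}

flatten_backward <- function(dG, in_dim) {
  dX <- dG
  dim(dX) <- in_dim
  dX
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Numerically stable mean binary cross-entropy from logits.
bce_from_logits <- function(z, y) {
  mean(pmax(z, 0) - y * z + log1p(exp(-abs(z))))
}

cnn_forward <- function(params, X, dropout_rate = 0, dropout_seed = NULL,
                        keep_cache = FALSE) {
  c1 <- conv_forward(X, params$conv1$W, params$conv1$b)
  r1 <- pmax(c1$out, 0)
  p1 <- pool_forward(r1)
  c2 <- conv_forward(p1$out, params$conv2$W, params$conv2$b)
  r2 <- pmax(c2$out, 0)
  p2 <- pool_forward(r2)
  c3 <- conv_forward(p2$out, params$conv3$W, params$conv3$b)
  r3 <- pmax(c3$out, 0)
  p3 <- pool_forward(r3)
  g <- flatten_forward(p3$out)
  drop_mask <- NULL
  if (dropout_rate > 0 && !is.null(dropout_seed)) {
    keep <- 1 - dropout_rate
    drop_mask <- withr::with_seed(dropout_seed, {
      matrix(runif(length(g)) < keep, nrow(g), ncol(g)) / keep
    })
    g <- g * drop_mask
  }
  z <- drop(crossprod(params$head$W, g)) + params$head$b
  res <- list(z = z, prob = sigmoid(z))
  if (keep_cache) {
    res$cache <- list(c1 = c1, r1 = r1, p1 = p1, c2 = c2, r2 = r2, p2 = p2,
                      c3 = c3, r3 = r3, p3 = p3, g = g,
                      drop_mask = drop_mask)
  }
  res
}

cnn_backward <- function(params, fwd, y) {
  ca <- fwd$cache
  N <- length(y)
  dz <- (fwd$prob - y) / N
  g <- ca$g
  dW_head <- g %*% matrix(dz, ncol = 1)
  db_head <- sum(dz)
  dg <- params$head$W %*% matrix(dz, nrow = 1)
  if (!is.null(ca$drop_mask)) dg <- dg * ca$drop_mask
  d3 <- flatten_backward(dg, dim(ca$p3$out))
  d3 <- pool_backward(d3, ca$p3)
  d3 <- d3 * (ca$c3$out > 0)
  b3 <- conv_backward(d3, ca$c3, params$conv3$W)
  d2 <- pool_backward(b3$dX, ca$p2)
  d2 <- d2 * (ca$c2$out > 0)
  b2 <- conv_backward(d2, ca$c2, params$conv2$W)
  d1 <- pool_backward(b2$dX, ca$p1)
  d1 <- d1 * (ca$c1$out > 0)
  b1 <- conv_backward(d1, ca$c1, params$conv1$W, need_dx = FALSE)
  list(conv1 = list(W = b1$dW, b = b1$db),
       conv2 = list(W = b2$dW, b = b2$db),
       conv3 = list(W = b3$dW, b = b3$db),
       head = list(W = dW_head, b = db_head))
}

# ---- model object --------------------------------------------------------

#' Build an (untrained) breathprint CNN
#'
#' Initialises the three-layer CNN deterministically from the config seed:
#' He-scaled Gaussian convolution weights, zero biases, and a
#' zero-initialised sigmoid head (so an all-zero input yields probability
#' 0.5 exactly).
#'
#' @param config A [cnn_config()].
#' @return An object of class `breathnet_cnn` with elements `params`,
#'   `config`, `history` (empty tibble) and `provenance`.
#' @export
build_model <- function(config = cnn_config()) {
  if (!inherits(config, "cnn_config")) {
    invalid_argument("`config` must be a cnn_config.")
  }
  k <- config$kernel_size
  ch <- c(14L, config$conv_channels)
  params <- withr::with_seed(derive_seed(config$seed, "init"), {
    p <- list()
    for (l in 1:3) {
      fan_in <- k * k * ch[l]
      p[[paste0("conv", l)]] <- list(
        W = array(rnorm(k * k * ch[l] * ch[l + 1], 0, sqrt(2 / fan_in)),
                  c(k, k, ch[l], ch[l + 1])),
        b = rep(0, ch[l + 1])
      )
    }
    p$head <- list(W = matrix(0, ch[4] * 4L, 1), b = 0)
    p
  })
  structure(
    list(params = params, config = config,
         history = tibble::tibble(epoch = integer(), loss = double(),
                                  val_auc = double(), val_loss = double()),
         provenance = list(trained = FALSE)),
    class = "breathnet_cnn"
  )
}

# Stack an images tibble into a (14, 16, 16, N) array.
images_to_array <- function(images) {
  if (!"image" %in% names(images) || nrow(images) == 0L) {
    invalid_argument("`images` must be a non-empty tibble with an `image` column.")
  }
  for (img in images$image) {
    if (!identical(dim(img), c(14L, 16L, 16L))) {
      invalid_argument("every image must be a 14 x 16 x 16 array.")
    }
  }
  X <- array(0, c(14L, 16L, 16L, nrow(images)))
  for (i in seq_len(nrow(images))) X[, , , i] <- images$image[[i]]
  X
}

#' Binary outcome coding for breathprint labels
#'
#' Lung cancer is the positive class (1); healthy and diseased controls are
#' both negative (0).
#'
#' @param labels Character vector of diagnosis labels.
#' @return Integer vector of 0/1.
#' @export
binary_labels <- function(labels) {
  as.integer(labels == "lung_cancer")
}

# ---- training ------------------------------------------------------------

#' Train the breathprint CNN
#'
#' Minimises binary cross-entropy with Adam over seeded, shuffled
#' minibatches. Samples are put into a canonical order (by `sample_id`)
#' before training, so the result is invariant to the input row order and
#' bit-reproducible given the config seed. When `validation` is supplied,
#' the validation AUC and cross-entropy are recorded each epoch; early
#' stopping monitors the validation cross-entropy and the weights of the
#' best epoch are restored. Validation labels are used for model selection
#' only, never for gradient updates.
#'
#' @param model A [build_model()] result.
#' @param images Training tibble with `image` list-column, `label`,
#'   `sample_id`.
#' @param config Optional [cnn_config()] overriding the model's config.
#' @param validation Optional validation tibble of the same shape.
#' @return The trained `breathnet_cnn` with `history` and `provenance`
#'   filled in.
#' @export
train <- function(model, images, config = NULL, validation = NULL) {
  if (!inherits(model, "breathnet_cnn")) {
    invalid_argument("`model` must be a breathnet_cnn.")
  }
  config <- config %||% model$config
  y_all <- binary_labels(images$label)
  if (length(unique(y_all)) < 2L) {
    invalid_argument("training data must contain both classes.")
  }
  ord <- order(images$sample_id)
  images <- images[ord, ]
  X <- images_to_array(images)
  y <- binary_labels(images$label)
  n <- length(y)

  val_X <- NULL; val_y <- NULL
  if (!is.null(validation)) {
    val_X <- images_to_array(validation)
    val_y <- binary_labels(validation$label)
  }

  params <- model$params
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  moments1 <- rapply(params, function(x) x * 0, how = "replace")
  moments2 <- rapply(params, function(x) x * 0, how = "replace")

  history <- list()
  snaps <- list()
  best <- list(auc = -Inf, loss = Inf, params = params, epoch = 0L)
  wait <- 0L
  t_step <- 0L

  for (epoch in seq_len(config$epochs)) {
    perm <- withr::with_seed(derive_seed(config$seed, paste0("perm_", epoch)),
                             sample.int(n))
    losses <- c()
    batch_starts <- seq(1L, n, by = config$batch_size)
    for (bi in seq_along(batch_starts)) {
      idx <- perm[batch_starts[bi]:min(batch_starts[bi] + config$batch_size - 1L, n)]
      Xb <- X[, , , idx, drop = FALSE]
      yb <- y[idx]
      dseed <- derive_seed(config$seed, paste0("drop_", epoch, "_", bi))
      fwd <- cnn_forward(params, Xb, dropout_rate = config$dropout_rate,
                         dropout_seed = dseed, keep_cache = TRUE)
      losses <- c(losses, bce_from_logits(fwd$z, yb))
      grads <- cnn_backward(params, fwd, yb)
      t_step <- t_step + 1L
      for (layer in names(params)) {
        for (pn in names(params[[layer]])) {
          g <- grads[[layer]][[pn]]
          moments1[[layer]][[pn]] <- beta1 * moments1[[layer]][[pn]] + (1 - beta1) * g
          moments2[[layer]][[pn]] <- beta2 * moments2[[layer]][[pn]] + (1 - beta2) * g^2
          mhat <- moments1[[layer]][[pn]] / (1 - beta1^t_step)
          vhat <- moments2[[layer]][[pn]] / (1 - beta2^t_step)
          params[[layer]][[pn]] <- params[[layer]][[pn]] -
            config$learning_rate * mhat / (sqrt(vhat) + eps)
        }
      }
    }
    val_auc <- NA_real_
    val_loss <- NA_real_
    if (!is.null(val_X)) {
      val_fwd <- cnn_forward(params, val_X)
      val_auc <- roc_auc(val_y, val_fwd$prob)
      val_loss <- bce_from_logits(val_fwd$z, val_y)
      # model selection on validation AUC, ties broken by the validation
      # cross-entropy (the AUC on a 50-sample set is a step function with
      # frequent ties). The three best epochs are kept and averaged at
      # prediction time (checkpoint averaging), damping selection noise.
      snaps[[epoch]] <- list(auc = val_auc, loss = val_loss,
                             params = params, epoch = epoch)
      improved <- val_auc > best$auc + 1e-9 ||
        (abs(val_auc - best$auc) <= 1e-9 && val_loss < best$loss - 1e-9)
      if (improved) {
        best <- list(auc = val_auc, loss = val_loss, params = params,
                     epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
      }
    }
    history[[epoch]] <- tibble::tibble(epoch = epoch, loss = mean(losses),
                                       val_auc = val_auc,
                                       val_loss = val_loss)
    if (!is.null(val_X) && wait >= config$patience) break
  }

  snapshots <- NULL
  if (!is.null(val_X) && is.finite(best$auc)) {
    params <- best$params
    keep <- head(order(-vapply(snaps, `[[`, 0, "auc"),
                       vapply(snaps, `[[`, 0, "loss")), 3L)
    if (length(keep) > 1L) {
      snapshots <- lapply(snaps[keep], `[[`, "params")
    }
  }

  model$params <- params
  model$snapshots <- snapshots
  model$config <- config
  model$history <- if (length(history)) dplyr::bind_rows(history) else model$history
  model$provenance <- list(
    trained = TRUE,
    train_ids = sort(images$sample_id),
    fingerprint = rlang::hash(sort(images$sample_id)),
    seed = config$seed,
    best_epoch = if (is.finite(best$auc)) best$epoch else length(history),
    finetune_ids = character()
  )
  model
}

#' Predict lung-cancer probabilities
#'
#' Deterministic forward pass (no dropout); one probability per image,
#' in input order. For a model trained with validation-based selection the
#' probabilities are the average over the retained epoch checkpoints.
#' Batched and single-sample evaluation agree to numerical round-off.
#'
#' @param model A `breathnet_cnn`.
#' @param images Tibble with an `image` list-column.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_proba <- function(model, images) {
  if (!inherits(model, "breathnet_cnn")) {
    invalid_argument("`model` must be a breathnet_cnn.")
  }
  X <- images_to_array(images)
  snaps <- model$snapshots %||% list(model$params)
  # checkpoints are combined on the logit scale (geometric mean of odds),
  # so a common intercept change shifts every score monotonically and
  # never reorders samples
  logits <- lapply(snaps, function(p) cnn_forward(p, X)$z)
  as.double(sigmoid(Reduce(`+`, logits) / length(logits)))
}

#' Fine-tune a trained CNN on a few target-site samples
#'
#' Adapts the model to the target site using a small held-out partition
#' (default 10 samples) with the layers named in
#' `config$finetune$frozen_layers` kept bit-identical. By default all three
#' convolutional layers are frozen and only the sigmoid head is updated: a
#' handful of samples cannot support full retraining. In this default case
#' the new head is found by an anchored two-direction logistic refit in the
#' pooled-feature space — the refit score is a combination of the source
#' model's head direction and the fine-tune set's class-mean contrast,
#' fitted by penalised Newton iterations with a ridge anchor
#' (`l2_anchor`) that pulls the solution toward the source head. This
#' bounds how far ten samples can rotate the decision direction while
#' still letting an informative target sample recalibrate it. When some
#' convolutional layers are left trainable, ordinary anchored Adam updates
#' are used instead. The fine-tuned samples' ids are recorded in the model
#' provenance, and any overlap with a previously registered evaluation set
#' raises a leakage error.
#'
#' @param model A trained `breathnet_cnn`.
#' @param finetune_images Tibble of fine-tuning samples; its size must
#'   equal `config$finetune$n_samples`.
#' @param config Optional [cnn_config()] override.
#' @return The fine-tuned model.
#' @export
fine_tune <- function(model, finetune_images, config = NULL) {
  if (!inherits(model, "breathnet_cnn")) {
    invalid_argument("`model` must be a breathnet_cnn.")
  }
  config <- config %||% model$config
  ft <- config$finetune
  if (nrow(finetune_images) != ft$n_samples) {
    invalid_argument(sprintf(
      "fine-tune set has %d samples but config$finetune$n_samples is %d.",
      nrow(finetune_images), ft$n_samples))
  }
  eval_ids <- model$provenance$eval_ids %||% character()
  overlap <- intersect(finetune_images$sample_id, eval_ids)
  if (length(overlap) > 0L) {
    leakage_error(paste0("fine-tune samples overlap an evaluation set: ",
                         paste(overlap, collapse = ", ")))
  }
  ord <- order(finetune_images$sample_id)
  finetune_images <- finetune_images[ord, ]
  X <- images_to_array(finetune_images)
  y <- binary_labels(finetune_images$label)

  params <- model$params
  anchor <- model$params
  frozen <- ft$frozen_layers
  trainable <- setdiff(names(params), frozen)
  if (ft$epochs > 0 && identical(sort(frozen), c("conv1", "conv2", "conv3"))) {
    params$head <- refit_head_anchored(params, X, y, ft)
    if (!is.null(model$snapshots)) {
      model$snapshots <- lapply(model$snapshots, function(p) {
        p$head <- refit_head_anchored(p, X, y, ft)
        p
      })
    }
  } else if (ft$epochs > 0) {
    model$snapshots <- NULL
    moments1 <- rapply(params, function(x) x * 0, how = "replace")
    moments2 <- rapply(params, function(x) x * 0, how = "replace")
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    t_step <- 0L
    for (epoch in seq_len(ft$epochs)) {
      fwd <- cnn_forward(params, X, keep_cache = TRUE)
      grads <- cnn_backward(params, fwd, y)
      t_step <- t_step + 1L
      for (layer in trainable) {
        for (pn in names(params[[layer]])) {
          g <- grads[[layer]][[pn]] +
            ft$l2_anchor * (params[[layer]][[pn]] - anchor[[layer]][[pn]])
          moments1[[layer]][[pn]] <- beta1 * moments1[[layer]][[pn]] + (1 - beta1) * g
          moments2[[layer]][[pn]] <- beta2 * moments2[[layer]][[pn]] + (1 - beta2) * g^2
          mhat <- moments1[[layer]][[pn]] / (1 - beta1^t_step)
          vhat <- moments2[[layer]][[pn]] / (1 - beta2^t_step)
          params[[layer]][[pn]] <- params[[layer]][[pn]] -
            ft$learning_rate * mhat / (sqrt(vhat) + eps)
        }
      }
    }
  }
  model$params <- params
  model$provenance$finetune_ids <- sort(finetune_images$sample_id)
  model$provenance$finetune_fingerprint <- rlang::hash(sort(finetune_images$sample_id))
  model
}

# Pooled (flattened) features of the frozen convolutional stack.
conv_features <- function(params, X) {
  c1 <- conv_forward(X, params$conv1$W, params$conv1$b)
  p1 <- pool_forward(pmax(c1$out, 0))
  c2 <- conv_forward(p1$out, params$conv2$W, params$conv2$b)
  p2 <- pool_forward(pmax(c2$out, 0))
  c3 <- conv_forward(p2$out, params$conv3$W, params$conv3$b)
  p3 <- pool_forward(pmax(c3$out, 0))
  flatten_forward(p3$out)
}

# Two-direction anchored logistic fit in feature space: the score combines
# the source head direction (standardised coefficient anchored at 1) and
# the fine-tune class-mean contrast (anchored at 0), with ridge strength
# l2_anchor bounding how far ten samples can rotate the decision
# direction. Deterministic penalised Newton iterations, no randomness.
anchored_logistic_head <- function(g, y, w0, ft) {
  n <- length(y)
  u <- rowMeans(g[, y == 1L, drop = FALSE]) -
    rowMeans(g[, y == 0L, drop = FALSE])
  s1 <- drop(crossprod(w0, g))
  s2 <- drop(crossprod(u, g))
  sd1 <- sd(s1); sd2 <- sd(s2)
  z1 <- if (sd1 > 1e-12) (s1 - mean(s1)) / sd1 else rep(0, n)
  z2 <- if (sd2 > 1e-12) (s2 - mean(s2)) / sd2 else rep(0, n)
  Z <- cbind(1, z1, z2)
  beta <- c(0, 1, 0)          # start at the source model's direction
  prior <- c(0, 1, 0)
  pen <- diag(c(0, ft$l2_anchor, ft$l2_anchor))
  for (it in seq_len(ft$epochs)) {
    eta <- drop(Z %*% beta)
    p <- sigmoid(eta)
    grad <- crossprod(Z, p - y) / n + pen %*% (beta - prior)
    Wdiag <- pmax(p * (1 - p), 1e-6)
    Hess <- crossprod(Z * Wdiag, Z) / n + pen
    step <- solve(Hess, grad)
    beta <- beta - drop(step)
    if (max(abs(step)) < 1e-10) break
  }
  w_new <- numeric(length(w0))
  b_new <- beta[1]
  if (sd1 > 1e-12) {
    w_new <- w_new + (beta[2] / sd1) * w0
    b_new <- b_new - beta[2] * mean(s1) / sd1
  }
  if (sd2 > 1e-12) {
    w_new <- w_new + (beta[3] / sd2) * u
    b_new <- b_new - beta[3] * mean(s2) / sd2
  }
  list(W = matrix(w_new, ncol = 1), b = b_new)
}

# One-dimensional maximum-likelihood intercept shift on fixed logits. The
# score mean(sigmoid(logit + delta)) - mean(y) is monotone in delta, so
# the optimum is found by root bracketing; the result is clamped so the
# recalibrated logits stay away from the range where probabilities
# saturate to exact 0/1 in double precision (which would destroy the
# score ordering).
recalibrate_intercept <- function(logit, y, safe = 30) {
  ybar <- mean(y)
  if (ybar <= 0 || ybar >= 1) return(0)
  width <- diff(range(logit)) + 100
  root <- stats::uniroot(function(d) mean(sigmoid(logit + d)) - ybar,
                         lower = -min(logit) - width,
                         upper = -max(logit) + width,
                         tol = 1e-10, extendInt = "upX")
  delta <- root$root
  lo <- -safe - min(logit)
  hi <- safe - max(logit)
  if (lo <= hi) min(max(delta, lo), hi) else -stats::median(logit)
}

# Head refit with a leave-one-out acceptance check: the anchored refit is
# adopted only when its leave-one-out cross-entropy on the fine-tune
# samples beats that of the unchanged source head. Otherwise the source
# direction is kept and only the intercept is recalibrated (a threshold
# shift that leaves the ranking untouched). With ten samples this guards
# against adapting the decision direction to an uninformative draw.
refit_head_anchored <- function(params, X, y, ft) {
  g <- conv_features(params, X)
  n <- length(y)
  w0 <- drop(params$head$W)
  loo_logit <- numeric(n)
  ok <- TRUE
  for (i in seq_len(n)) {
    yi <- y[-i]
    if (length(unique(yi)) < 2L) { ok <- FALSE; break }
    h <- anchored_logistic_head(g[, -i, drop = FALSE], yi, w0, ft)
    loo_logit[i] <- drop(crossprod(h$W, g[, i, drop = FALSE])) + h$b
  }
  if (ok) {
    orig_logit <- drop(crossprod(params$head$W, g)) + params$head$b
    auc_safe <- function(s) {
      if (sd(s) < 1e-12) return(0.5)
      roc_auc(y, s)
    }
    # adopt the refit only when it clearly wins on leave-one-out
    # cross-entropy without clearly damaging the leave-one-out ranking;
    # anything weaker becomes a threshold recalibration only (ten samples
    # rarely justify rotating the separating direction, but they do
    # justify rescuing a badly mis-scaled head)
    adopt <- bce_from_logits(loo_logit, y) <
      bce_from_logits(orig_logit, y) - 0.1 &&
      auc_safe(loo_logit) >= auc_safe(orig_logit) - 0.05
    if (!adopt) {
      b_shift <- recalibrate_intercept(orig_logit, y)
      return(list(W = params$head$W, b = params$head$b + b_shift))
    }
  }
  anchored_logistic_head(g, y, w0, ft)
}

#' Register an evaluation set on a model (leakage guard)
#'
#' Records the sample ids a model is about to be evaluated on, so a later
#' [fine_tune()] call on overlapping samples aborts.
#'
#' @param model A `breathnet_cnn`.
#' @param sample_ids Character vector of evaluation sample ids.
#' @return The model with updated provenance.
#' @export
register_eval_set <- function(model, sample_ids) {
  overlap <- intersect(sample_ids, model$provenance$finetune_ids %||% character())
  if (length(overlap) > 0L) {
    leakage_error(paste0("evaluation set contains fine-tune sample(s): ",
                         paste(overlap, collapse = ", ")))
  }
  model$provenance$eval_ids <- union(model$provenance$eval_ids %||% character(),
                                     sample_ids)
  model
}

#' @export
print.breathnet_cnn <- function(x, ...) {
  ch <- x$config$conv_channels
  n_par <- sum(rapply(x$params, length, how = "unlist"))
  cat("<breathnet_cnn> 3-layer CNN (", paste(ch, collapse = "-"),
      " filters), ", n_par, " parameters, ",
      if (isTRUE(x$provenance$trained)) "trained" else "untrained",
      "\n", sep = "")
  invisible(x)
}
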