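test_that("model construction is seeded and validates its inputs", {
  cfg <- cnn_config(seed = 21)
  imgs <- tiny_images(2, 1, 1, seed = 20)
  m1 <- build_model(cfg)
  m2 <- build_model(cfg)
  expect_identical(predict_proba(m1, imgs), predict_proba(m2, imgs))

  m3 <- build_model(cnn_config(seed = 22))
  expect_false(identical(m3$params$conv1$W, m1$params$conv1$W))

  expect_error(cnn_config(kernel_size = 5),
               class = "breathnet_invalid_argument")
  expect_error(cnn_config(kernel_size = 2),
               class = "breathnet_invalid_argument")
  expect_error(cnn_config(dropout_rate = 1),
               class = "breathnet_invalid_argument")

  bad <- imgs
  bad$image[[1]] <- array(0, c(14, 8, 8))
  expect_error(predict_proba(m1, bad), class = "breathnet_invalid_argument")
})

test_that("an all-zero input passes through the zero-initialised head to probability 0.5", {
  m <- build_model(cnn_config(seed = 1))
  zero <- tibble::tibble(sample_id = "z", label = "healthy_control",
                         image = list(array(0, c(14L, 16L, 16L))))
  expect_equal(predict_proba(m, zero), 0.5)
})

test_that("backpropagation matches numerical gradients", {
  ns <- asNamespace("breathnet")
  cfg <- cnn_config(conv_channels = c(3L, 4L, 5L), seed = 7)
  params <- build_model(cfg)$params
  withr::with_seed(2, {
    X <- array(rnorm(14 * 16 * 16 * 4), c(14, 16, 16, 4))
    params$head$W[] <- rnorm(length(params$head$W), 0, 0.1)
  })
  y <- c(1, 0, 1, 0)
  fwd <- ns$cnn_forward(params, X, keep_cache = TRUE)
  gr <- ns$cnn_backward(params, fwd, y)
  num_grad <- function(layer, pn, idx, eps = 1e-5) {
    p2 <- params
    p2[[layer]][[pn]][idx] <- p2[[layer]][[pn]][idx] + eps
    lp <- ns$bce_from_logits(ns$cnn_forward(p2, X)$z, y)
    p2[[layer]][[pn]][idx] <- p2[[layer]][[pn]][idx] - 2 * eps
    lm <- ns$bce_from_logits(ns$cnn_forward(p2, X)$z, y)
    (lp - lm) / (2 * eps)
  }
  withr::with_seed(3, {
    for (layer in c("conv1", "conv2", "conv3", "head")) {
      for (pn in c("W", "b")) {
        n <- length(params[[layer]][[pn]])
        for (idx in sample(n, min(3, n))) {
          a <- gr[[layer]][[pn]][idx]
          b <- num_grad(layer, pn, idx)
          expect_lt(abs(a - b) / max(1e-8, abs(a) + abs(b)), 1e-6)
        }
      }
    }
  })
})

test_that("training requires both classes and zero epochs keeps the initialisation", {
  imgs <- tiny_images(3, 1, 2, seed = 23)
  one_class <- imgs[imgs$label == "lung_cancer", ]
  m <- build_model(cnn_config(seed = 2))
  expect_error(train(m, one_class), class = "breathnet_invalid_argument")

  m0 <- train(m, imgs, cnn_config(epochs = 0, seed = 2))
  expect_identical(m0$params, m$params)
  expect_true(m0$provenance$trained)
})

test_that("training overfits a small linearly separable set to accuracy 1", {
  imgs <- separable_images(10)
  cfg <- cnn_config(epochs = 40, dropout_rate = 0, batch_size = 20, seed = 4)
  m <- train(build_model(cfg), imgs, cfg)
  pred <- as.integer(predict_proba(m, imgs) >= 0.5)
  expect_equal(mean(pred == binary_labels(imgs$label)), 1)
})

test_that("training is invariant to input row order and reproducible", {
  imgs <- tiny_images(4, 2, 3, seed = 24)
  cfg <- cnn_config(epochs = 3, seed = 6)
  m1 <- train(build_model(cfg), imgs, cfg)
  shuffled <- imgs[withr::with_seed(1, sample(nrow(imgs))), ]
  m2 <- train(build_model(cfg), shuffled, cfg)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
})

test_that("full-batch training with a small learning rate has non-increasing loss", {
  imgs <- separable_images(5, seed = 31)
  cfg <- cnn_config(epochs = 15, dropout_rate = 0, batch_size = 32,
                    learning_rate = 1e-4, seed = 8)
  m <- train(build_model(cfg), imgs, cfg)
  loss <- tidy(m)$loss
  expect_true(all(diff(loss) <= 1e-4))
})

test_that("predictions are in [0,1], order-preserving, and batch-size independent", {
  imgs <- tiny_images(3, 2, 2, seed = 25)
  cfg <- cnn_config(epochs = 2, seed = 9)
  m <- train(build_model(cfg), imgs, cfg)
  p <- predict_proba(m, imgs)
  expect_true(all(p >= 0 & p <= 1))
  expect_identical(predict_proba(m, imgs), p)
  one_at_a_time <- vapply(seq_len(nrow(imgs)),
                          function(i) predict_proba(m, imgs[i, ]), 0)
  expect_lt(max(abs(one_at_a_time - p)), 1e-6)
})

test_that("fine-tuning freezes the requested layers and respects its sample budget", {
  imgs <- tiny_images(4, 2, 3, seed = 26)
  cfg <- cnn_config(epochs = 2, seed = 10,
                    finetune = list(n_samples = 4L, epochs = 10L))
  m <- train(build_model(cfg), imgs, cfg)
  ft_set <- tiny_images(2, 1, 1, seed = 27, site = "S2")

  # epochs = 0 leaves all weights untouched
  cfg0 <- cnn_config(epochs = 2, seed = 10,
                     finetune = list(n_samples = 4L, epochs = 0L))
  expect_identical(fine_tune(m, ft_set, cfg0)$params, m$params)

  ft <- fine_tune(m, ft_set, cfg)
  for (l in c("conv1", "conv2", "conv3")) {
    expect_identical(ft$params[[l]], m$params[[l]])
  }
  expect_false(identical(ft$params$head, m$params$head))

  expect_error(fine_tune(m, ft_set[1:3, ], cfg),
               class = "breathnet_invalid_argument")
})

test_that("fine-tuning on registered evaluation samples aborts with a leakage error", {
  imgs <- tiny_images(4, 2, 3, seed = 28)
  cfg <- cnn_config(epochs = 1, seed = 11,
                    finetune = list(n_samples = 4L, epochs = 2L))
  m <- train(build_model(cfg), imgs, cfg)
  target <- tiny_images(2, 1, 1, seed = 29, site = "S2")
  m <- register_eval_set(m, target$sample_id)
  expect_error(fine_tune(m, target, cfg),
               class = "breathnet_leakage_error")

  # and the reverse direction: evaluating on fine-tuned samples
  m2 <- train(build_model(cfg), imgs, cfg)
  m2 <- fine_tune(m2, target, cfg)
  expect_error(register_eval_set(m2, target$sample_id[1]),
               class = "breathnet_leakage_error")
})
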