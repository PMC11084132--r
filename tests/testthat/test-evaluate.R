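test_that("AUC matches the exhaustive pairwise oracle", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(roc_auc(c(0, 1, 0, 1), rep(0.5, 4)), 0.5)

  labels <- c(0, 1, 0, 1, 1)
  scores <- c(0.3, 0.2, 0.5, 0.7, 0.5)
  expect_equal(roc_auc(labels, scores), pairwise_auc_oracle(labels, scores))

  withr::with_seed(50, {
    for (i in 1:20) {
      n <- sample(4:20, 1)
      l <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
      s <- round(runif(n), 2)  # rounding forces occasional ties
      expect_equal(roc_auc(l, s), pairwise_auc_oracle(l, s))
    }
  })
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)),
               class = "breathnet_invalid_argument")
})

test_that("AUC is rank-based: invariant under monotone transforms, antisymmetric under negation", {
  withr::with_seed(51, {
    l <- c(rep(1, 6), rep(0, 8))
    s <- rnorm(14)
    a <- roc_auc(l, s)
    expect_equal(roc_auc(l, exp(3 * s) + 2), a)
    expect_equal(roc_auc(l, -s), 1 - a)
  })
})

test_that("ROC curves are monotone staircases from (0,0) to (1,1)", {
  withr::with_seed(52, {
    rc <- roc_curve(rep(0:1, each = 10), runif(20))
  })
  expect_equal(rc$fpr[1], 0); expect_equal(rc$tpr[1], 0)
  expect_equal(rc$fpr[nrow(rc)], 1); expect_equal(rc$tpr[nrow(rc)], 1)
  expect_true(all(diff(rc$fpr) >= 0))
  expect_true(all(diff(rc$tpr) >= 0))
})

test_that("thresholded metrics match a counting oracle", {
  perfect <- classification_metrics(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9),
                                    "fixed", threshold = 0.5)
  expect_equal(unlist(perfect[, 1:3]), c(sensitivity = 1, specificity = 1,
                                         accuracy = 1))
  low <- classification_metrics(c(0, 1), c(0.4, 0.6), "fixed", threshold = 0)
  expect_equal(low$sensitivity, 1)
  expect_equal(low$specificity, 0)

  labels <- c(1, 0, 1, 1, 0, 0, 1, 0, 1, 0)
  scores <- c(0.9, 0.8, 0.7, 0.4, 0.4, 0.2, 0.55, 0.5, 0.3, 0.1)
  t <- 0.5
  cm <- classification_metrics(labels, scores, "fixed", threshold = t)
  # hand enumeration (ties at the threshold count as positive)
  tp <- sum(scores >= t & labels == 1); fn <- sum(scores < t & labels == 1)
  tn <- sum(scores < t & labels == 0); fp <- sum(scores >= t & labels == 0)
  expect_equal(cm$sensitivity, tp / (tp + fn))
  expect_equal(cm$specificity, tn / (tn + fp))
  expect_equal(cm$accuracy, (tp + tn) / 10)

  # the Youden rule resolves its threshold on validation data only
  ym <- classification_metrics(labels, scores, "youden_on_validation",
                               validation_labels = c(0, 0, 1, 1),
                               validation_scores = c(0.1, 0.45, 0.6, 0.9))
  expect_equal(ym$threshold, 0.6)
})

test_that("bootstrap CIs match an independently coded resampler seed-for-seed", {
  withr::with_seed(53, {
    labels <- rep(c(1, 0), c(12, 15))
    scores <- c(rnorm(12, 1), rnorm(15))
  })
  B <- 400L; alpha <- 0.05; seed <- 77L
  ci <- bootstrap_ci(roc_auc, labels, scores, B, alpha, seed)

  # independent implementation of the same stratified resampling stream
  idx1 <- which(labels == 1L); idx0 <- which(labels == 0L)
  stats <- withr::with_seed(seed, {
    vapply(seq_len(B), function(b) {
      i <- c(idx1[sample.int(length(idx1), replace = TRUE)],
             idx0[sample.int(length(idx0), replace = TRUE)])
      pairwise_auc_oracle(labels[i], scores[i])
    }, 0)
  })
  expected <- quantile(stats, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  expect_equal(unname(ci), expected, tolerance = 1e-12)
})

test_that("bootstrap intervals degenerate and nest correctly", {
  labels <- rep(c(1, 0), each = 10)
  scores <- rep(c(1, 0), each = 10)
  ci <- bootstrap_ci(roc_auc, labels, scores, B = 50, seed = 1)
  expect_equal(unname(ci), c(1, 1))

  withr::with_seed(54, {
    l <- rep(c(1, 0), c(15, 15)); s <- rnorm(30, l)
  })
  wide <- bootstrap_ci(roc_auc, l, s, B = 500, alpha = 0.05, seed = 3)
  narrow <- bootstrap_ci(roc_auc, l, s, B = 500, alpha = 0.5, seed = 3)
  expect_gte(narrow[1], wide[1])
  expect_lte(narrow[2], wide[2])
})

test_that("evaluation reports keep each point estimate inside its own CI", {
  withr::with_seed(55, {
    l <- rep(c(1, 0), c(20, 25)); s <- plogis(rnorm(45, 1.2 * l))
  })
  rep <- eval_report(l, s, condition = "demo", threshold = 0.5, B = 400,
                     seed = 5)
  expect_equal(rep$metric, c("auc", "sensitivity", "specificity", "accuracy"))
  expect_true(all(rep$conf_low <= rep$estimate + 1e-12))
  expect_true(all(rep$conf_high >= rep$estimate - 1e-12))
  expect_equal(unique(rep$n_evaluated), 45L)
})

test_that("subgroup accuracies agree with hand-computed fractions and partition n", {
  preds <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:12),
    label = rep(c("lung_cancer", "healthy_control"), 6),
    score = c(0.9, 0.1, 0.8, 0.6, 0.2, 0.3, 0.7, 0.2, 0.9, 0.8, 0.6, 0.1),
    age = c(70, 50, 66, 64, 80, 30, 65, 70, 40, 55, 72, 45),
    sex = rep(c("male", "female"), each = 6),
    smoking = rep(c("current", "never", "ex"), 4)
  )
  out <- subgroup_accuracy(preds, "age65", threshold = 0.5, B = 50, seed = 2)
  correct <- (preds$score >= 0.5) == (preds$label == "lung_cancer")
  older <- preds$age >= 65
  expect_equal(out$accuracy[out$subgroup == "age >= 65"], mean(correct[older]))
  expect_equal(out$accuracy[out$subgroup == "age < 65"], mean(correct[!older]))
  expect_equal(sum(out$n), 12)

  all_right <- preds
  all_right$score <- ifelse(all_right$label == "lung_cancer", 0.9, 0.1)
  perfect <- subgroup_accuracy(all_right, "smoking_ever", B = 50, seed = 2)
  expect_true(all(perfect$accuracy == 1))

  expect_error(subgroup_accuracy(preds, "shoe_size"),
               class = "breathnet_invalid_argument")
})

test_that("PCA embedding matches an independent eigendecomposition", {
  imgs <- tiny_images(3, 1, 2, seed = 30)
  emb <- pca_embed(imgs)
  ev <- attr(emb, "explained_variance")
  M <- t(vapply(imgs$image, as.vector, numeric(14 * 256)))
  lam <- eigen(stats::cov(M), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(ev, (lam / sum(lam))[1:2], tolerance = 1e-8)
  expect_true(all(diff(ev) <= 0) && all(ev >= 0 & ev <= 1))

  dup <- dplyr::bind_rows(imgs, imgs)
  demb <- pca_embed(dup)
  n <- nrow(imgs)
  expect_equal(demb$PC1[1:n], demb$PC1[(n + 1):(2 * n)])
  expect_equal(demb$PC2[1:n], demb$PC2[(n + 1):(2 * n)])

  expect_error(pca_embed(imgs[1:2, ]), class = "breathnet_invalid_argument")
})

test_that("AUC agrees with an established ROC library on random fixtures", {
  skip_if_not_installed("pROC")
  withr::with_seed(56, {
    for (i in 1:5) {
      l <- c(0, 1, sample(0:1, 18, replace = TRUE))
      s <- round(runif(20), 2)
      expect_equal(roc_auc(l, s),
                   as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                                  direction = "<"))))
    }
  })
})
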