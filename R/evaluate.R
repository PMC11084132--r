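#' Area under the ROC curve (Mann-Whitney form)
#'
#' Computes AUC as the Mann-Whitney pairwise statistic: the fraction of
#' (case, control) pairs in which the case scores higher, counting ties as
#' one half. Implemented via midranks, which is algebraically identical to
#' exhaustive pair enumeration.
#'
#' @param labels Binary vector (0/1 or logical); 1 is the positive class.
#' @param scores Numeric scores, higher meaning more positive.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.integer(labels)
  if (length(labels) != length(scores) || any(!labels %in% c(0L, 1L))) {
    invalid_argument("`labels` must be binary and match `scores` in length.")
  }
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    invalid_argument("both classes must be present to compute AUC.")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' Returns the ROC curve as a tibble of (false-positive rate, true-positive
#' rate, threshold) points, starting at (0, 0) and ending at (1, 1), with
#' both coordinates non-decreasing. The convention throughout the package is
#' that a sample is called positive when its score is `>=` the threshold.
#'
#' @inheritParams roc_auc
#' @return A tibble of class `breathnet_roc` with columns `fpr`, `tpr`,
#'   `threshold`.
#' @export
roc_curve <- function(labels, scores) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    invalid_argument("both classes must be present to compute a ROC curve.")
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1L) / n1, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0L) / n0, 0)
  out <- tibble::tibble(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1),
                        threshold = c(Inf, thr, -Inf))
  class(out) <- c("breathnet_roc", class(out))
  out
}

#' Pick the classification threshold by Youden's J on validation scores
#'
#' Maximises sensitivity + specificity - 1 over the observed validation
#' scores (candidates are the unique scores; positive means score `>=`
#' threshold). On ties the largest threshold (most specific rule) wins.
#'
#' @inheritParams roc_auc
#' @return A single threshold.
#' @export
youden_threshold <- function(labels, scores) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    invalid_argument("both classes must be present to pick a threshold.")
  }
  cand <- sort(unique(scores), decreasing = TRUE)
  j <- vapply(cand, function(t) {
    sum(scores >= t & labels == 1L) / n1 +
      sum(scores < t & labels == 0L) / n0 - 1
  }, 0)
  cand[which.max(j)]
}

#' Sensitivity, specificity and accuracy at a threshold
#'
#' Computes the thresholded confusion-matrix metrics; samples scoring
#' exactly at the threshold are classified positive. The threshold is
#' either fixed or resolved by Youden's J on a supplied validation set
#' (never on the evaluation scores themselves).
#'
#' @inheritParams roc_auc
#' @param threshold_rule `"youden_on_validation"` (requires
#'   `validation_labels`/`validation_scores`) or `"fixed"` (requires
#'   `threshold`).
#' @param threshold Fixed threshold when `threshold_rule = "fixed"`.
#' @param validation_labels,validation_scores Validation data for the
#'   Youden rule.
#' @return A one-row tibble: `sensitivity`, `specificity`, `accuracy`,
#'   `threshold`.
#' @export
classification_metrics <- function(labels, scores,
                                   threshold_rule = c("youden_on_validation",
                                                      "fixed"),
                                   threshold = 0.5,
                                   validation_labels = NULL,
                                   validation_scores = NULL) {
  threshold_rule <- match.arg(threshold_rule)
  labels <- as.integer(labels)
  if (sum(labels == 1L) == 0L || sum(labels == 0L) == 0L) {
    invalid_argument("both classes must be present.")
  }
  t <- if (threshold_rule == "fixed") {
    check_scalar_number(threshold, "threshold")
    threshold
  } else {
    if (is.null(validation_labels) || is.null(validation_scores)) {
      invalid_argument("the Youden rule needs validation labels and scores.")
    }
    youden_threshold(validation_labels, validation_scores)
  }
  pred <- as.integer(scores >= t)
  tp <- sum(pred == 1L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  tibble::tibble(
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    accuracy = (tp + tn) / length(labels),
    threshold = t
  )
}

#' Percentile bootstrap confidence interval for a score-based metric
#'
#' Resamples (label, score) pairs with replacement, stratified by class (so
#' every resample contains both classes), recomputes the metric `B` times
#' and returns the `alpha/2` and `1 - alpha/2` empirical quantiles.
#' Deterministic given the seed.
#'
#' @param metric A function `f(labels, scores)` returning a scalar.
#' @inheritParams roc_auc
#' @param B Number of bootstrap resamples.
#' @param alpha Two-sided miscoverage level (0.05 for a 95% CI).
#' @param seed Integer seed.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
bootstrap_ci <- function(metric, labels, scores, B = 1000L, alpha = 0.05,
                         seed = 1L) {
  if (B < 1) invalid_argument("`B` must be >= 1.")
  if (alpha <= 0 || alpha >= 1) invalid_argument("`alpha` must be in (0, 1).")
  stats <- bootstrap_replicates(list(metric), labels, scores, B, seed)[[1]]
  if (all(is.na(stats))) {
    invalid_argument("metric undefined for all bootstrap resamples.")
  }
  q <- quantile(stats, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE, names = FALSE)
  c(lower = q[1], upper = q[2])
}

# Shared resampling engine: one seeded stream of class-stratified resamples,
# evaluated under every metric in `metrics` so that CIs for different
# metrics of the same report come from the same resample set.
bootstrap_replicates <- function(metrics, labels, scores, B, seed) {
  labels <- as.integer(labels)
  idx1 <- which(labels == 1L)
  idx0 <- which(labels == 0L)
  if (length(idx1) == 0L || length(idx0) == 0L) {
    invalid_argument("both classes must be present for the stratified bootstrap.")
  }
  withr::with_seed(as.integer(seed), {
    out <- lapply(metrics, function(m) rep(NA_real_, B))
    for (b in seq_len(B)) {
      i <- c(idx1[sample.int(length(idx1), replace = TRUE)],
             idx0[sample.int(length(idx0), replace = TRUE)])
      for (mi in seq_along(metrics)) {
        out[[mi]][b] <- tryCatch(metrics[[mi]](labels[i], scores[i]),
                                 error = function(e) NA_real_)
      }
    }
    out
  })
}

#' Full evaluation report for one experimental condition
#'
#' Computes AUC, sensitivity, specificity and accuracy with percentile
#' bootstrap confidence intervals (all four metrics recomputed on the same
#' class-stratified resample set). The threshold is frozen from the
#' validation set by Youden's J unless given.
#'
#' @param labels Binary evaluation labels.
#' @param scores Evaluation scores.
#' @param condition Condition name recorded in the report.
#' @param validation_labels,validation_scores Validation data used only to
#'   resolve the threshold.
#' @param threshold Fixed threshold (overrides the Youden rule).
#' @param B,alpha,seed Bootstrap settings, see [bootstrap_ci()].
#' @return A tibble of class `eval_report` with one row per metric:
#'   `condition`, `metric`, `estimate`, `conf_low`, `conf_high`,
#'   `n_evaluated`, `threshold`.
#' @export
eval_report <- function(labels, scores, condition = "model",
                        validation_labels = NULL, validation_scores = NULL,
                        threshold = NULL, B = 1000L, alpha = 0.05,
                        seed = 1L) {
  labels <- as.integer(labels)
  t <- if (!is.null(threshold)) {
    threshold
  } else if (!is.null(validation_labels)) {
    youden_threshold(validation_labels, validation_scores)
  } else {
    0.5
  }
  cm <- classification_metrics(labels, scores, "fixed", threshold = t)
  point <- c(auc = roc_auc(labels, scores),
             sensitivity = cm$sensitivity,
             specificity = cm$specificity,
             accuracy = cm$accuracy)
  metric_fns <- list(
    auc = roc_auc,
    sensitivity = function(l, s) classification_metrics(l, s, "fixed",
                                                        threshold = t)$sensitivity,
    specificity = function(l, s) classification_metrics(l, s, "fixed",
                                                        threshold = t)$specificity,
    accuracy = function(l, s) classification_metrics(l, s, "fixed",
                                                     threshold = t)$accuracy
  )
  reps <- bootstrap_replicates(metric_fns, labels, scores, B, seed)
  ci <- lapply(reps, function(x) {
    quantile(x, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE, names = FALSE)
  })
  out <- tibble::tibble(
    condition = condition,
    metric = names(point),
    estimate = unname(point),
    conf_low = vapply(ci, `[`, 0, 1),
    conf_high = vapply(ci, `[`, 0, 2),
    n_evaluated = length(labels),
    threshold = t
  )
  class(out) <- c("eval_report", class(out))
  out
}

#' Per-subgroup classification accuracy
#'
#' Splits the evaluated samples by a demographic or clinical grouping and
#' reports each subgroup's accuracy with a percentile bootstrap CI (plain,
#' unstratified resampling of correctness indicators within the subgroup)
#' and its size. Subgroups with no samples are omitted.
#'
#' @param predictions Tibble with columns `sample_id`, `label`, `score`
#'   and the metadata columns of the cohort.
#' @param grouping One of `"age65"`, `"sex"`, `"smoking_ever"`,
#'   `"label_group"` (or any metadata column name present in
#'   `predictions`).
#' @param threshold Classification threshold (score `>=` threshold is
#'   called lung cancer).
#' @param B,alpha,seed Bootstrap settings.
#' @return A tibble: `subgroup`, `n`, `accuracy`, `conf_low`, `conf_high`.
#' @export
subgroup_accuracy <- function(predictions, grouping, threshold = 0.5,
                              B = 1000L, alpha = 0.05, seed = 1L) {
  g <- switch(
    grouping,
    age65 = ifelse(predictions$age >= 65, "age >= 65", "age < 65"),
    sex = predictions$sex,
    smoking_ever = ifelse(predictions$smoking %in% c("current", "ex"),
                          "ever smoker", "never smoker"),
    label_group = predictions$label,
    {
      if (!grouping %in% names(predictions)) {
        invalid_argument(sprintf("unknown grouping `%s`.", grouping))
      }
      as.character(predictions[[grouping]])
    }
  )
  correct <- as.integer(predictions$score >= threshold) ==
    binary_labels(predictions$label)
  res <- lapply(sort(unique(g)), function(lev) {
    ok <- correct[g == lev]
    n <- length(ok)
    boots <- withr::with_seed(derive_seed(seed, paste0("subgroup_", lev)), {
      vapply(seq_len(B),
             function(b) mean(ok[sample.int(n, replace = TRUE)]), 0)
    })
    q <- quantile(boots, c(alpha / 2, 1 - alpha / 2), names = FALSE)
    tibble::tibble(subgroup = lev, n = n, accuracy = mean(ok),
                   conf_low = q[1], conf_high = q[2])
  })
  dplyr::bind_rows(res)
}

#' Two-dimensional PCA embedding of breathprint images
#'
#' Flattens each image, mean-centres, and projects onto the top two
#' principal axes. Used to visualise the per-site clustering of
#' breathprints.
#'
#' @param images Tibble with an `image` list-column (metadata columns are
#'   carried through to the output).
#' @return A tibble with `PC1`, `PC2` and the input metadata; the
#'   `explained_variance` attribute holds the fraction of total variance
#'   captured by each of the two axes.
#' @export
pca_embed <- function(images) {
  if (nrow(images) < 3L) {
    invalid_argument("PCA embedding needs at least 3 samples.")
  }
  M <- t(vapply(images$image, function(im) as.vector(im),
                numeric(14L * 16L * 16L)))
  pc <- prcomp(M, center = TRUE, scale. = FALSE, rank. = 2L)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  out <- images[setdiff(names(images), c("image", "trace"))]
  out$PC1 <- pc$x[, 1]
  out$PC2 <- pc$x[, 2]
  attr(out, "explained_variance") <- ev[1:2]
  class(out) <- c("breathnet_pca", class(out))
  out
}

# ---- plotting ------------------------------------------------------------

#' @importFrom ggplot2 autoplot ggplot aes geom_path geom_abline geom_point
#'   geom_errorbarh labs theme_minimal facet_wrap geom_pointrange coord_flip
NULL

#' Plot a ROC curve
#'
#' @param object A [roc_curve()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.breathnet_roc <- function(object, ...) {
  ggplot(object, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    geom_path() +
    labs(x = "False-positive rate", y = "True-positive rate") +
    theme_minimal()
}

#' Plot a PCA embedding of breathprints
#'
#' @param object A [pca_embed()] result.
#' @param colour Column mapped to colour (default `site`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.breathnet_pca <- function(object, colour = "site", ...) {
  ev <- attr(object, "explained_variance")
  ggplot(object, aes(x = .data$PC1, y = .data$PC2,
                     colour = .data[[colour]])) +
    geom_point(alpha = 0.8) +
    labs(x = sprintf("PC1 (%.1f%%)", 100 * ev[1]),
         y = sprintf("PC2 (%.1f%%)", 100 * ev[2])) +
    theme_minimal()
}

#' Forest-style plot of an evaluation report
#'
#' @param object An [eval_report()] (or row-bound reports).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eval_report <- function(object, ...) {
  ggplot(object, aes(x = .data$estimate, y = .data$condition)) +
    geom_pointrange(aes(xmin = .data$conf_low, xmax = .data$conf_high)) +
    facet_wrap(~metric) +
    labs(x = "Estimate (95% bootstrap CI)", y = NULL) +
    theme_minimal()
}

#' @importFrom rlang .data
NULL
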