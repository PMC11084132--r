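#' Pearson chi-square test for a cohort contingency table
#'
#' Uncorrected Pearson chi-square test of independence (no Yates continuity
#' correction): statistic `sum((O - E)^2 / E)` with expected counts from
#' the product of margins over the grand total, `df = (r - 1)(c - 1)`, and
#' an upper-tail chi-square p-value. The uncorrected form is what
#' demographic cohort tables conventionally print; small expected counts
#' trigger a warning but never a silent switch to an exact test.
#'
#' @param table Either a non-negative integer matrix (rows = groups,
#'   columns = categories) or a long data frame with columns `group`,
#'   `category`, `count`.
#' @return A one-row tibble: `method`, `statistic`, `df`, `p_value`.
#' @examples
#' chisq_test(rbind(c(13, 105), c(12, 38)))
#' @export
chisq_test <- function(table) {
  m <- as_count_matrix(table)
  res <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  if (any(res$expected < 5)) {
    warn("some expected counts are below 5; the chi-square approximation may be poor.")
  }
  tibble::tibble(
    method = "Pearson chi-square (uncorrected)",
    statistic = unname(res$statistic),
    df = unname(res$parameter),
    p_value = unname(res$p.value)
  )
}

as_count_matrix <- function(table) {
  if (is.data.frame(table)) {
    need <- c("group", "category", "count")
    if (!all(need %in% names(table))) {
      invalid_argument("long-format tables need columns group, category, count.")
    }
    m <- stats::xtabs(count ~ group + category, data = table)
    m <- matrix(as.numeric(m), nrow = nrow(m), dimnames = dimnames(m))
  } else if (is.matrix(table)) {
    m <- table
  } else {
    invalid_argument("`table` must be a matrix or a long data frame.")
  }
  if (any(m < 0) || any(!is.finite(m)) || any(m != round(m))) {
    invalid_argument("counts must be finite non-negative integers.")
  }
  if (nrow(m) < 2L || ncol(m) < 2L) {
    invalid_argument("the table needs at least 2 rows and 2 columns.")
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    invalid_argument("the table has an all-zero row or column (zero margin).")
  }
  m
}

#' Two-sample t-test for continuous cohort variables
#'
#' Two-sided Student (pooled-variance) or Welch t-test.
#'
#' @param sample_a,sample_b Numeric vectors, each with at least 2 values.
#' @param variant `"pooled"` (classic Student) or `"welch"`.
#' @return A one-row tibble: `method`, `statistic`, `df`, `p_value`.
#' @export
t_test <- function(sample_a, sample_b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (length(sample_a) < 2L || length(sample_b) < 2L) {
    invalid_argument("each sample needs at least 2 observations.")
  }
  res <- stats::t.test(sample_a, sample_b, var.equal = variant == "pooled")
  tibble::tibble(
    method = if (variant == "pooled") "Student t-test (pooled)" else "Welch t-test",
    statistic = unname(res$statistic),
    df = unname(res$parameter),
    p_value = unname(res$p.value)
  )
}

#' One-way analysis of variance
#'
#' Classic fixed-effects one-way ANOVA: F = between-group mean square over
#' within-group mean square, with an upper-tail F p-value. When every group
#' is an identical constant (zero between-group sum of squares) the
#' statistic is reported as 0 with p = 1 by convention.
#'
#' @param samples A list of numeric vectors (>= 2 groups, each with >= 2
#'   values).
#' @return A one-row tibble: `method`, `statistic`, `df` (numerator),
#'   `df_residual`, `p_value`.
#' @export
one_way_anova <- function(samples) {
  if (!is.list(samples) || length(samples) < 2L) {
    invalid_argument("`samples` must be a list of at least 2 groups.")
  }
  if (any(vapply(samples, length, 0L) < 2L)) {
    invalid_argument("every group needs at least 2 observations.")
  }
  values <- unlist(samples)
  groups <- factor(rep(seq_along(samples), vapply(samples, length, 0L)))
  k <- length(samples); n <- length(values)
  grand <- mean(values)
  ss_between <- sum(tapply(values, groups, function(v) {
    length(v) * (mean(v) - grand)^2
  }))
  if (ss_between < .Machine$double.eps * max(1, sum(values^2))) {
    return(tibble::tibble(method = "One-way ANOVA", statistic = 0,
                          df = k - 1, df_residual = n - k, p_value = 1))
  }
  res <- stats::oneway.test(values ~ groups, var.equal = TRUE)
  tibble::tibble(
    method = "One-way ANOVA",
    statistic = unname(res$statistic),
    df = unname(res$parameter[1]),
    df_residual = unname(res$parameter[2]),
    p_value = unname(res$p.value)
  )
}

#' Packaged demographic contingency tables of the two-site study
#'
#' Loads the demographic count tables of the two-site clinical cohort
#' shipped with the package (long CSV: `comparison`, `group`, `category`,
#' `count`). Each `comparison` value names one contingency table, e.g.
#' smoking status of lung-cancer vs control participants within the
#' validation cohort, or training vs validation cohort margins.
#'
#' @return A tibble with columns `comparison`, `group`, `category`,
#'   `count`.
#' @export
table1_counts <- function() {
  path <- system.file("extdata", "cohort_table_counts.csv",
                      package = "breathnet")
  readr::read_csv(path, show_col_types = FALSE)
}

#' Chi-square p-values for every packaged demographic table
#'
#' Runs [chisq_test()] on each contingency table returned by
#' [table1_counts()].
#'
#' @return A tibble: `comparison`, `statistic`, `df`, `p_value`.
#' @export
table1_pvalues <- function() {
  counts <- table1_counts()
  counts |>
    dplyr::group_by(.data$comparison) |>
    dplyr::group_modify(function(d, key) {
      suppressWarnings(chisq_test(d))[, c("statistic", "df", "p_value")]
    }) |>
    dplyr::ungroup()
}
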