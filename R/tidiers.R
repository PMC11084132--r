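#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the training history of a breathprint CNN
#'
#' @param x A `breathnet_cnn`.
#' @param ... Unused.
#' @return A tibble with one row per training epoch: `epoch`, `loss`,
#'   `val_auc`.
#' @export
tidy.breathnet_cnn <- function(x, ...) {
  x$history
}

#' One-row summary of a breathprint CNN
#'
#' @param x A `breathnet_cnn`.
#' @param ... Unused.
#' @return A one-row tibble: `n_parameters`, `trained`, `epochs_run`,
#'   `best_epoch`, `final_loss`, `best_val_auc`.
#' @export
glance.breathnet_cnn <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    n_parameters = sum(rapply(x$params, length, how = "unlist")),
    trained = isTRUE(x$provenance$trained),
    epochs_run = nrow(h),
    best_epoch = x$provenance$best_epoch %||% NA_integer_,
    final_loss = if (nrow(h)) h$loss[nrow(h)] else NA_real_,
    best_val_auc = if (nrow(h) && any(is.finite(h$val_auc))) {
      max(h$val_auc, na.rm = TRUE)
    } else {
      NA_real_
    }
  )
}

#' Wide one-row-per-condition view of evaluation reports
#'
#' @param x An [eval_report()] tibble (possibly several row-bound reports).
#' @param ... Unused.
#' @return A tibble with one row per condition and evaluation set, metrics
#'   as columns.
#' @export
glance.eval_report <- function(x, ...) {
  x |>
    dplyr::select(dplyr::any_of(c("condition", "eval_set", "metric",
                                  "estimate"))) |>
    tidyr::pivot_wider(names_from = "metric", values_from = "estimate")
}
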