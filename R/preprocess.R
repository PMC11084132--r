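#' Resample a multichannel trace to a fixed length
#'
#' Linearly interpolates each sensor channel onto `target_length` evenly
#' spaced points spanning the original time axis; endpoints are preserved
#' exactly. A trace already at `target_length` is returned unchanged.
#'
#' @param channels A channels x time numeric matrix (one trace).
#' @param target_length Desired number of time points (default 256, the
#'   16 x 16 image size).
#' @return A matrix with the same number of channels and `target_length`
#'   columns.
#' @export
resample_trace <- function(channels, target_length = 256L) {
  if (!is.matrix(channels) || ncol(channels) < 2L) {
    invalid_argument("`channels` must be a matrix with at least 2 time points.")
  }
  if (ncol(channels) == target_length) return(channels)
  x_old <- seq(0, 1, length.out = ncol(channels))
  x_new <- seq(0, 1, length.out = target_length)
  out <- t(apply(channels, 1L, function(y) {
    approx(x_old, y, xout = x_new, method = "linear")$y
  }))
  dimnames(out) <- NULL
  out
}

#' Resample every trace in a cohort
#'
#' @param cohort A cohort tibble with a `trace` list-column
#'   (see [simulate_cohort()]).
#' @param target_length Desired number of time points per channel.
#' @return The cohort with every trace resampled.
#' @export
resample_traces <- function(cohort, target_length = 256L) {
  cohort$trace <- lapply(cohort$trace, resample_trace, target_length)
  cohort
}

#' Per-channel normalisation statistics from a training partition
#'
#' Computes per-channel mean, standard deviation, minimum and maximum over
#' all traces of a (training) cohort. Passing the result to
#' [trace_to_image()] or [cohort_to_images()] normalises other partitions
#' with training-only statistics, so no information flows from validation or
#' test samples into the representation.
#'
#' @param cohort A cohort tibble with a `trace` list-column.
#' @return A tibble with columns `channel`, `mean`, `sd`, `min`, `max`.
#' @export
channel_stats <- function(cohort) {
  if (nrow(cohort) == 0L) invalid_argument("cohort is empty.")
  all_mat <- do.call(cbind, cohort$trace)
  tibble::tibble(
    channel = seq_len(nrow(all_mat)),
    mean = rowMeans(all_mat),
    sd = apply(all_mat, 1L, sd),
    min = apply(all_mat, 1L, min),
    max = apply(all_mat, 1L, max)
  )
}

#' Convert one resampled trace to a 14-channel 16 x 16 breathprint image
#'
#' Each channel's 256 time points are placed row-major into a 16 x 16 grid
#' (0-based time index t goes to row `t %/% 16`, column `t %% 16`), so
#' flattening an unnormalised image row-major recovers the resampled trace
#' exactly. Normalisation is applied per channel according to `scheme`:
#' `"per_channel_zscore"` subtracts the channel mean and divides by the
#' channel standard deviation, `"per_channel_minmax"` maps the channel range
#' to `[0, 1]`, `"none"` leaves values untouched. With `stats = NULL` the
#' statistics come from the trace itself (`source = "self"`); supplying a
#' [channel_stats()] tibble uses frozen training-partition statistics
#' (`source = "train_set"`).
#'
#' @param channels A 14 x 256 numeric matrix.
#' @param scheme Normalisation scheme.
#' @param stats Optional [channel_stats()] tibble (training statistics).
#' @return A 14 x 16 x 16 numeric array with attributes `normalization`
#'   (scheme and statistics source).
#' @export
trace_to_image <- function(channels,
                           scheme = c("per_channel_zscore",
                                      "per_channel_minmax", "none"),
                           stats = NULL) {
  scheme <- match.arg(scheme)
  if (!is.matrix(channels) || nrow(channels) != 14L || ncol(channels) != 256L) {
    invalid_argument("`channels` must be a 14 x 256 matrix; resample first.")
  }
  if (any(!is.finite(channels))) invalid_argument("trace has non-finite values.")
  source <- if (is.null(stats)) "self" else "train_set"
  if (scheme != "none") {
    if (source == "self") {
      mu <- rowMeans(channels)
      sdev <- apply(channels, 1L, sd)
      lo <- apply(channels, 1L, min)
      hi <- apply(channels, 1L, max)
    } else {
      if (!all(c("mean", "sd", "min", "max") %in% names(stats)) ||
          nrow(stats) != 14L) {
        invalid_argument("`stats` must be a 14-row channel_stats() tibble.")
      }
      mu <- stats$mean; sdev <- stats$sd; lo <- stats$min; hi <- stats$max
    }
    if (scheme == "per_channel_zscore") {
      sdev[sdev == 0] <- 1
      channels <- (channels - mu) / sdev
    } else {
      rng <- hi - lo
      rng[rng == 0] <- 1
      channels <- (channels - lo) / rng
    }
  }
  img <- array(0, dim = c(14L, 16L, 16L))
  for (c in seq_len(14L)) {
    img[c, , ] <- matrix(channels[c, ], nrow = 16L, byrow = TRUE)
  }
  attr(img, "normalization") <- list(scheme = scheme, source = source)
  img
}

#' Flatten a breathprint image back to per-channel time series
#'
#' Inverse of the row-major grid layout of [trace_to_image()]: returns the
#' (normalised) 14 x 256 matrix such that
#' `flatten_image(trace_to_image(x, "none"))` equals `x` elementwise.
#'
#' @param image A 14 x 16 x 16 array.
#' @return A 14 x 256 matrix.
#' @export
flatten_image <- function(image) {
  if (!is.array(image) || !identical(dim(image), c(14L, 16L, 16L))) {
    invalid_argument("`image` must be a 14 x 16 x 16 array.")
  }
  out <- matrix(0, nrow = 14L, ncol = 256L)
  for (c in seq_len(14L)) out[c, ] <- as.vector(t(image[c, , ]))
  out
}

# Rebuild a 14 x 16 x 16 image from a 14 x 256 flattened matrix, preserving
# normalization provenance.
regrid_image <- function(flat, normalization = NULL) {
  img <- array(0, dim = c(14L, 16L, 16L))
  for (c in seq_len(14L)) img[c, , ] <- matrix(flat[c, ], nrow = 16L, byrow = TRUE)
  attr(img, "normalization") <- normalization
  img
}

#' Convert a cohort of traces to breathprint images
#'
#' Resamples every trace to 256 points and applies [trace_to_image()],
#' carrying metadata through. With `stats` from [channel_stats()] on the
#' training partition, all partitions share frozen training statistics.
#'
#' @inheritParams trace_to_image
#' @param cohort A cohort tibble with a `trace` list-column.
#' @return The cohort tibble with the `trace` column replaced by an `image`
#'   list-column of 14 x 16 x 16 arrays.
#' @export
cohort_to_images <- function(cohort,
                             scheme = c("per_channel_zscore",
                                        "per_channel_minmax", "none"),
                             stats = NULL) {
  scheme <- match.arg(scheme)
  cohort <- resample_traces(cohort, 256L)
  images <- lapply(cohort$trace, trace_to_image, scheme = scheme, stats = stats)
  out <- cohort[setdiff(names(cohort), "trace")]
  out$image <- images
  out
}

#' Write a cohort to delimited text files
#'
#' Persists the traces in long format (`sample_id`, `channel_index`,
#' `time_index`, `value`) and the metadata (one row per sample) as two CSV
#' files readable by [read_traces()].
#'
#' @param cohort A cohort tibble with a `trace` list-column.
#' @param data_path,metadata_path Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort, data_path, metadata_path) {
  long <- purrr::map2_dfr(cohort$sample_id, cohort$trace, function(id, tr) {
    tibble::tibble(
      sample_id = id,
      channel_index = rep(seq_len(nrow(tr)), each = ncol(tr)),
      time_index = rep(seq_len(ncol(tr)), times = nrow(tr)),
      value = as.vector(t(tr))
    )
  })
  readr::write_csv(long, data_path)
  meta <- cohort[setdiff(names(cohort), "trace")]
  readr::write_csv(meta, metadata_path)
  invisible(c(data_path, metadata_path))
}

#' Write breathprint images as flat CSV
#'
#' Persists an image tibble in long format (`sample_id`, `channel`, `row`,
#' `col`, `value`), readable by [read_images()].
#'
#' @param images Tibble with `sample_id` and an `image` list-column.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_images <- function(images, path) {
  long <- purrr::map2_dfr(images$sample_id, images$image, function(id, im) {
    tibble::tibble(
      sample_id = id,
      channel = rep(seq_len(14L), each = 256L),
      row = rep(rep(seq_len(16L), each = 16L), times = 14L),
      col = rep(seq_len(16L), times = 14L * 16L),
      value = as.vector(aperm(im, c(3, 2, 1)))
    )
  })
  readr::write_csv(long, path)
  invisible(path)
}

#' Read breathprint images from flat CSV
#'
#' @param path A CSV written by [write_images()].
#' @return A tibble with `sample_id` and an `image` list-column.
#' @export
read_images <- function(path) {
  long <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("sample_id", "channel", "row", "col", "value")
  if (!all(need %in% names(long))) {
    format_error("image file must have columns sample_id, channel, row, col, value.")
  }
  ids <- unique(long$sample_id)
  images <- lapply(ids, function(id) {
    rows <- long[long$sample_id == id, ]
    if (nrow(rows) != 14L * 256L) {
      format_error(paste0("sample ", id, " does not have 14 x 16 x 16 values."))
    }
    img <- array(0, dim = c(14L, 16L, 16L))
    img[cbind(rows$channel, rows$row, rows$col)] <- rows$value
    img
  })
  tibble::tibble(sample_id = ids, image = images)
}

#' Read a cohort from delimited text files
#'
#' Reads the long-format trace CSV and metadata CSV written by
#' [write_cohort()], validating that every metadata sample has exactly 14
#' channels of equal length and that no trace lacks metadata. Violations
#' raise a format error naming the offending sample.
#'
#' @param data_path,metadata_path CSV paths as written by [write_cohort()].
#' @return A cohort tibble with a `trace` list-column.
#' @export
read_traces <- function(data_path, metadata_path) {
  if (!file.exists(data_path) || !file.exists(metadata_path)) {
    format_error("trace or metadata file does not exist.")
  }
  long <- readr::read_csv(data_path, show_col_types = FALSE)
  meta <- readr::read_csv(metadata_path, show_col_types = FALSE)
  need <- c("sample_id", "channel_index", "time_index", "value")
  if (!all(need %in% names(long))) {
    format_error("trace file must have columns sample_id, channel_index, time_index, value.")
  }
  if (!"sample_id" %in% names(meta)) {
    format_error("metadata file must have a sample_id column.")
  }
  orphan <- setdiff(unique(long$sample_id), meta$sample_id)
  if (length(orphan) > 0L) {
    format_error(paste0("trace rows without metadata for sample(s): ",
                        paste(orphan, collapse = ", ")))
  }
  traces <- lapply(meta$sample_id, function(id) {
    rows <- long[long$sample_id == id, ]
    if (nrow(rows) == 0L) {
      format_error(paste0("metadata row without trace data for sample: ", id))
    }
    ch <- sort(unique(rows$channel_index))
    if (!identical(as.integer(ch), 1:14)) {
      format_error(paste0("sample ", id, " does not have exactly channels 1-14."))
    }
    lens <- table(rows$channel_index)
    if (length(unique(as.integer(lens))) != 1L) {
      format_error(paste0("sample ", id, " has ragged channel lengths."))
    }
    Tn <- as.integer(lens[[1]])
    mat <- matrix(0, nrow = 14L, ncol = Tn)
    rows <- rows[order(rows$channel_index, rows$time_index), ]
    for (c in 1:14) mat[c, ] <- rows$value[rows$channel_index == c]
    mat
  })
  meta$trace <- traces
  tibble::as_tibble(meta)
}
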