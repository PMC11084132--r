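# Shared fixtures, all generated in code.

# A small single-site cohort with both classes.
tiny_cohort <- function(n_cancer = 6, n_healthy = 2, n_diseased = 4,
                        seed = 42, site = "S1", ...) {
  simulate_cohort(n_cancer, n_healthy, n_diseased, site = site,
                  seed = seed, ...)
}

# Self-normalised images of a tiny cohort.
tiny_images <- function(..., scheme = "per_channel_zscore") {
  co <- tiny_cohort(...)
  cohort_to_images(co, scheme, channel_stats(co))
}

# A deterministic "image" whose flattened channels are set explicitly.
image_from_flat <- function(flat) {
  stopifnot(is.matrix(flat), nrow(flat) == 14, ncol(flat) == 256)
  img <- array(0, dim = c(14L, 16L, 16L))
  for (c in 1:14) img[c, , ] <- matrix(flat[c, ], nrow = 16, byrow = TRUE)
  img
}

# Linearly separable labelled images: class decided by the mean level of
# channel 1.
separable_images <- function(n_per_class = 10, seed = 99) {
  withr::with_seed(seed, {
    rows <- lapply(seq_len(2 * n_per_class), function(i) {
      pos <- i <= n_per_class
      flat <- matrix(rnorm(14 * 256, 0, 0.1), 14, 256)
      flat[1, ] <- flat[1, ] + if (pos) 2 else -2
      tibble::tibble(
        sample_id = sprintf("sep_%02d", i),
        label = if (pos) "lung_cancer" else "healthy_control",
        image = list(image_from_flat(flat))
      )
    })
    dplyr::bind_rows(rows)
  })
}

# Exhaustive pairwise AUC oracle (Mann-Whitney by enumeration).
pairwise_auc_oracle <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Plain DFT by direct summation, independent of stats::fft.
naive_dft <- function(x) {
  n <- length(x)
  vapply(0:(n - 1), function(k) {
    sum(x * exp(-2i * pi * k * (0:(n - 1)) / n))
  }, complex(1))
}
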