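#' Augmentation configuration
#'
#' Bundles the parameters of the two breathprint augmentation operators.
#' NSA (noise-shift augmentation) adds per-channel Gaussian noise scaled to
#' the channel's standard deviation and shifts the flattened 256-point time
#' series backward (toward earlier time). SDA (semi-supervised
#' domain-generalised augmentation) mixes the low-frequency Fourier
#' amplitude spectrum of a sample with that of a partner sample while
#' keeping the sample's phase spectrum, emulating cross-instrument style
#' variation. The exact published formulation of SDA lives in inaccessible
#' supplementary material; this operator is a documented reconstruction
#' following the Fourier domain-generalisation family.
#'
#' @param method `"NSA"` or `"SDA"`.
#' @param ratio Positive augmentation ratio; `1` adds one augmented copy per
#'   original (dataset doubles).
#' @param nsa_noise_sd Noise standard deviation as a fraction of each
#'   channel's standard deviation (NSA).
#' @param nsa_shift Non-negative integer backward shift, in positions along
#'   the flattened 256-point axis, strictly less than 256 (NSA). The
#'   operator applies this exact shift; at dataset level each augmented
#'   copy draws its shift uniformly from `0..nsa_shift`, producing a
#'   continuum of onsets.
#' @param sda_mix_lambda Mixing coefficient in `[0, 1]`, or `"uniform"` to
#'   draw it uniformly per call (SDA).
#' @param sda_low_freq_fraction Fraction in `(0, 1]` of the frequency axis
#'   (by distance from DC) whose amplitudes are mixed (SDA).
#' @param boundary Boundary rule for the backward shift: `"replicate"` pads
#'   the vacated tail with the last observed value; `"circular"` wraps.
#' @param seed Integer seed used by dataset-level augmentation.
#' @return An object of class `augmentation_config`.
#' @export
augmentation_config <- function(method = c("NSA", "SDA"),
                                ratio = 1,
                                nsa_noise_sd = 0.30,
                                nsa_shift = 16L,
                                sda_mix_lambda = "uniform",
                                sda_low_freq_fraction = 0.5,
                                boundary = c("replicate", "circular"),
                                seed = 1L) {
  method <- match.arg(method)
  boundary <- match.arg(boundary)
  check_scalar_number(ratio, "ratio")
  if (ratio <= 0) invalid_argument("`ratio` must be > 0.")
  check_scalar_number(nsa_noise_sd, "nsa_noise_sd")
  if (nsa_noise_sd < 0) invalid_argument("`nsa_noise_sd` must be >= 0.")
  check_scalar_number(nsa_shift, "nsa_shift")
  if (nsa_shift < 0 || nsa_shift >= 256) {
    invalid_argument("`nsa_shift` must be in [0, 255].")
  }
  if (!identical(sda_mix_lambda, "uniform")) {
    check_scalar_number(sda_mix_lambda, "sda_mix_lambda")
    if (sda_mix_lambda < 0 || sda_mix_lambda > 1) {
      invalid_argument("`sda_mix_lambda` must be in [0, 1] or \"uniform\".")
    }
  }
  check_scalar_number(sda_low_freq_fraction, "sda_low_freq_fraction")
  if (sda_low_freq_fraction <= 0 || sda_low_freq_fraction > 1) {
    invalid_argument("`sda_low_freq_fraction` must be in (0, 1].")
  }
  structure(
    list(method = method, ratio = ratio,
         nsa_noise_sd = nsa_noise_sd, nsa_shift = as.integer(nsa_shift),
         sda_mix_lambda = sda_mix_lambda,
         sda_low_freq_fraction = sda_low_freq_fraction,
         boundary = boundary, seed = as.integer(seed)),
    class = "augmentation_config"
  )
}

# Shift a series backward by s positions (events move toward earlier time):
# y[i] = x[i + s], with the vacated tail filled per the boundary rule.
shift_backward <- function(x, s, boundary = "replicate") {
  n <- length(x)
  if (s == 0L) return(x)
  if (boundary == "circular") {
    c(x[(s + 1L):n], x[1:s])
  } else {
    c(x[(s + 1L):n], rep(x[n], s))
  }
}

#' Noise-shift augmentation of one breathprint image
#'
#' Per channel: flattens the 16 x 16 plane row-major to its 256-point time
#' series, adds i.i.d. Gaussian noise with standard deviation
#' `nsa_noise_sd` times that channel's standard deviation, shifts the
#' series backward by `nsa_shift` positions (edge handling per the config's
#' boundary rule) and re-grids. The label is unchanged; the output is
#' deterministic given the seed.
#'
#' @param image A 14 x 16 x 16 breathprint array.
#' @param config An [augmentation_config()].
#' @param seed Integer seed for the noise draw.
#' @return An augmented 14 x 16 x 16 array.
#' @export
nsa_augment <- function(image, config = augmentation_config("NSA"), seed = 1L,
                        shift = config$nsa_shift) {
  flat <- flatten_image(image)
  flat <- withr::with_seed(as.integer(seed), {
    out <- flat
    for (c in seq_len(14L)) {
      s <- sd(flat[c, ])
      noisy <- flat[c, ] + rnorm(256L, 0, config$nsa_noise_sd * s)
      out[c, ] <- shift_backward(noisy, shift, config$boundary)
    }
    out
  })
  regrid_image(flat, attr(image, "normalization"))
}

#' Fourier amplitude-mixing augmentation of one breathprint image
#'
#' Per channel: takes the discrete Fourier transform of the flattened
#' 256-point series of `image_a` and of the partner `image_b`; inside the
#' lowest `sda_low_freq_fraction` of frequencies (symmetric around DC, so
#' the result stays real) replaces the amplitude of `a` by the convex
#' combination `(1 - lambda) * |A_a| + lambda * |A_b|`; keeps `a`'s phase
#' everywhere; inverse-transforms and takes the real part. With
#' `lambda = 0` or `image_b` equal to `image_a`, the output equals
#' `image_a` to round-trip precision.
#'
#' @param image_a Image whose phase (and label, at dataset level) is kept.
#' @param image_b Partner image contributing amplitude style.
#' @param config An [augmentation_config()].
#' @param seed Integer seed (used when `sda_mix_lambda = "uniform"`).
#' @return An augmented 14 x 16 x 16 array.
#' @export
sda_augment <- function(image_a, image_b,
                        config = augmentation_config("SDA"), seed = 1L) {
  fa <- flatten_image(image_a)
  fb <- flatten_image(image_b)
  lambda <- if (identical(config$sda_mix_lambda, "uniform")) {
    withr::with_seed(as.integer(seed), runif(1))
  } else {
    config$sda_mix_lambda
  }
  n <- 256L
  # Distance of each DFT bin from DC; the retained window is symmetric in
  # k <-> n - k, which keeps the inverse transform real.
  k <- 0:(n - 1L)
  freq_dist <- pmin(k, n - k)
  n_low <- ceiling(config$sda_low_freq_fraction * (n / 2))
  mix_mask <- freq_dist < n_low
  out <- fa
  for (c in seq_len(14L)) {
    Fa <- fft(fa[c, ])
    Fb <- fft(fb[c, ])
    amp <- Mod(Fa)
    amp[mix_mask] <- (1 - lambda) * amp[mix_mask] + lambda * Mod(Fb)[mix_mask]
    phase <- Arg(Fa)
    out[c, ] <- Re(fft(amp * exp(1i * phase), inverse = TRUE)) / n
  }
  regrid_image(out, attr(image_a, "normalization"))
}

#' Augment a labelled image set at a fixed ratio
#'
#' Returns the original images plus `ceiling(ratio * N)` augmented samples;
#' with `ratio = 1` the output has exactly `2 N` rows and every class count
#' doubles. Each augmented sample keeps its source's label and metadata and
#' is flagged in the `augmented` column. For SDA the partner is drawn
#' (seeded) from the same diagnosis group of the same set; a set of size
#' one partners with itself. For NSA each copy's backward shift is drawn
#' uniformly from `0..nsa_shift`.
#' Augmentation must only ever be applied to a training or fine-tuning
#' partition: if the input carries a `partition` column containing
#' `"validation"` or `"test"` samples, the call aborts with a leakage error.
#'
#' @param images A tibble with an `image` list-column and a `label` column
#'   (as produced by [cohort_to_images()]).
#' @param config An [augmentation_config()].
#' @return A tibble with the originals followed by the augmented samples,
#'   with `augmented` (logical) and `source_id` columns.
#' @export
augment_dataset <- function(images, config) {
  if (!inherits(config, "augmentation_config")) {
    invalid_argument("`config` must be an augmentation_config.")
  }
  if (nrow(images) == 0L) invalid_argument("`images` is empty.")
  if (!"image" %in% names(images)) {
    invalid_argument("`images` must have an `image` list-column.")
  }
  if ("partition" %in% names(images) &&
      any(images$partition %in% c("validation", "test"))) {
    leakage_error("augment_dataset() applied to validation/test samples; augmentation is restricted to the training partition.")
  }
  n <- nrow(images)
  n_aug <- as.integer(ceiling(config$ratio * n))
  src_idx <- rep_len(seq_len(n), n_aug)
  # SDA partners come from the same diagnosis group, so the mixed amplitude
  # profile injects instrument/subject style diversity without moving the
  # sample across the class boundary
  partner_idx <- withr::with_seed(derive_seed(config$seed, "sda_partner"), {
    vapply(src_idx, function(i) {
      pool <- which(images$label == images$label[i])
      if (length(pool) == 1L) pool else sample(pool, 1L)
    }, 0L)
  })
  aug_rows <- images[src_idx, ]
  # at dataset level each NSA copy draws its backward shift uniformly from
  # 0..nsa_shift, giving a continuum of onsets rather than two clusters
  shifts <- withr::with_seed(derive_seed(config$seed, "nsa_shift"),
                             sample.int(config$nsa_shift + 1L, n_aug,
                                        replace = TRUE) - 1L)
  aug_rows$image <- lapply(seq_len(n_aug), function(j) {
    i <- src_idx[j]
    s <- derive_seed(config$seed, paste0("aug_", j, "_", images$sample_id[i]))
    if (config$method == "NSA") {
      nsa_augment(images$image[[i]], config, seed = s, shift = shifts[j])
    } else {
      sda_augment(images$image[[i]], images$image[[partner_idx[j]]],
                  config, seed = s)
    }
  })
  aug_rows$sample_id <- sprintf("%s_aug%d", images$sample_id[src_idx],
                                ave(src_idx, src_idx, FUN = seq_along))
  images$augmented <- FALSE
  images$source_id <- images$sample_id
  aug_rows$augmented <- TRUE
  aug_rows$source_id <- images$sample_id[src_idx]
  dplyr::bind_rows(images, aug_rows)
}
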