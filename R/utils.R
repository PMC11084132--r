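#' @importFrom rlang abort warn %||%
#' @importFrom stats approx fft rnorm runif rbinom quantile sd var prcomp
#' @importFrom stats chisq.test t.test oneway.test pchisq pf pt setNames
#' @importFrom stats ave xtabs
#' @importFrom utils head tail
NULL

# Deterministic fan-out of one master seed into independent sub-seeds.
# Keeps every derived seed inside the 32-bit integer range R requires.
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- as.double(seed) %% 2147483647
  for (ch in utf8ToInt(label)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

check_scalar_number <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x))) {
    abort(sprintf("`%s` must be a single finite number.", name),
          class = "breathnet_invalid_argument")
  }
  invisible(x)
}

check_channel_vector <- function(x, name, n_channels = 14L) {
  if (!is.numeric(x) || length(x) != n_channels || any(!is.finite(x))) {
    abort(sprintf("`%s` must be a finite numeric vector of length %d.",
                  name, n_channels),
          class = "breathnet_invalid_argument")
  }
  invisible(x)
}

invalid_argument <- function(msg) {
  abort(msg, class = "breathnet_invalid_argument")
}

leakage_error <- function(msg) {
  abort(msg, class = "breathnet_leakage_error")
}

format_error <- function(msg) {
  abort(msg, class = "breathnet_format_error")
}
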