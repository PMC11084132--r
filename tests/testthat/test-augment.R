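test_that("NSA with zero noise and zero shift is the identity", {
  img <- tiny_images(2, 1, 1, seed = 10)$image[[1]]
  cfg <- augmentation_config("NSA", nsa_noise_sd = 0, nsa_shift = 0)
  expect_equal(nsa_augment(img, cfg, seed = 1), img, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("NSA backward shift moves an impulse toward earlier time", {
  flat <- matrix(0, 14, 256)
  k <- 40; s <- 7
  flat[5, k] <- 1
  img <- image_from_flat(flat)
  cfg <- augmentation_config("NSA", nsa_noise_sd = 0, nsa_shift = s)
  out <- flatten_image(nsa_augment(img, cfg, seed = 1))
  expect_equal(out[5, k - s], 1)
  expect_equal(sum(out != 0), 1)
})

test_that("NSA noise is centred: the mean of many copies recovers the original", {
  img <- tiny_images(1, 1, 1, seed = 11)$image[[2]]
  cfg <- augmentation_config("NSA", nsa_noise_sd = 0.3, nsa_shift = 0)
  m <- 2000L
  acc <- array(0, dim(img))
  for (i in seq_len(m)) acc <- acc + nsa_augment(img, cfg, seed = i)
  avg <- acc / m
  # per-pixel standard error of the mean: the vast majority of pixels must
  # sit within 3 se, and none may stray beyond a loose simultaneous bound
  # (the maximum of ~3.6k standard normals is typically around 3.5-4)
  flat <- flatten_image(img)
  se <- 0.3 * apply(flat, 1, sd) / sqrt(m)
  dev <- abs(flatten_image(avg) - flat) / se
  expect_lt(max(dev), 6)
  expect_gt(mean(dev < 3), 0.99)
})

test_that("NSA with noise off commutes with channel permutation", {
  img <- tiny_images(1, 1, 1, seed = 12)$image[[1]]
  cfg <- augmentation_config("NSA", nsa_noise_sd = 0, nsa_shift = 5)
  perm <- rev(seq_len(14))
  out1 <- nsa_augment(img, cfg, 1)[perm, , ]
  out2 <- nsa_augment(img[perm, , ], cfg, 1)
  expect_equal(out1, out2[, , ], ignore_attr = TRUE)
})

test_that("SDA identity limits hold to round-trip tolerance", {
  imgs <- tiny_images(2, 1, 1, seed = 13)
  a <- imgs$image[[1]]; b <- imgs$image[[2]]
  cfg0 <- augmentation_config("SDA", sda_mix_lambda = 0)
  expect_lt(max(abs(sda_augment(a, b, cfg0, 1) - a)), 1e-9)
  cfg_half <- augmentation_config("SDA", sda_mix_lambda = 0.5)
  expect_lt(max(abs(sda_augment(a, a, cfg_half, 1) - a)), 1e-9)
})

test_that("SDA preserves the phase spectrum (independent DFT check)", {
  imgs <- tiny_images(2, 1, 1, seed = 14)
  a <- imgs$image[[1]]; b <- imgs$image[[2]]
  cfg <- augmentation_config("SDA", sda_mix_lambda = 0.7,
                             sda_low_freq_fraction = 0.25)
  out <- sda_augment(a, b, cfg, 1)
  fa <- flatten_image(a); fo <- flatten_image(out)
  for (c in c(1, 8)) {
    Fa <- naive_dft(fa[c, ])
    Fo <- naive_dft(fo[c, ])
    keep <- Mod(Fo) > 1e-8 & Mod(Fa) > 1e-8
    # compare phases on the circle
    dphi <- Arg(Fo[keep] * Conj(Fa[keep]))
    expect_lt(max(abs(dphi)), 1e-6)
  }
})

test_that("SDA output amplitudes are convex combinations of the inputs", {
  imgs <- tiny_images(2, 1, 1, seed = 15)
  a <- imgs$image[[1]]; b <- imgs$image[[2]]
  for (lam in c(0.2, 0.9)) {
    cfg <- augmentation_config("SDA", sda_mix_lambda = lam)
    out <- sda_augment(a, b, cfg, 1)
    Fa <- fft(flatten_image(a)[4, ]); Fb <- fft(flatten_image(b)[4, ])
    Fo <- fft(flatten_image(out)[4, ])
    lohi <- pmin(Mod(Fa), Mod(Fb)) - 1e-7
    uphi <- pmax(Mod(Fa), Mod(Fb)) + 1e-7
    expect_true(all(Mod(Fo) >= lohi & Mod(Fo) <= uphi))
  }
})

test_that("dataset augmentation at ratio 1 exactly doubles every class count", {
  imgs <- tiny_images(5, 2, 3, seed = 16)
  for (method in c("NSA", "SDA")) {
    cfg <- augmentation_config(method, ratio = 1, seed = 3)
    out <- augment_dataset(imgs, cfg)
    expect_equal(nrow(out), 2 * nrow(imgs))
    expect_equal(sum(out$augmented), nrow(imgs))
    expect_equal(as.vector(table(out$label)),
                 2 * as.vector(table(imgs$label)))
    # augmented samples keep their source's label
    src <- setNames(imgs$label, imgs$sample_id)
    aug <- out[out$augmented, ]
    expect_equal(aug$label, unname(src[aug$source_id]))
  }
})

test_that("a single-sample SDA set partners with itself and duplicates", {
  imgs <- tiny_images(1, 0, 0, seed = 17)[1, ]
  cfg <- augmentation_config("SDA", ratio = 1, seed = 5)
  out <- augment_dataset(imgs, cfg)
  expect_equal(nrow(out), 2)
  expect_lt(max(abs(out$image[[2]] - out$image[[1]])), 1e-9)
})

test_that("augmentation refuses validation and test partitions", {
  imgs <- tiny_images(2, 1, 1, seed = 18)
  imgs$partition <- c("train", "train", "validation", "train")
  expect_error(augment_dataset(imgs, augmentation_config("NSA")),
               class = "breathnet_leakage_error")
  imgs$partition <- "test"
  expect_error(augment_dataset(imgs, augmentation_config("SDA")),
               class = "breathnet_leakage_error")
  imgs$partition <- "train"
  expect_silent(augment_dataset(imgs, augmentation_config("NSA")))
})

test_that("dataset augmentation is deterministic given its seed", {
  imgs <- tiny_images(3, 1, 2, seed = 19)
  cfg <- augmentation_config("NSA", seed = 11)
  expect_identical(augment_dataset(imgs, cfg), augment_dataset(imgs, cfg))
})
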