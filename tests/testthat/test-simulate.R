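test_that("traces are deterministic given seed and exactly reproduce the noiseless curve", {
  cm <- class_effect_model(effect_scale = 0)
  sm <- site_shift_model()
  a <- simulate_sensor_response(cm, sm, "lung_cancer", seed = 7, subject_sd = 0)
  b <- simulate_sensor_response(cm, sm, "lung_cancer", seed = 7, subject_sd = 0)
  expect_identical(a$channels, b$channels)

  # with all randomness off the trace no longer depends on the seed
  c <- simulate_sensor_response(cm, sm, "lung_cancer", seed = 99, subject_sd = 0)
  expect_equal(a$channels, c$channels)

  # and matches the documented exposure/recovery shape: rise to a peak
  # within the exposure phase, then monotone decay
  tr <- a$channels[1, ]
  peak_idx <- which.max(tr)
  expect_lt(peak_idx, 0.45 * length(tr))
  expect_true(all(diff(tr[peak_idx:length(tr)]) <= 1e-12))
  expect_true(all(diff(tr[1:peak_idx]) >= -1e-12))
})

test_that("label only enters through the class effect: effect_scale 0 makes classes identical", {
  cm <- class_effect_model(effect_scale = 0)
  sm <- site_shift_model(noise_sd = 0.1)
  case <- simulate_sensor_response(cm, sm, "lung_cancer", seed = 3)
  ctrl <- simulate_sensor_response(cm, sm, "healthy_control", seed = 3)
  dis <- simulate_sensor_response(cm, sm, "diseased_control", seed = 3)
  expect_equal(case$channels, ctrl$channels)
  expect_equal(case$channels, dis$channels)
})

test_that("additive noise has the configured variance", {
  cm <- class_effect_model()
  sigma <- 0.2
  noisy <- simulate_sensor_response(cm, site_shift_model(noise_sd = sigma),
                                    "healthy_control", T = 4096, seed = 5)
  clean <- simulate_sensor_response(cm, site_shift_model(noise_sd = 0),
                                    "healthy_control", T = 4096, seed = 5)
  diff <- noisy$channels - clean$channels
  # sampling bound: var estimate of N(0, s^2) over n points has
  # sd ~ s^2 * sqrt(2/(n-1))
  n <- ncol(diff)
  se <- sigma^2 * sqrt(2 / (n - 1))
  for (c in 1:14) {
    expect_lt(abs(var(diff[c, ]) - sigma^2), 4 * se)
  }
})

test_that("invalid arguments are rejected", {
  cm <- class_effect_model()
  expect_error(simulate_sensor_response(cm, site_shift_model(),
                                        "lung_cancer", T = 100, seed = 1),
               class = "breathnet_invalid_argument")
  expect_error(site_shift_model(gain = rep(0, 14)),
               class = "breathnet_invalid_argument")
  expect_error(site_shift_model(noise_sd = -1),
               class = "breathnet_invalid_argument")
  expect_error(class_effect_model(kinetic_rate_factor = 0),
               class = "breathnet_invalid_argument")
  expect_error(simulate_cohort(-1, 0, 0, seed = 1),
               class = "breathnet_invalid_argument")
})

test_that("cohorts have the requested composition and strictly increasing recruitment", {
  expect_equal(nrow(simulate_cohort(0, 0, 0, seed = 1)), 0)

  co <- simulate_cohort(5, 2, 3, site = "S2", seed = 8)
  expect_equal(nrow(co), 10)
  expect_equal(sum(co$label == "lung_cancer"), 5)
  expect_equal(sum(co$label == "healthy_control"), 2)
  expect_equal(sum(co$label == "diseased_control"), 3)
  expect_true(all(diff(co$recruitment_time) > 0))
  expect_true(all(vapply(co$trace, function(m) all(dim(m) == c(14, 256)), TRUE)))
  expect_true(all(vapply(co$trace, function(m) all(is.finite(m)), TRUE)))

  # same seed reproduces the cohort exactly
  co2 <- simulate_cohort(5, 2, 3, site = "S2", seed = 8)
  expect_identical(co, co2)
})

test_that("the default study reproduces the published cohort sizes", {
  g <- default_generator()
  expect_equal(g$counts$S1, c(90, 16, 62))
  expect_equal(g$counts$S2, c(28, 10, 25))
  study <- simulate_two_site_study(seed = 1)
  expect_equal(sum(study$site == "S1"), 168)
  expect_equal(sum(study$site == "S2"), 63)
})

test_that("site shift separates sites in PC space, identity models do not", {
  cm <- class_effect_model()
  g <- default_generator()
  mk <- function(site_model, site, seed) {
    simulate_cohort(6, 3, 5, site = site, class_model = cm,
                    site_model = site_model, seed = seed)
  }
  sep_stat <- function(study) {
    emb <- pca_embed(cohort_to_images(study, "none"))
    xy <- cbind(emb$PC1, emb$PC2)
    cen <- rowsum(xy, emb$site) / as.vector(table(emb$site))
    between <- sqrt(sum((cen[1, ] - cen[2, ])^2))
    within <- mean(sqrt(rowSums((xy - cen[emb$site, ])^2)))
    between / within
  }
  shifted <- dplyr::bind_rows(mk(g$site_models$S1, "S1", 1),
                              mk(g$site_models$S2, "S2", 2))
  identical_sites <- dplyr::bind_rows(mk(site_shift_model(), "S1", 1),
                                      mk(site_shift_model(), "S2", 2))
  expect_gt(sep_stat(shifted), 1)
  expect_lt(sep_stat(identical_sites), 1)
})

test_that("cohorts round-trip through the CSV writer/reader", {
  co <- tiny_cohort(2, 1, 1, seed = 5)
  dp <- withr::local_tempfile(fileext = ".csv")
  mp <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, dp, mp)
  back <- read_traces(dp, mp)
  expect_equal(back$sample_id, co$sample_id)
  expect_equal(back$label, co$label)
  for (i in seq_len(nrow(co))) {
    expect_equal(back$trace[[i]], co$trace[[i]])
  }
})
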