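#' Temporal 7:3 split of the source-site cohort
#'
#' Sorts the cohort by recruitment time and assigns the earliest
#' `ceiling(ratio * N)` samples to training and the remainder to
#' validation. Deterministic: no randomness is involved, and permuting the
#' input rows does not change the assignment (ties in recruitment time are
#' broken by `sample_id`).
#'
#' @param cohort A cohort tibble with `recruitment_time` and `sample_id`.
#' @param ratio Training fraction (default 0.7).
#' @return The cohort with a `partition` column (`"train"` /
#'   `"validation"`), sorted by recruitment time.
#' @export
split_cohort <- function(cohort, ratio = 0.7) {
  if (!"recruitment_time" %in% names(cohort) ||
      any(is.na(cohort$recruitment_time))) {
    invalid_argument("`cohort` must carry complete recruitment_time values.")
  }
  if (ratio <= 0 || ratio >= 1) invalid_argument("`ratio` must be in (0, 1).")
  cohort <- cohort[order(cohort$recruitment_time, cohort$sample_id), ]
  n_train <- as.integer(ceiling(ratio * nrow(cohort)))
  cohort$partition <- rep(c("train", "validation"),
                          c(n_train, nrow(cohort) - n_train))
  cohort
}

#' Mark the fine-tuning subset of the target-site cohort
#'
#' Selects `n` target-site samples for fine-tuning — the earliest by
#' recruitment time, stratified between lung-cancer and control as closely
#' as the cohort's class balance allows (largest-remainder allocation) —
#' and marks all remaining samples as the test set. Fine-tune and test ids
#' are disjoint by construction and together cover the target cohort.
#'
#' @param cohort The target-site cohort tibble.
#' @param n Number of fine-tuning samples (default 10).
#' @return The cohort with a `partition` column (`"finetune"` / `"test"`).
#' @export
select_finetune_subset <- function(cohort, n = 10L) {
  if (n > nrow(cohort)) {
    invalid_argument("`n` exceeds the target cohort size.")
  }
  cohort <- cohort[order(cohort$recruitment_time, cohort$sample_id), ]
  cohort$partition <- "test"
  if (n > 0L) {
    pos <- binary_labels(cohort$label) == 1L
    n_pos_cohort <- sum(pos)
    # largest-remainder allocation of n between the two classes
    raw <- n * c(n_pos_cohort, nrow(cohort) - n_pos_cohort) / nrow(cohort)
    take <- floor(raw)
    rem <- n - sum(take)
    if (rem > 0) {
      take[order(raw - floor(raw), decreasing = TRUE)[seq_len(rem)]] <-
        take[order(raw - floor(raw), decreasing = TRUE)[seq_len(rem)]] + 1
    }
    take <- pmin(take, c(n_pos_cohort, nrow(cohort) - n_pos_cohort))
    # spill over if one class cannot fill its quota
    deficit <- n - sum(take)
    if (deficit > 0) {
      room <- c(n_pos_cohort, nrow(cohort) - n_pos_cohort) - take
      for (j in order(room, decreasing = TRUE)) {
        add <- min(deficit, room[j]); take[j] <- take[j] + add
        deficit <- deficit - add
      }
    }
    ft_idx <- c(head(which(pos), take[1]), head(which(!pos), take[2]))
    cohort$partition[ft_idx] <- "finetune"
  }
  cohort
}

#' Experiment configuration for the cross-site pipeline
#'
#' One structured object that fixes everything about a run: the synthetic
#' generator (or pre-built cohorts), the CNN settings, the augmentation
#' settings per method, which Table-2-style conditions to run, whether to
#' repeat with the site roles reversed, the bootstrap settings, and one
#' master seed that fans out deterministically to every randomised stage.
#'
#' @param conditions Subset of `"baseline"`, `"finetune_only"`, `"SDA"`,
#'   `"NSA"`, `"SDA_finetune"`, `"NSA_finetune"`.
#' @param generator Generator settings, see [default_generator()].
#' @param model_config A [cnn_config()] (its seed is overridden by the
#'   master seed fan-out).
#' @param nsa_config,sda_config [augmentation_config()] objects for the two
#'   operators.
#' @param reverse_sites If `TRUE`, the whole experiment is repeated with
#'   S2 as source and S1 as target.
#' @param seed Master seed.
#' @param B,alpha Bootstrap resamples and miscoverage for the reports.
#' @param split_ratio Temporal training fraction at the source site.
#' @param n_finetune Target-site fine-tuning samples.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(conditions = c("baseline", "finetune_only",
                                             "SDA", "NSA", "SDA_finetune",
                                             "NSA_finetune"),
                              generator = default_generator(),
                              model_config = cnn_config(),
                              nsa_config = augmentation_config("NSA"),
                              sda_config = augmentation_config("SDA"),
                              reverse_sites = FALSE,
                              seed = 1L,
                              B = 1000L, alpha = 0.05,
                              split_ratio = 0.7,
                              n_finetune = 10L) {
  all_conditions <- c("baseline", "finetune_only", "SDA", "NSA",
                      "SDA_finetune", "NSA_finetune")
  conditions <- match.arg(conditions, all_conditions, several.ok = TRUE)
  if (length(conditions) == 0L) invalid_argument("at least one condition is required.")
  check_scalar_number(seed, "seed")
  structure(
    list(conditions = conditions, generator = generator,
         model_config = model_config, nsa_config = nsa_config,
         sda_config = sda_config, reverse_sites = reverse_sites,
         seed = as.integer(seed), B = as.integer(B), alpha = alpha,
         split_ratio = split_ratio, n_finetune = as.integer(n_finetune)),
    class = "experiment_config"
  )
}

# Train the source-site model for one augmentation setting ("none", "NSA",
# "SDA"), reusing the partitioned, normalised image tibbles.
train_condition_model <- function(aug, train_images, val_images, config,
                                  run_tag) {
  mc <- config$model_config
  # one model seed per run (not per condition): conditions are compared
  # pairwise on identical initialisation and shuffling streams, so the
  # contrast between them reflects the training data, not seed noise
  mc$seed <- derive_seed(config$seed, paste0("model_", run_tag))
  train_set <- train_images
  if (aug != "none") {
    ac <- if (aug == "NSA") config$nsa_config else config$sda_config
    ac$seed <- derive_seed(config$seed, paste0("augment_", aug, "_", run_tag))
    train_set <- augment_dataset(train_images, ac)
  }
  train(build_model(mc), train_set, config = mc, validation = val_images)
}

run_one_direction <- function(config, cohort, source_site, target_site,
                              run_tag) {
  source_cohort <- split_cohort(cohort[cohort$site == source_site, ],
                                config$split_ratio)
  target_cohort <- select_finetune_subset(cohort[cohort$site == target_site, ],
                                          config$n_finetune)

  stats <- channel_stats(source_cohort[source_cohort$partition == "train", ])
  source_images <- cohort_to_images(source_cohort, "per_channel_zscore", stats)
  target_images <- cohort_to_images(target_cohort, "per_channel_zscore", stats)

  train_images <- source_images[source_images$partition == "train", ]
  val_images <- source_images[source_images$partition == "validation", ]
  test_images <- target_images[target_images$partition == "test", ]
  finetune_images <- target_images[target_images$partition == "finetune", ]

  if (length(intersect(test_images$sample_id, finetune_images$sample_id)) > 0L) {
    leakage_error("fine-tune and test partitions overlap.")
  }

  needs <- list(
    baseline = "none", finetune_only = "none",
    SDA = "SDA", SDA_finetune = "SDA",
    NSA = "NSA", NSA_finetune = "NSA"
  )
  needed_augs <- unique(unlist(needs[config$conditions]))
  models <- lapply(setNames(needed_augs, needed_augs), function(aug) {
    m <- train_condition_model(aug, train_images, val_images, config, run_tag)
    register_eval_set(m, test_images$sample_id)
  })

  reports <- list()

  if ("baseline" %in% config$conditions) {
    base_val_scores <- predict_proba(models$none, val_images)
    reports$validation <- eval_report(
      binary_labels(val_images$label), base_val_scores,
      condition = "validation_same_site",
      validation_labels = binary_labels(val_images$label),
      validation_scores = base_val_scores,
      B = config$B, alpha = config$alpha,
      seed = derive_seed(config$seed, paste0("boot_val_", run_tag))
    )
    reports$validation$eval_set <- "validation"
  }

  for (cond in config$conditions) {
    aug <- needs[[cond]]
    model <- models[[aug]]
    finetuned <- grepl("finetune", cond)
    if (finetuned) {
      ft_config <- model$config
      ft_config$finetune$n_samples <- config$n_finetune
      model <- fine_tune(model, finetune_images, ft_config)
    }
    v_scores <- predict_proba(model, val_images)
    t_scores <- predict_proba(model, test_images)
    # fine-tuned heads are probability-calibrated to the target site, so
    # their natural operating point is 0.5; otherwise the threshold is
    # frozen from the source validation set by Youden's J
    rep <- eval_report(
      binary_labels(test_images$label), t_scores,
      condition = cond,
      validation_labels = if (finetuned) NULL else binary_labels(val_images$label),
      validation_scores = if (finetuned) NULL else v_scores,
      threshold = if (finetuned) 0.5 else NULL,
      B = config$B, alpha = config$alpha,
      seed = derive_seed(config$seed, paste0("boot_", cond, "_", run_tag))
    )
    rep$eval_set <- "test"
    reports[[cond]] <- rep
  }

  out <- dplyr::bind_rows(reports)
  out$source_site <- source_site
  out$target_site <- target_site
  out
}

#' Run the full cross-site experiment grid
#'
#' Executes the complete analytic flow on a two-site cohort: temporal 7:3
#' split at the source site, training-statistics normalisation, per-condition
#' training (with NSA/SDA augmentation of the training partition only),
#' validation-based early stopping and threshold selection, optional
#' fine-tuning on the held-out target subset, and bootstrap evaluation on
#' the target test set. With `reverse_sites = TRUE` the grid is repeated
#' with the site roles swapped. Every randomised stage derives its seed
#' from the master seed, so a rerun with the same config reproduces every
#' report exactly.
#'
#' @param config An [experiment_config()].
#' @param cohort Optional pre-built two-site cohort tibble; by default the
#'   configured generator simulates one.
#' @return A tibble of evaluation reports (one row per condition x metric),
#'   with `eval_set`, `source_site`, `target_site` columns.
#' @export
run_experiment <- function(config = experiment_config(), cohort = NULL) {
  if (!inherits(config, "experiment_config")) {
    invalid_argument("`config` must be an experiment_config.")
  }
  if (is.null(cohort)) {
    cohort <- simulate_two_site_study(derive_seed(config$seed, "generator"),
                                      config$generator)
  }
  out <- run_one_direction(config, cohort, "S1", "S2", "fwd")
  if (isTRUE(config$reverse_sites)) {
    rev <- run_one_direction(config, cohort, "S2", "S1", "rev")
    out <- dplyr::bind_rows(out, rev)
  }
  # manifest of resolved parameters and derived seeds, for exact reruns
  attr(out, "manifest") <- list(
    master_seed = config$seed,
    generator_seed = derive_seed(config$seed, "generator"),
    model_seed_fwd = derive_seed(config$seed, "model_fwd"),
    conditions = config$conditions,
    split_ratio = config$split_ratio,
    n_finetune = config$n_finetune,
    B = config$B, alpha = config$alpha,
    reverse_sites = isTRUE(config$reverse_sites)
  )
  out
}
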