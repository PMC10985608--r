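#' Experiment configuration
#'
#' One object driving the whole pipeline: generate -> filter -> split ->
#' preprocess -> train -> calibrate -> predict regions -> explain ->
#' evaluate. The cohort is split 80/20 into development and internal
#' validation, and the development set 80/20 into training and
#' calibration. A single master seed fans out deterministically to
#' per-stage seeds (see [stage_seed()]), so every stage is independently
#' reproducible.
#'
#' @param cohort A [cohort_config()] for the development-site cohort.
#' @param external Optional [site_shift()]; when given, a shifted
#'   external-site cohort of `external_n` patients is generated and
#'   evaluated with the same fitted state.
#' @param external_n External cohort size (default 10000).
#' @param dev_fraction,train_fraction Split fractions (defaults 0.80 and
#'   0.80).
#' @param stratify_split Stratify the random splits by outcome (default
#'   `FALSE`).
#' @param model_params Overrides for [train_gbm()].
#' @param confidence Confidence levels for the region tables.
#' @param mondrian,smoothed Conformal flags (defaults: Mondrian,
#'   non-smoothed deterministic p-values).
#' @param n_attribution Patients explained per cohort (default 20).
#' @param shapley_samples Permutations per explained patient.
#' @param n_background Background rows for the Shapley sampler.
#' @param bootstrap_B Bootstrap replicates for metric CIs.
#' @param seed Master seed.
#' @return An `experiment_config`.
#' @export
experiment_config <- function(cohort = cohort_config(n_patients = 20933L),
                              external = NULL,
                              external_n = 10000L,
                              dev_fraction = 0.80,
                              train_fraction = 0.80,
                              stratify_split = FALSE,
                              model_params = list(),
                              confidence = c(0.999, 0.95, 0.90, 0.85),
                              mondrian = TRUE,
                              smoothed = FALSE,
                              n_attribution = 20L,
                              shapley_samples = 100L,
                              n_background = 100L,
                              bootstrap_B = 2000L,
                              seed = 1L) {
  stopifnot(
    inherits(cohort, "cohort_config"),
    dev_fraction > 0, dev_fraction < 1,
    train_fraction > 0, train_fraction < 1,
    all(confidence > 0), all(confidence < 1)
  )
  if (!is.null(external)) stopifnot(inherits(external, "site_shift"))
  structure(
    list(cohort = cohort, external = external,
         external_n = as.integer(external_n),
         dev_fraction = dev_fraction, train_fraction = train_fraction,
         stratify_split = stratify_split, model_params = model_params,
         confidence = confidence, mondrian = mondrian, smoothed = smoothed,
         n_attribution = as.integer(n_attribution),
         shapley_samples = as.integer(shapley_samples),
         n_background = as.integer(n_background),
         bootstrap_B = as.integer(bootstrap_B),
         seed = as.integer(seed)),
    class = "experiment_config"
  )
}

#' Derive a per-stage seed from the master seed
#'
#' Deterministic fan-out keeping every derived seed a valid 32-bit
#' integer: `(master * 7919 + 104729 * stage_index) mod (2^31 - 1)`.
#' Stage indices: generate = 1, split = 2, model = 3, smoothing = 4,
#' attribution = 5, bootstrap = 6, external = 7.
#'
#' @param master Master integer seed.
#' @param stage Stage index.
#' @return Integer seed.
#' @export
stage_seed <- function(master, stage) {
  as.integer((as.double(master) * 7919 + 104729 * stage) %% 2147483647)
}

#' Split a cohort into training, calibration and validation partitions
#'
#' Random (optionally outcome-stratified) split: first development versus
#' internal validation, then the development rows into training and
#' calibration. Partitions are disjoint, their union is the cohort, and
#' sizes are within one row of the nominal fractions.
#'
#' @param cohort A filtered `raw_cohort`.
#' @param dev_fraction,train_fraction Fractions (defaults 0.80 / 0.80).
#' @param seed Integer seed.
#' @param stratify Stratify by outcome.
#' @return List of `raw_cohort`s: `training`, `calibration`, `validation`,
#'   plus the index vectors `idx`.
#' @export
split_cohort <- function(cohort, dev_fraction = 0.80, train_fraction = 0.80,
                         seed = 1L, stratify = FALSE) {
  stopifnot(inherits(cohort, "raw_cohort"))
  n <- nrow(cohort$patients)
  set.seed(seed)
  draw <- function(pool, frac, strata) {
    if (!stratify) return(sample(pool, round(frac * length(pool))))
    unlist(lapply(split(pool, strata[pool]), function(p) {
      sample(p, round(frac * length(p)))
    }), use.names = FALSE)
  }
  y <- cohort$patients$outcome
  dev <- sort(draw(seq_len(n), dev_fraction, y))
  val <- setdiff(seq_len(n), dev)
  tr <- sort(draw(dev, train_fraction, y))
  cal <- setdiff(dev, tr)
  for (part in list(tr, cal, val)) {
    if (length(unique(y[part])) < 2L) {
      stop("a partition contains a single outcome class; use a larger ",
           "cohort or stratify = TRUE", call. = FALSE)
    }
  }
  list(
    training = subset_cohort(cohort, tr),
    calibration = subset_cohort(cohort, cal),
    validation = subset_cohort(cohort, val),
    idx = list(training = tr, calibration = cal, validation = val)
  )
}

#' Run the end-to-end conformal mortality experiment
#'
#' Executes the full pipeline from one [experiment_config()]: synthetic
#' cohort generation, exclusion filtering, 80/20/80/20 splitting,
#' train-only preprocessing, gradient-boosted model fitting, Mondrian
#' calibration, prediction regions on the internal validation rows (and on
#' a shifted external cohort when configured), Shapley attributions for a
#' subsample, and the evaluation report. Deterministic under a fixed
#' master seed for the default (non-smoothed) path.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional directory; when given, cohorts, the
#'   preprocessor audit, per-patient regions and the report are written as
#'   CSV/JSON artifacts with the configuration and seeds embedded.
#' @return List: `internal`/`external` (`evaluation_report`s), `model`,
#'   `calibrator`, `preprocessor`, `exclusion_log`, `splits` (sizes),
#'   `attribution` (global importance), `config`.
#' @export
run_experiment <- function(config = experiment_config(), out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  cfg <- config$cohort
  cfg$seed <- stage_seed(config$seed, 1L)
  cohort <- generate_cohort(cfg)
  filtered <- apply_exclusion_filters(cohort)

  parts <- split_cohort(filtered$cohort,
                        dev_fraction = config$dev_fraction,
                        train_fraction = config$train_fraction,
                        seed = stage_seed(config$seed, 2L),
                        stratify = config$stratify_split)

  prep <- fit_preprocessor(parts$training)
  mm_train <- transform_cohort(prep, parts$training)
  mm_cal <- transform_cohort(prep, parts$calibration)
  mm_val <- transform_cohort(prep, parts$validation)

  model <- train_gbm(mm_train, params = config$model_params,
                     seed = stage_seed(config$seed, 3L))
  calibrator <- calibrate_mondrian(model, mm_cal,
                                   mondrian = config$mondrian)

  smooth_seed <- stage_seed(config$seed, 4L)
  pv_val <- conformal_pvalues(calibrator, model, mm_val,
                              smoothed = config$smoothed,
                              seed = if (config$smoothed) smooth_seed)
  internal <- evaluation_report(pv_val, mm_val$y,
                                confidence = config$confidence,
                                B = config$bootstrap_B,
                                seed = stage_seed(config$seed, 6L))

  # per-patient explanations on a validation subsample
  attr_seed <- stage_seed(config$seed, 5L)
  set.seed(attr_seed)
  bg <- mm_train$x[sample(nrow(mm_train$x),
                          min(config$n_background, nrow(mm_train$x))), ,
                   drop = FALSE]
  explained <- sample(nrow(mm_val$x),
                      min(config$n_attribution, nrow(mm_val$x)))
  attributions <- lapply(seq_along(explained), function(i) {
    shapley_attribution(model, mm_val$x[explained[i], ], bg,
                        n_samples = config$shapley_samples,
                        seed = attr_seed + i)
  })
  importance <- global_importance(
    attributions, feature_values = mm_val$x[explained, , drop = FALSE]
  )

  external <- NULL
  if (!is.null(config$external)) {
    ext_cfg <- config$cohort
    ext_cfg$n_patients <- config$external_n
    ext_cfg$seed <- stage_seed(config$seed, 7L)
    ext_cfg$shift <- config$external
    ext_cohort <- apply_exclusion_filters(generate_cohort(ext_cfg))$cohort
    mm_ext <- transform_cohort(prep, ext_cohort)
    pv_ext <- conformal_pvalues(calibrator, model, mm_ext,
                                smoothed = config$smoothed,
                                seed = if (config$smoothed) smooth_seed + 2L)
    external <- evaluation_report(pv_ext, mm_ext$y,
                                  confidence = config$confidence,
                                  B = config$bootstrap_B,
                                  seed = stage_seed(config$seed, 6L) + 1L)
  }

  result <- list(
    internal = internal, external = external,
    model = model, calibrator = calibrator, preprocessor = prep,
    exclusion_log = filtered$log,
    splits = vapply(parts$idx, length, integer(1)),
    attribution = importance,
    pvalues = list(internal = pv_val,
                   external = if (!is.null(config$external)) pv_ext),
    labels = list(internal = mm_val$y,
                  external = if (!is.null(config$external)) mm_ext$y),
    config = config
  )
  if (!is.null(out_dir)) write_experiment(result, out_dir)
  result
}

# Persist the machine-readable artifacts of a run.
write_experiment <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$exclusion_log,
                   file.path(out_dir, "exclusion_log.csv"),
                   row.names = FALSE)
  write_preprocessor(result$preprocessor,
                     file.path(out_dir, "preprocessor.json"))
  pv <- result$pvalues$internal
  regions <- predict_region(pv$p_survival, pv$p_nonsurvival, 0.10)
  write_regions(regions, file.path(out_dir, "regions_internal.csv"),
                true_labels = result$labels$internal)
  utils::write.csv(result$internal$region_table$regions,
                   file.path(out_dir, "region_table_internal.csv"),
                   row.names = FALSE)
  utils::write.csv(result$internal$error_curve,
                   file.path(out_dir, "error_curve_internal.csv"),
                   row.names = FALSE)
  utils::write.csv(result$attribution$ranking,
                   file.path(out_dir, "feature_importance.csv"),
                   row.names = FALSE)
  summary <- list(
    seed = result$config$seed,
    splits = as.list(result$splits),
    auc = result$internal$auc, brier = result$internal$brier,
    epsilon_star = result$internal$epsilon_star
  )
  if (!is.null(result$external)) {
    utils::write.csv(result$external$region_table$regions,
                     file.path(out_dir, "region_table_external.csv"),
                     row.names = FALSE)
    utils::write.csv(result$external$error_curve,
                     file.path(out_dir, "error_curve_external.csv"),
                     row.names = FALSE)
    summary$auc_external <- result$external$auc
    summary$brier_external <- result$external$brier
  }
  jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
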