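test_that("exclusion filters apply age, stay and missingness rules in order", {
  coh <- generate_cohort(small_config(n = 10, seed = 2))
  # hand-build violations: rows 1-3 each break exactly one rule
  coh$patients$age <- c(17, rep(50, 9))
  coh$patients$length_of_stay <- c(100, 20, rep(100, 8))
  for (nm in names(coh$vitals)) coh$vitals[[nm]][, ] <-
    matrix(rnorm(10 * ncol(coh$vitals[[nm]])), 10)
  for (nm in names(coh$labs)) coh$labs[[nm]][, ] <-
    matrix(rnorm(10 * ncol(coh$labs[[nm]])), 10)
  coh$patients$bmi <- rep(25, 10); coh$patients$gcs <- rep(14, 10)
  coh$patients$urine_output <- rep(1500, 10)
  # row 3: blank 8 of 21 schema variables (> 30%)
  for (nm in names(coh$vitals)) coh$vitals[[nm]][3, ] <- NA
  for (nm in names(coh$labs)) coh$labs[[nm]][3, ] <- NA
  coh$patients$urine_output[3] <- NA

  res <- apply_exclusion_filters(coh)
  expect_equal(res$log$n, c(1, 1, 1, 7))
  expect_equal(nrow(res$cohort$patients), 7)
  expect_false(any(res$cohort$patients$age < 18))
})

test_that("a stay of exactly 24 hours is retained (boundary kept)", {
  coh <- generate_cohort(small_config(n = 4, seed = 3))
  coh$patients$length_of_stay <- c(24.0, 23.9, 24.1, 500)
  res <- apply_exclusion_filters(coh)
  expect_equal(res$cohort$patients$patient_id, c(1L, 3L, 4L))
})

test_that("missing age or length of stay is a hard error", {
  coh <- generate_cohort(small_config(n = 5, seed = 4))
  coh$patients$length_of_stay <- NULL
  expect_error(apply_exclusion_filters(coh), "length_of_stay")
})

test_that("repeated measures aggregate with sample SD and NA sentinels", {
  coh <- generate_cohort(small_config(n = 3, seed = 5))
  coh$vitals$vital_01[1, ] <- c(10, 20, 30,
                                rep(NA, ncol(coh$vitals$vital_01) - 3))
  coh$vitals$vital_01[2, ] <- c(7, rep(NA, ncol(coh$vitals$vital_01) - 1))
  coh$vitals$vital_01[3, ] <- 5                        # constant series
  coh$labs$lab_01[1, ] <- c(NA, NA)                    # all-missing series
  agg <- aggregate_repeated_measures(coh)

  expect_equal(agg$vital_01_max[1], 30)
  expect_equal(agg$vital_01_min[1], 10)
  expect_equal(agg$vital_01_mean[1], 20)
  expect_equal(agg$vital_01_sd[1], 10)                 # n-1 denominator
  # single measurement: max=min=mean, SD missing
  expect_equal(agg$vital_01_max[2], 7)
  expect_equal(agg$vital_01_mean[2], 7)
  expect_true(is.na(agg$vital_01_sd[2]))
  expect_equal(agg$vital_01_sd[3], 0)
  expect_true(is.na(agg$lab_01_max[1]) && is.na(agg$lab_01_min[1]))
})

test_that("training standardisation yields mean 0 / SD 1 and fixed order", {
  coh <- generate_cohort(small_config(n = 300, seed = 6))
  prep <- fit_preprocessor(coh)
  mm <- transform_cohort(prep, coh)
  expect_identical(colnames(mm$x), prep$feature_names)
  scale_cols <- !prep$onehot_cols
  mu <- colMeans(mm$x[, scale_cols], na.rm = TRUE)
  sg <- apply(mm$x[, scale_cols], 2, sd, na.rm = TRUE)
  # BMI is imputed before standardisation, so its post-imputation moments
  # differ slightly from the raw training moments used for scaling
  not_bmi <- colnames(mm$x)[scale_cols] != "bmi"
  expect_lt(max(abs(mu[not_bmi])), 1e-8)
  expect_lt(max(abs(sg[not_bmi] - 1)), 1e-8)
})

test_that("standardisation arithmetic matches (x - mean) / sd", {
  coh <- generate_cohort(small_config(n = 100, seed = 8,
                                      missing_rate = 0))
  prep <- fit_preprocessor(coh)
  mm <- transform_cohort(prep, coh)
  expect_equal(unname(mm$x[1, "aps_iii"]),
               (coh$patients$aps_iii[1] - prep$mean[["aps_iii"]]) /
                 prep$sd[["aps_iii"]])
})

test_that("kNN BMI imputation matches a brute-force neighbour search", {
  coh <- generate_cohort(small_config(n = 120, seed = 9))
  # tiny age jitter so nearest-neighbour distances have no exact ties
  coh$patients$age <- coh$patients$age + seq_len(120) / 997
  coh$patients$bmi[1:10] <- NA
  prep <- fit_preprocessor(coh, k = 5)
  mm <- transform_cohort(prep, coh)

  # brute force on the same coordinates
  p <- coh$patients
  obs <- which(!is.na(p$bmi) & !is.na(p$age))
  code <- function(idx) {
    cbind((p$age[idx] - prep$knn$age_mu) / prep$knn$age_sd,
          outer(p$sex[idx], c("female", "male"), "==") * 1,
          outer(p$ethnicity[idx],
                c("asian", "black", "white", "other"), "==") * 1)
  }
  ref <- code(obs)
  for (i in 1:10) {
    d <- sqrt(rowSums(sweep(ref, 2, as.numeric(code(i)))^2))
    expected <- mean(p$bmi[obs[order(d)[1:5]]])
    got_std <- unname(mm$x[i, "bmi"])
    got <- got_std * prep$sd[["bmi"]] + prep$mean[["bmi"]]
    expect_equal(got, expected, tolerance = 1e-8)
  }
})

test_that("k = 1 imputation copies the nearest training neighbour's BMI", {
  coh <- generate_cohort(small_config(n = 50, seed = 10, missing_rate = 0))
  coh$patients$bmi[1] <- NA
  prep <- fit_preprocessor(coh, k = 1)
  mm <- transform_cohort(prep, coh)
  imputed <- mm$x[1, "bmi"] * prep$sd[["bmi"]] + prep$mean[["bmi"]]
  expect_true(any(abs(imputed - coh$patients$bmi[-1]) < 1e-8))
})

test_that("unseen categorical level maps to an all-zero one-hot block", {
  coh <- generate_cohort(small_config(n = 80, seed = 11))
  prep <- fit_preprocessor(coh)
  newc <- generate_cohort(small_config(n = 5, seed = 12))
  newc$patients$ethnicity[1] <- "unrecorded"
  mm <- transform_cohort(prep, newc)
  eth_cols <- grep("^ethnicity_", colnames(mm$x))
  expect_equal(sum(mm$x[1, eth_cols]), 0)
  expect_equal(sum(mm$x[2, eth_cols]), 1)
})

test_that("transform is immutable and leakage-free", {
  train <- generate_cohort(small_config(n = 150, seed = 13))
  prep <- fit_preprocessor(train)
  before <- serialize(prep, NULL)

  val_a <- generate_cohort(small_config(n = 40, seed = 14))
  val_b <- generate_cohort(small_config(n = 40, seed = 15))
  mm_a <- transform_cohort(prep, val_a)
  expect_identical(serialize(prep, NULL), before)

  # a validation row's transform is invariant to the other validation rows
  row1 <- sepsiscp:::subset_cohort(val_a, 1)
  mixed_plus <- sepsiscp:::subset_cohort(val_a, c(1, 2))
  expect_equal(transform_cohort(prep, row1)$x[1, ], mm_a$x[1, ])
  expect_equal(transform_cohort(prep, mixed_plus)$x[1, ], mm_a$x[1, ])
  expect_equal(transform_cohort(prep, val_b)$x[1, ],
               transform_cohort(prep, sepsiscp:::subset_cohort(val_b, 1))$x[1, ])

  # replay: a validation row identical to a training row transforms alike
  mm_train <- transform_cohort(prep, train)
  replay <- sepsiscp:::subset_cohort(train, 5)
  expect_equal(transform_cohort(prep, replay)$x[1, ], mm_train$x[5, ])
})

test_that("mean imputation path fills every missing value", {
  coh <- generate_cohort(small_config(n = 200, seed = 16,
                                      missing_rate = 0.15))
  prep <- fit_preprocessor(coh, impute_for_model = TRUE)
  mm <- transform_cohort(prep, coh)
  expect_false(anyNA(mm$x))
  expect_true(any(mm$mask))      # mask still records what was missing
})

test_that("schema mismatch names the offending column", {
  coh <- generate_cohort(small_config(n = 50, seed = 17))
  prep <- fit_preprocessor(coh)
  smaller <- generate_cohort(cohort_config(
    n_patients = 20, n_repeated_vitals = 2, n_continuous = 4,
    n_binary = 7, exclusion_fraction = 0, seed = 18
  ))
  expect_error(transform_cohort(prep, smaller), "vital_03")
})
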