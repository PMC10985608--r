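test_that("nonconformity is one minus the hypothesised-label probability", {
  expect_equal(sepsiscp:::nonconformity_from_prob(1, 1), 0)
  expect_equal(sepsiscp:::nonconformity_from_prob(0, 1), 1)
  expect_equal(sepsiscp:::nonconformity_from_prob(0.3, 1), 0.7)
  expect_equal(sepsiscp:::nonconformity_from_prob(0.3, 0), 0.3)
})

test_that("the calibrator stores sorted per-class scores and counts", {
  mm <- separable_matrix(n = 200, seed = 1)
  model <- train_gbm(mm, seed = 2)
  cal_mm <- separable_matrix(n = 120, seed = 3)
  cal <- calibrate_mondrian(model, cal_mm)
  expect_s3_class(cal, "mondrian_calibrator")
  expect_false(is.unsorted(cal$scores[["0"]]))
  expect_false(is.unsorted(cal$scores[["1"]]))
  expect_equal(cal$n0 + cal$n1, 120)
  expect_true(all(unlist(cal$scores) >= 0 & unlist(cal$scores) <= 1))
  expect_identical(cal, calibrate_mondrian(model, cal_mm))

  single <- cal_mm; single$y <- rep(0L, 120)
  expect_error(calibrate_mondrian(model, single), "both outcome classes")
})

test_that("p-values match hand counts including the tie convention", {
  # alpha above every calibration score with n_y = 9 -> p = 1/10
  cal <- make_calibrator(scores0 = seq(0.05, 0.45, by = 0.05),
                         scores1 = c(0.2, 0.5, 0.8))
  expect_equal(conformal_pvalue(cal, 0.99, 0), 0.1)
  # most conforming score -> maximal p-value
  expect_equal(conformal_pvalue(cal, 0, 0), 1.0)
  # ties counted with >=: {0.2, 0.5, 0.8} vs 0.5 -> (2 + 1) / 4
  expect_equal(conformal_pvalue(cal, 0.5, 1), 0.75)
})

test_that("p-values agree with brute-force counting over random calibrators", {
  set.seed(99)
  mismatches <- 0L
  for (i in 1:1000) {
    n <- sample(1:50, 1)
    # discretised scores force frequent ties
    ref <- round(runif(n), 2)
    other <- round(runif(max(n %/% 2, 1)), 2)
    cal <- make_calibrator(scores0 = ref, scores1 = other)
    a <- if (runif(1) < 0.5) round(runif(1), 2) else sample(ref, 1)
    got <- conformal_pvalue(cal, a, 0)
    want <- brute_pvalue(ref, a)
    if (!isTRUE(all.equal(got, want, tolerance = 1e-12))) {
      mismatches <- mismatches + 1L
    }
  }
  expect_identical(mismatches, 0L)
})

test_that("smoothed p-values use seeded uniform tie-breaking", {
  ref <- c(0.2, 0.5, 0.5, 0.8)
  cal <- make_calibrator(scores0 = ref, scores1 = c(0.1, 0.9))
  p1 <- conformal_pvalue(cal, 0.5, 0, smoothed = TRUE, seed = 7)
  p2 <- conformal_pvalue(cal, 0.5, 0, smoothed = TRUE, seed = 7)
  expect_identical(p1, p2)
  expect_error(conformal_pvalue(cal, 0.5, 0, smoothed = TRUE), "seed")
  set.seed(7); tau <- runif(1)
  expect_equal(p1, brute_pvalue(ref, 0.5, smoothed = TRUE, tau = tau))
  # smoothed p never exceeds the conservative non-smoothed p
  expect_lte(p1, conformal_pvalue(cal, 0.5, 0))
})

test_that("the worked single-patient example types all three regions", {
  r <- predict_region(0.37, 0.08, epsilon = c(0.40, 0.15, 0.05))
  expect_equal(r$label_set,
               c("{null}", "{survival}", "{survival, nonsurvival}"))
  expect_equal(r$region_type, c("empty", "single", "multiple"))
  # inclusion is strict: p = epsilon excludes the label
  at_eps <- predict_region(0.40, 0.40, epsilon = 0.40)
  expect_equal(at_eps$region_type, "empty")
})

test_that("outcome classification mirrors the worked prediction table", {
  # regions {1}, {0}, {0,1}, {null} against truths 1, 1, 1, 0
  regions <- predict_region(
    p_survival = c(0.01, 0.90, 0.60, 0.02),
    p_nonsurvival = c(0.90, 0.01, 0.70, 0.03),
    epsilon = 0.15
  )
  out <- classify_outcomes(regions, c(1, 1, 1, 0))
  expect_equal(as.character(out$outcome),
               c("correct_single", "error_single", "multiple", "empty"))
  overall <- out$table[out$table$group == "overall", ]
  expect_equal(sum(overall$n), 4)
  expect_error(classify_outcomes(regions, c(1, 2, 0, 0)), "binary")
})

test_that("regions nest and error grows monotonically in significance", {
  coh <- generate_cohort(cohort_config(n_patients = 4000, seed = 41,
                                       exclusion_fraction = 0))
  parts <- split_cohort(coh, seed = 42)
  prep <- fit_preprocessor(parts$training)
  model <- train_gbm(transform_cohort(prep, parts$training), seed = 43)
  cal <- calibrate_mondrian(model, transform_cohort(prep, parts$calibration))
  mm_val <- transform_cohort(prep, parts$validation)
  pv <- sepsiscp:::conformal_pvalues(cal, model, mm_val)

  grid <- seq(0, 1, by = 0.05)
  prev_in0 <- prev_in1 <- rep(TRUE, nrow(mm_val$x))
  for (eps in grid) {
    r <- predict_region(pv$p_survival, pv$p_nonsurvival, eps)
    # per-patient nesting: regions at larger epsilon are subsets
    expect_true(all(!r$in_survival | prev_in0))
    expect_true(all(!r$in_nonsurvival | prev_in1))
    prev_in0 <- r$in_survival; prev_in1 <- r$in_nonsurvival
  }
  curve <- cp_error_curve(pv, mm_val$y, grid)
  expect_true(all(diff(curve$error) >= -1e-12))
  expect_true(all(diff(curve$frac_multiple) <= 1e-12))
})

test_that("Mondrian per-class coverage holds on exchangeable data", {
  coh <- generate_cohort(cohort_config(n_patients = 6000, seed = 51,
                                       exclusion_fraction = 0))
  parts <- split_cohort(coh, seed = 52)
  prep <- fit_preprocessor(parts$training)
  model <- train_gbm(transform_cohort(prep, parts$training), seed = 53)
  cal <- calibrate_mondrian(model, transform_cohort(prep, parts$calibration))
  mm_val <- transform_cohort(prep, parts$validation)
  pv <- sepsiscp:::conformal_pvalues(cal, model, mm_val)
  y <- mm_val$y

  for (eps in c(0.05, 0.10, 0.20, 0.35)) {
    r <- predict_region(pv$p_survival, pv$p_nonsurvival, eps)
    for (cls in 0:1) {
      idx <- which(y == cls)
      excl <- if (cls == 1) !r$in_nonsurvival[idx] else !r$in_survival[idx]
      n_cal_cls <- if (cls == 1) cal$n1 else cal$n0
      # test-set sampling plus finite-calibration coverage fluctuation
      se <- sqrt(eps * (1 - eps) *
                   (1 / length(idx) + 1 / (n_cal_cls + 2)))
      expect_lte(mean(excl), eps + 3 * se)
    }
  }
})

test_that("p-values of true labels are super-uniform under exchangeability", {
  coh <- generate_cohort(cohort_config(n_patients = 5000, seed = 61,
                                       exclusion_fraction = 0))
  parts <- split_cohort(coh, seed = 62)
  prep <- fit_preprocessor(parts$training)
  model <- train_gbm(transform_cohort(prep, parts$training), seed = 63)
  cal <- calibrate_mondrian(model, transform_cohort(prep, parts$calibration))
  mm_val <- transform_cohort(prep, parts$validation)
  p_true <- conformal_pvalue(
    cal, nonconformity(model, mm_val, mm_val$y), mm_val$y
  )
  for (t in seq(0.05, 0.95, by = 0.15)) {
    se <- sqrt(t * (1 - t) *
                 (1 / length(p_true) + 1 / (min(cal$n0, cal$n1) + 2)))
    expect_lte(mean(p_true <= t), t + 3 * se)
  }
})

test_that("marginal (non-Mondrian) mode pools the calibration classes", {
  mm <- separable_matrix(n = 200, seed = 71)
  model <- train_gbm(mm, seed = 72)
  cal_mm <- separable_matrix(n = 100, seed = 73)
  marg <- calibrate_mondrian(model, cal_mm, mondrian = FALSE)
  pooled <- sort(c(marg$scores[["0"]], marg$scores[["1"]]))
  p <- conformal_pvalue(marg, 0.5, 1)
  expect_equal(p, brute_pvalue(pooled, 0.5))
})
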