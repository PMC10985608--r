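#' Configuration for a synthetic ICU sepsis cohort
#'
#' Describes a cohort generated from a single latent severity factor:
#' correlated vitals and labs, binary comorbidity/treatment flags, integer
#' severity scores and an in-hospital mortality outcome whose prevalence is
#' controlled exactly by numerically solving the logistic intercept.
#'
#' @param n_patients Number of patients to generate.
#' @param target_prevalence Expected fraction of nonsurvivors (default 0.165).
#' @param n_repeated_vitals Number of vital-sign features, each emitted as a
#'   fixed-length per-hour series of `vital_points` measurements.
#' @param n_continuous Number of laboratory features, each emitted as a
#'   `lab_points`-point series (first-day min/max pairs).
#' @param n_binary Number of binary flags. The first flags take clinically
#'   named roles (pulmonary infection, vasopressor use, comorbidities).
#' @param missing_rate Per-variable probability that a patient's value (or
#'   whole series) is missing. MCAR unless `mar_missingness = TRUE`, in which
#'   case the rate increases with latent severity.
#' @param bmi_missing_rate Extra missingness for BMI so the kNN imputer has
#'   real work (BMI is the one variable the pipeline imputes by kNN).
#' @param exclusion_fraction Fraction of rows deliberately violating the
#'   inclusion criteria (age < 18, ICU stay < 24 h, > 30% missing) so the
#'   exclusion filters are exercised.
#' @param vital_points,lab_points Series lengths (defaults 24 and 2).
#' @param mar_missingness If `TRUE`, missingness probability is keyed to the
#'   latent severity (missing-at-random); default is MCAR.
#' @param shift Optional [site_shift()] describing a second-site distribution
#'   shift; `NULL` for the development cohort.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   configuration.
#' @return An object of class `cohort_config`.
#' @seealso [generate_cohort()], [site_shift()], [apply_site_shift()]
#' @export
cohort_config <- function(n_patients,
                          target_prevalence = 0.165,
                          n_repeated_vitals = 7L,
                          n_continuous = 26L,
                          n_binary = 7L,
                          missing_rate = 0.05,
                          bmi_missing_rate = 0.10,
                          exclusion_fraction = 0.05,
                          vital_points = 24L,
                          lab_points = 2L,
                          mar_missingness = FALSE,
                          shift = NULL,
                          seed = 1L) {
  stopifnot(
    length(n_patients) == 1L, n_patients >= 1,
    target_prevalence > 0, target_prevalence < 1,
    n_repeated_vitals >= 1, n_continuous >= 1, n_binary >= 1,
    missing_rate >= 0, missing_rate <= 0.95,
    bmi_missing_rate >= 0, bmi_missing_rate <= 0.95,
    exclusion_fraction >= 0, exclusion_fraction < 1,
    vital_points >= 1, lab_points >= 1
  )
  if (!is.null(shift) && !inherits(shift, "site_shift")) {
    stop("`shift` must be NULL or a site_shift object", call. = FALSE)
  }
  structure(
    list(
      n_patients = as.integer(n_patients),
      target_prevalence = target_prevalence,
      n_repeated_vitals = as.integer(n_repeated_vitals),
      n_continuous = as.integer(n_continuous),
      n_binary = as.integer(n_binary),
      missing_rate = missing_rate,
      bmi_missing_rate = bmi_missing_rate,
      exclusion_fraction = exclusion_fraction,
      vital_points = as.integer(vital_points),
      lab_points = as.integer(lab_points),
      mar_missingness = mar_missingness,
      shift = shift,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Distribution shift for an external-site cohort
#'
#' Parameterises interdatabase heterogeneity: feature marginals are moved by
#' `mean_shift` (in within-site SD units) and widened by `scale_factor`, and
#' the latent outcome model's weights are shrunk by `coefficient_perturbation`
#' so the feature-outcome relationship learned on the development site no
#' longer holds exactly.
#'
#' @param mean_shift Per-feature offset in SD units; a scalar is recycled
#'   across vitals and labs, or a named vector keyed by feature name.
#' @param scale_factor Per-feature SD multiplier (strictly positive); scalar
#'   or named vector, like `mean_shift`.
#' @param coefficient_perturbation Relative shrinkage in `[0, 1)` applied to
#'   every outcome-model weight; larger values make outcomes noisier in the
#'   features, degrading externally validated discrimination.
#' @param prevalence_override Optional outcome prevalence for the shifted
#'   site (defaults to the development cohort's target).
#' @return An object of class `site_shift`.
#' @export
site_shift <- function(mean_shift = 0,
                       scale_factor = 1,
                       coefficient_perturbation = 0,
                       prevalence_override = NULL) {
  stopifnot(
    all(scale_factor > 0),
    coefficient_perturbation >= 0, coefficient_perturbation < 1
  )
  if (!is.null(prevalence_override)) {
    stopifnot(prevalence_override > 0, prevalence_override < 1)
  }
  structure(
    list(
      mean_shift = mean_shift,
      scale_factor = scale_factor,
      coefficient_perturbation = coefficient_perturbation,
      prevalence_override = prevalence_override
    ),
    class = "site_shift"
  )
}

# Feature naming. The first binary flags take fixed clinical roles; extras are
# generic comorbidity columns.
flag_names <- function(n_binary) {
  base <- c(
    "pulmonary_infection", "vasopressor", "chronic_kidney_disease",
    "congestive_heart_failure", "chronic_pulmonary_disease",
    "diabetes", "liver_disease"
  )
  if (n_binary <= length(base)) {
    base[seq_len(n_binary)]
  } else {
    c(base, sprintf("comorbidity_%02d", seq_len(n_binary - length(base))))
  }
}

vital_names <- function(k) sprintf("vital_%02d", seq_len(k))
lab_names <- function(k) sprintf("lab_%02d", seq_len(k))

# Latent-factor loadings and baselines. Deterministic in the feature counts
# alone (not the cohort seed) so that internal and external cohorts share one
# generating structure.
cohort_structure <- function(config) {
  kv <- config$n_repeated_vitals
  kl <- config$n_continuous
  kb <- config$n_binary
  sgn <- function(k) rep_len(c(1, -1), k)
  list(
    vital_mu = 70 + 8 * seq_len(kv),
    vital_load = sgn(kv) * seq(0.4, 1.0, length.out = kv),
    vital_sd = 6 + 0.5 * seq_len(kv),
    vital_point_sd = rep(3, kv),
    lab_mu = 20 + 4 * seq_len(kl),
    lab_load = sgn(kl) * seq(0.3, 0.9, length.out = kl),
    lab_sd = 4 + 0.25 * seq_len(kl),
    lab_point_sd = rep(1.5, kl),
    flag_base = rep_len(c(0.45, 0.50, 0.17, 0.32, 0.28, 0.33, 0.08), kb),
    flag_slope = seq(0.5, 1.1, length.out = kb),
    # outcome model weights on the latent scale
    beta = c(z = 1.7, vasopressor = 0.5, pulmonary_infection = 0.4,
             age = 0.25)
  )
}

# Solve the logistic intercept by bisection so that the mean outcome
# probability over the realized linear predictors equals the target.
solve_intercept <- function(eta, target, tol = 1e-10) {
  f <- function(c0) mean(stats::plogis(c0 + eta)) - target
  lo <- -30; hi <- 30
  stopifnot(f(lo) < 0, f(hi) > 0)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Generate a synthetic sepsis cohort
#'
#' Draws a cohort from the latent-severity model described in
#' [cohort_config()]. A single severity factor z per patient drives
#' correlated vital/lab series, binary flags, severity scores (APS III,
#' SOFA, GCS), urine output and the mortality outcome; the logistic
#' intercept is solved by bisection so expected prevalence equals
#' `target_prevalence`. A configurable fraction of rows violate the
#' inclusion criteria to give the exclusion filters real work.
#'
#' @param config A [cohort_config()].
#' @return A `raw_cohort`: a list with `patients` (one row per patient:
#'   demographics, flags, scores, urine output, length of stay, outcome),
#'   `vitals` and `labs` (named lists of patients-by-timepoints matrices
#'   with `NA` sentinels for missing series), the generating `config` and
#'   the latent severity vector `latent`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 200, seed = 7))
#' mean(coh$patients$outcome)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  st <- cohort_structure(config)
  shift <- config$shift

  ms <- function(feature) { # mean shift in SD units, per feature
    if (is.null(shift)) return(0)
    v <- shift$mean_shift
    if (length(v) == 1L && is.null(names(v))) return(unname(v))
    if (feature %in% names(v)) unname(v[[feature]]) else 0
  }
  sf <- function(feature) {
    if (is.null(shift)) return(1)
    v <- shift$scale_factor
    if (length(v) == 1L && is.null(names(v))) return(unname(v))
    if (feature %in% names(v)) unname(v[[feature]]) else 1
  }

  set.seed(config$seed)
  z <- stats::rnorm(n)

  # demographics
  age <- round(66 + 6 * z + 11 * stats::rnorm(n))
  age <- pmin(pmax(age, 18), 99)
  bmi <- round(27.5 - 0.4 * z + 5.5 * stats::rnorm(n), 1)
  bmi <- pmin(pmax(bmi, 13), 60)
  sex <- ifelse(stats::runif(n) < 0.57, "male", "female")
  ethnicity <- sample(c("asian", "black", "white", "other"), n,
                      replace = TRUE, prob = c(0.03, 0.10, 0.68, 0.19))

  # repeated vital series: per-patient level set by the latent factor,
  # per-hour noise around it
  vitals <- vector("list", config$n_repeated_vitals)
  names(vitals) <- vital_names(config$n_repeated_vitals)
  for (j in seq_along(vitals)) {
    nm <- names(vitals)[j]
    level <- st$vital_mu[j] + ms(nm) * st$vital_sd[j] +
      sf(nm) * st$vital_sd[j] * (st$vital_load[j] * z +
                                   sqrt(1 - st$vital_load[j]^2) * stats::rnorm(n))
    vitals[[j]] <- level + matrix(
      stats::rnorm(n * config$vital_points, sd = st$vital_point_sd[j]),
      nrow = n
    )
  }

  labs <- vector("list", config$n_continuous)
  names(labs) <- lab_names(config$n_continuous)
  for (j in seq_along(labs)) {
    nm <- names(labs)[j]
    level <- st$lab_mu[j] + ms(nm) * st$lab_sd[j] +
      sf(nm) * st$lab_sd[j] * (st$lab_load[j] * z +
                                 sqrt(1 - st$lab_load[j]^2) * stats::rnorm(n))
    labs[[j]] <- level + matrix(
      stats::rnorm(n * config$lab_points, sd = st$lab_point_sd[j]),
      nrow = n
    )
  }

  # binary flags, severity scores, urine output
  flags <- matrix(0L, n, config$n_binary,
                  dimnames = list(NULL, flag_names(config$n_binary)))
  for (j in seq_len(config$n_binary)) {
    pr <- stats::plogis(stats::qlogis(st$flag_base[j]) + st$flag_slope[j] * z)
    flags[, j] <- as.integer(stats::runif(n) < pr)
  }
  gcs <- pmin(pmax(round(14 - 1.8 * z + 1.2 * stats::rnorm(n)), 3), 15)
  aps_iii <- pmax(round(52 + 16 * z + 9 * stats::rnorm(n)), 0)
  sofa <- pmin(pmax(round(6 + 2.5 * z + 1.5 * stats::rnorm(n)), 0), 24)
  urine_output <- round(exp(7.2 - 0.45 * z + 0.45 * stats::rnorm(n)))
  length_of_stay <- round(exp(4.5 + 0.3 * z + 0.6 * stats::rnorm(n)), 1)
  length_of_stay <- pmax(length_of_stay, 24)

  # outcome via logistic model; intercept solved to hit target prevalence
  pert <- if (is.null(shift)) 0 else shift$coefficient_perturbation
  beta <- st$beta * (1 - pert)
  eta <- beta[["z"]] * z +
    beta[["vasopressor"]] * flags[, "vasopressor"] +
    beta[["pulmonary_infection"]] * flags[, "pulmonary_infection"] +
    beta[["age"]] * (age - 66) / 10
  target <- config$target_prevalence
  if (!is.null(shift) && !is.null(shift$prevalence_override)) {
    target <- shift$prevalence_override
  }
  c0 <- solve_intercept(eta, target)
  outcome <- as.integer(stats::runif(n) < stats::plogis(c0 + eta))

  patients <- data.frame(
    patient_id = seq_len(n),
    age = age, bmi = bmi, sex = sex, ethnicity = ethnicity,
    flags,
    gcs = gcs, aps_iii = aps_iii, sofa = sofa,
    urine_output = urine_output,
    length_of_stay = length_of_stay,
    outcome = outcome,
    stringsAsFactors = FALSE
  )

  cohort <- structure(
    list(patients = patients, vitals = vitals, labs = labs,
         config = config, latent = z),
    class = "raw_cohort"
  )
  cohort <- inject_missingness(cohort)
  inject_exclusion_violations(cohort)
}

# MCAR (default) or severity-keyed MAR missingness: a hit blanks the whole
# schema variable for that patient (scalar NA or all-NA series).
inject_missingness <- function(cohort) {
  config <- cohort$config
  n <- nrow(cohort$patients)
  rate <- config$missing_rate
  p_miss <- function() {
    if (config$mar_missingness) {
      stats::plogis(stats::qlogis(pmax(rate, 1e-6)) + 0.5 * cohort$latent)
    } else {
      rep(rate, n)
    }
  }
  maskable <- c("urine_output", "gcs")
  for (v in maskable) {
    hit <- stats::runif(n) < p_miss()
    cohort$patients[[v]][hit] <- NA
  }
  hit <- stats::runif(n) < pmin(p_miss() + config$bmi_missing_rate, 0.95)
  cohort$patients$bmi[hit] <- NA
  for (j in seq_along(cohort$vitals)) {
    hit <- stats::runif(n) < p_miss()
    cohort$vitals[[j]][hit, ] <- NA
  }
  for (j in seq_along(cohort$labs)) {
    hit <- stats::runif(n) < p_miss()
    cohort$labs[[j]][hit, ] <- NA
  }
  cohort
}

# Force a configurable fraction of rows to violate one inclusion criterion
# each (cycled): under-age, short stay, or excess missingness.
inject_exclusion_violations <- function(cohort) {
  frac <- cohort$config$exclusion_fraction
  if (frac <= 0) return(cohort)
  n <- nrow(cohort$patients)
  n_bad <- floor(frac * n)
  if (n_bad == 0L) return(cohort)
  bad <- sample(n, n_bad)
  kind <- rep_len(1:3, n_bad)
  cohort$patients$age[bad[kind == 1]] <-
    sample(14:17, sum(kind == 1), replace = TRUE)
  cohort$patients$length_of_stay[bad[kind == 2]] <-
    round(stats::runif(sum(kind == 2), 2, 23.9), 1)
  over <- bad[kind == 3]
  if (length(over)) {
    # blank enough lab series to push the missing fraction past 30%
    n_blank <- ceiling(0.4 * n_schema_variables(cohort))
    n_blank <- min(n_blank, length(cohort$labs))
    for (j in seq_len(n_blank)) cohort$labs[[j]][over, ] <- NA
  }
  cohort
}

#' Generate a distribution-shifted external cohort
#'
#' Convenience wrapper: attaches a [site_shift()] to a [cohort_config()] and
#' generates. With a zero shift the result is identical to
#' [generate_cohort()] under the same seed.
#'
#' @param config A [cohort_config()] (its own `shift`, if any, is replaced).
#' @param shift A [site_shift()].
#' @return A `raw_cohort`.
#' @export
apply_site_shift <- function(config, shift) {
  stopifnot(inherits(config, "cohort_config"), inherits(shift, "site_shift"))
  config$shift <- shift
  generate_cohort(config)
}

# Number of schema variables counted once each by the missing-fraction rule.
n_schema_variables <- function(cohort) {
  4L +                                  # age, bmi, sex, ethnicity
    length(cohort$vitals) + length(cohort$labs) +
    cohort$config$n_binary +
    3L +                                # gcs, aps_iii, sofa
    1L                                  # urine output
}

#' @export
print.raw_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic sepsis cohort: %d patients, %d vitals x %d pts, %d labs x %d pts, prevalence %.3f\n",
    nrow(x$patients), length(x$vitals), x$config$vital_points,
    length(x$labs), x$config$lab_points, mean(x$patients$outcome)
  ))
  invisible(x)
}

# Row subset preserving all parallel components.
subset_cohort <- function(cohort, idx) {
  cohort$patients <- cohort$patients[idx, , drop = FALSE]
  rownames(cohort$patients) <- NULL
  cohort$vitals <- lapply(cohort$vitals, function(m) m[idx, , drop = FALSE])
  cohort$labs <- lapply(cohort$labs, function(m) m[idx, , drop = FALSE])
  cohort$latent <- cohort$latent[idx]
  cohort
}

#' Write / read a cohort as plain-text files
#'
#' `write_cohort()` writes `patients.csv` (one row per patient),
#' `measures.csv` (repeated vitals/labs in long format: patient_id,
#' variable, time index, value) and `params.json` (the generating
#' configuration and seed). `read_cohort()` reconstructs the `raw_cohort`.
#' The latent severity vector is a simulation-internal quantity and is not
#' serialized.
#'
#' @param cohort A `raw_cohort`.
#' @param dir Directory to write to / read from (created if needed).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` a
#'   `raw_cohort` (with `latent = NULL`).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$patients, file.path(dir, "patients.csv"),
                   row.names = FALSE)
  long <- do.call(rbind, c(
    lapply(names(cohort$vitals), function(nm) {
      m <- cohort$vitals[[nm]]
      data.frame(patient_id = rep(cohort$patients$patient_id, ncol(m)),
                 variable = nm, idx = rep(seq_len(ncol(m)), each = nrow(m)),
                 value = as.vector(m))
    }),
    lapply(names(cohort$labs), function(nm) {
      m <- cohort$labs[[nm]]
      data.frame(patient_id = rep(cohort$patients$patient_id, ncol(m)),
                 variable = nm, idx = rep(seq_len(ncol(m)), each = nrow(m)),
                 value = as.vector(m))
    })
  ))
  utils::write.csv(long, file.path(dir, "measures.csv"), row.names = FALSE)
  cfg <- cohort$config
  cfg$shift <- if (is.null(cfg$shift)) NULL else unclass(cfg$shift)
  jsonlite::write_json(unclass(cfg), file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  patients <- utils::read.csv(file.path(dir, "patients.csv"),
                              stringsAsFactors = FALSE)
  long <- utils::read.csv(file.path(dir, "measures.csv"),
                          stringsAsFactors = FALSE)
  cfg <- jsonlite::read_json(file.path(dir, "params.json"),
                             simplifyVector = TRUE)
  shift <- NULL
  if (!is.null(cfg$shift)) {
    shift <- do.call(site_shift, cfg$shift)
  }
  config <- cohort_config(
    n_patients = cfg$n_patients, target_prevalence = cfg$target_prevalence,
    n_repeated_vitals = cfg$n_repeated_vitals, n_continuous = cfg$n_continuous,
    n_binary = cfg$n_binary, missing_rate = cfg$missing_rate,
    bmi_missing_rate = cfg$bmi_missing_rate,
    exclusion_fraction = cfg$exclusion_fraction,
    vital_points = cfg$vital_points, lab_points = cfg$lab_points,
    mar_missingness = cfg$mar_missingness, shift = shift, seed = cfg$seed
  )
  unpack <- function(nm) {
    sub <- long[long$variable == nm, ]
    sub <- sub[order(sub$idx, sub$patient_id), ]
    matrix(sub$value, nrow = nrow(patients))
  }
  vitals <- lapply(vital_names(config$n_repeated_vitals), unpack)
  names(vitals) <- vital_names(config$n_repeated_vitals)
  labs <- lapply(lab_names(config$n_continuous), unpack)
  names(labs) <- lab_names(config$n_continuous)
  structure(
    list(patients = patients, vitals = vitals, labs = labs,
         config = config, latent = NULL),
    class = "raw_cohort"
  )
}
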