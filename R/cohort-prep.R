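#' Apply the cohort inclusion criteria
#'
#' Retains patients aged >= 18 years, with an ICU stay of at least
#' `los_min` hours (stays shorter than 24 h are read as "discharged within
#' 24 hours" and excluded; the boundary value 24.0 is kept) and with at most
#' `max_missing` of the schema variables missing. Each excluded row is
#' attributed to the first matching rule, in that order.
#'
#' @param cohort A `raw_cohort`.
#' @param los_min Minimum length of stay in hours (default 24; strict `<`
#'   excludes).
#' @param max_missing Maximum tolerated missing fraction over the
#'   pre-aggregation feature schema, each variable counted once (default 0.30).
#' @return A list with `cohort` (the filtered `raw_cohort`) and `log`, a
#'   data frame of exclusion counts per reason plus the number retained.
#' @export
apply_exclusion_filters <- function(cohort, los_min = 24, max_missing = 0.30) {
  stopifnot(inherits(cohort, "raw_cohort"))
  p <- cohort$patients
  if (is.null(p$age) || is.null(p$length_of_stay)) {
    stop("cohort must carry `age` and `length_of_stay`", call. = FALSE)
  }
  miss <- missing_fraction(cohort)
  under_age <- !is.na(p$age) & p$age < 18
  short_stay <- !under_age & !is.na(p$length_of_stay) &
    p$length_of_stay < los_min
  too_missing <- !under_age & !short_stay & miss > max_missing
  keep <- !(under_age | short_stay | too_missing)
  log <- data.frame(
    reason = c("age_under_18", "los_under_24h", "missing_over_30pct",
               "retained"),
    n = c(sum(under_age), sum(short_stay), sum(too_missing), sum(keep))
  )
  list(cohort = subset_cohort(cohort, which(keep)), log = log)
}

# Fraction of schema variables missing per patient; a series counts as
# missing only when entirely NA.
missing_fraction <- function(cohort) {
  p <- cohort$patients
  scalars <- cbind(
    is.na(p$age), is.na(p$bmi), is.na(p$sex), is.na(p$ethnicity),
    is.na(p$gcs), is.na(p$aps_iii), is.na(p$sofa), is.na(p$urine_output)
  )
  flags <- sapply(flag_names(cohort$config$n_binary),
                  function(f) is.na(p[[f]]))
  series <- sapply(c(cohort$vitals, cohort$labs),
                   function(m) rowSums(!is.na(m)) == 0L)
  n_missing <- rowSums(scalars) + rowSums(flags) + rowSums(series)
  n_missing / n_schema_variables(cohort)
}

#' Aggregate repeated measurements to first-day summaries
#'
#' Vital-sign series are reduced to max/min/mean/SD columns (sample SD,
#' n - 1 denominator; the SD of a single measurement is `NA`, not 0) and
#' laboratory series to max/min columns. All-missing series yield `NA`
#' sentinels throughout.
#'
#' @param cohort A `raw_cohort`.
#' @return A data frame of aggregate columns, one row per patient, in a
#'   fixed column order (`<vital>_max/min/mean/sd`, then `<lab>_max/min`).
#' @export
aggregate_repeated_measures <- function(cohort) {
  stopifnot(inherits(cohort, "raw_cohort"))
  agg1 <- function(m, fns) {
    out <- lapply(fns, function(f) apply(m, 1, f))
    as.data.frame(out)
  }
  safe_max <- function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
  safe_min <- function(x) if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE)
  safe_mean <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  safe_sd <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2L) NA_real_ else stats::sd(x)
  }
  out <- vector("list", length(cohort$vitals) + length(cohort$labs))
  i <- 1L
  for (nm in names(cohort$vitals)) {
    a <- agg1(cohort$vitals[[nm]],
              list(max = safe_max, min = safe_min,
                   mean = safe_mean, sd = safe_sd))
    names(a) <- paste(nm, c("max", "min", "mean", "sd"), sep = "_")
    out[[i]] <- a; i <- i + 1L
  }
  for (nm in names(cohort$labs)) {
    a <- agg1(cohort$labs[[nm]], list(max = safe_max, min = safe_min))
    names(a) <- paste(nm, c("max", "min"), sep = "_")
    out[[i]] <- a; i <- i + 1L
  }
  do.call(cbind, out)
}

# Assemble the pre-encoding model frame: scalars + flags + aggregates.
# `bmi` stays a raw column here; kNN imputation happens at transform time.
model_frame <- function(cohort) {
  p <- cohort$patients
  fn <- flag_names(cohort$config$n_binary)
  cbind(
    p[, c("age", "bmi", "sex", "ethnicity", fn,
          "gcs", "aps_iii", "sofa", "urine_output")],
    aggregate_repeated_measures(cohort)
  )
}

one_hot <- function(x, levels, prefix) {
  m <- sapply(levels, function(l) as.numeric(!is.na(x) & x == l))
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  colnames(m) <- paste(prefix, levels, sep = "_")
  m            # unseen levels at transform time give an all-zero block
}

#' Fit the preprocessing state on training data only
#'
#' Learns every statistic the transform needs from the training partition:
#' one-hot category lists for sex and ethnicity, per-column means and SDs
#' for standardisation and mean imputation, and the kNN reference table
#' (standardised age plus demographic one-hots, with observed BMI) used to
#' impute missing BMI. Constant columns are dropped with a warning. The
#' returned state is immutable: transforming any cohort never updates it.
#'
#' @param train A `raw_cohort` (the training partition, already filtered).
#' @param k Neighbour count for BMI imputation (default 5).
#' @param impute_for_model If `TRUE`, [transform_cohort()] mean-imputes all
#'   remaining missing values (random forest / logistic regression path);
#'   if `FALSE` they pass through as `NA` for models with native
#'   missing-value handling (gradient boosting path).
#' @return An object of class `preprocessor_state`.
#' @export
fit_preprocessor <- function(train, k = 5L, impute_for_model = FALSE) {
  stopifnot(inherits(train, "raw_cohort"), k >= 1)
  mf <- model_frame(train)
  cat_levels <- list(
    sex = c("female", "male"),
    ethnicity = c("asian", "black", "white", "other")
  )
  enc <- encode_frame(mf, cat_levels)
  mu <- colMeans(enc, na.rm = TRUE)
  sigma <- apply(enc, 2, stats::sd, na.rm = TRUE)
  all_na <- !is.finite(mu)
  constant <- !all_na & (!is.finite(sigma) | sigma == 0)
  # one-hot indicator columns are kept unstandardised
  onehot_cols <- grepl("^(sex|ethnicity)_", colnames(enc))
  drop <- (all_na | constant) & !onehot_cols
  if (any(drop)) {
    warning("dropping constant or all-missing feature(s): ",
            paste(colnames(enc)[drop], collapse = ", "), call. = FALSE)
  }
  keep <- colnames(enc)[!drop]

  # kNN reference: training rows with observed BMI, demographic coordinates
  age_mu <- mean(mf$age, na.rm = TRUE)
  age_sd <- stats::sd(mf$age, na.rm = TRUE)
  obs <- !is.na(mf$bmi) & !is.na(mf$age)
  ref <- cbind(
    age = (mf$age[obs] - age_mu) / age_sd,
    one_hot(mf$sex[obs], cat_levels$sex, "sex"),
    one_hot(mf$ethnicity[obs], cat_levels$ethnicity, "ethnicity")
  )

  structure(
    list(
      cat_levels = cat_levels,
      feature_names = keep,
      mean = mu[keep], sd = sigma[keep],
      onehot_cols = onehot_cols[!drop],
      knn = list(k = as.integer(k), ref = ref, bmi = mf$bmi[obs],
                 age_mu = age_mu, age_sd = age_sd),
      impute_for_model = impute_for_model
    ),
    class = "preprocessor_state"
  )
}

encode_frame <- function(mf, cat_levels) {
  num <- mf[, setdiff(names(mf), names(cat_levels)), drop = FALSE]
  cbind(
    as.matrix(num),
    one_hot(mf$sex, cat_levels$sex, "sex"),
    one_hot(mf$ethnicity, cat_levels$ethnicity, "ethnicity")
  )
}

# Brute-force kNN on the demographic coordinates; chunked so the distance
# matrix stays small. Mean BMI of the k nearest training rows.
knn_impute_bmi <- function(state, mf) {
  idx <- which(is.na(mf$bmi))
  if (!length(idx)) return(mf$bmi)
  q <- cbind(
    age = (mf$age[idx] - state$knn$age_mu) / state$knn$age_sd,
    one_hot(mf$sex[idx], state$cat_levels$sex, "sex"),
    one_hot(mf$ethnicity[idx], state$cat_levels$ethnicity, "ethnicity")
  )
  q[is.na(q)] <- 0
  ref <- state$knn$ref
  k <- min(state$knn$k, nrow(ref))
  out <- mf$bmi
  chunk <- 500L
  for (s in seq(1L, length(idx), by = chunk)) {
    rows <- s:min(s + chunk - 1L, length(idx))
    # squared Euclidean distances query-chunk x reference
    d2 <- outer(rowSums(q[rows, , drop = FALSE]^2), rowSums(ref^2), "+") -
      2 * q[rows, , drop = FALSE] %*% t(ref)
    for (i in seq_along(rows)) {
      nb <- order(d2[i, ])[seq_len(k)]
      out[idx[rows[i]]] <- mean(state$knn$bmi[nb])
    }
  }
  out
}

#' Transform a cohort into the fixed-width model matrix
#'
#' Applies the fitted [fit_preprocessor()] state without modification:
#' aggregation, one-hot encoding with training categories (unseen levels
#' map to an all-zero block), kNN BMI imputation, and standardisation by
#' training means/SDs. Missing values other than BMI pass through as `NA`
#' unless the state was fitted with `impute_for_model = TRUE`, in which
#' case they are filled with the training mean.
#'
#' @param state A `preprocessor_state`.
#' @param cohort A `raw_cohort`.
#' @return A `model_matrix`: list with numeric matrix `x` (patients by
#'   features, column order fixed by the state), `feature_names`, outcome
#'   vector `y`, logical missingness `mask` aligned to `x`, and
#'   `patient_id`.
#' @export
transform_cohort <- function(state, cohort) {
  stopifnot(inherits(state, "preprocessor_state"),
            inherits(cohort, "raw_cohort"))
  mf <- model_frame(cohort)
  mf$bmi <- knn_impute_bmi(state, mf)
  enc <- encode_frame(mf, state$cat_levels)
  missing_cols <- setdiff(state$feature_names, colnames(enc))
  if (length(missing_cols)) {
    stop("cohort schema mismatch; missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- enc[, state$feature_names, drop = FALSE]
  mask <- is.na(x)
  scale_cols <- !state$onehot_cols
  x[, scale_cols] <- sweep(
    sweep(x[, scale_cols, drop = FALSE], 2, state$mean[scale_cols], "-"),
    2, state$sd[scale_cols], "/"
  )
  if (state$impute_for_model) {
    # training mean on the standardised scale is 0; one-hots keep their mean
    for (j in seq_len(ncol(x))) {
      fill <- if (scale_cols[j]) 0 else state$mean[j]
      x[mask[, j], j] <- fill
    }
  }
  structure(
    list(x = x, feature_names = state$feature_names,
         y = cohort$patients$outcome, mask = mask,
         patient_id = cohort$patients$patient_id),
    class = "model_matrix"
  )
}

#' @export
print.preprocessor_state <- function(x, ...) {
  cat(sprintf(
    "preprocessor_state: %d features, kNN(k=%d) BMI imputation, %s path\n",
    length(x$feature_names), x$knn$k,
    if (x$impute_for_model) "mean-imputed" else "missing-passthrough"
  ))
  invisible(x)
}

#' Serialize a preprocessor state to JSON for audit
#'
#' @param state A `preprocessor_state`.
#' @param path File to write.
#' @return `path`, invisibly.
#' @export
write_preprocessor <- function(state, path) {
  out <- list(
    feature_names = state$feature_names,
    mean = as.list(state$mean), sd = as.list(state$sd),
    cat_levels = state$cat_levels,
    knn_k = state$knn$k, knn_n_ref = nrow(state$knn$ref),
    impute_for_model = state$impute_for_model
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
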