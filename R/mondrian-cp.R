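#' Nonconformity score of an example for a hypothesised label
#'
#' The score is one minus the model's predicted probability of the
#' hypothesised label: alpha(x, y) = 1 - P(y | x). A perfectly conforming
#' example (probability 1) scores 0; a maximally strange one scores 1. The
#' score is monotone decreasing in the predicted probability of y.
#'
#' @param model A `risk_model`.
#' @param x A `model_matrix`, numeric matrix or single feature vector.
#' @param y Hypothesised label(s), 0 = survival, 1 = nonsurvival (recycled).
#' @return Numeric vector of scores in \[0, 1\].
#' @export
nonconformity <- function(model, x, y) {
  p1 <- predict_risk(model, x)
  nonconformity_from_prob(p1, y)
}

# Same, from already-computed P(nonsurvival).
nonconformity_from_prob <- function(p_nonsurvival, y) {
  stopifnot(all(y %in% c(0, 1)))
  ifelse(rep_len(y, length(p_nonsurvival)) == 1,
         1 - p_nonsurvival, p_nonsurvival)
}

#' Build the (Mondrian) conformal calibrator
#'
#' Scores every calibration example against its true label and stores the
#' per-class sorted nonconformity arrays. Class-conditional (Mondrian)
#' calibration computes p-values within each outcome class, giving
#' per-class validity under class imbalance; `mondrian = FALSE` pools the
#' two classes into a single (marginal) reference distribution for
#' ablation.
#'
#' @param model A fitted `risk_model` trained on a partition disjoint from
#'   the calibration rows.
#' @param calibration_matrix A `model_matrix` for the calibration partition.
#' @param mondrian Class-conditional if `TRUE` (default).
#' @return A `mondrian_calibrator` with sorted per-class score arrays and
#'   class counts.
#' @export
calibrate_mondrian <- function(model, calibration_matrix, mondrian = TRUE) {
  stopifnot(inherits(model, "risk_model"),
            inherits(calibration_matrix, "model_matrix"))
  y <- calibration_matrix$y
  if (anyNA(y) || !all(y %in% c(0, 1))) {
    stop("calibration outcome must be binary 0/1", call. = FALSE)
  }
  if (mondrian && length(unique(y)) < 2L) {
    stop("both outcome classes must be present in the calibration set; ",
         "Mondrian p-values are undefined otherwise", call. = FALSE)
  }
  p1 <- predict_risk(model, calibration_matrix)
  alpha <- nonconformity_from_prob(p1, y)
  structure(
    list(
      scores = list("0" = sort(alpha[y == 0]), "1" = sort(alpha[y == 1])),
      n0 = sum(y == 0), n1 = sum(y == 1),
      mondrian = mondrian
    ),
    class = "mondrian_calibrator"
  )
}

#' @export
print.mondrian_calibrator <- function(x, ...) {
  cat(sprintf(
    "%s conformal calibrator: n0=%d survivors, n1=%d nonsurvivors\n",
    if (x$mondrian) "Mondrian (class-conditional)" else "marginal",
    x$n0, x$n1
  ))
  invisible(x)
}

#' Conformal p-value of a nonconformity score
#'
#' The p-value is the (corrected) proportion of calibration examples of the
#' hypothesised class at least as nonconforming as the query:
#' p = (#\{alpha_i >= alpha\} + 1) / (n_y + 1). The smoothed variant breaks
#' ties with a seeded uniform tau:
#' p = (#\{alpha_i > alpha\} + tau (#\{alpha_i = alpha\} + 1)) / (n_y + 1),
#' which makes the p-value exactly (rather than super-) uniform under
#' exchangeability.
#'
#' @param calibrator A `mondrian_calibrator`.
#' @param score Numeric vector of nonconformity scores.
#' @param y Hypothesised label(s), recycled against `score`.
#' @param smoothed Use the tie-broken variant (default `FALSE`).
#' @param seed Seed for the smoothing uniforms (required when `smoothed`).
#' @return p-values in (0, 1\].
#' @export
conformal_pvalue <- function(calibrator, score, y, smoothed = FALSE,
                             seed = NULL) {
  stopifnot(inherits(calibrator, "mondrian_calibrator"),
            all(y %in% c(0, 1)))
  y <- rep_len(y, length(score))
  if (smoothed) {
    if (is.null(seed)) stop("smoothed p-values need a seed", call. = FALSE)
    set.seed(seed)
    tau <- stats::runif(length(score))
  }
  ref_for <- function(lbl) {
    if (calibrator$mondrian) calibrator$scores[[as.character(lbl)]]
    else sort(c(calibrator$scores[["0"]], calibrator$scores[["1"]]))
  }
  out <- numeric(length(score))
  for (lbl in unique(y)) {
    ref <- ref_for(lbl)
    n <- length(ref)
    if (n < 1L) stop("empty calibration class: ", lbl, call. = FALSE)
    idx <- which(y == lbl)
    # counts via binary search on the sorted reference array
    n_le <- findInterval(score[idx], ref)              # #{ref <= s}
    n_lt <- findInterval(score[idx], ref, left.open = TRUE)  # #{ref < s}
    n_ge <- n - n_lt
    n_eq <- n_le - n_lt
    if (smoothed) {
      out[idx] <- (n - n_le + tau[idx] * (n_eq + 1)) / (n + 1)
    } else {
      out[idx] <- (n_ge + 1) / (n + 1)
    }
  }
  out
}

#' Form a prediction region from the two label p-values
#'
#' A label enters the region iff its p-value strictly exceeds the
#' significance level epsilon (= 1 - confidence). Regions are typed empty
#' (no label), single, or multiple (both labels).
#'
#' @param p_survival,p_nonsurvival p-values in (0, 1\] (vectors allowed).
#' @param epsilon Significance level in \[0, 1\].
#' @return A data frame with one row per patient: the p-values, `epsilon`,
#'   logical inclusion flags `in_survival`/`in_nonsurvival`, `region_type`
#'   and a printable `label_set` string.
#' @examples
#' # three confidence levels for one patient
#' predict_region(0.37, 0.08, epsilon = c(0.40, 0.15, 0.05))
#' @export
predict_region <- function(p_survival, p_nonsurvival, epsilon) {
  stopifnot(all(epsilon >= 0), all(epsilon <= 1))
  k <- max(length(p_survival), length(p_nonsurvival), length(epsilon))
  p0 <- rep_len(p_survival, k)
  p1 <- rep_len(p_nonsurvival, k)
  eps <- rep_len(epsilon, k)
  in0 <- p0 > eps
  in1 <- p1 > eps
  region_type <- ifelse(in0 & in1, "multiple",
                        ifelse(in0 | in1, "single", "empty"))
  label_set <- ifelse(in0 & in1, "{survival, nonsurvival}",
                      ifelse(in0, "{survival}",
                             ifelse(in1, "{nonsurvival}", "{null}")))
  data.frame(
    p_survival = p0, p_nonsurvival = p1, epsilon = eps,
    in_survival = in0, in_nonsurvival = in1,
    region_type = region_type, label_set = label_set,
    stringsAsFactors = FALSE
  )
}

#' Conformal prediction regions for new patients
#'
#' Computes both hypothesised-label p-values for each row and forms the
#' region at the requested significance level.
#'
#' @param calibrator A `mondrian_calibrator`.
#' @param model The `risk_model` the calibrator was built on.
#' @param x A `model_matrix` or numeric matrix.
#' @param epsilon Significance level (scalar).
#' @param smoothed,seed Passed to [conformal_pvalue()].
#' @return The [predict_region()] data frame, plus `patient_id` when `x`
#'   is a `model_matrix`.
#' @export
conformal_predict <- function(calibrator, model, x, epsilon = 0.10,
                              smoothed = FALSE, seed = NULL) {
  pv <- conformal_pvalues(calibrator, model, x, smoothed, seed)
  out <- predict_region(pv$p_survival, pv$p_nonsurvival, epsilon)
  if (inherits(x, "model_matrix")) out$patient_id <- x$patient_id
  out
}

# Both-label p-values for each row; shared by conformal_predict and the
# evaluation curves (which sweep epsilon without re-scoring).
conformal_pvalues <- function(calibrator, model, x, smoothed = FALSE,
                              seed = NULL) {
  p1 <- predict_risk(model, x)
  a_surv <- nonconformity_from_prob(p1, 0)
  a_nons <- nonconformity_from_prob(p1, 1)
  if (smoothed && is.null(seed)) {
    stop("smoothed p-values need a seed", call. = FALSE)
  }
  data.frame(
    p_survival = conformal_pvalue(calibrator, a_surv, 0, smoothed,
                                  if (smoothed) seed else NULL),
    p_nonsurvival = conformal_pvalue(calibrator, a_nons, 1, smoothed,
                                     if (smoothed) seed + 1L else NULL),
    prob_nonsurvival = p1
  )
}

#' Classify region outcomes against the true labels
#'
#' A single-label region is correct iff its sole label equals the truth;
#' multiple and empty regions are typed as such (an empty region always
#' misses the truth). The tabulation reports counts and percentages per
#' outcome class and overall.
#'
#' @param regions A [predict_region()] data frame.
#' @param true_labels Binary vector, same length.
#' @return List with `outcome` (per-row factor: correct_single,
#'   error_single, multiple, empty) and `table` (per-class tabulation).
#' @export
classify_outcomes <- function(regions, true_labels) {
  stopifnot(nrow(regions) == length(true_labels))
  if (anyNA(true_labels) || !all(true_labels %in% c(0, 1))) {
    stop("true labels must be binary 0/1", call. = FALSE)
  }
  truth_in <- ifelse(true_labels == 1, regions$in_nonsurvival,
                     regions$in_survival)
  outcome <- ifelse(
    regions$region_type == "multiple", "multiple",
    ifelse(regions$region_type == "empty", "empty",
           ifelse(truth_in, "correct_single", "error_single"))
  )
  outcome <- factor(outcome,
                    levels = c("empty", "error_single", "correct_single",
                               "multiple"))
  tab_for <- function(idx) {
    n <- length(idx)
    counts <- table(outcome[idx])
    data.frame(outcome = names(counts), n = as.integer(counts),
               pct = if (n) 100 * as.integer(counts) / n else rep(0, 4))
  }
  tab <- rbind(
    cbind(group = "survivors", tab_for(which(true_labels == 0))),
    cbind(group = "nonsurvivors", tab_for(which(true_labels == 1))),
    cbind(group = "overall", tab_for(seq_along(true_labels)))
  )
  list(outcome = outcome, table = tab)
}

#' Export prediction regions as CSV
#'
#' @param regions A [predict_region()] data frame (with `patient_id`).
#' @param true_labels Optional binary truth vector to append outcome
#'   classes.
#' @param path File to write.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path, true_labels = NULL) {
  out <- regions
  if (!is.null(true_labels)) {
    out$true_label <- true_labels
    out$outcome <- as.character(classify_outcomes(regions,
                                                  true_labels)$outcome)
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
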