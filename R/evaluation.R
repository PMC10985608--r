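#' Area under the ROC curve
#'
#' Rank-statistic (Mann-Whitney) formulation with midrank handling of
#' ties, so AUC is invariant under strictly monotone transforms of the
#' scores.
#'
#' @param scores Numeric risk scores (higher = more at risk).
#' @param labels Binary outcomes, 1 = nonsurvival.
#' @return AUC in \[0, 1\].
#' @export
cp_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC needs both outcome classes", call. = FALSE)
  }
  r <- rank(scores)                      # midranks for ties
  n0 <- as.double(n0); n1 <- as.double(n1)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

#' Brier score
#'
#' Mean squared difference between the predicted nonsurvival probability
#' and the binary outcome; lower is better.
#'
#' @param probs Predicted P(nonsurvival) in \[0, 1\].
#' @param labels Binary outcomes.
#' @return Brier score in \[0, 1\].
#' @export
brier_score <- function(probs, labels) {
  stopifnot(length(probs) == length(labels), all(labels %in% c(0, 1)))
  mean((probs - labels)^2)
}

#' Reliability (calibration) curve
#'
#' Bins predictions into equal-width probability bins and compares mean
#' predicted probability with the observed outcome rate per bin.
#'
#' @param probs Predicted probabilities.
#' @param labels Binary outcomes.
#' @param bins Number of equal-width bins (default 10).
#' @return Data frame: bin midpoint, n, mean predicted, observed rate.
#' @export
reliability_curve <- function(probs, labels, bins = 10L) {
  stopifnot(length(probs) == length(labels), bins >= 2)
  edges <- seq(0, 1, length.out = bins + 1L)
  bin <- cut(probs, edges, include.lowest = TRUE, labels = FALSE)
  out <- lapply(seq_len(bins), function(b) {
    idx <- which(bin == b)
    data.frame(
      midpoint = (edges[b] + edges[b + 1L]) / 2,
      n = length(idx),
      predicted = if (length(idx)) mean(probs[idx]) else NA_real_,
      observed = if (length(idx)) mean(labels[idx]) else NA_real_
    )
  })
  do.call(rbind, out)
}

#' Stratified bootstrap confidence interval for a metric
#'
#' Resamples within each outcome class (so every replicate keeps both
#' classes and the class balance) and returns the percentile interval.
#'
#' @param metric Function of (scores, labels), e.g. [cp_auc()] or
#'   [brier_score()].
#' @param scores,labels As for the metric.
#' @param B Number of replicates (default 2000).
#' @param seed Integer seed.
#' @param conf Interval mass (default 0.95).
#' @return List: `estimate`, `lower`, `upper`, `B`, `seed`.
#' @export
bootstrap_ci <- function(metric, scores, labels, B = 2000L, seed = 1L,
                         conf = 0.95) {
  stopifnot(B >= 100, length(scores) == length(labels))
  set.seed(seed)
  i0 <- which(labels == 0)
  i1 <- which(labels == 1)
  stat <- numeric(B)
  for (b in seq_len(B)) {
    idx <- c(sample(i0, length(i0), replace = TRUE),
             sample(i1, length(i1), replace = TRUE))
    stat[b] <- metric(scores[idx], labels[idx])
  }
  q <- stats::quantile(stat, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                       names = FALSE)
  list(estimate = metric(scores, labels), lower = q[1], upper = q[2],
       B = as.integer(B), seed = as.integer(seed))
}

#' Conformal error and label-distribution curves over a significance grid
#'
#' For each significance level, forms the regions from the per-patient
#' p-values and reports the observed prediction error (fraction of true
#' labels not included in the region — empty regions count as errors) and
#' the empty/single/multiple fractions. `epsilon_star` is the significance
#' level maximising the single-prediction fraction (ties broken toward the
#' smallest level).
#'
#' @param pvalues Data frame with `p_survival` and `p_nonsurvival` (one
#'   row per patient), e.g. from `conformal_predict()` output columns.
#' @param labels Binary true outcomes.
#' @param eps_grid Significance grid (default 0 to 1 by 0.01).
#' @return `cp_error_curve()`: data frame (epsilon, error, per-class
#'   errors, empty/single/multiple fractions) with attribute
#'   `epsilon_star`. `cp_label_distribution()` returns the same curve plus
#'   `epsilon_star` as a list element.
#' @export
cp_error_curve <- function(pvalues, labels, eps_grid = seq(0, 1, by = 0.01)) {
  if (!length(eps_grid)) stop("empty significance grid", call. = FALSE)
  stopifnot(nrow(pvalues) == length(labels), all(labels %in% c(0, 1)))
  p0 <- pvalues$p_survival
  p1 <- pvalues$p_nonsurvival
  is1 <- labels == 1
  rows <- lapply(eps_grid, function(eps) {
    in0 <- p0 > eps
    in1 <- p1 > eps
    truth_in <- ifelse(is1, in1, in0)
    data.frame(
      epsilon = eps,
      error = mean(!truth_in),
      error_survivors = mean(!truth_in[!is1]),
      error_nonsurvivors = mean(!truth_in[is1]),
      frac_empty = mean(!in0 & !in1),
      frac_single = mean(xor(in0, in1)),
      frac_multiple = mean(in0 & in1)
    )
  })
  curve <- do.call(rbind, rows)
  attr(curve, "epsilon_star") <-
    curve$epsilon[which.max(curve$frac_single)]
  curve
}

#' @rdname cp_error_curve
#' @export
cp_label_distribution <- function(pvalues, labels,
                                  eps_grid = seq(0, 1, by = 0.01)) {
  curve <- cp_error_curve(pvalues, labels, eps_grid)
  list(curve = curve, epsilon_star = attr(curve, "epsilon_star"))
}

#' Region tabulation across confidence levels
#'
#' For each confidence level, tabulates empty / single-error /
#' single-correct / multiple counts and percentages per outcome class and
#' overall. When model probabilities are supplied, an error-rate-matched
#' point-prediction comparison is appended: the classification threshold
#' is chosen on the evaluated rows so the point classifier's error rate in
#' nonsurvivors equals the conformal single-error rate in nonsurvivors at
#' `match_confidence`.
#'
#' @param pvalues Data frame with `p_survival`, `p_nonsurvival`.
#' @param labels Binary true outcomes.
#' @param confidence Confidence levels (default 0.999, 0.95, 0.90, 0.85).
#' @param point_probs Optional P(nonsurvival) for the comparison block.
#' @param match_confidence Level whose nonsurvivor single-error rate the
#'   point classifier is matched to (default 0.90).
#' @return List: `regions` (long data frame over confidence levels),
#'   `point_prediction` (or `NULL`), `efficiency` (single-correct fraction
#'   per confidence level).
#' @export
region_table <- function(pvalues, labels,
                         confidence = c(0.999, 0.95, 0.90, 0.85),
                         point_probs = NULL, match_confidence = 0.90) {
  stopifnot(nrow(pvalues) == length(labels))
  blocks <- lapply(confidence, function(conf) {
    regions <- predict_region(pvalues$p_survival, pvalues$p_nonsurvival,
                              1 - conf)
    tab <- classify_outcomes(regions, labels)$table
    cbind(confidence = conf, tab)
  })
  regions <- do.call(rbind, blocks)
  eff <- vapply(confidence, function(conf) {
    sub <- regions[regions$confidence == conf &
                     regions$group == "overall", ]
    sub$n[sub$outcome == "correct_single"] / sum(sub$n)
  }, numeric(1))
  point <- NULL
  if (!is.null(point_probs)) {
    sub <- regions[regions$confidence == match_confidence &
                     regions$group == "nonsurvivors", ]
    target <- sub$n[sub$outcome == "error_single"] / sum(sub$n)
    point <- point_prediction_comparison(point_probs, labels, target)
  }
  list(regions = regions,
       efficiency = data.frame(confidence = confidence, efficiency = eff),
       point_prediction = point)
}

# Point-prediction comparison of Table-4 style: threshold set so the
# error rate among true nonsurvivors equals `target_rate`.
point_prediction_comparison <- function(probs, labels, target_rate) {
  p1 <- sort(probs[labels == 1])
  n1 <- length(p1)
  k <- round(target_rate * n1)
  thr <- if (k == 0) {
    -Inf
  } else if (k == n1) {
    Inf
  } else {
    (p1[k] + p1[k + 1]) / 2          # exact when the order stats differ
  }
  pred <- as.integer(probs >= thr)
  err <- pred != labels
  tab_for <- function(idx) {
    data.frame(n_error = sum(err[idx]), n_correct = sum(!err[idx]),
               pct_error = 100 * mean(err[idx]))
  }
  cbind(
    group = c("survivors", "nonsurvivors", "overall"),
    rbind(tab_for(which(labels == 0)), tab_for(which(labels == 1)),
          tab_for(seq_along(labels))),
    threshold = thr, target_nonsurvivor_error = target_rate
  )
}

#' Assemble the full evaluation report
#'
#' Discrimination (AUC with stratified-bootstrap CI), calibration (Brier
#' score with CI, reliability curve), region tabulations across confidence
#' levels with the point-prediction comparison, and the conformal error /
#' label-distribution curves.
#'
#' @param pvalues Per-patient p-value data frame (with
#'   `prob_nonsurvival`, as returned by the pipeline's conformal scorer).
#' @param labels Binary outcomes.
#' @param confidence Confidence levels for the region tables.
#' @param B Bootstrap replicates (default 2000).
#' @param seed Seed for the bootstrap.
#' @return An `evaluation_report` list.
#' @export
evaluation_report <- function(pvalues, labels,
                              confidence = c(0.999, 0.95, 0.90, 0.85),
                              B = 2000L, seed = 1L) {
  probs <- pvalues$prob_nonsurvival
  curve <- cp_error_curve(pvalues, labels)
  structure(
    list(
      auc = bootstrap_ci(cp_auc, probs, labels, B = B, seed = seed),
      brier = bootstrap_ci(brier_score, probs, labels, B = B,
                           seed = seed + 1L),
      reliability = reliability_curve(probs, labels),
      region_table = region_table(pvalues, labels, confidence,
                                  point_probs = probs),
      error_curve = curve,
      epsilon_star = attr(curve, "epsilon_star"),
      n = length(labels)
    ),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation report (n=%d)\n", x$n))
  cat(sprintf("  AUC   %.3f (95%% CI %.3f-%.3f)\n",
              x$auc$estimate, x$auc$lower, x$auc$upper))
  cat(sprintf("  Brier %.3f (95%% CI %.3f-%.3f)\n",
              x$brier$estimate, x$brier$lower, x$brier$upper))
  ov <- x$region_table$regions
  ov <- ov[ov$group == "overall", ]
  for (conf in unique(ov$confidence)) {
    sub <- ov[ov$confidence == conf, ]
    cat(sprintf(
      "  conf %.3f: error %.1f%%, single-correct %.1f%%, multiple %.1f%%\n",
      conf,
      sub$pct[sub$outcome == "error_single"] +
        sub$pct[sub$outcome == "empty"],
      sub$pct[sub$outcome == "correct_single"],
      sub$pct[sub$outcome == "multiple"]
    ))
  }
  cat(sprintf("  epsilon* (max single fraction) = %.2f\n", x$epsilon_star))
  invisible(x)
}
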