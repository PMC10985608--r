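#' Train the gradient-boosted mortality risk model
#'
#' Fits a gradient-boosted tree ensemble (xgboost, binary logistic
#' objective, single-threaded for determinism) on the model matrix.
#' Missing feature values are handled natively by the learner — no
#' imputation on this path. Hyperparameters default to fixed, sensible
#' values; an optional seeded random search over an inner split of the
#' training partition is available, and `tune_matrix` lets the calibration
#' set drive tuning instead (at the cost of weakening the exchangeability
#' assumption behind the conformal layer — see the package vignette).
#'
#' @param train_matrix A `model_matrix` from [transform_cohort()].
#' @param params Named list overriding the defaults (`nrounds`, `eta`,
#'   `max_depth`, `min_child_weight`, `subsample`, `colsample_bytree`).
#' @param seed Integer seed; a fitted model predicts deterministically.
#' @param tune One of "none" (default) or "random": seeded random search of
#'   `n_tune` candidate settings scored by log-loss on a held-out inner
#'   fifth of the training rows.
#' @param n_tune Candidates for random search.
#' @param tune_matrix Optional `model_matrix` used as the tuning holdout in
#'   place of the inner split (pass the calibration partition to reproduce
#'   the tune-on-calibration variant).
#' @return A `risk_model` whose [predict_risk()] returns P(nonsurvival | x)
#'   in \[0, 1\].
#' @export
train_gbm <- function(train_matrix, params = list(), seed = 1L,
                      tune = c("none", "random"), n_tune = 10L,
                      tune_matrix = NULL) {
  stopifnot(inherits(train_matrix, "model_matrix"))
  tune <- match.arg(tune)
  y <- train_matrix$y
  check_binary_outcome(y)
  defaults <- list(nrounds = 150L, eta = 0.1, max_depth = 4L,
                   min_child_weight = 5, subsample = 0.8,
                   colsample_bytree = 0.8)
  p <- utils::modifyList(defaults, params)

  if (tune == "random") {
    p <- tune_gbm_random(train_matrix, p, seed, n_tune, tune_matrix)
  }

  set.seed(seed)
  fit <- fit_xgb(train_matrix$x, y, p)
  new_risk_model("gbm", fit, train_matrix, p, seed)
}

fit_xgb <- function(x, y, p) {
  dm <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  xgboost::xgb.train(
    params = list(
      objective = "binary:logistic", eta = p$eta, max_depth = p$max_depth,
      min_child_weight = p$min_child_weight, subsample = p$subsample,
      colsample_bytree = p$colsample_bytree, nthread = 1
    ),
    data = dm, nrounds = p$nrounds, verbose = 0
  )
}

tune_gbm_random <- function(train_matrix, p, seed, n_tune, tune_matrix) {
  set.seed(seed + 101L)
  n <- nrow(train_matrix$x)
  if (is.null(tune_matrix)) {
    hold <- sample(n, floor(n / 5))
    x_tr <- train_matrix$x[-hold, , drop = FALSE]
    y_tr <- train_matrix$y[-hold]
    x_ho <- train_matrix$x[hold, , drop = FALSE]
    y_ho <- train_matrix$y[hold]
  } else {
    x_tr <- train_matrix$x; y_tr <- train_matrix$y
    x_ho <- tune_matrix$x; y_ho <- tune_matrix$y
  }
  best <- p; best_loss <- Inf
  for (i in seq_len(n_tune)) {
    cand <- p
    cand$eta <- stats::runif(1, 0.03, 0.3)
    cand$max_depth <- sample(3:7, 1)
    cand$min_child_weight <- sample(c(1, 5, 10, 20), 1)
    cand$subsample <- stats::runif(1, 0.6, 1)
    cand$colsample_bytree <- stats::runif(1, 0.6, 1)
    fit <- fit_xgb(x_tr, y_tr, cand)
    pr <- pmin(pmax(stats::predict(fit, x_ho), 1e-12), 1 - 1e-12)
    loss <- -mean(y_ho * log(pr) + (1 - y_ho) * log(1 - pr))
    if (loss < best_loss) { best <- cand; best_loss <- loss }
  }
  best
}

#' Train a comparator baseline model
#'
#' Random forest (ranger, probability forest) or logistic regression
#' (`stats::glm`). Both require a fully imputed matrix (fit the
#' preprocessor with `impute_for_model = TRUE`); they share the
#' [predict_risk()] contract with the boosted model.
#'
#' @param train_matrix A `model_matrix` without missing values.
#' @param kind "random_forest" or "logistic_regression".
#' @param seed Integer seed.
#' @return A `risk_model`.
#' @export
train_baseline <- function(train_matrix,
                           kind = c("random_forest", "logistic_regression"),
                           seed = 1L) {
  stopifnot(inherits(train_matrix, "model_matrix"))
  kind <- match.arg(kind)
  check_binary_outcome(train_matrix$y)
  if (anyNA(train_matrix$x)) {
    stop("baseline models need a mean-imputed matrix; refit the ",
         "preprocessor with impute_for_model = TRUE", call. = FALSE)
  }
  if (kind == "random_forest") {
    df <- as.data.frame(train_matrix$x)
    df$.outcome <- factor(train_matrix$y, levels = c(0, 1))
    fit <- ranger::ranger(
      dependent.variable.name = ".outcome", data = df,
      probability = TRUE, num.trees = 500, seed = seed, num.threads = 1
    )
  } else {
    df <- as.data.frame(train_matrix$x)
    df$.outcome <- train_matrix$y
    fit <- suppressWarnings(
      stats::glm(.outcome ~ ., data = df, family = stats::binomial())
    )
  }
  new_risk_model(kind, fit, train_matrix, list(), seed)
}

new_risk_model <- function(kind, fit, train_matrix, params, seed) {
  structure(
    list(kind = kind, fit = fit,
         feature_names = train_matrix$feature_names,
         n_train = nrow(train_matrix$x), params = params, seed = seed),
    class = "risk_model"
  )
}

check_binary_outcome <- function(y) {
  if (anyNA(y) || !all(y %in% c(0, 1))) {
    stop("outcome must be binary 0/1 with no missing values", call. = FALSE)
  }
  if (length(unique(y)) < 2L) {
    stop("training outcome contains a single class", call. = FALSE)
  }
  invisible(TRUE)
}

#' Predict the probability of nonsurvival
#'
#' @param model A `risk_model`.
#' @param x A `model_matrix` or a numeric matrix with the model's feature
#'   columns.
#' @return Numeric vector of P(nonsurvival | x) in \[0, 1\];
#'   P(survival) is its complement.
#' @export
predict_risk <- function(model, x) {
  UseMethod("predict_risk")
}

#' @export
predict_risk.risk_model <- function(model, x) {
  if (inherits(x, "model_matrix")) x <- x$x
  if (is.null(dim(x))) x <- matrix(x, nrow = 1,
                                   dimnames = list(NULL, model$feature_names))
  x <- x[, model$feature_names, drop = FALSE]
  p <- switch(
    model$kind,
    gbm = stats::predict(model$fit, x),
    random_forest = {
      xi <- x
      xi[is.na(xi)] <- 0
      stats::predict(model$fit, data = as.data.frame(xi),
                     num.threads = 1)$predictions[, "1"]
    },
    logistic_regression = {
      xi <- x
      xi[is.na(xi)] <- 0
      unname(stats::predict(model$fit, newdata = as.data.frame(xi),
                            type = "response"))
    },
    stop("unknown model kind: ", model$kind)
  )
  pmin(pmax(as.numeric(p), 0), 1)
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("risk_model (%s): %d features, n_train=%d, seed=%d\n",
              x$kind, length(x$feature_names), x$n_train, x$seed))
  invisible(x)
}

#' Severity-score baseline as a risk ordering
#'
#' Uses a conventional severity score column (APS III or SOFA) directly as
#' the risk ranking, min-max rescaled to \[0, 1\] within the given matrix so
#' it can enter Brier-style comparisons. A constant column rescales to 0.5
#' (AUC 0.5 by construction).
#'
#' @param matrix A `model_matrix`.
#' @param score_column "aps_iii" or "sofa".
#' @return Numeric vector in \[0, 1\], one value per patient.
#' @export
score_baseline <- function(matrix, score_column = c("aps_iii", "sofa")) {
  stopifnot(inherits(matrix, "model_matrix"))
  score_column <- match.arg(score_column)
  if (!score_column %in% matrix$feature_names) {
    stop("score column not present in matrix: ", score_column, call. = FALSE)
  }
  s <- matrix$x[, score_column]
  rng <- range(s, na.rm = TRUE)
  if (diff(rng) == 0) return(rep(0.5, length(s)))
  (s - rng[1]) / diff(rng)
}
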