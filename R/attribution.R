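#' Monte-Carlo Shapley attribution for one patient
#'
#' Permutation-sampling estimate of the Shapley values of the model's
#' probability output. For each sampled feature ordering, one background
#' row is drawn; features are switched from the background value to the
#' patient's value in order, and the change in model output at each switch
#' is the feature's marginal contribution for that sample. Contributions
#' are averaged over samples; phi_0 is the mean prediction over the whole
#' background set. Attribution is on the probability scale, matching the
#' "pushes the risk up / down" reading of the outputs.
#'
#' @param model A `risk_model`, or any function mapping a numeric matrix to
#'   a numeric vector of outputs.
#' @param x Feature vector for the patient (named, or ordered as the model
#'   expects).
#' @param background A numeric matrix (or `model_matrix`) of reference
#'   rows, e.g. 100 training rows.
#' @param n_samples Number of sampled permutations (default 200).
#' @param seed Integer seed; the estimate is deterministic given it.
#' @return An `attribution` object: per-feature `phi`, base value `phi0`,
#'   the model `prediction`, per-feature Monte-Carlo standard errors `se`,
#'   `n_samples` and `seed`.
#' @export
shapley_attribution <- function(model, x, background, n_samples = 200L,
                                seed = 1L) {
  if (n_samples < 1L) stop("n_samples must be >= 1", call. = FALSE)
  if (inherits(background, "model_matrix")) background <- background$x
  if (is.null(dim(background)) || nrow(background) < 1L) {
    stop("background must be a nonempty matrix", call. = FALSE)
  }
  f <- if (inherits(model, "risk_model")) {
    function(m) predict_risk(model, m)
  } else if (is.function(model)) {
    model
  } else {
    stop("model must be a risk_model or a function", call. = FALSE)
  }
  if (!is.null(colnames(background)) && !is.null(names(x)) &&
      all(colnames(background) %in% names(x))) {
    x <- x[colnames(background)]
  }
  x <- as.numeric(x)
  d <- ncol(background)
  stopifnot(length(x) == d)

  set.seed(seed)
  # one composite matrix: for sample s, rows are the background row with
  # the first 0, 1, ..., d features (in permuted order) switched to x
  comp <- matrix(0, nrow = n_samples * (d + 1L), ncol = d)
  perms <- matrix(0L, n_samples, d)
  for (s in seq_len(n_samples)) {
    perm <- sample.int(d)
    perms[s, ] <- perm
    b <- background[sample.int(nrow(background), 1L), ]
    block <- (s - 1L) * (d + 1L)
    cur <- b
    comp[block + 1L, ] <- cur
    for (step in seq_len(d)) {
      cur[perm[step]] <- x[perm[step]]
      comp[block + 1L + step, ] <- cur
    }
  }
  colnames(comp) <- colnames(background)
  fx <- f(comp)

  contrib <- matrix(0, n_samples, d)   # per-sample marginal contributions
  for (s in seq_len(n_samples)) {
    block <- (s - 1L) * (d + 1L)
    diffs <- diff(fx[block + seq_len(d + 1L)])
    contrib[s, perms[s, ]] <- diffs
  }
  phi <- colMeans(contrib)
  se <- apply(contrib, 2, stats::sd) / sqrt(n_samples)
  nms <- colnames(background) %||% sprintf("x%d", seq_len(d))
  names(phi) <- names(se) <- nms
  structure(
    list(phi = phi, phi0 = mean(f(background)),
         prediction = unname(as.numeric(
           f(matrix(x, nrow = 1,
                    dimnames = list(NULL, colnames(background))))
         )[1]),
         se = se, n_samples = as.integer(n_samples), seed = as.integer(seed)),
    class = "attribution"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.attribution <- function(x, ...) {
  top <- sort(abs(x$phi), decreasing = TRUE)
  cat(sprintf(
    "shapley attribution: prediction %.4f = base %.4f + sum(phi) %.4f (%d samples)\n",
    x$prediction, x$phi0, sum(x$phi), x$n_samples
  ))
  cat("top contributions:\n")
  print(round(x$phi[names(top)[seq_len(min(5, length(top)))]], 4))
  invisible(x)
}

#' Global feature importance from per-patient attributions
#'
#' Ranks features by the mean absolute Shapley value across patients, with
#' deterministic alphabetical tie-breaking, and returns the per-patient
#' (feature value, phi) pairs needed for beeswarm-style plots.
#'
#' @param attributions A list of `attribution` objects sharing one feature
#'   schema.
#' @param feature_values Optional matrix of the patients' feature values
#'   (rows aligned with `attributions`) to attach for plotting.
#' @return List with `ranking` (data frame: feature, mean_abs_phi, rank)
#'   and `phi` (patients-by-features matrix; plus `values` if supplied).
#' @export
global_importance <- function(attributions, feature_values = NULL) {
  if (!length(attributions)) stop("no attributions supplied", call. = FALSE)
  phi <- t(vapply(attributions, function(a) a$phi,
                  numeric(length(attributions[[1]]$phi))))
  colnames(phi) <- names(attributions[[1]]$phi)
  mean_abs <- colMeans(abs(phi))
  ord <- order(-mean_abs, colnames(phi))
  ranking <- data.frame(
    feature = colnames(phi)[ord],
    mean_abs_phi = unname(mean_abs[ord]),
    rank = seq_along(ord),
    stringsAsFactors = FALSE
  )
  out <- list(ranking = ranking, phi = phi)
  if (!is.null(feature_values)) out$values <- feature_values
  out
}

#' Export a per-patient attribution as a waterfall-style table
#'
#' @param attribution An `attribution`.
#' @param feature_values Optional named vector of the patient's feature
#'   values.
#' @param path Optional CSV path; when `NULL` the data frame is returned
#'   only.
#' @return Data frame (feature, value, phi) sorted by |phi| descending.
#' @export
attribution_table <- function(attribution, feature_values = NULL,
                              path = NULL) {
  df <- data.frame(
    feature = names(attribution$phi),
    value = if (is.null(feature_values)) NA_real_
            else as.numeric(feature_values[names(attribution$phi)]),
    phi = unname(attribution$phi),
    stringsAsFactors = FALSE
  )
  df <- df[order(-abs(df$phi), df$feature), ]
  rownames(df) <- NULL
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
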