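# Shared fixtures and independent oracles for the test suite.

small_config <- function(n = 400, seed = 1, missing_rate = 0.02,
                         exclusion_fraction = 0, ...) {
  cohort_config(n_patients = n, seed = seed,
                n_repeated_vitals = 3L, n_continuous = 4L, n_binary = 7L,
                exclusion_fraction = exclusion_fraction,
                missing_rate = missing_rate, ...)
}

# A clean model_matrix built directly from numbers (bypasses the cohort
# machinery) for unit tests of the model and conformal layers.
toy_matrix <- function(x, y) {
  if (is.null(colnames(x))) colnames(x) <- sprintf("f%02d", seq_len(ncol(x)))
  structure(
    list(x = x, feature_names = colnames(x), y = y,
         mask = is.na(x), patient_id = seq_len(nrow(x))),
    class = "model_matrix"
  )
}

# A separable two-feature binary problem.
separable_matrix <- function(n = 200, seed = 42) {
  set.seed(seed)
  y <- rep(c(0L, 1L), each = n / 2)
  x <- cbind(f1 = y * 4 + rnorm(n, sd = 0.1), f2 = rnorm(n))
  toy_matrix(x, y)
}

# Brute-force conformal p-value by direct counting (independent of the
# binary-search implementation).
brute_pvalue <- function(ref, score, smoothed = FALSE, tau = NULL) {
  n <- length(ref)
  if (smoothed) {
    (sum(ref > score) + tau * (sum(ref == score) + 1)) / (n + 1)
  } else {
    (sum(ref >= score) + 1) / (n + 1)
  }
}

make_calibrator <- function(scores0, scores1, mondrian = TRUE) {
  structure(
    list(scores = list("0" = sort(scores0), "1" = sort(scores1)),
         n0 = length(scores0), n1 = length(scores1), mondrian = mondrian),
    class = "mondrian_calibrator"
  )
}

# Exact Shapley values by full subset enumeration, with the coalition value
# v(S) = mean over all background rows of f(x_S combined with background).
exact_shapley <- function(f, x, background) {
  d <- length(x)
  stopifnot(d <= 12)
  v <- function(S) {
    comp <- background
    for (j in S) comp[, j] <- x[j]
    mean(f(comp))
  }
  phi <- numeric(d)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), d))
  for (j in seq_len(d)) {
    for (r in seq_len(nrow(subsets))) {
      inS <- which(unlist(subsets[r, ]))
      if (j %in% inS) next
      s <- length(inS)
      w <- factorial(s) * factorial(d - s - 1) / factorial(d)
      phi[j] <- phi[j] + w * (v(c(inS, j)) - v(inS))
    }
  }
  phi
}
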