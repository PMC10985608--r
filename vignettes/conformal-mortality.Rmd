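---
title: "Class-conditional conformal prediction for ICU sepsis mortality: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Class-conditional conformal prediction for ICU sepsis mortality: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sepsiscp)
```

# The model

`sepsiscp` predicts in-hospital mortality for ICU patients with sepsis and,
crucially, quantifies how much each individual prediction can be trusted.
The underlying scorer is a gradient-boosted tree ensemble returning
P̂(nonsurvival | x) from ~100 first-day features (demographics, infection
sites, comorbidities, severity scores, aggregated vitals and labs,
vasopressor use, urine output). On top of it sits an inductive conformal
predictor.

## Inductive conformal prediction

Split the development data into a *training* partition (fits the scorer and
every preprocessing statistic) and a disjoint *calibration* partition. The
nonconformity of an example for a hypothesised label is

$$\alpha(x, y) = 1 - \hat{P}(y \mid x),$$

so a perfectly conforming example scores 0. For a new patient and candidate
label $y$, the p-value is the corrected fraction of calibration examples at
least as nonconforming:

$$p_y = \frac{\#\{i : y_i = y,\ \alpha_i \ge \alpha(x,y)\} + 1}{n_y + 1},$$

and the region at significance $\varepsilon$ is
$\Gamma_\varepsilon = \{y : p_y > \varepsilon\}$ (strict inequality; a
p-value exactly equal to $\varepsilon$ excludes the label). Under
exchangeability of calibration and test examples,
$P(y_{\text{true}} \notin \Gamma_\varepsilon) \le \varepsilon$.

## Why Mondrian (class-conditional)?

With ~16.5% nonsurvivors, a marginal conformal predictor can meet its
overall error budget while spending nearly all of it on the minority class.
The Mondrian construction computes each label's p-value against calibration
examples *of that label only*, which makes the guarantee hold separately
within survivors and within nonsurvivors. It is the package default;
`calibrate_mondrian(..., mondrian = FALSE)` provides the pooled marginal
variant for ablation.

Regions are typed: **single** (one label — actionable), **multiple** (both
labels — the model cannot discriminate at this confidence, flag for
clinician review), **empty** (no label — the patient conforms to neither
class, i.e. looks unlike the calibration data). Raising the confidence
level trades errors for multiples; `cp_label_distribution()` reports the
significance level $\varepsilon^*$ that maximises the single-prediction
fraction (ties resolved toward the smallest $\varepsilon$).

## p-value conventions

Two conventions are deliberate and configurable:

* **Non-smoothed, +1-corrected p-values by default.** They are
  deterministic and conservatively valid at finite samples, and worked
  single-patient examples stay reproducible. The smoothed variant
  ($p = (\#\{\alpha_i > \alpha\} + \tau(\#\{\alpha_i = \alpha\}+1))/(n_y+1)$
  with seeded uniform $\tau$) achieves exact rather than super-uniform
  p-values and is available behind `smoothed = TRUE` with an explicit seed.
* **Ties counted with ≥** ("at least as extreme"), the conservative
  reading; the smoothed variant randomises over the tie mass instead.

# The synthetic cohort generator

Real analogues of these data are credentialed critical-care extracts that
cannot ship with a package. The generator reproduces the *statistical
structure* the analysis depends on — not any real database's marginals —
so that every stage has honest work to do:

* A single latent severity factor $z \sim N(0,1)$ per patient drives
  correlated vital/lab levels through per-feature loadings with alternating
  signs, binary comorbidity/treatment flags through logistic links,
  monotone integer severity scores (APS III, SOFA, inverted GCS), urine
  output (log-normal, decreasing in $z$) and length of stay.
* Vitals are emitted as 24-point per-hour series and labs as 2-point
  series, so the max/min/mean/SD and max/min aggregations operate on real
  repeated measures.
* The outcome follows a logistic model in $z$, vasopressor use, pulmonary
  infection and age, with the intercept solved by bisection so the expected
  prevalence equals the configured target (default 0.165) exactly; no
  closed form exists once binary covariates enter the linear predictor.
* Missingness is MCAR per schema variable by default (the data source
  being emulated does not state a mechanism); an option keyed to severity
  (MAR) exists but is off by default. BMI receives extra missingness so
  the kNN imputer is genuinely exercised.
* A configurable fraction of rows (default 5%) violates one inclusion
  criterion each — age < 18, stay < 24 h, > 30% missing — to exercise the
  exclusion filters.

Loadings and baselines depend only on the feature counts, never on the
cohort seed, so an internal and an external cohort share one generating
structure.

**What passing tests do and do not show.** The generator produces
exchangeable rows, a single dominant severity axis, Gaussian feature noise
and MCAR missingness. Real ICU extracts have multi-axis physiology,
informative missingness, measurement artefacts and site-specific coding
practices. Validity results here demonstrate that the conformal machinery
is correct under its assumptions; they do not certify any particular error
rate on real hospital data, where the guarantee holds only to the extent
that calibration and deployment populations are exchangeable.

## The external-site shift

`site_shift()` emulates interdatabase heterogeneity with three knobs:
per-feature mean offsets (in SD units), per-feature scale factors, and a
relative shrinkage of the outcome-model weights (plus an optional
prevalence override). The canonical external configuration used in the
examples — mean shift +0.3 SD, scale factor 0.75, weight shrinkage 0.25,
prevalence 0.17 — compresses the continuous marginals: an external case
mix whose measurements are less extreme is genuinely harder to separate,
so the model trained on the development site shows both a lower external
AUC and a higher fraction of multiple predictions at fixed confidence,
the qualitative external-validation pattern this pipeline is designed to
surface. The shrunk weights additionally decouple features from outcomes,
adding irreducible label noise.

# Preprocessing and leakage control

Every fitted statistic — one-hot category lists, per-column means/SDs,
mean-imputation values, the kNN reference table — is a pure function of the
training partition (`fit_preprocessor()`), and `transform_cohort()` applies
the state immutably to any cohort. Specific conventions:

* **Exclusions**: age ≥ 18, stay ≥ 24 h (a stay of exactly 24.0 h is kept;
  "within 24 hours" is read as strictly less; the boundary is a function
  argument), missing fraction ≤ 30% computed over the pre-aggregation
  schema with each variable counted once (a series counts as missing only
  when entirely missing). Excluded rows are attributed to the first
  matching rule in that order.
* **Aggregation**: sample SD (n − 1); the SD of a single measurement is
  missing, not zero — one observation carries no dispersion information.
* **BMI imputation**: k-nearest neighbours on standardised age plus
  sex/ethnicity one-hots, k = 5, Euclidean distance, mean of neighbour
  BMIs, reference restricted to training rows with observed BMI. The
  emulated protocol names the algorithm but not k, the metric, or the
  exact coordinates; all three are package decisions exposed as arguments.
* **Unseen categorical levels** at transform time map to an all-zero
  one-hot block — no refitting on validation data under any circumstance.
* **Two imputation paths**: the boosted model receives missing values
  as-is (native handling, `impute_for_model = FALSE`); random forest and
  logistic regression receive training-mean imputation. Constant or
  all-missing columns are dropped with a warning.

# Model fitting

The boosted model uses fixed, conventional hyperparameters (150 rounds,
learning rate 0.1, depth 4, minimum child weight 5, 80% row/column
subsampling, single-threaded for bit-reproducibility). The emulated
protocol tuned hyperparameters on the calibration set with a Bayesian
optimiser; reusing the calibration set for model selection weakens the
exchangeability assumption that underwrites the conformal guarantee, so by
default tuning (when requested) is a seeded random search over an inner
split of the *training* partition, and passing the calibration matrix via
`tune_matrix` restores the tune-on-calibration behaviour for comparison.
Labels are fixed as 0 = survival, 1 = nonsurvival throughout.

# Attribution

`shapley_attribution()` estimates Shapley values of the model's probability
output by permutation sampling: for each sampled feature ordering a random
background row is drawn, features are switched one at a time from the
background value to the patient's value, and the per-switch output changes
are averaged over samples. One predict call per patient evaluates all
composites, so tree-model overhead is paid once. The estimator is
model-agnostic and satisfies efficiency, null-feature and symmetry in
expectation; per-feature Monte-Carlo standard errors are returned so those
axioms can be checked at 3-SE tolerance. Attribution is on the probability
scale — "pushes the risk up/down" — rather than log-odds; the base value is
the mean prediction over the background set (default: 100 seeded training
rows). Exact subset-enumeration Shapley is exponential in features and is
used only as a test oracle at small dimension.

# Evaluation

* **AUC** by the midrank Mann-Whitney statistic (tie-safe, transform
  invariant); **Brier score** as mean squared probability error;
  **reliability curves** with 10 equal-width bins (bin count unstated in
  the emulated protocol; 10 is the field convention).
* **Bootstrap CIs**: stratified within outcome classes (every replicate
  keeps both classes and the class balance), percentile intervals, default
  B = 2000, seeded. Percentile rather than BCa: with n in the thousands
  and smooth statistics the difference is negligible and percentile is
  transparent.
* **Conformal curves** over an ε grid of 0 to 1 in steps of 0.01: observed
  error (true label outside the region; empty regions count as errors),
  and empty/single/multiple fractions. At ε = 0 every region is
  {survival, nonsurvival}; at ε = 1 every region is empty.
* **Region tables** at confidence 0.999/0.95/0.90/0.85 per class and
  overall, plus an error-rate-matched point-prediction comparison: the
  plain classifier's threshold is chosen on the evaluated rows so its
  error rate among true nonsurvivors equals the conformal single-error
  rate in nonsurvivors, making the comparison read at matched minority
  sensitivity. The threshold search runs on the evaluation partition
  itself, as that tabulation implies.

# Numerical and statistical choices

* **Intercept bisection** to ±1e-10 on the realised linear predictors;
  the empirical prevalence then deviates from target only by binomial
  noise.
* **p-value counting** uses binary search (`findInterval`) on the sorted
  calibration arrays; a brute-force counting oracle verifies exact
  agreement, including ties, in the tests.
* **Validity test tolerances.** Checking per-class error against ε from
  one simulation involves two Monte-Carlo sources: test-set sampling
  (SE $\sqrt{\varepsilon(1-\varepsilon)/n_{\text{test},y}}$) and the
  coverage fluctuation induced by the finite calibration class, which is
  Beta-distributed with SD approximately
  $\sqrt{\varepsilon(1-\varepsilon)/(n_{\text{cal},y}+2)}$ and dominates
  at calibration sizes in the low thousands. One-sided validity checks
  use three combined SEs pointwise. For the smoothed variant, deviations
  of the error curve from the diagonal are algebraically a two-sample CDF
  comparison between calibration and test scores, so the *joint* check
  over a grid uses the two-sample Kolmogorov-Smirnov band
  $1.36\sqrt{1/(n_{\text{cal},y}+2) + 1/n_{\text{test},y}}$ rather than a
  pointwise band, which would be guaranteed to produce false alarms
  somewhere on a fine grid.
* **Problem sizes.** Unit tests run cohorts of a few hundred to a few
  thousand patients with a reduced feature schema (3 vitals, 4 labs); the
  end-to-end validity simulation uses 8,000 training / 2,000 calibration /
  20,000 test patients at the full schema, sized so per-class error
  estimates resolve well below the tolerance bands while the whole suite
  remains quick on a single CPU.
* **Seed fan-out**: `stage_seed(master, stage)` derives per-stage 32-bit
  seeds as `(master * 7919 + 104729 * stage) mod (2^31 - 1)`, so any stage
  can be rerun in isolation.
* **Degenerate inputs**: single-class training or calibration partitions,
  empty calibration classes, all-missing features, constant score columns
  and schema mismatches all fail fast with named errors rather than
  propagating NaNs.

# Known limitations

* The synthetic schema approximates the category structure and count of a
  first-day ICU feature set, not the identities or marginals of any real
  extract; absolute AUC/Brier values on synthetic cohorts are properties
  of the generator, not of any hospital population.
* The conformal guarantee is marginal over calibration draws; conditional
  on one calibration set, per-class error fluctuates at the
  $1/\sqrt{n_{\text{cal},y}}$ scale, which is visible for the minority
  class at realistic calibration sizes.
* No conformal regression, cross-conformal or jackknife+ variants; no
  interaction Shapley values; no probability recalibration layer (the
  conformal layer supersedes it for the set-valued output).
* The deep-learning comparator from the emulated protocol is omitted: it
  plays no role in the validity analysis and its training cost is out of
  proportion to its contribution here.
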