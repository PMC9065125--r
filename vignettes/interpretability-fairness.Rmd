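---
title: "Auditing ICU mortality predictors: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing ICU mortality predictors: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`icufair` implements a complete evaluation workflow for in-hospital
mortality predictors trained on intensive-care time series: feature
attribution, remove-and-retrain (ROAR) scoring of attribution quality,
trustworthiness curves, AUC-based group-fairness auditing, treatment
disparity summaries, and statistics linking feature importance to fairness.
Because the clinical databases this kind of audit targets are
access-controlled, the package ships a synthetic cohort generator with
planted ground truth; every downstream stage is validated against what was
planted.

This vignette explains the models and procedures, the parameters that
matter, the numerical conventions, and the limits of what the synthetic
validation shows.

## The synthetic cohort generator

`generate_cohort()` simulates, per ICU stay, a long event table of hourly
clinical measurements, static demographics (age, ethnicity, gender, marital
status, insurance), admission and comorbidity flags, ventilation treatment
spans, and a binary in-hospital mortality label. Defaults mirror the shape
of a preprocessed intensive-care cohort: `t_hours = 24` hourly steps and
164 features split 122 temporal / 5 demographic / 4 admission /
33 comorbidity, with a ~7% mortality prevalence.

Design choices, fixed once:

* **Temporal process.** Each temporal feature follows a stationary Gaussian
  lag-1 autoregressive process (default mean 0, sd 1, autocorrelation 0.5).
  AR(1) is the simplest process with hourly correlation structure; nothing
  downstream depends on richer dynamics.
* **Labels.** Mortality is logistic:
  `logit P(death) = b0 + sum_j beta_j s_j(x) + offsets`, where each planted
  feature contributes through a declared 24-hour summary (mean, max or min)
  and demographic levels contribute additive offsets (defaults: +0.5 for
  age >= 78, -0.5 for age < 55, +0.3 for one ethnicity level, which makes
  group-dependent risk available to the fairness analyses). The intercept
  `b0` is calibrated by root finding so that the Monte-Carlo mean of the
  logistic over the simulated covariates equals the configured prevalence;
  the realised rate is then binomial around it.
* **Ground truth.** The planted coefficients define an oracle importance
  ranking (`oracle_importance()`, `planted_importance()`); ties break to
  the lower feature id so every ordering is deterministic.
* **Treatments.** Per ventilation category, adoption is Bernoulli and the
  summed span duration is exponential, optionally varying by a demographic
  level. The default invasive-ventilation configuration plants a 0.3
  adoption gap and an 18-hour mean-duration gap between two ethnicity
  levels, which the fairness module must recover within binomial/normal
  standard error.
* **Missingness** is completely at random (each event independently deleted
  with `missing_rate`, default 0.3 in the full pipeline demonstrations, 0
  where a test requires an exact round-trip). Informative missingness is a
  non-goal.
* **Timestamps.** By default temporal events sit exactly on hour marks, and
  one extra hour beyond the modelling window is emitted so coverage-based
  filtering keeps the stay; this makes the generator-to-matrix round trip
  exact, which the tests exploit. `event_jitter = TRUE` scatters events
  inside their hour to exercise binning.
* Demographic group probabilities are near-uniform placeholders (they are
  not calibrated to any particular hospital population); age is generated
  as continuous years and binned downstream.

What passing tests on this cohort do **not** show: robustness to real EHR
pathologies (unit errors, informative missingness, regime changes,
label leakage), or that any particular clinical conclusion transfers. The
generator validates the *machinery*, not the epidemiology.

## Preprocessing

The pipeline is cohort selection → event cleaning → coverage filtering →
hourly binning → imputation → tabular summarisation.

* `select_cohort()`: age >= 15 years, first known ICU stay, duration
  between 12 h and 10 days.
* `clean_events()`: unit conversion (user-supplied factors, applied before
  duplicate handling), duplicate (stay, feature, time) records collapsed —
  numeric to their mean, categorical to the first-appearing value — and
  range tokens `"lo-hi"` replaced by their midpoint. Unparsable numeric
  values are dropped with a counted warning. Cleaning is idempotent.
* `filter_stays()`: the anchor is the earliest record within 6 h prior to
  admission; stays must have records spanning 24 h to 10 days from the
  anchor. Events before the 6-hour window are ignored entirely (their fate
  is otherwise unspecified; ignoring them keeps the anchor rule local).
* `build_matrix()`: half-open hourly bins `[anchor + h, anchor + h + 1)`
  (half-open so boundary events are never double-counted), bin averaging,
  truncation to the first 24 h, static features broadcast across time.
  Categorical features are label-encoded over their sorted observed levels
  and the dictionaries travel with the matrix.
* `impute()`: forward fill along time, then backward fill; features
  entirely missing for a stay are filled with the per-feature training-set
  mean. Means are computed on the 60% training split only, after the split,
  so no test information leaks into imputation. Imputation is idempotent.
* `summarize_tabular()`: min/max/mean per temporal feature (plus sum for
  sum-flagged features such as an accumulating urinary output), static
  features pass through; with the default spec this gives
  122 × 3 + 1 + 5 + 4 + 33 = 409 columns. Columns are ordered by spec and
  summary kind, deterministically.

A 30-hour extraction with a trailing 6-hour trim (sometimes used to avoid
label leakage near death) is deliberately omitted.

## Models

All classifiers obey one contract: `fit()` (seeded), `predict_proba()`,
exact `input_gradient()` by backpropagation, and, for glassbox models,
`glassbox_importance()`. The reference architectures are deliberately
small — a logistic model, a one-hidden-layer tanh network, an Elman
recurrent network over `(T, F)` sequences, and an attention model over
per-feature time averages whose attention × |weight| (normalised to sum
to 1) is its built-in interpretation. They stand in for large sequence
models so ROAR's repeated retraining stays desk-scale; the architectures
themselves are not the contribution.

Training is full-batch Adam on cross-entropy with ridge decay (1e-2 on
standardised weights; output biases are not decayed), internal per-column
standardisation (gradients are chain-ruled back to the raw input scale, so
attribution methods see the raw-scale model), a base-rate-initialised
output bias, and best-validation-epoch checkpointing over a fixed budget
(default 200 epochs, lr 0.1). All randomness flows through a single seed;
refitting with the same data and seed is bit-reproducible. Sequence inputs
are flattened with time fastest within feature: column `(f - 1) * T + t`.

`binary_metrics()` computes AUROC as the midrank Mann-Whitney statistic
(ties count one half) and AUPRC as the precision-recall step integral over
distinct thresholds.

## Attribution methods

All interpreters work on the flattened input and return signed per-entry
scores; importance is the absolute value. Gradient methods (saliency,
integrated gradients, gradient SHAP, noise tunnel) require the gradient
capability and refuse models without it rather than substituting.
Numerical conventions:

* Integrated gradients use a left-Riemann quadrature with a configurable
  step count (default 50); completeness holds to `1e-2` at 200 steps on all
  reference models.
* The default baseline draws each coordinate from U[0, 1]; the squared
  discrete-derivative method (`arch_detect()`) fixes the all-zero baseline
  as its definition requires, and scores 0 whenever `|x_i| < 1e-12` (the
  quotient is otherwise undefined at the baseline).
* Shapley sampling averages marginal contributions over sampled feature
  permutations (default 25); it is unbiased and is tested against a full
  720-permutation enumeration at d = 6.
* Feature permutation shuffles each column once across the whole evaluation
  batch (the default batch is the full set) and reports the batch-mean
  absolute output change.
* Occlusion slides a `(time × feature)` window (default 1×1, equal to
  feature ablation) with stride 1; overlapping windows are averaged.
* Wherever ranks are formed from scores, ties resolve deterministically:
  per-sample global rankings break ties to the lower feature index;
  subgroup rank profiles use dense ranks so fully tied profiles rank 1.
* Every stochastic interpreter is a pure function of (model, inputs,
  configuration including seed).

## ROAR and trustworthiness

`run_ablation_curve()` evaluates an importance ranking by replacing, for a
grid of drop ratios, each sample's own top-ranked input entries (ties to
the lower index; at least one entry whenever the ratio is positive;
`k = round(ratio * d)`) with the feature's training-set mean, retraining
the model from scratch on the modified training set, and measuring AUPRC,
AUROC and the trustworthiness score on the modified test set. Retraining
seeds derive deterministically from (ranking label, ratio index, base
seed), so performance and trustworthiness readings at a ratio always come
from the same retrained model. The 0% ratio is included in the default
grid to anchor the trapezoid at the unablated model; curve areas are
trapezoidal and normalised by the ratio span, so a constant curve scores
its constant. Lower area = faster information loss = better ranking.

The trustworthiness score generalises mean true-class confidence: a sample
contributes `C^alpha` when the prediction is correct and `(1 - C)^beta`
when wrong, with `alpha = beta = 1` by default so the score is the mean
probability assigned to the true class. A constant predictor at prevalence
`p` scores `p^2 + (1 - p)^2` (0.8698 at p = 0.07), the analytic anchor for
the full-ablation point.

## Fairness and interaction analyses

`resolve_groups()` maps stays to protected-group levels, dropping unclear
labels ('None', 'Unknown', 'Unable to obtain'); age uses the fixed
left-closed bins <55 / 55–67 / 67–78 / >=78 years by default, with an
option to recompute quartile cut points from a training split (the fixed
printed bins are the default because they make results comparable across
datasets). `group_auc()` stratifies test predictions; single-class groups
are flagged undefined and excluded from the min / macro-average /
smallest-group summaries rather than imputed. The overall AUC is always
computed on the pooled set, never reconstructed from group AUCs.
`treatment_summary()` reports both a per-patient mean duration
(non-adopters contribute 0 h) and a per-adopter mean, since either
convention is defensible. Comorbidity-restricted audits are supported by
filtering stays before grouping.

Group feature importance `g_{i,A}` is the exact mean of per-sample
importance within each level; it satisfies the weighted-mean identity
(size-weighted group means reproduce the overall mean to 1e-12), and a
200-replicate permutation null (`disparity_permutation_null()`) calibrates
observed disparities. Importance-versus-min-AUC trends report Spearman
alongside Pearson because attribution scales differ across interpreters.
Top-k agreement uses Jaccard similarity with k = 50 by default
(configurable; the desk-scale demonstrations use k = 20 with 164 features).

## Problem sizes and expected behaviour

The packaged demonstrations and the acceptance script use cohorts of
500–2000 stays: a full-shape cohort (164 features, 30% missingness) for the
pipeline, model and fairness analyses, and a 20-temporal-feature cohort
with five planted coefficients of magnitude 2 for ROAR. At these sizes the
oracle ranking's ROAR area is clearly below a random ranking's, the
squared-discrete-derivative interpreter lands near the oracle, the planted
adoption gap is recovered within 3 standard errors, and the full-ablation
trust reading approaches the constant-predictor closed form. These sizes
were chosen as the smallest at which the planted signal is reliably
recoverable by a calibrated logistic fit; the generator's effect sizes are
not tuned to any particular test outcome.

## Known limitations

* Reference models are small and trained with a simple fixed-budget
  optimiser; they demonstrate the audit machinery rather than
  state-of-the-art prediction.
* Attribution methods that require layer-internal propagation rules
  (DeepLift-style backpropagation of reference activations) are out of
  scope by design.
* The generator's missingness is uninformative, its physiology is
  synthetic, and its demographic distributions are placeholders; real-data
  conclusions require real data.
* Treatment-disparity summaries are descriptive; no causal adjustment for
  confounding is attempted.
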