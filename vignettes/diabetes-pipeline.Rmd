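---
title: "Methods: the diabgan classification pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the diabgan classification pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(diabgan)
```

This vignette is the package's account of its methods: what each stage
computes, the assumptions behind it, the knobs that matter, and the choices
we made where the design was genuinely open.

## The data model

Everything operates on plain tibbles: numeric feature columns plus one
integer label column (`Outcome` by default). Missingness is ordinary `NA`;
`detect_missing()` is the only function that creates it, by recoding the
designated zero-coded columns. This keeps the whole pipeline composable with
dplyr and avoids a parallel mask structure — the mask *is* `is.na()`.

## Zero-as-missing and mean/median joint imputation

In the PIMA schema a recorded zero in Glucose, BloodPressure, SkinThickness,
Insulin or BMI is not a measurement; `detect_missing()` recodes those cells
and reports per-column counts. Pregnancies is deliberately excluded: zero
pregnancies is a real observation, so its zeros are counted when asked for
but never recoded or filled.

The fill rule is per column, computed from observed values only:

* sample skewness (adjusted Fisher–Pearson, the `type = 2` estimator) at or
  below `skew_threshold` → fill with the **mean**;
* above the threshold → fill with the **median**.

The joint mean/median idea is aimed at keeping the post-imputation
distribution close to normal: for a symmetric column the mean is the natural
center, while for a heavy-tailed column (Insulin, the pedigree function) the
mean is dragged by the tail and the median is the better location estimate.
The exact switching rule is this package's design choice — a skewness cutoff
with default 0.5, a conventional boundary between "approximately symmetric"
and "moderately skewed" — and it is a config knob (`skew_threshold` in
`run_config()`), not a claim about the one true rule. Imputation plans are
fitted on training data and applied to held-out data inside
cross-validation.

Applying a plan is idempotent: filled cells are no longer `NA`, so a second
application changes nothing.

## Outlier capping

`fit_cap_bounds()` computes per-column quartiles and the Tukey fences

```
IQR   = Q3 − Q1
upper = Q3 + 1.5 · IQR
lower = Q1 − 1.5 · IQR
```

and `apply_cap()` clamps each value into `[lower, upper]`. Q2 (the median)
is stored for reporting although the clamp does not use it. Quartiles use
linear interpolation between order statistics at position `(n − 1)·p`
(R's default type-7 rule); the convention is stated explicitly because the
fence values depend on it. Capping preserves sample size and is monotone and
idempotent per column. The blunt alternative — dropping out-of-fence rows —
is available as `remove_outliers()` for comparisons, but capping is the
default because row deletion shrinks an already small cohort and removes
genuine extreme patients along with noise. Inside cross-validation the
fences are fitted on the training fold only; this costs nothing and removes
a leakage path the protocol would otherwise have.

## Glucose relabeling

`relabel_glucose()` maps fasting glucose to three classes using the standard
diagnostic cutoffs: ≤ 99 mg/dL normal (code 0), 100–125 prediabetes
(code 1), > 125 diabetes (code 2). Both thresholds are arguments; the
boundaries are inclusive on the low side exactly as the diagnostic table
reads (99 is normal, 125 is prediabetes, 126 is diabetes). Relabeling reads
only the Glucose column, so it should run after imputation — a zero-coded
missing glucose would otherwise land in "normal".

## SMOTE, ENN and the hybrid

`smote_oversample()` creates minority samples by interpolation:
`x_new = x_i + u·(x_nn − x_i)` with `u ~ U[0, 1]` and `x_nn` drawn from the
`k_smote` nearest same-class neighbours. Every synthetic point is therefore
a convex combination of two originals, which the tests verify by solving
for `u` on each output row. Neighbour search runs on internally standardized
features — PIMA columns span three orders of magnitude, and unstandardized
Euclidean distance would be an Insulin ranking — while interpolation happens
on the original scale (the two commute, since standardization is affine).

`enn_filter()` removes a sample when a strict majority of its `k_enn`
nearest neighbours (excluding itself) carries a different label; ties keep
the sample (conservative deletion). It applies to all classes, majority
included. `smoteenn()` runs SMOTE first, then ENN on the combined data. In a
multiclass setting every non-majority class is oversampled toward the
majority count.

Where resampling happens relative to the cross-validation split is a real
protocol fork: rebalancing the whole dataset before folding lets synthetic
points built from test rows leak into training, and flatters every metric.
The default rebalances training folds only; `resample_before_split = TRUE`
reproduces the whole-dataset protocol, and the result object records which
one ran. We assert neither as "the" published protocol, because published
comparisons frequently do not say.

## The adversarial classifier

The discriminator is a shared leaky-rectifier trunk (slope 0.2, default
widths 128→64) with two heads:

* an **adversarial head**, one sigmoid unit `D(x) ∈ (0, 1)` scoring real vs
  generated;
* a **classification head**, a softmax `C(x)` over the class codes.

The generator maps latent Gaussian noise (default 64 dimensions) through
128→128 hidden layers to a feature vector, linear at the output, in
standardized feature space. The combined objective is

```
V(D, G, C) = E[log D(x)] + E[log(1 − D(G(z)))] + λ · L_C(C(x), y)
L_C        = −(1/N) Σᵢ Σₖ y_{ik} log p_{ik}
```

with `λ` (`lambda_c`, default 1) weighting the classification term and the
cross-entropy computed on real labeled samples only — generated samples
carry no class label and influence `C` only through the shared trunk. At
`λ = 0` the objective reduces exactly to the plain two-player GAN value,
which the tests assert numerically.

Two readings in the training step deserve a note, since the compact
objective is ambiguous about signs:

* the discriminator/classifier update *minimizes* the adversarial
  binary cross-entropy plus `λ` times the classification cross-entropy —
  i.e. the classification head is trained to reduce `L_C`, as any working
  classifier must be, while `combined_objective()` reports the value
  `adversarial + λ·L_C` as stated;
* the generator uses the **non-saturating** loss `−E[log D(G(z))]` rather
  than minimizing `E[log(1 − D(G(z)))]`. This is the standard remedy for
  vanishing early-training gradients and is a documented deviation from the
  minimax form.

The shared-trunk-plus-two-heads realization (rather than a single
(K+1)-way softmax) keeps `D` and `C` as separate maps, as the objective
treats them, while still forcing them to share representations — which is
where the semi-supervised benefit comes from.

Other numerical choices: Adam with β₁ = 0.5 (damps the oscillation between
the two players), β₂ = 0.999, learning rate 2e-4; He-style initialization;
probabilities clamped at ε = 1e-7 inside every log so a saturated head
yields a large finite loss, never infinity; a non-finite loss aborts with a
diagnostic rather than training onward from garbage. Features are
standardized to zero mean/unit variance with statistics from the training
data; the standardizer is stored and reused at prediction and when
de-standardizing generated samples. Prediction takes the arg-max of `C(x)`
with ties broken toward the lowest class code. All randomness — weights,
shuffling, latent draws — flows from `config$seed`, and two runs with the
same seed produce bit-identical training histories.

Epochs (default 300) and batch size (default 64) were fixed once for the
few-hundred-sample, eight-feature regime this package targets; on the
separable-Gaussian oracle fixture the defaults reach held-out accuracy ≥
0.95 with a wide margin, and the cross-validation harness uses fewer epochs
(120–200, stated per call) where the task is run many times per fold set.

## Correlation and logistic analysis

`pearson_matrix()` computes the sample Pearson coefficient (covariance over
the product of standard deviations) pairwise; zero-variance columns give
flagged `NA` entries, never a silent 0. `fit_logistic()` fits the binomial
model by iteratively reweighted least squares, with standard errors from the
inverse observed information, the Wald statistic `(β̂/se)²` against χ²₁,
`OR = exp(β̂)` and the 95% interval `exp(β̂ ± 1.96·se)`. Perfect separation
is flagged (`converged = FALSE`, `separation_suspected = TRUE`) instead of
crashing.

The default `event_level = 0` models the probability of the *negative*
outcome. That orientation matches the conventional presentation in which
risk features (pregnancies, glucose, BMI, pedigree) carry negative
coefficients and odds ratios below 1 — "each unit increase decreases the
probability of staying disease-free". A flag flips the orientation, which
exactly negates coefficients and inverts odds ratios (tested). P-values are
reported raw with 1% / 5% / 10% significance stars (strict inequalities);
no multiple-testing correction is applied, matching the analysis style this
reproduces.

## Evaluation

`stratified_folds()` deals each class's shuffled indices round-robin, so
per-class counts across folds differ by at most one — with only a few
hundred positives, unstratified folds can visibly distort per-fold
prevalence. Metrics: accuracy; precision/recall/F1 for the positive class in
binary tasks (positive = the higher class code, i.e. the diseased class) and
macro-averaged across classes otherwise; AUC by the rank statistic with ties
counting ½ (constant scores give exactly 0.5), macro one-vs-rest for three
or more classes. The averaging convention is recorded in the result's
protocol descriptor because published metric sets often leave it unstated.

`run_cv()` fits imputation, cap bounds and (by default) SMOTEENN inside each
training fold, trains the adversarial classifier, and scores the untouched
test fold; index bookkeeping asserts the partition. Per-fold seeds derive
deterministically from the master seed.

## The synthetic generator

`generate_pima_like()` emulates the structure that makes the real cohort
awkward: exact 500:268 class imbalance, class-conditional feature
distributions (normals for roughly symmetric measurements; lognormals for
Insulin and the pedigree function so the median imputation branch fires; a
bimodal age distribution in the healthy class), multiplicative outliers at a
1% rate, and zero-coded missingness injected at the real cohort's observed
per-column rates (374/768 for Insulin, 227/768 for SkinThickness, ...).
Zeros are injected after outliers so missingness detection sees realistic
mixtures. Negative draws are reflected to positive, since the measurements
are physically non-negative.

What it does **not** emulate: the real joint dependence structure between
features (columns are conditionally independent given the class), the exact
real marginals, and any measurement-error process. Passing tests on this
generator therefore demonstrate that the machinery is correct and behaves
sensibly under imbalance, skew, outliers and missingness — not that any
particular accuracy carries over to the real cohort. The one check that
targets the real data (row count, class split, per-column zero counts)
requires the public download and is reported as failing when the file is
absent.

`generate_separable_gaussians()` provides the oracle fixture for classifier
correctness: unit-variance Gaussian classes centred `separation` standard
deviations from the origin along distinct axes. At separation 8 the Bayes
error is negligible, so any correct classifier must score near 1 and a low
score indicates a defect rather than a hard problem.

## Problem sizes

The test suite trains the default-configuration classifier once on 480
samples of the Gaussian fixture, runs small cross-validations (120 samples,
3 folds, reduced epochs and widths), and checks confidence-interval coverage
over 500 replicates of 150 observations. The acceptance script uses the full
768-row synthetic cohort with 10 folds at 120 epochs per fold for both
tasks. These sizes were chosen as the smallest at which each property is
sharply testable.

## Known limitations

* The classifier is a dense-network method for small tabular data; no
  convolutional/recurrent variants, no GPU path.
* SMOTE/ENN use exact pairwise distances — fine for thousands of rows, not
  for millions.
* Logistic inference is unregularized maximum likelihood; under perfect
  separation it flags rather than penalizes.
* Published headline metrics for this kind of pipeline depend on the
  resampling placement and averaging conventions of the original
  experiments; where those are unstated, exact numeric reproduction is not
  claimable, and this package instead makes the protocol explicit and
  records it with every result.
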