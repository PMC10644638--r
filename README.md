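# diabgan

Diabetes classification from clinical tabular data with a semi-supervised
generative adversarial classifier, plus the full preprocessing, rebalancing
and evaluation pipeline around it.

## Who this is for

Analysts working with PIMA-schema clinical tables (Pregnancies, Glucose,
BloodPressure, SkinThickness, Insulin, BMI, DiabetesPedigreeFunction, Age,
Outcome) — or any small, imbalanced, low-quality tabular cohort — who need:

- **zero-as-missing handling**: physiologically impossible zeros in columns
  such as BMI or blood pressure are detected, counted and imputed with a
  skewness-guided mean/median rule;
- **outlier capping**: values are clamped at the Tukey fences
  `IQR = Q3 − Q1`, `upper = Q3 + 1.5·IQR`, `lower = Q1 − 1.5·IQR`, keeping
  every row;
- **glucose relabeling**: fasting-glucose cutoffs (≤ 99 normal, 100–125
  prediabetes, ≥ 126 diabetes, in mg/dL) turn the binary task into three
  classes;
- **SMOTEENN**: from-scratch SMOTE interpolation of the minority class
  followed by edited-nearest-neighbour cleaning of every class;
- **an adversarial classifier**: a GAN whose discriminator has a shared
  trunk with two heads — an adversarial head `D(x) ∈ (0,1)` and a softmax
  classification head `C(x)` — trained on the objective

  `V(D, G, C) = E[log D(x)] + E[log(1 − D(G(z)))] + λ·L_C(C(x), y)`,

  with `L_C = −(1/N) Σᵢ Σₖ y_{ik} log p_{ik}` the categorical
  cross-entropy on the real labeled samples. The generator's synthetic
  samples act as continuous data augmentation that sharpens the shared
  representation;
- **evaluation**: stratified k-fold cross-validation with accuracy,
  precision, recall, F1 and rank-statistic AUC, with all preprocessing and
  resampling fitted inside training folds by default (no leakage);
- **feature analysis**: logistic regression with Wald tests, odds ratios and
  95% confidence intervals, presented publication-style with significance
  stars.

A synthetic PIMA-like generator ships with the package so every stage is
testable without downloading anything.

## Worked example

```r
library(diabgan)

# a synthetic cohort shaped like the PIMA table: 500 controls, 268 cases,
# zero-coded missingness, heavy-tailed Insulin
cohort <- generate_pima_like(synthetic_spec(seed = 42))
zero_missing_counts(cohort)
#> # A tibble: 5 × 2
#>   feature       n_zero
#>   <chr>          <int>
#> 1 Glucose            4
#> 2 BloodPressure     31
#> 3 SkinThickness    243
#> 4 Insulin          375
#> 5 BMI                8

cfg <- run_config(cv_folds = 5, seed = 42, gan = dcsgan_config(epochs = 60))
res <- run_pipeline(cohort, cfg, task = "binary")
#> 5-fold cross-validation (resampling: training folds only, seed 42)
#>   statistic accuracy precision recall     f1    auc
#> 1 mean        0.779     0.652  0.791  0.714  0.880
#> 2 sd          0.0241    0.0390 0.0311 0.0271 0.0265
```

The mean row is the cross-validated performance of the adversarial
classifier on held-out folds: 77.9% accuracy against a 65.1% majority-class
floor, with AUC 0.88. The sd row shows fold-to-fold spread.

Feature analysis on the imputed data, modeling the probability of the
*negative* outcome (so protective directions read as odds ratios below 1):

```r
clean <- detect_missing(cohort) |> (\(d) apply_imputation(d, fit_imputation(d)))()
tidy(fit_logistic(clean, event_level = 0))
#>   term                     coefficient  p_value odds_ratio stars
#> 1 (Intercept)                  9.72    2.74e-36  16617.    ***
#> 2 Pregnancies                 -0.221   2.38e-11      0.802 ***
#> 3 Glucose                     -0.0319  7.16e-19      0.969 ***
#> ...
```

Each unit of Glucose multiplies the odds of being disease-free by 0.969 in
this synthetic cohort; stars mark 1% / 5% / 10% significance.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/diabgan.R simulate --out cohort.csv --seed 1
Rscript inst/cli/diabgan.R evaluate --data cohort.csv --folds 10 --seed 1 --out report.yaml
Rscript inst/cli/diabgan.R analyze --data cohort.csv --out logit.csv
```

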