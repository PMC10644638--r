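#' Count zero-coded missing values per designated feature
#'
#' @param data A data frame.
#' @param features Columns in which a literal 0 encodes a missing value.
#' @return A tibble with columns `feature` and `n_zero`.
#' @export
zero_missing_counts <- function(data, features = zero_missing_defaults()) {
  check_features(data, features)
  tibble::tibble(
    feature = features,
    n_zero = purrr::map_int(features, ~ sum(data[[.x]] == 0, na.rm = TRUE))
  )
}

#' Mark zero-coded values as missing
#'
#' In the PIMA schema a 0 in columns such as `Glucose` or `BMI` is not a
#' measurement but an absent one. This replaces those zeros with `NA` so
#' downstream stages treat them as missing, and records how many were found
#' per column in the `zero_counts` attribute (also available via
#' [zero_missing_counts()]). Non-designated columns are untouched.
#'
#' @inheritParams zero_missing_counts
#' @return The data with designated zeros set to `NA`; attribute
#'   `zero_counts` holds the per-feature counts.
#' @export
detect_missing <- function(data, features = zero_missing_defaults()) {
  counts <- zero_missing_counts(data, features)
  out <- data
  for (f in features) {
    out[[f]][!is.na(out[[f]]) & out[[f]] == 0] <- NA_real_
  }
  attr(out, "zero_counts") <- counts
  out
}

#' Sample skewness (adjusted Fisher-Pearson)
#'
#' @param x Numeric vector; `NA`s dropped.
#' @return The bias-adjusted sample skewness coefficient; 0 for constant or
#'   too-short input.
#' @export
sample_skewness <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3 || sd(x) == 0) return(0)
  e1071::skewness(x, type = 2)
}

#' Fit a mean/median joint imputation plan
#'
#' For every column containing at least one missing value, records a fill
#' value computed from the observed entries of that column: the mean when
#' the distribution is close to symmetric (|sample skewness| below
#' `skew_threshold`), the median otherwise. Filling skewed columns with the
#' median rather than the mean keeps the imputed distribution closer to
#' normal, which is the point of the joint strategy.
#'
#' @param data A data frame where missing values are `NA` (see
#'   [detect_missing()]).
#' @param skew_threshold Absolute skewness at or below which the mean is
#'   used; above it the median. Default 0.5.
#' @param features Columns eligible for imputation; defaults to every
#'   numeric column.
#' @param include_complete If `TRUE`, plan every listed feature even when it
#'   currently has no missing values. Used when the plan will be applied to
#'   other data (e.g. a held-out fold) that may carry missingness the
#'   fitting data does not.
#' @return A tibble of class `imputation_plan` with columns `feature`,
#'   `strategy` (`"mean"`/`"median"`), `fill_value`, `skewness`, `n_missing`.
#' @export
fit_imputation <- function(data, skew_threshold = 0.5, features = NULL,
                           include_complete = FALSE) {
  if (skew_threshold < 0) abort("skew_threshold must be >= 0")
  if (is.null(features)) {
    features <- names(data)[purrr::map_lgl(data, is.numeric)]
  }
  check_features(data, features)
  needs <- if (include_complete) features else
    features[purrr::map_lgl(features, ~ anyNA(data[[.x]]))]
  rows <- purrr::map(needs, function(f) {
    obs <- data[[f]][!is.na(data[[f]])]
    if (length(obs) == 0) {
      abort(paste0("feature '", f, "' is entirely missing; cannot impute"))
    }
    if (length(obs) < 2) {
      abort(paste0("feature '", f, "' has fewer than 2 observed values"))
    }
    sk <- sample_skewness(obs)
    strategy <- if (abs(sk) <= skew_threshold) "mean" else "median"
    tibble::tibble(
      feature = f,
      strategy = strategy,
      fill_value = if (strategy == "mean") mean(obs) else median(obs),
      skewness = sk,
      n_missing = sum(is.na(data[[f]]))
    )
  })
  plan <- dplyr::bind_rows(rows)
  if (nrow(plan) == 0) {
    plan <- tibble::tibble(feature = character(), strategy = character(),
                           fill_value = double(), skewness = double(),
                           n_missing = integer())
  }
  class(plan) <- c("imputation_plan", class(plan))
  plan
}

#' Apply an imputation plan
#'
#' Replaces every `NA` of each planned column with that column's fill value.
#' Observed cells are unchanged; applying the same plan twice is a no-op on
#' the second pass.
#'
#' @param data A data frame.
#' @param plan An [fit_imputation()] plan (fitted on data with the same
#'   column names, typically the training split).
#' @return The data with planned columns completed.
#' @export
apply_imputation <- function(data, plan) {
  check_features(data, plan$feature)
  out <- data
  for (i in seq_len(nrow(plan))) {
    f <- plan$feature[i]
    out[[f]][is.na(out[[f]])] <- plan$fill_value[i]
  }
  out
}

#' Fit interquartile-range cap bounds (Tukey fences)
#'
#' For each column computes the quartiles Q1, Q2, Q3 by linear interpolation
#' between order statistics (position (n-1)p), the interquartile range
#' IQR = Q3 - Q1, and the fences upper = Q3 + 1.5 IQR and
#' lower = Q1 - 1.5 IQR. Q2 (the median) is stored for reporting though the
#' clamp itself only uses the fences.
#'
#' @param data A data frame with no missing values in the chosen columns
#'   (impute first).
#' @param features Columns to fit; defaults to all numeric columns. Each
#'   needs at least 4 observations.
#' @return A tibble of class `cap_bounds` with columns `feature`, `q1`,
#'   `q2`, `q3`, `iqr`, `lower`, `upper`.
#' @examples
#' fit_cap_bounds(data.frame(x = c(1, 2, 3, 4, 100)))
#' @export
fit_cap_bounds <- function(data, features = NULL) {
  if (is.null(features)) {
    features <- names(data)[purrr::map_lgl(data, is.numeric)]
  }
  check_features(data, features)
  rows <- purrr::map(features, function(f) {
    v <- data[[f]]
    if (anyNA(v)) abort(paste0("feature '", f, "' has missing values; impute before capping"))
    if (length(v) < 4) abort(paste0("feature '", f, "' has fewer than 4 values"))
    q <- unname(quantile(v, c(0.25, 0.5, 0.75), type = 7))
    iqr <- q[3] - q[1]
    tibble::tibble(feature = f, q1 = q[1], q2 = q[2], q3 = q[3], iqr = iqr,
                   lower = q[1] - 1.5 * iqr, upper = q[3] + 1.5 * iqr)
  })
  bounds <- dplyr::bind_rows(rows)
  class(bounds) <- c("cap_bounds", class(bounds))
  bounds
}

#' Cap values at the Tukey fences
#'
#' Clamps each value of a bounded column into `[lower, upper]`:
#' `min(max(v, lower), upper)`. No rows are deleted, so unlike outright
#' outlier removal the sample size is preserved.
#'
#' @param data A data frame.
#' @param bounds A [fit_cap_bounds()] result (typically fitted on the
#'   training split only).
#' @return The data with bounded columns clamped.
#' @export
apply_cap <- function(data, bounds) {
  check_features(data, bounds$feature)
  out <- data
  for (i in seq_len(nrow(bounds))) {
    f <- bounds$feature[i]
    out[[f]] <- pmin(pmax(out[[f]], bounds$lower[i]), bounds$upper[i])
  }
  out
}

#' Drop rows containing out-of-fence values
#'
#' The blunt alternative to [apply_cap()]: removes every row where any
#' bounded column falls outside its Tukey fences. Kept for comparisons;
#' capping is the recommended default because it preserves sample size.
#'
#' @inheritParams apply_cap
#' @return The data with offending rows removed.
#' @export
remove_outliers <- function(data, bounds) {
  check_features(data, bounds$feature)
  keep <- rep(TRUE, nrow(data))
  for (i in seq_len(nrow(bounds))) {
    v <- data[[bounds$feature[i]]]
    keep <- keep & v >= bounds$lower[i] & v <= bounds$upper[i]
  }
  data[keep, , drop = FALSE]
}

#' Relabel samples into three classes by fasting glucose
#'
#' Replaces the label column using the fasting-plasma-glucose diagnostic
#' cutoffs: glucose at or below `normal_threshold` is `normal` (code 0),
#' above it and at or below `diabetes_threshold` is `prediabetes` (code 1),
#' and strictly above `diabetes_threshold` is `diabetes` (code 2). The
#' defaults 99 and 125 mg/dL match the standard diagnostic table, turning
#' the binary task into a three-class one.
#'
#' @param data A data frame with a `Glucose` column (impute it first so no
#'   zero-coded values leak into the thresholds).
#' @param label_column Name of the label column to (over)write.
#' @param normal_threshold Inclusive upper glucose bound for `normal`.
#' @param diabetes_threshold Inclusive upper glucose bound for
#'   `prediabetes`; values above it are `diabetes`.
#' @return The data with `label_column` replaced by codes 0/1/2; attribute
#'   `label_names` carries the code-to-name map.
#' @export
relabel_glucose <- function(data, label_column = "Outcome",
                            normal_threshold = 99, diabetes_threshold = 125) {
  if (!"Glucose" %in% names(data)) abort("feature 'Glucose' not found")
  if (normal_threshold >= diabetes_threshold) {
    abort("normal_threshold must be below diabetes_threshold")
  }
  g <- data$Glucose
  out <- data
  out[[label_column]] <- dplyr::case_when(
    g <= normal_threshold ~ 0L,
    g <= diabetes_threshold ~ 1L,
    TRUE ~ 2L
  )
  attr(out, "label_names") <- glucose_class_codes()
  out
}

check_features <- function(data, features) {
  missing <- setdiff(features, names(data))
  if (length(missing) > 0) {
    abort(paste0("unknown feature(s): ", paste(missing, collapse = ", ")))
  }
  invisible(TRUE)
}
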