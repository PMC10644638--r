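#' Specification of a synthetic PIMA-like dataset
#'
#' Describes a two-class clinical table with the PIMA schema: class counts
#' (default 500 non-diabetic vs 268 diabetic), class-conditional feature
#' distributions (normals for roughly symmetric measurements, lognormals for
#' the heavy-tailed Insulin and pedigree function, a two-component normal
#' mixture for Age), per-feature zero-coded missingness rates (defaults are
#' the observed PIMA zero fractions, e.g. 374/768 for Insulin), and a small
#' rate of multiplicative outliers.
#'
#' @param n_per_class Named vector of class counts, names are the class
#'   codes (default `c("0" = 500, "1" = 268)`).
#' @param features Named list of feature specs; each is a list with `dist`
#'   (`"normal"`, `"lognormal"` or `"mixture"`) and per-class parameter
#'   lists. See the default for the expected shape.
#' @param zero_missing_rate Named vector of probabilities that a cell in the
#'   feature is zeroed out (missing-coded).
#' @param outlier_rate Probability a cell is inflated into an outlier.
#' @param outlier_multiplier Multiplicative inflation factor (> 1).
#' @param seed Generation seed.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_class = c("0" = 500L, "1" = 268L),
                           features = NULL,
                           zero_missing_rate = c(
                             Glucose = 5 / 768, BloodPressure = 35 / 768,
                             SkinThickness = 227 / 768, Insulin = 374 / 768,
                             BMI = 11 / 768),
                           outlier_rate = 0.01, outlier_multiplier = 5,
                           seed = 1L) {
  if (any(n_per_class <= 0)) abort("class counts must be positive")
  if (any(zero_missing_rate < 0 | zero_missing_rate > 1)) {
    abort("zero_missing_rate values must lie in [0, 1]")
  }
  if (outlier_rate < 0 || outlier_rate > 1) abort("outlier_rate must lie in [0, 1]")
  if (outlier_multiplier <= 1) abort("outlier_multiplier must exceed 1")
  if (is.null(features)) features <- default_pima_features()
  structure(list(n_per_class = n_per_class, features = features,
                 zero_missing_rate = zero_missing_rate,
                 outlier_rate = outlier_rate,
                 outlier_multiplier = outlier_multiplier,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Class-conditional distributions chosen to echo the published PIMA
# summaries: diabetics run higher on every risk feature; Insulin and the
# pedigree function are right-skewed so the median branch of the imputer is
# exercised; Age is bimodal in the healthy class.
default_pima_features <- function() {
  norm2 <- function(m0, s0, m1, s1)
    list(dist = "normal", params = list("0" = c(mean = m0, sd = s0),
                                        "1" = c(mean = m1, sd = s1)))
  lnorm2 <- function(ml0, sl0, ml1, sl1)
    list(dist = "lognormal", params = list("0" = c(meanlog = ml0, sdlog = sl0),
                                           "1" = c(meanlog = ml1, sdlog = sl1)))
  list(
    Pregnancies = norm2(3.3, 3.0, 4.9, 3.7),
    Glucose = norm2(110, 24, 142, 30),
    BloodPressure = norm2(68, 17, 71, 20),
    SkinThickness = norm2(20, 14, 23, 17),
    Insulin = lnorm2(4.2, 0.8, 4.9, 0.9),
    BMI = norm2(30.3, 7.0, 35.1, 7.3),
    DiabetesPedigreeFunction = lnorm2(-0.95, 0.60, -0.75, 0.62),
    Age = list(dist = "mixture",
               params = list("0" = list(weights = c(0.7, 0.3),
                                        means = c(27, 45), sds = c(5, 10)),
                             "1" = list(weights = c(0.5, 0.5),
                                        means = c(30, 45), sds = c(6, 9))))
  )
}

draw_feature <- function(fs, cl, n) {
  p <- fs$params[[cl]]
  switch(fs$dist,
    normal = rnorm(n, p[["mean"]], p[["sd"]]),
    lognormal = rlnorm(n, p[["meanlog"]], p[["sdlog"]]),
    mixture = {
      comp <- sample.int(length(p$weights), n, replace = TRUE, prob = p$weights)
      rnorm(n, p$means[comp], p$sds[comp])
    },
    abort(paste0("unknown distribution: ", fs$dist))
  )
}

#' Generate a synthetic PIMA-like dataset
#'
#' Draws exact class counts from the class-conditional feature
#' distributions, reflects any negative draws back to positive (clinical
#' measurements are non-negative), inflates a random subset of cells by the
#' outlier multiplier, and finally zeroes out cells at the requested
#' missing-coding rates (zero injection happens after outlier injection so
#' missingness detection sees realistic mixtures). Pregnancies is rounded to
#' a non-negative integer count.
#'
#' @param spec A [synthetic_spec()].
#' @param label_column Name of the label column to write.
#' @return A tibble with the spec's feature columns plus integer labels.
#' @export
generate_pima_like <- function(spec = synthetic_spec(),
                               label_column = "Outcome") {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  classes <- names(spec$n_per_class)
  blocks <- purrr::map(classes, function(cl) {
    n <- spec$n_per_class[[cl]]
    cols <- purrr::map(spec$features, draw_feature, cl = cl, n = n)
    tibble::as_tibble(cols) |>
      dplyr::mutate(!!sym(label_column) := as.integer(cl))
  })
  out <- dplyr::bind_rows(blocks)

  feat_names <- names(spec$features)
  for (f in feat_names) {
    v <- abs(out[[f]])
    out_idx <- runif(length(v)) < spec$outlier_rate
    v[out_idx] <- v[out_idx] * spec$outlier_multiplier
    out[[f]] <- v
  }
  if ("Pregnancies" %in% feat_names) {
    out$Pregnancies <- pmax(0, round(out$Pregnancies))
  }
  for (f in intersect(names(spec$zero_missing_rate), feat_names)) {
    zero_idx <- runif(nrow(out)) < spec$zero_missing_rate[[f]]
    out[[f]][zero_idx] <- 0
  }
  out
}

#' Generate balanced, linearly separable Gaussian classes
#'
#' Test fixture: class `c` is an isotropic unit-variance Gaussian centred at
#' `separation` times the `c`-th coordinate unit vector. With large
#' separation any reasonable classifier approaches perfect accuracy, which
#' makes the fixture a sharp oracle for classifier correctness.
#'
#' @param n Total samples (divisible by `n_classes`).
#' @param p Feature dimension (at least `n_classes`).
#' @param separation Distance of each class centre from the origin, in
#'   within-class standard deviations.
#' @param n_classes Number of classes (codes 0..n_classes-1).
#' @param seed Generation seed.
#' @param label_column Name of the label column.
#' @return A tibble with features `X1..Xp` and integer labels.
#' @export
generate_separable_gaussians <- function(n = 600L, p = 8L, separation = 8,
                                         n_classes = 2L, seed = 1L,
                                         label_column = "Outcome") {
  if (n %% n_classes != 0) abort("n must be divisible by n_classes")
  if (p < n_classes) abort("p must be at least n_classes")
  if (separation < 0) abort("separation must be >= 0")
  set.seed(seed)
  per <- n %/% n_classes
  x <- matrix(rnorm(n * p), n, p)
  labels <- rep(seq_len(n_classes) - 1L, each = per)
  for (c in seq_len(n_classes)) {
    rows <- which(labels == c - 1L)
    x[rows, c] <- x[rows, c] + separation
  }
  colnames(x) <- paste0("X", seq_len(p))
  perm <- sample.int(n)
  out <- tibble::as_tibble(as.data.frame(x[perm, , drop = FALSE]))
  out[[label_column]] <- labels[perm]
  out
}

#' Write the generative truth sidecar
#'
#' Records every generative parameter of a synthetic spec as YAML next to
#' the data it produced, so a run is auditable and exactly repeatable.
#'
#' @param spec A [synthetic_spec()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_synthetic_spec <- function(spec, path) {
  stopifnot(inherits(spec, "synthetic_spec"))
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}
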