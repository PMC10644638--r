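#' Resampling configuration
#'
#' @param k_smote Number of minority nearest neighbours SMOTE interpolates
#'   toward (default 5; must be below the minority class size).
#' @param k_enn Number of neighbours in the edited-nearest-neighbour vote
#'   (default 3).
#' @param target_ratio Desired minority:majority ratio after SMOTE, in
#'   (0, 1]; 1 balances the classes.
#' @param seed Seed for the interpolation draws.
#' @return A list of class `resample_config`.
#' @export
resample_config <- function(k_smote = 5L, k_enn = 3L, target_ratio = 1.0,
                            seed = 1L) {
  if (k_smote < 1 || k_enn < 1) abort("k_smote and k_enn must be >= 1")
  if (target_ratio <= 0 || target_ratio > 1) abort("target_ratio must be in (0, 1]")
  structure(list(k_smote = as.integer(k_smote), k_enn = as.integer(k_enn),
                 target_ratio = target_ratio, seed = as.integer(seed)),
            class = "resample_config")
}

# Column-standardize a numeric matrix; zero-variance columns get scale 1 so
# they contribute nothing to distances without dividing by zero.
standardize_fit <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2, sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  list(center = center, scale = scale)
}

standardize_apply <- function(x, std) {
  sweep(sweep(x, 2, std$center, "-"), 2, std$scale, "/")
}

destandardize <- function(x, std) {
  sweep(sweep(x, 2, std$scale, "*"), 2, std$center, "+")
}

feature_matrix <- function(data, label_column) {
  feats <- setdiff(names(data), label_column)
  bad <- feats[!purrr::map_lgl(data[feats], is.numeric)]
  if (length(bad) > 0) abort(paste0("non-numeric feature(s): ", paste(bad, collapse = ", ")))
  as.matrix(data[feats])
}

# Squared Euclidean distances from each row of a to each row of b.
cross_dist2 <- function(a, b) {
  aa <- rowSums(a^2)
  bb <- rowSums(b^2)
  d2 <- outer(aa, bb, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

#' SMOTE oversampling
#'
#' Generates synthetic samples for every under-represented class by linear
#' interpolation: a synthetic point is `x_i + u * (x_nn - x_i)` with `u`
#' uniform on \[0, 1\] and `x_nn` one of the `k_smote` nearest same-class
#' neighbours of `x_i`. Neighbours are found in internally standardized
#' feature space (so no single wide-ranging column such as Insulin dominates
#' the metric) while the interpolation itself is on the original scale.
#' Original rows are preserved verbatim, synthetics are appended.
#'
#' @param data A data frame of numeric features plus a label column.
#' @param label_column Name of the label column.
#' @param config A [resample_config()].
#' @return The augmented tibble; attribute `n_synthetic` gives the number of
#'   appended rows per class.
#' @export
smote_oversample <- function(data, label_column = "Outcome",
                             config = resample_config()) {
  labels <- data[[label_column]]
  if (is.null(labels)) abort(paste0("label column '", label_column, "' not found"))
  classes <- sort(unique(labels))
  if (length(classes) < 2) abort("need at least 2 classes")
  counts <- table(factor(labels, levels = classes))
  n_major <- max(counts)
  x <- feature_matrix(data, label_column)
  std <- standardize_fit(x)
  z <- standardize_apply(x, std)

  set.seed(config$seed)
  synth <- list()
  n_synth <- integer(0)
  for (cl in classes) {
    n_cl <- counts[[as.character(cl)]]
    n_target <- round(config$target_ratio * n_major)
    n_new <- n_target - n_cl
    if (n_new <= 0) next
    if (n_cl <= config$k_smote) {
      abort(sprintf(
        "class %s has %d samples but k_smote = %d; lower k_smote below the minority class size",
        cl, n_cl, config$k_smote))
    }
    idx <- which(labels == cl)
    zc <- z[idx, , drop = FALSE]
    d2 <- cross_dist2(zc, zc)
    diag(d2) <- Inf
    ord <- apply(d2, 1, function(r) order(r)[seq_len(config$k_smote)])
    nn <- if (config$k_smote == 1) matrix(ord, ncol = 1) else t(ord)

    base <- rep_len(seq_len(n_cl), n_new)
    pick <- sample.int(config$k_smote, n_new, replace = TRUE)
    u <- runif(n_new)
    xi <- x[idx[base], , drop = FALSE]
    xn <- x[idx[nn[cbind(base, pick)]], , drop = FALSE]
    new_x <- xi + u * (xn - xi)
    synth[[as.character(cl)]] <- tibble::as_tibble(as.data.frame(new_x)) |>
      dplyr::mutate(!!sym(label_column) := cl)
    n_synth[as.character(cl)] <- n_new
  }
  out <- dplyr::bind_rows(c(list(tibble::as_tibble(data)), unname(synth)))
  attr(out, "n_synthetic") <- n_synth
  out
}

#' Edited-nearest-neighbour retained indices
#'
#' For every sample, takes the majority vote of the labels of its `k`
#' nearest neighbours (Euclidean, on internally standardized features,
#' excluding the sample itself). A sample is dropped only when a strict
#' majority of its neighbours carries a different label; ties keep the
#' sample. Applied to all classes.
#'
#' @inheritParams smote_oversample
#' @param k Number of voting neighbours.
#' @return Integer vector of retained row indices, in original order.
#' @export
enn_keep_indices <- function(data, label_column = "Outcome", k = 3L) {
  labels <- data[[label_column]]
  if (is.null(labels)) abort(paste0("label column '", label_column, "' not found"))
  n <- length(labels)
  if (n <= k + 1) abort("need more than k + 1 samples for the neighbour vote")
  x <- feature_matrix(data, label_column)
  z <- standardize_apply(x, standardize_fit(x))
  d2 <- cross_dist2(z, z)
  diag(d2) <- Inf
  keep <- vapply(seq_len(n), function(i) {
    nb <- order(d2[i, ])[seq_len(k)]
    votes <- table(labels[nb])
    top <- names(votes)[votes == max(votes)]
    length(top) > 1 || top == as.character(labels[i])
  }, logical(1))
  which(keep)
}

#' Edited-nearest-neighbour cleaning
#'
#' @inheritParams enn_keep_indices
#' @return The data restricted to rows retained by [enn_keep_indices()].
#' @export
enn_filter <- function(data, label_column = "Outcome", k = 3L) {
  idx <- enn_keep_indices(data, label_column, k)
  out <- tibble::as_tibble(data)[idx, , drop = FALSE]
  attr(out, "kept_indices") <- idx
  out
}

#' SMOTE followed by edited-nearest-neighbour cleaning (SMOTEENN)
#'
#' The hybrid rebalancer: SMOTE first brings the minority class up toward
#' the majority count, then ENN removes ambiguous samples of every class
#' from the combined data, sharpening the class boundary. Deterministic
#' given `config$seed`.
#'
#' @inheritParams smote_oversample
#' @return The resampled tibble; attributes `n_synthetic` and
#'   `class_counts` (before, after SMOTE, after ENN).
#' @export
smoteenn <- function(data, label_column = "Outcome", config = resample_config()) {
  count_by <- function(d) table(factor(d[[label_column]]))
  before <- count_by(data)
  over <- smote_oversample(data, label_column, config)
  after_smote <- count_by(over)
  out <- enn_filter(over, label_column, config$k_enn)
  attr(out, "n_synthetic") <- attr(over, "n_synthetic")
  attr(out, "class_counts") <- list(before = before, after_smote = after_smote,
                                    after_enn = count_by(out))
  out
}

#' Minority:majority class ratio
#'
#' @param labels Vector of class labels.
#' @return Smallest class count divided by largest.
#' @export
imbalance_ratio <- function(labels) {
  counts <- table(labels)
  min(counts) / max(counts)
}
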