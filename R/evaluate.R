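#' Stratified fold assignment
#'
#' Partitions sample indices into `k` disjoint test sets preserving class
#' proportions: within each class the indices are shuffled and dealt
#' round-robin, so per-class counts across folds differ by at most one.
#'
#' @param labels Vector of class labels.
#' @param k Number of folds (every class needs at least `k` members).
#' @param seed Shuffle seed.
#' @return List of `k` integer vectors of test indices.
#' @export
stratified_folds <- function(labels, k = 10L, seed = 1L) {
  if (k < 2) abort("k must be >= 2")
  counts <- table(labels)
  if (any(counts < k)) {
    abort(sprintf("class '%s' has %d members, fewer than k = %d folds",
                  names(counts)[which.min(counts)], min(counts), k))
  }
  set.seed(seed)
  folds <- vector("list", k)
  for (cl in names(counts)) {
    idx <- sample(which(as.character(labels) == cl))
    assign <- rep_len(seq_len(k), length(idx))
    for (f in seq_len(k)) folds[[f]] <- c(folds[[f]], idx[assign == f])
  }
  lapply(folds, sort)
}

# Rank-statistic AUC for one positive class: probability a positive scores
# above a uniformly drawn negative, ties counting 1/2 (mid-ranks).
auc_rank <- function(scores, positive) {
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics from predictions and scores
#'
#' Accuracy, precision, recall, F1 and AUC plus the confusion matrix. For a
#' binary task the positive class is the highest class code (the diseased
#' class under both the 0/1 and 0/1/2 codings); with three or more classes
#' precision/recall/F1 are macro-averaged and AUC is macro one-vs-rest.
#' AUC uses the rank statistic with ties contributing 1/2, so constant
#' scores give exactly 0.5.
#'
#' @param y_true True class codes.
#' @param y_pred Predicted class codes.
#' @param scores Matrix or data frame of class probabilities, one column per
#'   class in ascending code order (e.g. the `.prob_*` columns of
#'   [predict.dcsgan()]). Rows must sum to 1.
#' @return A one-row tibble with `accuracy`, `precision`, `recall`, `f1`,
#'   `auc` and a `confusion` list-column holding the (true x predicted)
#'   count matrix.
#' @export
compute_metrics <- function(y_true, y_pred, scores) {
  n <- length(y_true)
  if (n == 0) abort("empty input")
  if (length(y_pred) != n) abort("y_true and y_pred lengths differ")
  scores <- as.matrix(scores)
  if (nrow(scores) != n) abort("scores rows must match y_true")
  if (any(abs(rowSums(scores) - 1) > 1e-6)) abort("score rows must sum to 1")

  classes <- sort(unique(c(y_true, y_pred)))
  if (ncol(scores) < length(classes)) abort("scores need one column per class")
  ft <- factor(y_true, levels = classes)
  fp <- factor(y_pred, levels = classes)
  cm <- table(true = ft, predicted = fp)

  per_class <- purrr::map(seq_along(classes), function(j) {
    tp <- cm[j, j]
    prec <- if (sum(cm[, j]) == 0) 0 else tp / sum(cm[, j])
    rec <- if (sum(cm[j, ]) == 0) 0 else tp / sum(cm[j, ])
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    auc <- auc_rank(scores[, j], y_true == classes[j])
    tibble::tibble(precision = prec, recall = rec, f1 = f1, auc = auc)
  }) |> dplyr::bind_rows()

  if (length(classes) == 2) {
    pos <- which.max(classes)  # positive class = higher code (diseased)
    summary <- per_class[pos, ]
  } else {
    summary <- dplyr::summarise(per_class,
                                dplyr::across(dplyr::everything(),
                                              ~ mean(.x, na.rm = TRUE)))
  }

  tibble::tibble(
    accuracy = mean(y_true == y_pred),
    precision = summary$precision,
    recall = summary$recall,
    f1 = summary$f1,
    auc = summary$auc,
    confusion = list(unclass(cm))
  )
}

#' Cross-validated evaluation of the full pipeline
#'
#' Stratified k-fold cross-validation of the preprocessing + resampling +
#' adversarial-classifier pipeline. By default everything data-dependent is
#' fitted on the training fold only: zero-as-missing imputation and cap
#' bounds are learned on the training rows and applied to the held-out rows,
#' and SMOTEENN rebalances the training rows only, so no held-out
#' information leaks into the model. `resample_before_split = TRUE` in the
#' config instead rebalances the whole dataset before folding - the
#' optimistic protocol some published comparisons use - and is provided for
#' reproducing that setting, clearly recorded in the protocol descriptor.
#'
#' @param data A labeled data frame (zeros still allowed; imputation happens
#'   per fold).
#' @param label_column Name of the label column.
#' @param config A [run_config()].
#' @param resample Whether to apply SMOTEENN (default TRUE).
#' @return An object of class `cv_result` with per-fold metrics, aggregate
#'   mean/sd, and a protocol descriptor.
#' @export
run_cv <- function(data, label_column = "Outcome", config = run_config(),
                   resample = TRUE) {
  data <- tibble::as_tibble(data)
  if (is.null(data[[label_column]])) {
    abort(paste0("label column '", label_column, "' not found"))
  }
  zm <- intersect(config$zero_missing_features, names(data))

  if (resample && config$resample_before_split) {
    pre <- detect_missing(data, zm)
    pre <- apply_imputation(pre, fit_imputation(pre, config$skew_threshold))
    rs_cfg <- config$resample
    rs_cfg$seed <- derive_seed(config$seed, 1L)
    data <- smoteenn(pre, label_column, rs_cfg)
    zm <- character(0)  # already imputed
  }

  folds <- stratified_folds(data[[label_column]], config$cv_folds,
                            derive_seed(config$seed, 2L))
  cap_feats <- config$cap_features %||%
    setdiff(names(data)[purrr::map_lgl(data, is.numeric)], label_column)

  fold_rows <- purrr::imap(folds, function(test_idx, f) {
    stopifnot(length(intersect(test_idx, setdiff(seq_len(nrow(data)), test_idx))) == 0)
    train <- data[-test_idx, , drop = FALSE]
    test <- data[test_idx, , drop = FALSE]

    train <- detect_missing(train, zm)
    test <- detect_missing(test, zm)
    # plan every designated feature: the held-out fold can carry zero-coded
    # missingness in a column the training fold happens to observe completely
    plan <- fit_imputation(train, config$skew_threshold, features = zm,
                           include_complete = TRUE)
    train <- apply_imputation(train, plan)
    test <- apply_imputation(test, plan)

    if (nrow(train) >= 4) {  # fences need at least 4 order statistics
      bounds <- fit_cap_bounds(train, cap_feats)
      train <- apply_cap(train, bounds)
      test <- apply_cap(test, bounds)
    }

    if (resample && !config$resample_before_split) {
      rs_cfg <- config$resample
      rs_cfg$seed <- derive_seed(config$seed, 100L + f)
      train <- smoteenn(train, label_column, rs_cfg)
    }

    gan_cfg <- config$gan
    gan_cfg$seed <- derive_seed(config$seed, 200L + f)
    gan_cfg$n_classes <- length(unique(data[[label_column]]))
    model <- train_dcsgan(train, label_column, gan_cfg)

    preds <- predict(model, test)
    scores <- as.matrix(preds[grep("^\\.prob_", names(preds))])
    metrics <- compute_metrics(test[[label_column]], preds$.pred_class, scores)
    dplyr::bind_cols(tibble::tibble(fold = f, n_test = nrow(test)), metrics)
  })
  per_fold <- dplyr::bind_rows(fold_rows)

  metric_cols <- c("accuracy", "precision", "recall", "f1", "auc")
  summary <- dplyr::bind_rows(
    dplyr::summarise(per_fold, dplyr::across(dplyr::all_of(metric_cols),
                                             ~ mean(.x, na.rm = TRUE))) |>
      dplyr::mutate(statistic = "mean", .before = 1),
    dplyr::summarise(per_fold, dplyr::across(dplyr::all_of(metric_cols),
                                             ~ sd(.x, na.rm = TRUE))) |>
      dplyr::mutate(statistic = "sd", .before = 1)
  )

  structure(
    list(per_fold = per_fold, summary = summary,
         protocol = list(
           cv_folds = config$cv_folds,
           seed = config$seed,
           resample = resample,
           resample_placement = if (!resample) "none"
             else if (config$resample_before_split) "whole-dataset (leaky)"
             else "training folds only",
           metric_averaging = "macro (binary: positive = highest code)")),
    class = "cv_result"
  )
}

#' @describeIn run_cv `tidy()` returns the per-fold metric table.
#' @param x A `cv_result`.
#' @param ... Unused.
#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) x$per_fold

#' @describeIn run_cv `glance()` returns one row of aggregate means and sds.
#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  means <- x$summary[x$summary$statistic == "mean", -1]
  sds <- x$summary[x$summary$statistic == "sd", -1]
  names(sds) <- paste0(names(sds), "_sd")
  dplyr::bind_cols(means, sds,
                   tibble::tibble(folds = x$protocol$cv_folds,
                                  resample_placement = x$protocol$resample_placement))
}

#' @describeIn run_cv `autoplot()` draws per-fold metric distributions.
#' @param object A `cv_result`.
#' @method autoplot cv_result
#' @export
autoplot.cv_result <- function(object, ...) {
  long <- tidyr::pivot_longer(object$per_fold,
                              dplyr::all_of(c("accuracy", "precision",
                                              "recall", "f1", "auc")),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = NULL, title = "Cross-validated metrics") +
    ggplot2::theme_minimal()
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (resampling: %s, seed %d)\n",
              x$protocol$cv_folds, x$protocol$resample_placement,
              x$protocol$seed))
  print(x$summary)
  invisible(x)
}
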