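#' Read a tabular clinical dataset from CSV
#'
#' Reads a comma-separated file with a mandatory header row into a tibble.
#' Every non-label cell must parse as a number; the first offending cell is
#' reported by row and column. Column order is preserved.
#'
#' @param path Path to a CSV file (comma separator, dot decimal, UTF-8).
#' @param label_column Name of the label column, or `NULL` for an unlabeled
#'   dataset. When present it is coerced to integer class codes.
#' @return A tibble with numeric feature columns and, when requested, an
#'   integer label column.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' write.csv(data.frame(A = 1:3, B = c(0.5, 1, 2), Outcome = c(0, 1, 0)),
#'           tf, row.names = FALSE)
#' read_dataset(tf, label_column = "Outcome")
#' @export
read_dataset <- function(path, label_column = "Outcome") {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path))
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) == 0) abort("file has no columns")
  if (anyDuplicated(names(raw))) abort("duplicated column names in header")
  if (!is.null(label_column) && !label_column %in% names(raw)) {
    abort(paste0("label column '", label_column, "' not found in ", path))
  }
  parsed <- purrr::imap(raw, function(col, nm) {
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col) & trimws(col) != "")
    if (length(bad) > 0) {
      abort(sprintf("cell at row %d, column '%s' does not parse as a number: '%s'",
                    bad[1], nm, col[bad[1]]))
    }
    num
  })
  out <- tibble::as_tibble(parsed)
  if (!is.null(label_column)) {
    out[[label_column]] <- as.integer(out[[label_column]])
  }
  out
}

#' Write a tabular dataset to CSV
#'
#' Writes a header row plus one line per sample, using full precision so a
#' subsequent [read_dataset()] round-trips the values. A zero-row dataset
#' yields a header-only file.
#'
#' @param data A data frame of numeric columns.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  stopifnot(is.data.frame(data))
  readr::write_csv(tibble::as_tibble(data), path, progress = FALSE)
  invisible(path)
}

#' Assemble a run configuration
#'
#' Bundles every knob of the pipeline: which columns carry zero-coded
#' missingness, the skewness cutoff that switches imputation from mean to
#' median, which columns are capped, resampling and GAN settings, the fold
#' count, and a single master seed from which every stochastic stage derives
#' its own stream.
#'
#' @param zero_missing_features Columns whose zeros are treated as missing.
#' @param skew_threshold Absolute sample-skewness above which the median is
#'   used as the fill value (default 0.5).
#' @param cap_features Columns to cap at the Tukey fences, or `NULL` for all
#'   feature columns.
#' @param resample Settings from [resample_config()].
#' @param gan Settings from [dcsgan_config()].
#' @param cv_folds Number of cross-validation folds (>= 2).
#' @param resample_before_split If `TRUE`, apply SMOTEENN to the whole
#'   dataset before the folds are drawn (the leaky, publication-style
#'   protocol); default applies it inside training folds only.
#' @param seed Master seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(zero_missing_features = zero_missing_defaults(),
                       skew_threshold = 0.5,
                       cap_features = NULL,
                       resample = resample_config(),
                       gan = dcsgan_config(),
                       cv_folds = 10L,
                       resample_before_split = FALSE,
                       seed = 1L) {
  if (cv_folds < 2) abort("cv_folds must be >= 2")
  if (skew_threshold < 0) abort("skew_threshold must be >= 0")
  structure(
    list(
      zero_missing_features = zero_missing_features,
      skew_threshold = skew_threshold,
      cap_features = cap_features,
      resample = resample,
      gan = gan,
      cv_folds = as.integer(cv_folds),
      resample_before_split = isTRUE(resample_before_split),
      seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' Read or write a run configuration as YAML
#'
#' @param config A `run_config` object.
#' @param path File path.
#' @return `read_run_config()` returns a `run_config`; `write_run_config()`
#'   returns `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, c(
    raw[setdiff(names(raw), c("resample", "gan"))],
    list(resample = do.call(resample_config, raw$resample %||% list()),
         gan = do.call(dcsgan_config, raw$gan %||% list()))
  ))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Stage-tagged log line on stderr.
log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}
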