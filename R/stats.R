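#' Pearson correlation matrix
#'
#' Pairwise Pearson coefficients: covariance over the product of standard
#' deviations, computed with sample moments. Zero-variance columns yield
#' `NA` entries (including their diagonal) and a warning, never a silent 0.
#'
#' @param data A data frame; non-numeric columns are dropped with a message.
#' @return A symmetric p x p matrix of class `correlation_matrix` with unit
#'   diagonal wherever the column has positive variance.
#' @export
pearson_matrix <- function(data) {
  num <- names(data)[purrr::map_lgl(data, is.numeric)]
  dropped <- setdiff(names(data), num)
  if (length(dropped) > 0) {
    log_stage("stats", "dropping non-numeric column(s): ", paste(dropped, collapse = ", "))
  }
  x <- as.matrix(data[num])
  if (nrow(x) < 2) abort("need at least 2 rows to correlate")
  const <- apply(x, 2, sd) == 0
  m <- suppressWarnings(stats::cor(x))
  if (any(const)) {
    warn(paste0("zero-variance column(s) yield undefined correlations: ",
                paste(num[const], collapse = ", ")))
    m[const, ] <- NA_real_
    m[, const] <- NA_real_
  }
  structure(m, class = c("correlation_matrix", class(m)))
}

#' @method tidy correlation_matrix
#' @export
tidy.correlation_matrix <- function(x, ...) {
  m <- unclass(x)
  tibble::as_tibble(as.data.frame(as.table(m)), .name_repair = "minimal") |>
    setNames(c("feature_x", "feature_y", "correlation")) |>
    tibble::as_tibble()
}

#' @describeIn pearson_matrix heat-map of the correlation matrix.
#' @param object A `correlation_matrix`.
#' @param ... Unused.
#' @method autoplot correlation_matrix
#' @export
autoplot.correlation_matrix <- function(object, ...) {
  long <- tidy.correlation_matrix(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$feature_x, y = .data$feature_y,
                                     fill = .data$correlation)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, title = "Pearson correlation matrix") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Logistic regression with Wald inference
#'
#' Fits a binomial logistic model of the event `label == event_level` on all
#' feature columns by iteratively reweighted least squares, then derives the
#' Wald table: standard errors from the inverse observed information, Wald
#' statistic `(coefficient / se)^2` referred to a chi-square with 1 df,
#' odds ratio `exp(coefficient)` and its 95% interval
#' `exp(coefficient +/- 1.96 se)`.
#'
#' The default `event_level = 0` models the probability of the *negative*
#' outcome, so protective predictors (more pregnancies, higher glucose or
#' BMI) appear with negative coefficients and odds ratios below 1, matching
#' the usual epidemiological presentation of the PIMA analysis.
#'
#' @param data A data frame of numeric predictors plus a binary label column.
#' @param label_column Name of the label column (exactly two distinct values).
#' @param event_level Which label value is modeled as the event.
#' @return An object of class `logistic_fit`; see [tidy.logistic_fit()] for
#'   the per-predictor table.
#' @export
fit_logistic <- function(data, label_column = "Outcome", event_level = 0) {
  labels <- data[[label_column]]
  if (is.null(labels)) abort(paste0("label column '", label_column, "' not found"))
  vals <- sort(unique(labels))
  if (length(vals) != 2) abort("labels must take exactly two values")
  if (!event_level %in% vals) abort("event_level not among the observed labels")
  y <- as.integer(labels == event_level)
  x <- tibble::as_tibble(data)[setdiff(names(data), label_column)]

  fit_df <- dplyr::bind_cols(tibble::tibble(.event = y), x)
  warned_sep <- FALSE
  fit <- withCallingHandlers(
    glm(.event ~ ., data = fit_df, family = binomial(),
        control = list(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|algorithm did not converge",
                conditionMessage(w))) {
        warned_sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )

  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  wald <- (est / se)^2
  table <- tibble::tibble(
    term = names(est),
    coefficient = unname(est),
    std_error = unname(se),
    wald = unname(wald),
    p_value = unname(pchisq(wald, df = 1, lower.tail = FALSE)),
    odds_ratio = exp(unname(est)),
    ci_lower = exp(unname(est) - 1.96 * unname(se)),
    ci_upper = exp(unname(est) + 1.96 * unname(se))
  )
  table$term[table$term == "(Intercept)"] <- "(Intercept)"

  structure(
    list(table = table, event_level = event_level,
         converged = fit$converged && !warned_sep,
         separation_suspected = warned_sep,
         n_iterations = fit$iter, log_likelihood = as.numeric(stats::logLik(fit)),
         n = nrow(data), model = fit),
    class = "logistic_fit"
  )
}

#' Significance stars
#'
#' `"***"`, `"**"`, `"*"` for p strictly below 0.01, 0.05 and 0.10; empty
#' string otherwise (so p = 0.05 earns a single star and p = 0.175 none).
#'
#' @param p_value Numeric vector of p-values in \[0, 1\].
#' @return Character vector of markers.
#' @export
significance_stars <- function(p_value) {
  if (any(p_value < 0 | p_value > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  dplyr::case_when(
    p_value < 0.01 ~ "***",
    p_value < 0.05 ~ "**",
    p_value < 0.10 ~ "*",
    TRUE ~ ""
  )
}

#' @describeIn fit_logistic `tidy()` returns the Wald table (coefficient,
#'   standard error, Wald statistic, p-value with stars, odds ratio, 95% CI).
#' @param x A `logistic_fit`.
#' @param ... Unused.
#' @method tidy logistic_fit
#' @export
tidy.logistic_fit <- function(x, ...) {
  dplyr::mutate(x$table, stars = significance_stars(.data$p_value))
}

#' @describeIn fit_logistic `glance()` returns a one-row fit summary.
#' @method glance logistic_fit
#' @export
glance.logistic_fit <- function(x, ...) {
  tibble::tibble(n = x$n, event_level = x$event_level,
                 converged = x$converged,
                 separation_suspected = x$separation_suspected,
                 n_iterations = x$n_iterations,
                 log_likelihood = x$log_likelihood)
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic regression (event: label == %s, n = %d, %s)\n",
              format(x$event_level), x$n,
              if (x$converged) "converged" else "NOT converged"))
  print(tidy.logistic_fit(x))
  invisible(x)
}

#' Write a publication-style logistic regression report
#'
#' CSV with the coefficient, standard error, Wald statistic, p-value (with
#' significance stars), odds ratio and its 95% confidence bounds for each
#' predictor.
#'
#' @param fit A [fit_logistic()] result.
#' @param path Output CSV path.
#' @return The report tibble, invisibly.
#' @export
write_logistic_report <- function(fit, path) {
  report <- tidy.logistic_fit(fit)
  readr::write_csv(report, path, progress = FALSE)
  invisible(report)
}
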