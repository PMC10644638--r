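test_that("zero-coded missing detection counts and masks exactly the zeros", {
  d <- tibble::tibble(a = c(0, 1, 0, 2, 3), b = c(1, 2, 3, 4, 5), Outcome = 0:4)
  out <- detect_missing(d, "a")
  expect_equal(attr(out, "zero_counts")$n_zero, 2L)
  expect_equal(which(is.na(out$a)), c(1L, 3L))
  expect_identical(out$b, d$b)  # non-designated column untouched

  none <- detect_missing(tibble::tibble(a = c(1, 2)), "a")
  expect_equal(attr(none, "zero_counts")$n_zero, 0L)
  expect_false(anyNA(none$a))
  expect_error(detect_missing(d, "nope"), "unknown feature")
})

test_that("imputation strategy follows the skewness rule", {
  # symmetric observed values -> mean
  d <- tibble::tibble(x = c(1, 2, 3, NA))
  plan <- fit_imputation(d, skew_threshold = 0.5)
  expect_equal(plan$strategy, "mean")
  expect_equal(plan$fill_value, 2)

  # heavy right tail: adjusted Fisher-Pearson skewness oracle says > 0.5
  obs <- c(1, 1, 1, 1, 100)
  n <- length(obs)
  m2 <- mean((obs - mean(obs))^2)
  m3 <- mean((obs - mean(obs))^3)
  g1 <- m3 / m2^1.5
  oracle_skew <- g1 * sqrt(n * (n - 1)) / (n - 2)
  expect_gt(oracle_skew, 0.5)
  d2 <- tibble::tibble(x = c(obs, NA))
  plan2 <- fit_imputation(d2, skew_threshold = 0.5)
  expect_equal(plan2$skewness, oracle_skew, tolerance = 1e-12)
  expect_equal(plan2$strategy, "median")
  expect_equal(plan2$fill_value, 1)

  # feature without missing values gets no plan entry...
  d3 <- tibble::tibble(full = c(1, 2, 3), holed = c(NA, 1, 2))
  expect_identical(fit_imputation(d3)$feature, "holed")
  # ...unless the plan must also cover other data (held-out folds) that may
  # be missing where the fitting data is complete
  plan_all <- fit_imputation(d3, include_complete = TRUE)
  expect_setequal(plan_all$feature, c("full", "holed"))
  other <- tibble::tibble(full = c(NA, 5), holed = c(1, 2))
  expect_false(anyNA(apply_imputation(other, plan_all)))
  expect_error(fit_imputation(tibble::tibble(x = c(NA_real_, NA_real_))),
               "entirely missing")
})

test_that("applying an imputation plan fills masked cells and is idempotent", {
  d <- detect_missing(tibble::tibble(x = c(0, 4, 6)), "x")
  plan <- fit_imputation(d)
  filled <- apply_imputation(d, plan)
  expect_equal(filled$x, c(5, 4, 6))
  expect_equal(apply_imputation(filled, plan), filled)

  # on synthetic data: designated columns end up zero-free
  syn <- small_pima(150, 80, seed = 11)
  dm <- detect_missing(syn)
  done <- apply_imputation(dm, fit_imputation(dm))
  expect_equal(sum(zero_missing_counts(done)$n_zero), 0L)
  expect_false(anyNA(done))
})

test_that("cap bounds follow the Tukey fence formulas", {
  b <- fit_cap_bounds(data.frame(x = c(1, 2, 3, 4, 100)))
  expect_equal(b$q1, 2); expect_equal(b$q3, 4); expect_equal(b$iqr, 2)
  expect_equal(b$upper, 7); expect_equal(b$lower, -1)

  const <- fit_cap_bounds(data.frame(x = c(5, 5, 5, 5)))
  expect_equal(const$iqr, 0)
  expect_equal(const$upper, 5); expect_equal(const$lower, 5)

  # quartiles 0 and 1 give fences 2.5 and -1.5
  unitq <- fit_cap_bounds(data.frame(x = c(0, 0, 0, 1, 1, 1)))
  expect_equal(unitq$q1, 0); expect_equal(unitq$q3, 1)
  expect_equal(unitq$upper, 2.5); expect_equal(unitq$lower, -1.5)

  expect_error(fit_cap_bounds(data.frame(x = c(1, 2, 3))), "fewer than 4")
  expect_error(fit_cap_bounds(data.frame(x = c(1, NA, 3, 4))), "missing")
})

test_that("capping clamps into the fences, keeps rows, and is idempotent", {
  d <- tibble::tibble(x = c(1, 2, 3, 4, 100, -10))
  b <- fit_cap_bounds(tibble::tibble(x = c(1, 2, 3, 4, 100)))
  capped <- apply_cap(d, b)
  expect_equal(nrow(capped), nrow(d))
  expect_equal(capped$x, c(1, 2, 3, 4, 7, -1))
  expect_true(all(capped$x >= b$lower & capped$x <= b$upper))
  expect_equal(apply_cap(capped, b), capped)

  # order preservation (monotone map)
  set.seed(1)
  v <- tibble::tibble(x = rnorm(50, sd = 10))
  cv <- apply_cap(v, fit_cap_bounds(v))
  expect_true(all(diff(cv$x[order(v$x)]) >= 0))

  # in-range data is untouched
  inr <- tibble::tibble(x = c(2, 3, 3.5, 4))
  expect_equal(apply_cap(inr, b), inr)

  # removal alternative actually drops rows
  expect_equal(nrow(remove_outliers(d, b)), 4)
})

test_that("glucose relabeling uses the diagnostic boundaries", {
  d <- tibble::tibble(Glucose = c(80, 99, 100, 110, 125, 126, 130),
                      Other = 1:7, Outcome = rep(0L, 7))
  r <- relabel_glucose(d)
  expect_equal(r$Outcome, c(0L, 0L, 1L, 1L, 1L, 2L, 2L))
  expect_equal(attr(r, "label_names"), glucose_class_codes())

  # labels depend only on Glucose
  d2 <- d
  d2$Other <- rev(d2$Other)
  expect_equal(relabel_glucose(d2)$Outcome, r$Outcome)
  expect_error(relabel_glucose(tibble::tibble(x = 1)), "Glucose")
  expect_error(relabel_glucose(d, normal_threshold = 130, diabetes_threshold = 125),
               "below")
})
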