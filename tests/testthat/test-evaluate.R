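test_that("stratified folds partition the data and balance classes", {
  labels <- rep(c(0, 1), each = 50)
  folds <- stratified_folds(labels, k = 10, seed = 3)
  expect_length(folds, 10)
  for (f in folds) {
    expect_equal(sum(labels[f] == 0), 5)
    expect_equal(sum(labels[f] == 1), 5)
  }

  # partition property on ragged random labels
  set.seed(12)
  lab2 <- sample(0:2, 101, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  f2 <- stratified_folds(lab2, k = 4, seed = 9)
  all_idx <- sort(unlist(f2))
  expect_equal(all_idx, seq_along(lab2))              # union = everything
  expect_equal(anyDuplicated(unlist(f2)), 0L)         # pairwise disjoint
  for (cl in 0:2) {                                   # per-class counts +/- 1
    per <- vapply(f2, function(f) sum(lab2[f] == cl), integer(1))
    expect_lte(diff(range(per)), 1)
  }

  expect_identical(stratified_folds(lab2, 4, seed = 9), f2)
  expect_error(stratified_folds(c(0, 0, 1), k = 2), "fewer than")
})

test_that("metrics agree with hand evaluation of the confusion matrix", {
  # TP = 8, FP = 2, FN = 1, TN = 9 with positive class 1
  y_true <- c(rep(1, 8), rep(0, 2), rep(1, 1), rep(0, 9))
  y_pred <- c(rep(1, 8), rep(1, 2), rep(0, 1), rep(0, 9))
  scores <- cbind(1 - 0.1 - 0.8 * (y_pred == 1), 0.1 + 0.8 * (y_pred == 1))
  m <- compute_metrics(y_true, y_pred, scores)
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$precision, 0.8)
  expect_equal(m$recall, 8 / 9)
  expect_equal(m$f1, 2 * 0.8 * (8 / 9) / (0.8 + 8 / 9), tolerance = 1e-12)
  cm <- m$confusion[[1]]
  expect_equal(sum(cm), 20)
  expect_equal(cm["1", "1"], 8); expect_equal(cm["0", "1"], 2)

  # perfect prediction: all metrics 1
  perf <- compute_metrics(c(0, 1, 1), c(0, 1, 1),
                          cbind(c(1, 0, 0), c(0, 1, 1)))
  expect_equal(unlist(perf[c("accuracy", "precision", "recall", "f1", "auc")]),
               rep(1, 5), ignore_attr = TRUE)

  # constant scores: rank AUC is exactly 1/2
  tie <- compute_metrics(c(0, 1, 0, 1), c(0, 0, 0, 0),
                         matrix(0.5, 4, 2))
  expect_equal(tie$auc, 0.5)
  expect_error(compute_metrics(integer(0), integer(0), matrix(0, 0, 2)), "empty")
})

test_that("rank AUC equals the pairwise oracle and pROC on random inputs", {
  set.seed(8)
  for (rep in 1:5) {
    n <- 30
    y <- sample(0:1, n, replace = TRUE)
    if (length(unique(y)) < 2) next
    s1 <- round(runif(n), 1)  # coarse grid forces ties
    scores <- cbind(1 - s1, s1)
    m <- compute_metrics(y, as.integer(s1 > 0.5), scores)
    expect_equal(m$auc, auc_pair_oracle(s1, y == 1), tolerance = 1e-12)
    if (requireNamespace("pROC", quietly = TRUE)) {
      ref <- as.numeric(pROC::auc(pROC::roc(y, s1, quiet = TRUE,
                                            direction = "<", levels = c(0, 1))))
      expect_equal(m$auc, ref, tolerance = 1e-12)
    }
  }
})

test_that("macro averaging over three classes matches per-class hand computation", {
  y_true <- c(0, 0, 1, 1, 2, 2)
  y_pred <- c(0, 1, 1, 1, 2, 0)
  scores <- matrix(1 / 3, 6, 3)
  scores[cbind(1:6, y_pred + 1)] <- 0.5
  scores <- scores / rowSums(scores)
  m <- compute_metrics(y_true, y_pred, scores)
  # per-class precision: 1/2, 2/3, 1; recall: 1/2, 1, 1/2
  expect_equal(m$precision, mean(c(1 / 2, 2 / 3, 1)))
  expect_equal(m$recall, mean(c(1 / 2, 1, 1 / 2)))
})

test_that("cross-validation holds out every row exactly once and is recorded", {
  d <- generate_separable_gaussians(n = 120, p = 4, separation = 8, seed = 44)
  cfg <- run_config(cv_folds = 3, seed = 5,
                    zero_missing_features = character(0),
                    resample = resample_config(k_smote = 3, k_enn = 3),
                    gan = dcsgan_config(latent_dim = 8, gen_hidden = 16,
                                        disc_hidden = c(16, 8), epochs = 200,
                                        batch_size = 16))
  res <- run_cv(d, config = cfg)
  expect_equal(sum(res$per_fold$n_test), 120)
  expect_gte(glance(res)$accuracy, 0.95)  # separable classes
  expect_equal(res$protocol$seed, 5L)
  expect_equal(res$protocol$resample_placement, "training folds only")
  expect_true(all(res$per_fold$accuracy >= 0 & res$per_fold$accuracy <= 1))

  # minimal case: 2 folds on 4 balanced samples runs and partitions
  tiny <- tibble::tibble(x = c(0, 0.1, 10, 10.1), y = c(0, 0.1, 10, 10.1),
                         Outcome = c(0L, 0L, 1L, 1L))
  tiny_cfg <- run_config(cv_folds = 2, seed = 1,
                         zero_missing_features = character(0),
                         gan = dcsgan_config(latent_dim = 4, gen_hidden = 8,
                                             disc_hidden = 8, epochs = 2,
                                             batch_size = 2))
  tiny_res <- run_cv(tiny, config = tiny_cfg, resample = FALSE)
  expect_equal(sum(tiny_res$per_fold$n_test), 4)

  # whole-dataset resampling is recorded as the leaky protocol
  leaky_cfg <- cfg
  leaky_cfg$resample_before_split <- TRUE
  leaky <- run_cv(d, config = leaky_cfg)
  expect_match(leaky$protocol$resample_placement, "leaky")
})
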