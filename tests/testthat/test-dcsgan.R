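test_that("classification cross-entropy matches an independent log-loss oracle", {
  expect_equal(classifier_loss(matrix(c(1, 0), 1), 0L), 0)
  expect_equal(classifier_loss(matrix(c(0.5, 0.5), 1), 0L), log(2),
               tolerance = 1e-10)

  # averaging: N identical samples give the N = 1 loss
  p <- matrix(rep(c(0.3, 0.7), each = 6), ncol = 2)
  expect_equal(classifier_loss(p, rep(1L, 6)),
               classifier_loss(matrix(c(0.3, 0.7), 1), 1L))

  set.seed(42)
  for (rep in 1:5) {
    k <- sample(2:4, 1)
    n <- sample(3:20, 1)
    raw <- matrix(runif(n * k, 0.05, 1), n, k)
    probs <- raw / rowSums(raw)
    labels <- sample(0:(k - 1), n, replace = TRUE)
    expect_equal(classifier_loss(probs, labels), logloss_oracle(probs, labels),
                 tolerance = 1e-10)
  }

  # zero probability at the true class is clamped, never infinite
  expect_true(is.finite(classifier_loss(matrix(c(0, 1), 1), 0L)))
  expect_error(classifier_loss(matrix(c(0.5, 0.4), 1), 0L), "sum to 1")
  expect_error(classifier_loss(matrix(c(0.5, 0.5), 1), 2L), "out of range")
})

test_that("adversarial value matches hand evaluation and its symmetries", {
  expect_equal(adversarial_value(0.5, 0.5), 2 * log(0.5), tolerance = 1e-12)
  # perfect discriminator: value approaches 0 from below
  v <- adversarial_value(1 - 1e-9, 1e-9)
  expect_lt(v, 0); expect_gt(v, -1e-8)
  # permutation invariance within each vector
  set.seed(7)
  dr <- runif(10, 0.01, 0.99); df <- runif(10, 0.01, 0.99)
  expect_equal(adversarial_value(dr, df),
               adversarial_value(sample(dr), sample(df)))
  expect_error(adversarial_value(c(0.5, 1), 0.5), "strictly in")
})

test_that("combined objective is linear in lambda and reduces to the GAN value at 0", {
  set.seed(11)
  dr <- runif(8, 0.05, 0.95); df <- runif(8, 0.05, 0.95)
  raw <- matrix(runif(16, 0.05, 1), 8, 2); probs <- raw / rowSums(raw)
  labels <- sample(0:1, 8, replace = TRUE)

  at0 <- combined_objective(dr, df, probs, labels, 0)
  expect_equal(at0$value_v, adversarial_value(dr, df), tolerance = 1e-12)

  at1 <- combined_objective(dr, df, probs, labels, 1)
  at2 <- combined_objective(dr, df, probs, labels, 2)
  adv <- adversarial_value(dr, df)
  expect_equal(at2$value_v - adv, 2 * (at1$value_v - adv), tolerance = 1e-12)

  # joint optimum: perfect discriminator and classifier
  perfect <- combined_objective(1 - 1e-12, 1e-12,
                                matrix(c(1, 0), 1), 0L, 1)
  expect_equal(perfect$value_v, 0, tolerance = 1e-9)
})

test_that("a small adversarial step does not decrease the adversarial value", {
  set.seed(123)
  p <- 4; B <- 16
  disc <- diabgan:::disc_init(p, c(16, 8), 2)
  x_real <- matrix(rnorm(B * p, mean = 1), B, p)
  x_fake <- matrix(rnorm(B * p, mean = -1), B, p)
  y <- matrix(0, B, 2); y[cbind(1:B, sample(1:2, B, TRUE))] <- 1

  value_at <- function(d) {
    fr <- diabgan:::disc_forward(d, x_real)
    ff <- diabgan:::disc_forward(d, x_fake)
    adversarial_value(pmin(pmax(fr$d, 1e-12), 1 - 1e-12),
                      pmin(pmax(ff$d, 1e-12), 1 - 1e-12))
  }
  before <- value_at(disc)
  g <- diabgan:::disc_grads(disc, x_real, y, x_fake, lambda_c = 0)$grads
  step <- function(pars, grads, lr) {
    if (is.list(pars)) purrr::map2(pars, grads, step, lr = lr)
    else pars - lr * grads
  }
  after <- value_at(step(disc, g, 1e-4))
  expect_gte(after, before)
})

test_that("training is seed-reproducible and epochs = 0 is a no-op", {
  d <- generate_separable_gaussians(n = 80, p = 3, separation = 6, seed = 5)
  cfg <- dcsgan_config(latent_dim = 8, gen_hidden = 16, disc_hidden = c(16, 8),
                       epochs = 5, batch_size = 16, seed = 31)
  m1 <- train_dcsgan(d, config = cfg)
  m2 <- train_dcsgan(d, config = cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$generator, m2$generator)

  m0 <- train_dcsgan(d, config = dcsgan_config(epochs = 0, batch_size = 16, seed = 1))
  expect_equal(nrow(m0$history), 0)
  expect_s3_class(m0, "dcsgan")

  unlabeled <- d[setdiff(names(d), "Outcome")]
  expect_error(train_dcsgan(unlabeled, config = cfg), "labels")
})

test_that("the classifier separates well-separated Gaussian classes", {
  fx <- gaussian_fixture()
  preds <- predict(fx$model, fx$test)
  expect_gte(mean(preds$.pred_class == fx$test$Outcome), 0.95)

  # training-set accuracy is just as high
  tr <- predict(fx$model, fx$train)
  expect_gte(mean(tr$.pred_class == fx$train$Outcome), 0.95)

  # probability rows sum to 1; duplicated inputs predict identically
  probs <- as.matrix(preds[grep("^\\.prob_", names(preds))])
  expect_lt(max(abs(rowSums(probs) - 1)), 1e-6)
  two <- predict(fx$model, fx$test[c(1, 1), ])
  expect_identical(two[1, ], two[2, ])

  expect_error(predict(fx$model, fx$test[, 1:3]), "lacks feature")
})

test_that("generated samples track the training distribution", {
  fx <- gaussian_fixture()
  g1 <- generate_samples(fx$model, 200, seed = 8)
  expect_equal(dim(g1), c(200L, 8L))
  expect_identical(g1, generate_samples(fx$model, 200, seed = 8))
  expect_error(generate_samples(fx$model, 0), "positive")

  real <- as.matrix(fx$train[paste0("X", 1:8)])
  # distribution matching, checked loosely: generated means stay well inside
  # the real per-feature spread
  expect_lt(max(abs(colMeans(g1) - colMeans(real)) / apply(real, 2, sd)), 0.5)
})

test_that("a trained model round-trips through its JSON serialization", {
  fx <- gaussian_fixture()
  tf <- withr::local_tempfile(fileext = ".json")
  write_dcsgan(fx$model, tf)
  back <- read_dcsgan(tf)
  expect_equal(predict(back, fx$test), predict(fx$model, fx$test))
  expect_equal(back$history, fx$model$history)
})
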