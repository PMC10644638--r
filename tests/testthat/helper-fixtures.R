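# Shared fixtures. The trained Gaussian-fixture model is expensive (default
# config, ~600 samples) so it is built once per session and memoised.

.fixture_cache <- new.env(parent = emptyenv())

# Two well-separated unit-variance Gaussian classes in 8 dimensions; the
# train/test split plus a model trained with the default configuration.
gaussian_fixture <- function() {
  if (is.null(.fixture_cache$gauss)) {
    d <- generate_separable_gaussians(n = 600, p = 8, separation = 8,
                                      n_classes = 2, seed = 20260101)
    train <- d[1:480, ]
    test <- d[481:600, ]
    model <- train_dcsgan(train, config = dcsgan_config(seed = 99))
    .fixture_cache$gauss <- list(train = train, test = test, model = model)
  }
  .fixture_cache$gauss
}

small_pima <- function(n0 = 120, n1 = 60, seed = 7) {
  generate_pima_like(synthetic_spec(
    n_per_class = c("0" = n0, "1" = n1), seed = seed))
}

# Independent log-loss oracle: plain double loop, no shared code with
# classifier_loss().
logloss_oracle <- function(probs, labels) {
  total <- 0
  for (i in seq_len(nrow(probs))) {
    total <- total - log(probs[i, labels[i] + 1])
  }
  total / nrow(probs)
}

# Independent Pearson oracle: sample moments, double loop.
pearson_oracle <- function(x) {
  p <- ncol(x)
  out <- matrix(NA_real_, p, p)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      xi <- x[, i]; xj <- x[, j]
      covij <- sum((xi - mean(xi)) * (xj - mean(xj))) / (length(xi) - 1)
      out[i, j] <- covij / (sd(xi) * sd(xj))
    }
  }
  out
}

# Independent AUC oracle: all positive/negative pairs, ties count 1/2.
auc_pair_oracle <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + (a > b) + 0.5 * (a == b)
  }
  total / (length(pos) * length(neg))
}

# Independent logistic maximum-likelihood oracle via general-purpose
# optimisation of the log-likelihood (no IRLS).
logistic_mle_oracle <- function(x, y) {
  nll <- function(beta) {
    eta <- cbind(1, x) %*% beta
    -sum(y * eta - log1p(exp(eta)))
  }
  optim(rep(0, ncol(x) + 1), nll, method = "BFGS",
        control = list(maxit = 500, reltol = 1e-14))$par
}

# Find, for a synthetic row, the closest point on any segment between two
# originals of its class; returns the smallest residual norm.
segment_residual <- function(s, originals) {
  best <- Inf
  n <- nrow(originals)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- originals[i, ]; b <- originals[j, ]
      ab <- b - a
      denom <- sum(ab^2)
      u <- if (denom == 0) 0 else sum((s - a) * ab) / denom
      u <- min(max(u, 0), 1)
      best <- min(best, sqrt(sum((a + u * ab - s)^2)))
    }
  }
  best
}

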