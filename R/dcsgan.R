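#' DCSGAN configuration
#'
#' Architecture and training knobs for the semi-supervised adversarial
#' classifier. The discriminator is a shared multilayer trunk with two
#' heads: a sigmoid adversarial head D(x) scoring real vs generated, and a
#' softmax classification head C(x) over the class codes. The generator
#' maps latent Gaussian noise to feature vectors in standardized space.
#'
#' @param latent_dim Latent noise dimension (default 64).
#' @param gen_hidden Generator hidden-layer widths (default `c(128, 128)`).
#' @param disc_hidden Discriminator trunk widths (default `c(128, 64)`).
#' @param lambda_c Weight of the classification cross-entropy in the
#'   combined objective (default 1).
#' @param learning_rate Adam step size (default 2e-4).
#' @param epochs Training epochs (default 300).
#' @param batch_size Minibatch size (default 64).
#' @param n_classes Number of classes, or `NULL` to infer from the labels.
#' @param seed Seed governing initialization, shuffling and noise draws.
#' @return A list of class `dcsgan_config`.
#' @export
dcsgan_config <- function(latent_dim = 64L, gen_hidden = c(128L, 128L),
                          disc_hidden = c(128L, 64L), lambda_c = 1.0,
                          learning_rate = 2e-4, epochs = 300L,
                          batch_size = 64L, n_classes = NULL, seed = 1L) {
  if (any(c(latent_dim, gen_hidden, disc_hidden) < 1)) abort("all widths must be >= 1")
  if (!is.finite(lambda_c) || lambda_c < 0) abort("lambda_c must be finite and >= 0")
  if (batch_size < 2) abort("batch_size must be >= 2")
  if (epochs < 0) abort("epochs must be >= 0")
  structure(list(latent_dim = as.integer(latent_dim),
                 gen_hidden = as.integer(gen_hidden),
                 disc_hidden = as.integer(disc_hidden),
                 lambda_c = lambda_c, learning_rate = learning_rate,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 n_classes = if (is.null(n_classes)) NULL else as.integer(n_classes),
                 seed = as.integer(seed)),
            class = "dcsgan_config")
}

## ---- objective pieces ------------------------------------------------------

PROB_EPS <- 1e-7

#' Classification cross-entropy loss
#'
#' Mean over samples of the negative log-probability assigned to the true
#' class: the categorical cross-entropy with one-hot targets. Probabilities
#' are clamped at 1e-7 inside the log so a zero at the true class yields a
#' large finite loss, never infinity.
#'
#' @param class_probs Matrix (n x K), each row a probability vector.
#' @param labels Integer class codes 0..K-1 (code j selects column j + 1).
#' @return Non-negative scalar; 0 only for a perfect classifier.
#' @examples
#' classifier_loss(matrix(c(0.5, 0.5), 1), 0L)  # log(2)
#' @export
classifier_loss <- function(class_probs, labels) {
  class_probs <- as.matrix(class_probs)
  n <- nrow(class_probs)
  if (n == 0 || length(labels) != n) abort("labels must match rows of class_probs")
  if (any(abs(rowSums(class_probs) - 1) > 1e-6)) abort("rows of class_probs must sum to 1")
  if (any(labels < 0 | labels >= ncol(class_probs))) abort("label code out of range")
  p_true <- class_probs[cbind(seq_len(n), labels + 1L)]
  -mean(log(pmax(p_true, PROB_EPS)))
}

#' Adversarial value of the minimax game
#'
#' `mean(log d_real) + mean(log(1 - d_fake))`: the quantity the
#' discriminator drives toward 0 (its supremum) and the generator drives
#' down. Inputs must be strictly inside (0, 1).
#'
#' @param d_real Discriminator outputs on real samples.
#' @param d_fake Discriminator outputs on generated samples.
#' @return Scalar value, at most 0 in the balanced case `d = 0.5` sense.
#' @examples
#' adversarial_value(0.5, 0.5)  # 2 * log(0.5)
#' @export
adversarial_value <- function(d_real, d_fake) {
  if (any(d_real <= 0 | d_real >= 1) || any(d_fake <= 0 | d_fake >= 1)) {
    abort("discriminator outputs must lie strictly in (0, 1)")
  }
  mean(log(d_real)) + mean(log(1 - d_fake))
}

#' Combined adversarial + classification objective
#'
#' The semi-supervised objective: the adversarial value plus
#' `lambda_c` times the classification cross-entropy on the real labeled
#' samples (generated samples carry no class label). With `lambda_c = 0`
#' this reduces exactly to the plain GAN value.
#'
#' @inheritParams adversarial_value
#' @inheritParams classifier_loss
#' @param lambda_c Non-negative classification weight.
#' @return List with `value_v` (combined value) and `loss_c`.
#' @export
combined_objective <- function(d_real, d_fake, class_probs, labels, lambda_c) {
  if (!is.finite(lambda_c) || lambda_c < 0) abort("lambda_c must be finite and >= 0")
  loss_c <- classifier_loss(class_probs, labels)
  list(value_v = adversarial_value(d_real, d_fake) + lambda_c * loss_c,
       loss_c = loss_c)
}

## ---- network internals -----------------------------------------------------

leaky <- function(x, slope = 0.2) x * (x > 0) + slope * x * (x <= 0)
leaky_grad <- function(a, slope = 0.2) (a > 0) + slope * (a <= 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(a) {
  a <- a - apply(a, 1, max)
  e <- exp(a)
  e / rowSums(e)
}

# An MLP is a list of weight matrices W[[i]] (in x out) and bias vectors
# b[[i]]; leaky-rectifier activations, final layer linear when final_linear.
mlp_init <- function(dims) {
  L <- length(dims) - 1
  list(
    W = lapply(seq_len(L), function(i)
      matrix(rnorm(dims[i] * dims[i + 1], sd = sqrt(2 / dims[i])),
             dims[i], dims[i + 1])),
    b = lapply(seq_len(L), function(i) rep(0, dims[i + 1]))
  )
}

mlp_forward <- function(net, x, final_linear = FALSE) {
  L <- length(net$W)
  h <- vector("list", L + 1)
  a <- vector("list", L)
  h[[1]] <- x
  for (i in seq_len(L)) {
    a[[i]] <- sweep(h[[i]] %*% net$W[[i]], 2, net$b[[i]], "+")
    h[[i + 1]] <- if (i == L && final_linear) a[[i]] else leaky(a[[i]])
  }
  list(h = h, a = a, out = h[[L + 1]], final_linear = final_linear)
}

# d_out: gradient wrt the network output. Returns per-layer grads and the
# gradient wrt the input (needed to push generator gradients through the
# discriminator trunk).
mlp_backward <- function(net, cache, d_out) {
  L <- length(net$W)
  dW <- vector("list", L)
  db <- vector("list", L)
  d_h <- d_out
  for (i in rev(seq_len(L))) {
    d_a <- if (i == L && cache$final_linear) d_h else d_h * leaky_grad(cache$a[[i]])
    dW[[i]] <- crossprod(cache$h[[i]], d_a)
    db[[i]] <- colSums(d_a)
    d_h <- tcrossprod(d_a, net$W[[i]])
  }
  list(dW = dW, db = db, d_input = d_h)
}

# Adam with beta1 = 0.5 (the usual GAN setting damps momentum oscillation
# between the two players). params/grads are nested lists of arrays.
adam_init <- function(params) {
  zero <- function(p) if (is.list(p)) lapply(p, zero) else p * 0
  list(m = zero(params), v = zero(params), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.5, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      res <- purrr::pmap(list(p, g, m, v), upd)
      return(list(p = lapply(res, `[[`, "p"), m = lapply(res, `[[`, "m"),
                  v = lapply(res, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  res <- upd(params, grads, state$m, state$v)
  list(params = res$p, state = list(m = res$m, v = res$v, t = t))
}

disc_init <- function(p, disc_hidden, n_classes) {
  trunk <- mlp_init(c(p, disc_hidden))
  last <- disc_hidden[length(disc_hidden)]
  list(trunk = trunk,
       wa = matrix(rnorm(last, sd = sqrt(2 / last)), last, 1), ba = 0,
       Wc = matrix(rnorm(last * n_classes, sd = sqrt(2 / last)), last, n_classes),
       bc = rep(0, n_classes))
}

disc_forward <- function(disc, x) {
  cache <- mlp_forward(disc$trunk, x, final_linear = FALSE)
  h <- cache$out
  a_adv <- drop(h %*% disc$wa) + disc$ba
  logits <- sweep(h %*% disc$Wc, 2, disc$bc, "+")
  list(cache = cache, h = h, d = sigmoid(a_adv), probs = softmax_rows(logits))
}

# One discriminator/classifier update on a fixed batch. Gradients descend
# the negated value: real scored toward 1, fake toward 0, cross-entropy on
# real labels weighted lambda_c. Returns grads so callers can also inspect.
disc_grads <- function(disc, x_real, y_onehot, x_fake, lambda_c) {
  B <- nrow(x_real)
  fr <- disc_forward(disc, x_real)
  ff <- disc_forward(disc, x_fake)

  loss_adv <- -mean(log(pmax(fr$d, PROB_EPS))) - mean(log(pmax(1 - ff$d, PROB_EPS)))
  p_true <- rowSums(fr$probs * y_onehot)
  loss_c <- -mean(log(pmax(p_true, PROB_EPS)))

  d_a_adv_r <- matrix((fr$d - 1) / B, ncol = 1)
  d_logits <- lambda_c * (fr$probs - y_onehot) / B
  d_h_r <- d_a_adv_r %*% t(disc$wa) + d_logits %*% t(disc$Wc)
  d_a_adv_f <- matrix(ff$d / nrow(x_fake), ncol = 1)
  d_h_f <- d_a_adv_f %*% t(disc$wa)

  back_r <- mlp_backward(disc$trunk, fr$cache, d_h_r)
  back_f <- mlp_backward(disc$trunk, ff$cache, d_h_f)

  grads <- list(
    trunk = list(W = purrr::map2(back_r$dW, back_f$dW, `+`),
                 b = purrr::map2(back_r$db, back_f$db, `+`)),
    wa = crossprod(fr$h, d_a_adv_r) + crossprod(ff$h, d_a_adv_f),
    ba = sum(d_a_adv_r) + sum(d_a_adv_f),
    Wc = crossprod(fr$h, d_logits),
    bc = colSums(d_logits)
  )
  list(grads = grads, loss_adv = loss_adv, loss_c = loss_c)
}

# Generator update: non-saturating loss -mean(log D(G(z))), gradients pushed
# through a frozen discriminator trunk.
gen_grads <- function(gen, disc, z) {
  gc <- mlp_forward(gen, z, final_linear = TRUE)
  fd <- disc_forward(disc, gc$out)
  B <- nrow(z)
  loss_g <- -mean(log(pmax(fd$d, PROB_EPS)))
  d_a_adv <- matrix((fd$d - 1) / B, ncol = 1)
  d_h <- d_a_adv %*% t(disc$wa)
  d_x <- mlp_backward(disc$trunk, fd$cache, d_h)$d_input
  back <- mlp_backward(gen, gc, d_x)
  list(grads = list(W = back$dW, b = back$db), loss_g = loss_g)
}

## ---- training --------------------------------------------------------------

#' Train the semi-supervised adversarial classifier
#'
#' Alternating minibatch training: each step first updates the
#' discriminator/classifier (real samples scored toward 1 by the adversarial
#' head, generated samples toward 0, and the classification head fit to the
#' real labels with weight `lambda_c`), then updates the generator with the
#' non-saturating objective (raise `log D(G(z))`). Features are standardized
#' to zero mean and unit variance (fit on the training data) before the
#' networks; generated samples are mapped back to the original scale.
#' Training is fully reproducible from `config$seed`.
#'
#' @param data A data frame of numeric features plus a label column.
#' @param label_column Name of the integer label column.
#' @param config A [dcsgan_config()].
#' @return An object of class `dcsgan` with the generator and discriminator
#'   parameters, the standardizer, the class-code levels, and a per-epoch
#'   `history` tibble (`loss_d`, `loss_g`, `loss_c`, `train_accuracy`).
#' @export
train_dcsgan <- function(data, label_column = "Outcome",
                         config = dcsgan_config()) {
  labels <- data[[label_column]]
  if (is.null(labels)) abort(paste0("label column '", label_column, "' not found; training needs labels"))
  levels <- sort(unique(as.integer(labels)))
  n_classes <- config$n_classes %||% length(levels)
  if (n_classes < length(levels)) abort("n_classes below the number of observed classes")
  x <- feature_matrix(data, label_column)
  n <- nrow(x)
  if (n < config$batch_size) abort("need at least batch_size samples")
  y_idx <- match(as.integer(labels), levels)

  std <- standardize_fit(x)
  z_x <- standardize_apply(x, std)
  p <- ncol(x)

  set.seed(config$seed)
  gen <- mlp_init(c(config$latent_dim, config$gen_hidden, p))
  disc <- disc_init(p, config$disc_hidden, n_classes)
  st_d <- adam_init(disc)
  st_g <- adam_init(gen)

  onehot <- matrix(0, n, n_classes)
  onehot[cbind(seq_len(n), y_idx)] <- 1

  B <- config$batch_size
  n_batches <- max(1L, floor(n / B))
  history <- vector("list", config$epochs)

  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(n)
    ld <- lg <- lc <- 0
    for (bi in seq_len(n_batches)) {
      take <- perm[((bi - 1) * B + 1):min(bi * B, n)]
      xb <- z_x[take, , drop = FALSE]
      yb <- onehot[take, , drop = FALSE]

      z <- matrix(rnorm(length(take) * config$latent_dim), length(take))
      x_fake <- mlp_forward(gen, z, final_linear = TRUE)$out

      dstep <- disc_grads(disc, xb, yb, x_fake, config$lambda_c)
      if (!is.finite(dstep$loss_adv) || !is.finite(dstep$loss_c)) {
        abort(sprintf("non-finite discriminator loss at epoch %d; lower the learning rate", epoch))
      }
      upd <- adam_step(disc, dstep$grads, st_d, config$learning_rate)
      disc <- upd$params; st_d <- upd$state

      z2 <- matrix(rnorm(length(take) * config$latent_dim), length(take))
      gstep <- gen_grads(gen, disc, z2)
      if (!is.finite(gstep$loss_g)) {
        abort(sprintf("non-finite generator loss at epoch %d", epoch))
      }
      upd <- adam_step(gen, gstep$grads, st_g, config$learning_rate)
      gen <- upd$params; st_g <- upd$state

      ld <- ld + dstep$loss_adv; lc <- lc + dstep$loss_c; lg <- lg + gstep$loss_g
    }
    acc <- mean(max.col(disc_forward(disc, z_x)$probs, ties.method = "first") == y_idx)
    history[[epoch]] <- tibble::tibble(
      epoch = epoch, loss_d = ld / n_batches, loss_g = lg / n_batches,
      loss_c = lc / n_batches, train_accuracy = acc)
  }

  structure(
    list(generator = gen, discriminator = disc, standardizer = std,
         levels = levels, feature_names = colnames(x), config = config,
         history = if (config$epochs > 0) dplyr::bind_rows(history) else
           tibble::tibble(epoch = integer(), loss_d = double(), loss_g = double(),
                          loss_c = double(), train_accuracy = double())),
    class = "dcsgan"
  )
}

#' Predict class codes and probabilities
#'
#' Standardizes new samples with the standardizer stored at training time,
#' evaluates the classification head, and takes the arg-max with ties broken
#' toward the lowest class code.
#'
#' @param object A trained [train_dcsgan()] model.
#' @param newdata A data frame containing the training feature columns.
#' @param ... Unused.
#' @return A tibble with `.pred_class` (original class codes) and one
#'   `.prob_<code>` column per class; probability rows sum to 1.
#' @export
predict.dcsgan <- function(object, newdata, ...) {
  missing <- setdiff(object$feature_names, names(newdata))
  if (length(missing) > 0) {
    abort(paste0("newdata lacks feature(s): ", paste(missing, collapse = ", ")))
  }
  x <- as.matrix(newdata[object$feature_names])
  z <- standardize_apply(x, object$standardizer)
  probs <- disc_forward(object$discriminator, z)$probs
  k_obs <- length(object$levels)
  cls <- object$levels[max.col(probs[, seq_len(k_obs), drop = FALSE],
                               ties.method = "first")]
  out <- tibble::tibble(.pred_class = cls)
  for (j in seq_len(ncol(probs))) {
    code <- if (j <= k_obs) object$levels[j] else j - 1L
    out[[paste0(".prob_", code)]] <- probs[, j]
  }
  out
}

#' Draw synthetic samples from the trained generator
#'
#' @param model A trained [train_dcsgan()] model.
#' @param n Number of samples (> 0).
#' @param seed Seed for the latent draws.
#' @return A tibble of `n` rows on the original feature scale.
#' @export
generate_samples <- function(model, n, seed = 1L) {
  stopifnot(inherits(model, "dcsgan"))
  if (n <= 0) abort("n must be positive")
  set.seed(seed)
  z <- matrix(rnorm(n * model$config$latent_dim), n)
  x <- mlp_forward(model$generator, z, final_linear = TRUE)$out
  x <- destandardize(x, model$standardizer)
  colnames(x) <- model$feature_names
  tibble::as_tibble(as.data.frame(x))
}

#' Serialize a trained model to a portable JSON file
#'
#' Stores the full parameter set, configuration and standardizer so the
#' model round-trips exactly through [read_dcsgan()].
#'
#' @param model A `dcsgan` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dcsgan <- function(model, path) {
  stopifnot(inherits(model, "dcsgan"))
  writeLines(jsonlite::serializeJSON(unclass(model), digits = NA), path)
  invisible(path)
}

#' @rdname write_dcsgan
#' @export
read_dcsgan <- function(path) {
  obj <- jsonlite::unserializeJSON(paste(readLines(path), collapse = "\n"))
  class(obj$config) <- "dcsgan_config"
  structure(obj, class = "dcsgan")
}

#' @export
print.dcsgan <- function(x, ...) {
  cat("Semi-supervised adversarial classifier (dcsgan)\n")
  cat(sprintf("  features: %d  classes: %s\n", length(x$feature_names),
              paste(x$levels, collapse = ", ")))
  cat(sprintf("  epochs trained: %d  lambda_c: %g\n", nrow(x$history),
              x$config$lambda_c))
  if (nrow(x$history) > 0) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  final losses  D: %.4f  G: %.4f  C: %.4f  train acc: %.3f\n",
                last$loss_d, last$loss_g, last$loss_c, last$train_accuracy))
  }
  invisible(x)
}

#' @describeIn train_dcsgan `tidy()` returns the per-epoch training history.
#' @method tidy dcsgan
#' @export
tidy.dcsgan <- function(x, ...) x$history

#' @describeIn train_dcsgan `glance()` returns a one-row summary of the fit.
#' @method glance dcsgan
#' @export
glance.dcsgan <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    epochs = nrow(h),
    n_features = length(x$feature_names),
    n_classes = length(x$levels),
    lambda_c = x$config$lambda_c,
    final_loss_d = if (nrow(h)) h$loss_d[nrow(h)] else NA_real_,
    final_loss_g = if (nrow(h)) h$loss_g[nrow(h)] else NA_real_,
    final_loss_c = if (nrow(h)) h$loss_c[nrow(h)] else NA_real_,
    train_accuracy = if (nrow(h)) h$train_accuracy[nrow(h)] else NA_real_
  )
}

#' @describeIn train_dcsgan `autoplot()` draws the loss and accuracy curves.
#' @param x,object A `dcsgan` model.
#' @method autoplot dcsgan
#' @export
autoplot.dcsgan <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, -"epoch",
                              names_to = "series", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = "Adversarial training history") +
    ggplot2::theme_minimal()
}
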