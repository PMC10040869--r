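# Minimal feed-forward multilayer perceptron for binary classification.
#
# The installed R stack has no multi-hidden-layer perceptron (nnet is
# single-layer), so the classifier is implemented here: Glorot-uniform
# initialization, full-batch Adam on the binary cross-entropy with an L2
# penalty alpha/(2n) * sum(W^2), and early stopping when the loss stops
# improving. Fully deterministic under `seed`.

#' Fit a multilayer perceptron classifier
#'
#' @param x numeric matrix (n x p) of features.
#' @param y binary labels (0/1).
#' @param hidden integer vector of hidden layer sizes, e.g. `c(50, 50)`.
#' @param activation `"relu"` or `"tanh"` for the hidden layers; the output is
#'   a logistic unit.
#' @param alpha L2 regularization strength.
#' @param learning_rate Adam step size.
#' @param max_iter maximum full-batch iterations.
#' @param tol minimum loss improvement; training stops after `patience`
#'   consecutive iterations below it.
#' @param patience consecutive non-improving iterations tolerated.
#' @param seed RNG seed for the weight initialization.
#' @return an `lvs_mlp` model; score with [predict.lvs_mlp()].
#' @export
mlp_fit <- function(x, y, hidden = 50, activation = c("relu", "tanh"),
                    alpha = 1e-4, learning_rate = 0.01, max_iter = 100,
                    tol = 1e-4, patience = 10, seed = 1) {
  activation <- match.arg(activation)
  x <- as.matrix(x); storage.mode(x) <- "double"
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), all(y %in% c(0, 1)))
  hidden <- as.integer(hidden)
  sizes <- c(ncol(x), hidden, 1L)
  L <- length(sizes) - 1L
  n <- nrow(x)

  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  W <- lapply(seq_len(L), function(l) {
    lim <- sqrt(6 / (sizes[l] + sizes[l + 1]))
    matrix(stats::runif(sizes[l] * sizes[l + 1], -lim, lim), sizes[l], sizes[l + 1])
  })
  b <- lapply(seq_len(L), function(l) numeric(sizes[l + 1]))

  act <- if (activation == "relu") function(z) pmax(z, 0) else tanh
  dact <- if (activation == "relu") function(a) (a > 0) * 1 else function(a) 1 - a^2

  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(v) v * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  best_loss <- Inf; stall <- 0L; n_iter <- 0L

  for (it in seq_len(max_iter)) {
    # forward
    A <- vector("list", L + 1L); A[[1L]] <- x
    for (l in seq_len(L - 1L)) {
      A[[l + 1L]] <- act(sweep(A[[l]] %*% W[[l]], 2, b[[l]], "+"))
    }
    z <- as.vector(A[[L]] %*% W[[L]]) + b[[L]]
    p <- 1 / (1 + exp(-z))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    l2 <- sum(vapply(W, function(w) sum(w^2), 0))
    loss <- -mean(y * log(p) + (1 - y) * log(1 - p)) + alpha * l2 / (2 * n)

    # backward
    delta <- matrix((p - y) / n, n, 1)
    gW <- vector("list", L); gb <- vector("list", L)
    for (l in L:1) {
      gW[[l]] <- crossprod(A[[l]], delta) + (alpha / n) * W[[l]]
      gb[[l]] <- colSums(delta)
      if (l > 1) delta <- (delta %*% t(W[[l]])) * dact(A[[l]])
    }
    # Adam update
    for (l in seq_len(L)) {
      mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW[[l]]
      vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW[[l]]^2
      mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb[[l]]
      vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb[[l]]^2
      c1 <- 1 - beta1^it; c2 <- 1 - beta2^it
      W[[l]] <- W[[l]] - learning_rate * (mW[[l]] / c1) / (sqrt(vW[[l]] / c2) + eps)
      b[[l]] <- b[[l]] - learning_rate * (mb[[l]] / c1) / (sqrt(vb[[l]] / c2) + eps)
    }
    n_iter <- it
    if (best_loss - loss < tol) stall <- stall + 1L else stall <- 0L
    if (loss < best_loss) best_loss <- loss
    if (stall >= patience) break
  }

  structure(list(W = W, b = b, activation = activation, hidden = hidden,
                 alpha = alpha, n_iter = n_iter, loss = best_loss, seed = seed),
            class = "lvs_mlp")
}

#' @export
predict.lvs_mlp <- function(object, newdata, ...) {
  x <- as.matrix(newdata); storage.mode(x) <- "double"
  L <- length(object$W)
  act <- if (object$activation == "relu") function(z) pmax(z, 0) else tanh
  a <- x
  for (l in seq_len(L - 1L)) {
    a <- act(sweep(a %*% object$W[[l]], 2, object$b[[l]], "+"))
  }
  z <- as.vector(a %*% object$W[[L]]) + object$b[[L]]
  1 / (1 + exp(-z))
}

#' @export
print.lvs_mlp <- function(x, ...) {
  cat(sprintf("<mlp: hidden (%s), %s, alpha %g, %d iterations, loss %.4g>\n",
              paste(x$hidden, collapse = ", "), x$activation, x$alpha,
              x$n_iter, x$loss))
}
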