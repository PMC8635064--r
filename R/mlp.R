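# Single-hidden-layer feed-forward network for binary classification,
# trained full-batch with Adam on cross-entropy + L2. Supports the
# logistic, tanh and relu hidden activations used by the classifier
# suite; output unit is always a sigmoid.

act_fun <- function(name) {
  switch(name,
    logistic = list(f = function(z) 1 / (1 + exp(-z)),
                    df = function(z, a) a * (1 - a)),
    tanh = list(f = tanh, df = function(z, a) 1 - a^2),
    relu = list(f = function(z) pmax(z, 0),
                df = function(z, a) (z > 0) * 1),
    stop("unknown activation: ", name)
  )
}

#' Fit a one-hidden-layer neural network classifier
#'
#' Binary cross-entropy loss with L2 penalty, trained full-batch with
#' Adam. Training stops when the loss has improved by less than `tol`
#' for 10 consecutive epochs, or at `max_epochs`.
#' @param x Numeric matrix (rows = samples).
#' @param y 0/1 numeric vector.
#' @param hidden Number of hidden units.
#' @param activation `"logistic"`, `"tanh"` or `"relu"`.
#' @param max_epochs Epoch cap (default 1000).
#' @param tol Early-stopping tolerance on the loss (default 1e-4).
#' @param alpha L2 penalty weight (default 1e-4).
#' @param lr Adam step size (default 1e-3).
#' @param seed Integer seed for weight initialization.
#' @return An `mlp` model object.
#' @export
mlp_fit <- function(x, y, hidden = 200, activation = "logistic",
                    max_epochs = 1000, tol = 1e-4, alpha = 1e-4,
                    lr = 1e-3, seed = 1L) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(x); p <- ncol(x)
  act <- act_fun(activation)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  lim1 <- sqrt(6 / (p + hidden)); lim2 <- sqrt(6 / (hidden + 1))
  W1 <- matrix(stats::runif(p * hidden, -lim1, lim1), p, hidden)
  b1 <- numeric(hidden)
  w2 <- matrix(stats::runif(hidden, -lim2, lim2), hidden, 1)
  b2 <- 0
  # Adam state
  m <- list(W1 = W1 * 0, b1 = b1 * 0, w2 = w2 * 0, b2 = 0)
  v <- m
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  best <- Inf; stall <- 0L
  for (epoch in seq_len(max_epochs)) {
    z1 <- sweep(x %*% W1, 2, b1, "+")
    h <- act$f(z1)
    z2 <- drop(h %*% w2) + b2
    pr <- 1 / (1 + exp(-z2))
    pr <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
    loss <- -mean(y * log(pr) + (1 - y) * log(1 - pr)) +
      alpha * (sum(W1^2) + sum(w2^2)) / (2 * n)
    if (best - loss < tol) stall <- stall + 1L else stall <- 0L
    if (loss < best) best <- loss
    if (stall >= 10L) break
    d2 <- matrix((pr - y) / n, ncol = 1)
    g_w2 <- crossprod(h, d2) + alpha * w2 / n
    g_b2 <- sum(d2)
    d1 <- (d2 %*% t(w2)) * act$df(z1, h)
    g_W1 <- crossprod(x, d1) + alpha * W1 / n
    g_b1 <- colSums(d1)
    upd <- function(par, g, mk, vk) {
      m[[mk]] <<- beta1 * m[[mk]] + (1 - beta1) * g
      v[[vk]] <<- beta2 * v[[vk]] + (1 - beta2) * g^2
      mhat <- m[[mk]] / (1 - beta1^epoch)
      vhat <- v[[vk]] / (1 - beta2^epoch)
      par - lr * mhat / (sqrt(vhat) + eps)
    }
    W1 <- upd(W1, g_W1, "W1", "W1"); b1 <- upd(b1, g_b1, "b1", "b1")
    w2 <- upd(w2, g_w2, "w2", "w2"); b2 <- upd(b2, g_b2, "b2", "b2")
  }
  structure(list(W1 = W1, b1 = b1, w2 = w2, b2 = b2,
                 activation = activation, epochs = epoch, loss = best),
            class = "mlp")
}

#' Predict class-1 probabilities from a fitted network
#' @param object An `mlp` model.
#' @param newdata Numeric matrix.
#' @param ... Unused.
#' @return Numeric vector of probabilities.
#' @export
predict.mlp <- function(object, newdata, ...) {
  act <- act_fun(object$activation)
  h <- act$f(sweep(as.matrix(newdata) %*% object$W1, 2, object$b1, "+"))
  drop(1 / (1 + exp(-(h %*% object$w2 + object$b2))))
}
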