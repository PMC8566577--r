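#' Train a shallow fully connected network
#'
#' Single-hidden-layer binary classifier trained with minibatch ADAM,
#' cross-entropy loss with L2 weight decay, a cap of `max_epochs` passes over
#' the training data and early stopping with `patience` epochs without
#' improvement of the validation loss (the best-validation weights are
#' restored). Deterministic for a fixed seed.
#'
#' @param X Training feature matrix (rows already standardized upstream).
#' @param y Class labels (two levels).
#' @param hidden Hidden-layer width.
#' @param activation `"relu"`, `"sigmoid"` or `"tanh"`.
#' @param validation_idx Row indices of `X` held out as the validation set;
#'   must be non-empty and disjoint from training happens implicitly (rows
#'   not in `validation_idx` are the training rows).
#' @param seed RNG seed for the weight initialization.
#' @param max_epochs Maximum training epochs.
#' @param patience Early-stopping patience, epochs.
#' @param weight_decay L2 penalty coefficient.
#' @param lr ADAM step size.
#' @param batch_size Minibatch size (capped at the training-set size).
#' @return An `ann_model` with weights and the training trace.
#' @export
train_ann <- function(X, y, hidden = 50L,
                      activation = c("relu", "sigmoid", "tanh"),
                      validation_idx, seed = 1L, max_epochs = 1000L,
                      patience = 50L, weight_decay = 1e-3, lr = 1e-3,
                      batch_size = 16L) {
  activation <- match.arg(activation)
  if (missing(validation_idx) || length(validation_idx) == 0L) {
    abort_value("`validation_idx` must be a non-empty set of row indices")
  }
  lev <- sort(unique(as.character(y)))
  if (length(lev) != 2L) abort_value("binary targets required")
  yy <- as.numeric(as.character(y) == lev[2])
  tr <- setdiff(seq_len(nrow(X)), validation_idx)
  Xt <- X[tr, , drop = FALSE]; yt <- yy[tr]
  Xv <- X[validation_idx, , drop = FALSE]; yv <- yy[validation_idx]

  p <- ncol(X)
  act <- switch(activation,
    relu = list(f = function(z) pmax(z, 0), df = function(z, a) (z > 0) * 1),
    sigmoid = list(f = function(z) 1 / (1 + exp(-z)),
                   df = function(z, a) a * (1 - a)),
    tanh = list(f = base::tanh, df = function(z, a) 1 - a^2)
  )
  with_seed(seed, {
    W1 <- matrix(stats::rnorm(p * hidden, sd = sqrt(2 / p)), p, hidden)
    b1 <- numeric(hidden)
    W2 <- matrix(stats::rnorm(hidden, sd = sqrt(2 / hidden)), hidden, 1)
    b2 <- 0
  })
  params <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  m <- lapply(params, function(w) w * 0)
  v <- lapply(params, function(w) w * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  nt <- nrow(Xt)

  forward <- function(P, X) {
    Z1 <- sweep(X %*% P$W1, 2, P$b1, "+")
    A1 <- act$f(Z1)
    Z2 <- as.numeric(A1 %*% P$W2) + P$b2
    prob <- 1 / (1 + exp(-Z2))
    list(Z1 = Z1, A1 = A1, prob = prob)
  }
  bce <- function(prob, y) {
    pr <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
    -mean(y * log(pr) + (1 - y) * log(1 - pr))
  }

  best <- list(loss = Inf, params = params, epoch = 0L)
  wait <- 0L
  trace <- numeric(0)
  batch_size <- min(batch_size, nt)
  step <- 0L
  rng <- with_seed(derive_seed(seed, 1L), {
    # pre-drawn shuffles keep the whole run reproducible
    lapply(seq_len(max_epochs), function(i) sample.int(nt))
  })
  for (epoch in seq_len(max_epochs)) {
    ord <- rng[[epoch]]
    starts <- seq(1L, nt, by = batch_size)
    for (s0 in starts) {
      bi <- ord[s0:min(s0 + batch_size - 1L, nt)]
      Xb <- Xt[bi, , drop = FALSE]
      yb <- yt[bi]
      nb <- length(bi)
      fw <- forward(params, Xb)
      delta2 <- (fw$prob - yb) / nb
      gW2 <- crossprod(fw$A1, delta2) + weight_decay * params$W2
      gb2 <- sum(delta2)
      dA1 <- delta2 %*% t(params$W2)
      dZ1 <- dA1 * act$df(fw$Z1, fw$A1)
      gW1 <- crossprod(Xb, dZ1) + weight_decay * params$W1
      gb1 <- colSums(dZ1)
      grads <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
      step <- step + 1L
      for (nm in names(params)) {
        m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * grads[[nm]]
        v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * grads[[nm]]^2
        mhat <- m[[nm]] / (1 - beta1^step)
        vhat <- v[[nm]] / (1 - beta2^step)
        params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
    val_loss <- bce(forward(params, Xv)$prob, yv)
    trace <- c(trace, val_loss)
    if (val_loss < best$loss - 1e-9) {
      best <- list(loss = val_loss, params = params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  structure(
    list(params = best$params, levels = lev, activation = activation,
         hidden = hidden, stopped_epoch = length(trace),
         best_epoch = best$epoch, val_trace = trace,
         forward = NULL),
    class = "ann_model"
  )
}

#' @export
predict.ann_model <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  P <- object$params
  actf <- switch(object$activation,
    relu = function(z) pmax(z, 0),
    sigmoid = function(z) 1 / (1 + exp(-z)),
    tanh = base::tanh
  )
  A1 <- actf(sweep(newdata %*% P$W1, 2, P$b1, "+"))
  prob <- 1 / (1 + exp(-(as.numeric(A1 %*% P$W2) + P$b2)))
  if (type == "prob") return(prob)
  factor(ifelse(prob > 0.5, object$levels[2], object$levels[1]),
         levels = object$levels)
}
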