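# Fully connected feed-forward regressor trained with Adam, minibatch MSE,
# inverted dropout, early stopping on a carved-out validation fraction, and
# learning-rate reduction on plateau.  Written against plain matrices; the
# user-facing entry point is gag_train(family = "fcnn").

fcnn_activations <- list(
  relu = list(f = function(x) pmax(x, 0),
              d = function(x) (x > 0) * 1),
  elu = list(f = function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1),
             d = function(x) ifelse(x > 0, 1, exp(pmin(x, 0)))),
  gelu = list(f = function(x) x * stats::pnorm(x),
              d = function(x) stats::pnorm(x) + x * stats::dnorm(x)),
  leakyrelu = list(f = function(x) ifelse(x > 0, x, 0.01 * x),
                   d = function(x) ifelse(x > 0, 1, 0.01)),
  sigmoid = list(f = stats::plogis,
                 d = function(x) { s <- stats::plogis(x); s * (1 - s) }),
  tanh = list(f = tanh,
              d = function(x) 1 - tanh(x)^2))

fcnn_init <- function(sizes) {
  L <- length(sizes) - 1L
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1L], sd = sqrt(2 / sizes[l])),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- numeric(sizes[l + 1L])
  }
  list(W = W, b = b)
}

# forward pass; when training=TRUE draws inverted-dropout masks on the input
# and every hidden activation
fcnn_forward <- function(par, X, act, dropout, training = FALSE) {
  L <- length(par$W)
  A <- X
  masks <- vector("list", L)
  cache <- list(A = vector("list", L), Z = vector("list", L))
  for (l in seq_len(L)) {
    if (training && dropout > 0) {
      m <- matrix(runif(length(A)) >= dropout, nrow(A), ncol(A)) / (1 - dropout)
      A <- A * m
      masks[[l]] <- m
    }
    cache$A[[l]] <- A
    Z <- A %*% par$W[[l]] + rep(par$b[[l]], each = nrow(A))
    cache$Z[[l]] <- Z
    A <- if (l < L) act$f(Z) else Z
  }
  list(out = A, cache = cache, masks = masks)
}

fcnn_backward <- function(par, fw, y, act, weight_decay) {
  L <- length(par$W)
  m <- length(y)
  dW <- vector("list", L)
  db <- vector("list", L)
  dZ <- 2 * (fw$out - y) / m
  for (l in rev(seq_len(L))) {
    dW[[l]] <- crossprod(fw$cache$A[[l]], dZ) + weight_decay * par$W[[l]]
    db[[l]] <- colSums(dZ)
    if (l > 1L) {
      dA <- tcrossprod(dZ, par$W[[l]]) * act$d(fw$cache$Z[[l - 1L]])
      if (!is.null(fw$masks[[l]])) dA <- dA * fw$masks[[l]]
      dZ <- dA
    }
  }
  list(dW = dW, db = db)
}

#' Train a fully connected neural-network regressor
#'
#' Feed-forward network with linear output, MSE loss, Adam optimisation
#' (learning rate 0.001, L2 weight decay 1e-4 by default), inverted dropout
#' on the input and hidden activations, early stopping (patience 15 epochs)
#' monitored on a carved-out fraction of the training rows, and halving of
#' the learning rate when that validation loss plateaus.  With no hidden
#' layers the network is an input-to-output linear map with input dropout.
#'
#' @param X Scaled feature matrix.
#' @param y Numeric target.
#' @param hidden Integer vector of hidden-layer widths (empty for none).
#' @param dropout Dropout rate in \[0, 1).
#' @param activation One of `"relu"`, `"elu"`, `"gelu"`, `"leakyrelu"`,
#'   `"sigmoid"`, `"tanh"`.
#' @param learning_rate,weight_decay Adam step size and L2 penalty.
#' @param batch_size Minibatch size.
#' @param max_epochs Epoch cap.
#' @param min_steps Minimum total optimizer steps: on tables small enough
#'   that `max_epochs` epochs yield fewer minibatch steps than this, the
#'   epoch cap (and the patience, proportionally) is extended so the
#'   effective optimisation budget does not shrink with table size.
#' @param patience Early-stopping patience (epochs without improvement).
#' @param lr_factor,lr_patience Plateau learning-rate reduction factor and
#'   patience.
#' @param val_fraction Fraction of rows carved out for early stopping.
#' @param seed Integer seed controlling initialisation, batching and dropout.
#' @return A `gag_fcnn` with weights, the training log and configuration.
#' @export
fcnn_train <- function(X, y, hidden = integer(0), dropout = 0.01,
                       activation = "relu", learning_rate = 1e-3,
                       weight_decay = 1e-4, batch_size = 256,
                       max_epochs = 200, min_steps = 25000, patience = 15,
                       lr_factor = 0.5, lr_patience = 7, val_fraction = 0.1,
                       seed = 1L) {
  stopifnot(is.matrix(X), nrow(X) == length(y),
            dropout >= 0, dropout < 1,
            activation %in% names(fcnn_activations))
  act <- fcnn_activations[[activation]]
  sizes <- c(ncol(X), hidden, 1L)
  # optimise on the standardized target: Adam's step size is scale-free, so
  # without this the parameter distance to the optimum grows with the target
  # scale and small tables cannot converge within the epoch budget
  y_center <- mean(y)
  y_scale <- sd(y)
  if (!is.finite(y_scale) || y_scale == 0) y_scale <- 1
  y <- (y - y_center) / y_scale
  local_seed(seed, {
    n <- nrow(X)
    n_val <- max(1L, round(val_fraction * n))
    val_idx <- sample.int(n, n_val)
    Xtr <- X[-val_idx, , drop = FALSE]
    ytr <- y[-val_idx]
    Xva <- X[val_idx, , drop = FALSE]
    yva <- y[val_idx]
    par <- fcnn_init(sizes)
    L <- length(par$W)
    adam <- list(mW = lapply(par$W, function(w) w * 0),
                 vW = lapply(par$W, function(w) w * 0),
                 mb = lapply(par$b, function(bb) bb * 0),
                 vb = lapply(par$b, function(bb) bb * 0))
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    t <- 0L
    lr <- learning_rate
    best <- list(loss = Inf, par = par)
    stall <- 0L
    lr_stall <- 0L
    log <- numeric(0)
    steps_per_epoch <- ceiling(nrow(Xtr) / batch_size)
    epoch_cap <- max(max_epochs, ceiling(min_steps / steps_per_epoch))
    scale_up <- epoch_cap / max_epochs
    patience_eff <- ceiling(patience * scale_up)
    lr_patience_eff <- ceiling(lr_patience * scale_up)
    for (epoch in seq_len(epoch_cap)) {
      ord <- sample.int(nrow(Xtr))
      starts <- seq(1L, nrow(Xtr), by = batch_size)
      for (s in starts) {
        idx <- ord[s:min(s + batch_size - 1L, nrow(Xtr))]
        fw <- fcnn_forward(par, Xtr[idx, , drop = FALSE], act, dropout,
                           training = TRUE)
        gr <- fcnn_backward(par, fw, ytr[idx], act, weight_decay)
        t <- t + 1L
        for (l in seq_len(L)) {
          adam$mW[[l]] <- beta1 * adam$mW[[l]] + (1 - beta1) * gr$dW[[l]]
          adam$vW[[l]] <- beta2 * adam$vW[[l]] + (1 - beta2) * gr$dW[[l]]^2
          adam$mb[[l]] <- beta1 * adam$mb[[l]] + (1 - beta1) * gr$db[[l]]
          adam$vb[[l]] <- beta2 * adam$vb[[l]] + (1 - beta2) * gr$db[[l]]^2
          mhW <- adam$mW[[l]] / (1 - beta1^t)
          vhW <- adam$vW[[l]] / (1 - beta2^t)
          mhb <- adam$mb[[l]] / (1 - beta1^t)
          vhb <- adam$vb[[l]] / (1 - beta2^t)
          par$W[[l]] <- par$W[[l]] - lr * mhW / (sqrt(vhW) + eps)
          par$b[[l]] <- par$b[[l]] - lr * mhb / (sqrt(vhb) + eps)
        }
      }
      val_loss <- mean((fcnn_forward(par, Xva, act, 0)$out - yva)^2)
      log <- c(log, val_loss)
      if (val_loss < best$loss - 1e-12) {
        best <- list(loss = val_loss, par = par)
        stall <- 0L
        lr_stall <- 0L
      } else {
        stall <- stall + 1L
        lr_stall <- lr_stall + 1L
        if (lr_stall >= lr_patience_eff) {
          lr <- lr * lr_factor
          lr_stall <- 0L
        }
        if (stall >= patience_eff) break
      }
    }
    structure(list(W = best$par$W, b = best$par$b, sizes = sizes,
                   activation = activation, dropout = dropout,
                   y_center = y_center, y_scale = y_scale,
                   val_log = log, seed = seed),
              class = "gag_fcnn")
  })
}

#' Predict with a fitted FCNN
#' @param object A `gag_fcnn`.
#' @param X Scaled feature matrix with the training column count.
#' @param ... Unused.
#' @return Numeric predictions (deterministic; dropout disabled).
#' @export
predict.gag_fcnn <- function(object, X, ...) {
  stopifnot(ncol(X) == object$sizes[1L])
  act <- fcnn_activations[[object$activation]]
  drop(fcnn_forward(object, X, act, 0)$out) * object$y_scale + object$y_center
}

#' Monte Carlo dropout prediction
#'
#' Runs `n_passes` stochastic forward passes with dropout active at
#' inference; the per-row spread across passes is an uncertainty estimate.
#'
#' @param object A `gag_fcnn`.
#' @param X Scaled feature matrix.
#' @param n_passes Number of stochastic passes (default 30).
#' @param seed Integer seed for the dropout masks.
#' @return List with per-row `mean` and population `sd` over passes.
#' @export
fcnn_mc_dropout <- function(object, X, n_passes = 30, seed = 1L) {
  act <- fcnn_activations[[object$activation]]
  preds <- local_seed(seed, vapply(seq_len(n_passes), function(i)
    drop(fcnn_forward(object, X, act, object$dropout, training = TRUE)$out),
    numeric(nrow(X))))
  preds <- matrix(preds, nrow = nrow(X)) * object$y_scale + object$y_center
  mu <- rowMeans(preds)
  list(mean = mu, sd = sqrt(rowMeans((preds - mu)^2)))
}
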