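# Small feed-forward neural network (logistic hidden units, linear output)
# trained by full-batch backpropagation of errors with Adam updates. Depth
# is a hyperparameter (the emulator selection spans one to four hidden
# layers), which is why this is not delegated to a single-hidden-layer
# fitter.

.mlp_init <- function(sizes) {
  lapply(seq_len(length(sizes) - 1), function(l) {
    fan_in <- sizes[l]
    matrix(stats::runif((fan_in + 1) * sizes[l + 1], -0.5, 0.5) /
             sqrt(fan_in), fan_in + 1, sizes[l + 1])
  })
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# forward pass; returns list of layer activations (inputs first)
.mlp_forward <- function(W, X) {
  acts <- vector("list", length(W) + 1)
  acts[[1]] <- X
  for (l in seq_along(W)) {
    z <- cbind(1, acts[[l]]) %*% W[[l]]
    acts[[l + 1]] <- if (l < length(W)) .sigmoid(z) else z
  }
  acts
}

#' Fit a feed-forward network
#'
#' @param X input matrix (rows = samples), already normalized to \[0, 1\].
#' @param Y target matrix, normalized.
#' @param hidden integer vector of hidden-layer sizes (length = depth).
#' @param epochs training epochs (full-batch).
#' @param lr Adam learning rate.
#' @param l2 L2 weight penalty.
#' @param seed RNG seed for the weight initialisation.
#' @return an `mlp` object (weights + training loss trace).
#' @keywords internal
mlp_fit <- function(X, Y, hidden = c(8), epochs = 1500, lr = 0.01,
                    l2 = 1e-4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  sizes <- c(ncol(X), hidden, ncol(Y))
  W <- .mlp_init(sizes)
  mW <- lapply(W, function(w) w * 0)
  vW <- lapply(W, function(w) w * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  loss <- numeric(epochs)
  nl <- length(W)
  for (e in seq_len(epochs)) {
    acts <- .mlp_forward(W, X)
    err <- acts[[nl + 1]] - Y
    loss[e] <- mean(err^2)
    delta <- 2 * err / (n * ncol(Y)) # dL/dz at linear output
    for (l in rev(seq_len(nl))) {
      grad <- crossprod(cbind(1, acts[[l]]), delta) + l2 * W[[l]]
      if (l > 1) {
        a <- acts[[l]]
        delta <- (delta %*% t(W[[l]][-1, , drop = FALSE])) * a * (1 - a)
      }
      mW[[l]] <- b1 * mW[[l]] + (1 - b1) * grad
      vW[[l]] <- b2 * vW[[l]] + (1 - b2) * grad^2
      mhat <- mW[[l]] / (1 - b1^e)
      vhat <- vW[[l]] / (1 - b2^e)
      W[[l]] <- W[[l]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  structure(list(W = W, sizes = sizes, loss = loss), class = "mlp")
}

.mlp_predict <- function(fit, X) {
  acts <- .mlp_forward(fit$W, as.matrix(X))
  acts[[length(acts)]]
}
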