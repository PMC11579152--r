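#' Fit a small feed-forward neural network
#'
#' A fully connected multilayer perceptron for binary classification:
#' rectifier (ReLU) hidden activations, a single sigmoid output unit,
#' binary cross-entropy loss, trained full-batch with the Adam optimiser.
#' The default architecture is the eight-layer stack
#' 100, 150, 200, 150, 46, 20, 10, 1 used by the classification pipeline.
#' Weights use He initialisation, seeded for reproducibility.
#'
#' @param X Numeric feature matrix (rows = observations), already
#'   standardised by the caller.
#' @param y Binary 0/1 response vector.
#' @param hidden Integer vector of hidden-layer widths (the output layer of
#'   one neuron is appended automatically).
#' @param epochs Number of full-batch Adam steps.
#' @param lr Learning rate.
#' @param seed Integer seed for weight initialisation.
#' @param weights Optional per-observation weights for the loss (defaults
#'   to equal weights); normalised to mean 1.
#' @return An object of class `thetanav_mlp`.
#' @export
mlp_fit <- function(X, y, hidden = c(100, 150, 200, 150, 46, 20, 10),
                    epochs = 200, lr = 1e-3, seed = 1L, weights = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  if (is.null(weights)) weights <- rep(1, length(y))
  weights <- weights / mean(weights)
  dims <- c(ncol(X), hidden, 1L)
  L <- length(dims) - 1
  with_seed(seed, {
    W <- lapply(seq_len(L), function(l) {
      matrix(rnorm(dims[l] * dims[l + 1], 0, sqrt(2 / dims[l])), dims[l], dims[l + 1])
    })
    b <- lapply(seq_len(L), function(l) numeric(dims[l + 1]))
    mW <- lapply(W, function(w) w * 0); vW <- mW
    mb <- lapply(b, function(x) x * 0); vb <- mb
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    n <- nrow(X)
    for (it in seq_len(epochs)) {
      # forward
      A <- vector("list", L + 1)
      A[[1]] <- X
      for (l in seq_len(L)) {
        Z <- sweep(A[[l]] %*% W[[l]], 2, b[[l]], "+")
        A[[l + 1]] <- if (l < L) pmax(Z, 0) else 1 / (1 + exp(-Z))
      }
      p <- A[[L + 1]]
      # backward: dL/dZ_out for BCE + sigmoid is (p - y)/n
      delta <- weights * (p - y) / n
      for (l in L:1) {
        gW <- crossprod(A[[l]], delta)
        gb <- colSums(delta)
        if (l > 1) delta <- (delta %*% t(W[[l]])) * (A[[l]] > 0)
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
        mhW <- mW[[l]] / (1 - beta1^it); vhW <- vW[[l]] / (1 - beta2^it)
        mhb <- mb[[l]] / (1 - beta1^it); vhb <- vb[[l]] / (1 - beta2^it)
        W[[l]] <- W[[l]] - lr * mhW / (sqrt(vhW) + eps)
        b[[l]] <- b[[l]] - lr * mhb / (sqrt(vhb) + eps)
      }
    }
    structure(list(W = W, b = b, dims = dims, epochs = epochs, lr = lr),
              class = "thetanav_mlp")
  })
}

#' Predict probabilities from a fitted MLP
#'
#' @param object A `thetanav_mlp` fit.
#' @param newdata Feature matrix on the training scale.
#' @param ... Unused.
#' @return Numeric vector of class-1 probabilities.
#' @export
predict.thetanav_mlp <- function(object, newdata, ...) {
  A <- as.matrix(newdata)
  L <- length(object$W)
  for (l in seq_len(L)) {
    Z <- sweep(A %*% object$W[[l]], 2, object$b[[l]], "+")
    A <- if (l < L) pmax(Z, 0) else 1 / (1 + exp(-Z))
  }
  as.numeric(A)
}
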