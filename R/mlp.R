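#' Multilayer perceptron specification
#'
#' Fully connected feed-forward network: linear input layer, hidden
#' layers with rectified linear unit (ReLU) activation
#' \eqn{\mathrm{ReLU}(z) = \max(0, z)}, linear output layer. The
#' default is the 14-layer architecture used throughout the package
#' (input of the 4 selected features, twelve hidden layers, output of
#' the 2 moduli); hidden width is configurable.
#'
#' @param n_in Input width.
#' @param hidden Integer vector of hidden-layer widths.
#' @param n_out Output width.
#' @return A list of class `mlp_spec`; `layer_sizes` has length 14 at
#'   the defaults.
#' @export
mlp_spec <- function(n_in = 4, hidden = rep(24L, 12), n_out = 2) {
  stopifnot(n_in >= 1, n_out >= 1, all(hidden >= 1))
  structure(list(layer_sizes = c(n_in, as.integer(hidden), n_out),
                 n_layers = length(hidden) + 2L),
            class = "mlp_spec")
}

# uniform fan-in initialization, U(-1/sqrt(fan_in), 1/sqrt(fan_in))
mlp_init <- function(spec, seed = 1L) {
  set.seed(seed)
  sizes <- spec$layer_sizes
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    bound <- 1 / sqrt(sizes[l])
    W[[l]] <- matrix(runif(sizes[l] * sizes[l + 1], -bound, bound),
                     sizes[l], sizes[l + 1])
    b[[l]] <- runif(sizes[l + 1], -bound, bound)
  }
  list(W = W, b = b)
}

#' Forward pass of a multilayer perceptron
#'
#' Layered affine-then-ReLU composition with a linear final layer,
#' \eqn{y = \psi(\sum_i w_i x_i + w_{bias})} per neuron.
#'
#' @param model A `trained_model` (or a bare list with `W`, `b`).
#' @param X Numeric matrix (rows = samples) in the network's scaled
#'   input space.
#' @return Matrix of outputs (scaled space).
#' @export
mlp_forward <- function(model, X) {
  W <- model$W %||% model$params$W
  b <- model$b %||% model$params$b
  X <- as.matrix(X)
  if (ncol(X) != nrow(W[[1]])) {
    ath_abort(sprintf("input width %d does not match network input %d",
                      ncol(X), nrow(W[[1]])), "atheromech_shape_error")
  }
  A <- X
  L <- length(W)
  for (l in seq_len(L)) {
    A <- A %*% W[[l]]
    A <- A + rep(b[[l]], each = nrow(A))
    if (l < L) A[A < 0] <- 0
  }
  A
}

# forward with cached activations for backpropagation
mlp_forward_cached <- function(params, X) {
  L <- length(params$W)
  As <- vector("list", L + 1)
  As[[1]] <- X
  for (l in seq_len(L)) {
    Z <- As[[l]] %*% params$W[[l]]
    Z <- Z + rep(params$b[[l]], each = nrow(Z))
    if (l < L) Z[Z < 0] <- 0
    As[[l + 1]] <- Z
  }
  As
}

# gradients of mean squared error wrt all weights/biases
mlp_backward <- function(params, As, Y, trainable = NULL) {
  L <- length(params$W)
  m <- nrow(Y)
  dW <- vector("list", L); db <- vector("list", L)
  dZ <- 2 * (As[[L + 1]] - Y) / (m * ncol(Y))
  for (l in L:1) {
    if (is.null(trainable) || trainable[l]) {
      dW[[l]] <- crossprod(As[[l]], dZ)
      db[[l]] <- colSums(dZ)
    }
    if (l > 1) {
      # ReLU mask: A > 0 exactly where the unit was active
      dZ <- tcrossprod(dZ, params$W[[l]]) * (As[[l]] > 0)
    }
  }
  list(dW = dW, db = db)
}

# Adam state and update
adam_init <- function(params) {
  zero_like <- function(p) lapply(p, function(x) x * 0)
  list(mW = zero_like(params$W), vW = zero_like(params$W),
       mb = zero_like(params$b), vb = zero_like(params$b), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, trainable = NULL) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (l in seq_along(params$W)) {
    if (!is.null(trainable) && !trainable[l]) next
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * grads$dW[[l]]
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * grads$dW[[l]]^2
    params$W[[l]] <- params$W[[l]] -
      lr * (state$mW[[l]] / bc1) / (sqrt(state$vW[[l]] / bc2) + eps)
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * grads$db[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * grads$db[[l]]^2
    params$b[[l]] <- params$b[[l]] -
      lr * (state$mb[[l]] / bc1) / (sqrt(state$vb[[l]] / bc2) + eps)
  }
  list(params = params, state = state)
}

mse_of <- function(params, X, Y) {
  pred <- mlp_forward(params, X)
  mean((pred - Y)^2)
}
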