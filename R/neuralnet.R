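sigmoid <- function(z) 1 / (1 + exp(-z))

#' Construct one-hidden-layer network parameters
#'
#' A feed-forward network with `n_in` inputs, `n_hidden` logistic hidden
#' units and one logistic output unit (class probability of "intron").
#' The full parameter vector has length `n_hidden * (n_in + 1) +
#' (n_hidden + 1)`.
#'
#' @param n_in input dimension.
#' @param n_hidden hidden units; default `max(4, ceiling((n_in + 1) / 2))`.
#' @param theta optional flattened parameter vector (see
#'   [flatten_params()]); zeros when omitted.
#' @return a `network_params` object.
#' @export
network_params <- function(n_in, n_hidden = max(4L, ceiling((n_in + 1) / 2)),
                           theta = NULL) {
  n_in <- as.integer(n_in); n_hidden <- as.integer(n_hidden)
  stopifnot(n_in >= 1L, n_hidden >= 1L)
  net <- structure(list(n_in = n_in, n_hidden = n_hidden,
                        W1 = matrix(0, n_hidden, n_in),
                        b1 = numeric(n_hidden),
                        w2 = numeric(n_hidden), b2 = 0),
                   class = "network_params")
  if (!is.null(theta)) net <- unflatten_params(net, theta)
  net
}

#' @rdname network_params
#' @param net a `network_params` object.
#' @export
n_params <- function(net) {
  net$n_hidden * (net$n_in + 1L) + net$n_hidden + 1L
}

#' Flatten network parameters to a single numeric vector
#'
#' The layout is `(W1 by column, b1, w2, b2)`; [unflatten_params()] inverts
#' it exactly, so `flatten -> unflatten` round-trips bit-for-bit.
#'
#' @param net a `network_params` object.
#' @return numeric vector of length [n_params()].
#' @export
flatten_params <- function(net) {
  c(as.numeric(net$W1), net$b1, net$w2, net$b2)
}

#' @rdname flatten_params
#' @param theta flattened parameter vector.
#' @export
unflatten_params <- function(net, theta) {
  if (length(theta) != n_params(net)) {
    stop("parameter vector has length ", length(theta), "; expected ",
         n_params(net))
  }
  h <- net$n_hidden; d <- net$n_in
  net$W1 <- matrix(theta[seq_len(h * d)], h, d)
  net$b1 <- theta[h * d + seq_len(h)]
  net$w2 <- theta[h * (d + 1L) + seq_len(h)]
  net$b2 <- theta[h * (d + 2L) + 1L]
  net
}

#' Forward pass of the network
#'
#' @param net a `network_params` object.
#' @param X numeric matrix (rows = instances) or a single vector of length
#'   `n_in`.
#' @return numeric vector of outputs, each strictly in (0, 1).
#' @export
nn_forward <- function(net, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (ncol(X) != net$n_in) {
    stop("input has ", ncol(X), " attributes; network expects ", net$n_in)
  }
  H <- sigmoid(sweep(X %*% t(net$W1), 2L, net$b1, `+`))
  as.numeric(sigmoid(H %*% net$w2 + net$b2))
}

nn_mse <- function(net, X, y) {
  mean((nn_forward(net, X) - y)^2)
}

# Analytic gradient of the mean-squared-error loss, flattened in the same
# layout as flatten_params().
nn_gradient <- function(net, X, y) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  n <- nrow(X)
  H <- sigmoid(sweep(X %*% t(net$W1), 2L, net$b1, `+`))
  out <- as.numeric(sigmoid(H %*% net$w2 + net$b2))
  delta_out <- 2 * (out - y) * out * (1 - out) / n
  g_w2 <- as.numeric(crossprod(H, delta_out))
  g_b2 <- sum(delta_out)
  delta_h <- tcrossprod(delta_out, net$w2) * H * (1 - H)
  g_W1 <- crossprod(delta_h, X)          # n_hidden x n_in
  g_b1 <- colSums(delta_h)
  c(as.numeric(g_W1), g_b1, g_w2, g_b2)
}

#' Train a network by back-propagation
#'
#' Full-batch gradient descent on the mean squared error between the network
#' output and the 0/1 labels, for a fixed number of epochs.
#'
#' @param net starting `network_params`.
#' @param X numeric matrix of training inputs (rows = instances).
#' @param y 0/1 label vector.
#' @param learning_rate positive step size.
#' @param epochs number of full-batch updates; 0 returns `net` unchanged.
#' @return the trained `network_params`.
#' @export
bp_train <- function(net, X, y, learning_rate = 0.1, epochs = 5000L) {
  stopifnot(learning_rate > 0, epochs >= 0L)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  theta <- flatten_params(net)
  for (e in seq_len(epochs)) {
    g <- nn_gradient(net, X, y)
    theta <- theta - learning_rate * g
    if (any(!is.finite(theta))) stop("non-finite parameters at epoch ", e)
    net <- unflatten_params(net, theta)
  }
  net
}

#' Min-max input scaling fitted on training data
#'
#' Maps every attribute to `[0, 1]` using the training-fold minimum and
#' range; constant attributes map to 0. The fitted scaler is applied
#' unchanged to test data (values may then fall slightly outside `[0, 1]`).
#'
#' @param X training feature matrix.
#' @return a `minmax_scaler` with the per-attribute minima and ranges.
#' @export
fit_scaler <- function(X) {
  mins <- apply(X, 2L, min)
  ranges <- apply(X, 2L, max) - mins
  structure(list(mins = mins, ranges = ifelse(ranges == 0, 1, ranges)),
            class = "minmax_scaler")
}

#' @rdname fit_scaler
#' @param scaler a fitted `minmax_scaler`.
#' @export
apply_scaler <- function(scaler, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  sweep(sweep(X, 2L, scaler$mins, `-`), 2L, scaler$ranges, `/`)
}

#' Hybrid training: harmony-search initialization followed by back-propagation
#'
#' The flattened parameter vector is first optimized globally by
#' [sahs_optimize()] over the training mean squared error inside
#' `weight_bounds`; the best harmony then seeds [bp_train()] for local
#' refinement. The returned network never has a higher training error than
#' the harmony-search solution that seeded it.
#'
#' @param X numeric matrix of (already scaled) training inputs.
#' @param y 0/1 labels.
#' @param n_hidden hidden units (see [network_params()]).
#' @param weight_bounds symmetric search interval for the initial weights.
#' @param sahs a [sahs_config()].
#' @param learning_rate,epochs back-propagation settings (see [bp_train()]).
#' @return the trained `network_params`, with attributes `sahs_mse` and
#'   `final_mse` recording the training error before and after refinement.
#' @export
train_hybrid <- function(X, y,
                         n_hidden = max(4L, ceiling((ncol(X) + 1) / 2)),
                         weight_bounds = c(-3, 3),
                         sahs = sahs_config(),
                         learning_rate = 0.1, epochs = 5000L) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1L)
  template <- network_params(ncol(X), n_hidden)
  objective <- function(theta) nn_mse(unflatten_params(template, theta), X, y)
  fit <- sahs_optimize(objective, weight_bounds, sahs, dim = n_params(template))
  init <- unflatten_params(template, fit$best)
  trained <- bp_train(init, X, y, learning_rate = learning_rate,
                      epochs = epochs)
  final_mse <- nn_mse(trained, X, y)
  if (final_mse > fit$best_fitness) {
    trained <- init
    final_mse <- fit$best_fitness
  }
  attr(trained, "sahs_mse") <- fit$best_fitness
  attr(trained, "final_mse") <- final_mse
  trained
}
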