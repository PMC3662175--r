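#' Multiplicatively disturb one attribute of a data matrix
#'
#' Column `j` is multiplied by `1 + d` (`direction = "up"`) or `1 - d`
#' (`direction = "down"`); every other entry is returned untouched. Because
#' the disturbance is multiplicative, zero-valued attributes are immovable;
#' this is a property of the measurement, not patched away.
#'
#' @param X numeric matrix of instances (rows).
#' @param j attribute index, `1..ncol(X)`.
#' @param d disturbance ratio in `(0, 1)`.
#' @param direction `"up"` or `"down"`.
#' @return the disturbed matrix.
#' @export
disturb <- function(X, j, d, direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (j < 1L || j > ncol(X)) {
    stop("attribute index ", j, " out of range 1..", ncol(X))
  }
  factor <- if (direction == "up") 1 + d else 1 - d
  X[, j] <- X[, j] * factor
  X
}

#' Relative sensitivity of each input attribute of a trained network
#'
#' For each attribute `j`, every training instance is re-evaluated with the
#' attribute increased and decreased by the disturbance ratio `d`; the raw
#' sensitivity of `j` is the sum over instances of the two absolute output
#' changes. Raw sensitivities are normalized by the smallest one, so the
#' least influential attribute scores exactly 1 and every other score is the
#' factor by which that attribute moves the network output more.
#'
#' @param net a `network_params` object, or any function mapping an input
#'   matrix to a numeric output vector (useful for closed-form checks).
#' @param X numeric matrix of the training instances as the network consumes
#'   them (i.e., after any input scaling).
#' @param d disturbance ratio in `(0, 1)`; default 0.1 (a +/-10%
#'   perturbation).
#' @param epsilon positive guard for the normalizing denominator.
#' @return list with `rs` (relative sensitivities, min exactly 1) and `raw`
#'   (the unnormalized per-attribute sums).
#' @export
relative_sensitivity <- function(net, X, d = 0.1, epsilon = 1e-12) {
  stopifnot(d > 0, d < 1, epsilon > 0)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  predict_fun <- if (is.function(net)) net else function(M) nn_forward(net, M)
  base <- predict_fun(X)
  raw <- vapply(seq_len(ncol(X)), function(j) {
    up <- predict_fun(disturb(X, j, d, "up"))
    down <- predict_fun(disturb(X, j, d, "down"))
    sum(abs(up - base)) + sum(abs(down - base))
  }, numeric(1))
  if (all(raw < epsilon)) {
    stop("degenerate network: no attribute influences the output ",
         "(all raw sensitivities below ", epsilon, ")")
  }
  rs <- raw / max(min(raw), epsilon)
  names(rs) <- names(raw) <- colnames(X)
  list(rs = rs, raw = raw)
}

#' Derive pattern weights from training data via network sensitivity
#'
#' The full weight-derivation pipeline for one pattern category: encode the
#' records into per-pattern counts, min-max scale, train a hybrid
#' SAHS-initialized back-propagation network against the intron labels, and
#' convert the trained network into per-pattern weights by relative
#' sensitivity. One network per category reproduces the per-table
#' normalization of the published weight tables (each table has exactly one
#' weight of 1.00).
#'
#' @param records data frame of sequence records with labels.
#' @param patterns pattern table of a single category.
#' @param d disturbance ratio (see [relative_sensitivity()]).
#' @param ... passed to [train_hybrid()] (`n_hidden`, `sahs`, `epochs`, ...).
#' @return the pattern table with its `weight` column replaced by the
#'   computed relative sensitivities, plus a `raw_sensitivity` column.
#' @export
derive_pattern_weights <- function(records, patterns, d = 0.1, ...) {
  X <- encode_dataset(records, patterns)
  scaler <- fit_scaler(X)
  Xs <- apply_scaler(scaler, X)
  net <- train_hybrid(Xs, records$label, ...)
  sens <- relative_sensitivity(net, Xs, d = d)
  out <- patterns
  out$weight <- unname(sens$rs)
  out$raw_sensitivity <- unname(sens$raw)
  out
}
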