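#' Configuration for the self-adaptive harmony search optimizer
#'
#' @param hms harmony memory size (number of stored candidate vectors).
#' @param hmcr harmony-memory consideration rate in `[0, 1]`: the probability
#'   that a component is drawn from memory rather than sampled uniformly
#'   inside the bounds.
#' @param par pitch-adjustment rate in `[0, 1]`: the probability that a
#'   memory-drawn component is nudged toward the memory's current extremes.
#' @param max_evals total objective-evaluation budget (includes the initial
#'   memory).
#' @param seed integer seed.
#' @return a `sahs_config` list.
#' @export
sahs_config <- function(hms = 30L, hmcr = 0.9, par = 0.3,
                        max_evals = 10000L, seed = 1L) {
  stopifnot(hms >= 2L, hmcr >= 0, hmcr <= 1, par >= 0, par <= 1,
            max_evals >= hms)
  structure(list(hms = as.integer(hms), hmcr = hmcr, par = par,
                 max_evals = as.integer(max_evals), seed = as.integer(seed)),
            class = "sahs_config")
}

#' Minimize an objective with self-adaptive harmony search
#'
#' Continuous harmony search in which pitch adjustment is driven by the
#' memory itself instead of a fixed bandwidth: a memory-drawn component `x`
#' is, with probability `par`, moved toward the memory's per-dimension
#' maximum (`x + U(0,1) * (max - x)`, with probability 1/2) or minimum
#' (`x - U(0,1) * (x - min)`). As the memory contracts around good regions
#' the adjustment step shrinks automatically. New harmonies replace the
#' current worst memory member only when strictly better.
#'
#' @param objective function mapping a numeric vector of length `D` to a
#'   single finite numeric value (minimized).
#' @param bounds numeric matrix with `D` rows and columns `lower`, `upper`
#'   (or a 2-vector recycled over dimensions via `dim`).
#' @param config a [sahs_config()].
#' @param dim problem dimension, required when `bounds` is a 2-vector.
#' @return list with `best` (the best vector ever evaluated), `best_fitness`,
#'   and `history` (running best fitness after each evaluation,
#'   non-increasing).
#' @examples
#' sphere <- function(x) sum(x^2)
#' fit <- sahs_optimize(sphere, c(-5, 5), sahs_config(max_evals = 2000), dim = 3)
#' fit$best_fitness
#' @export
sahs_optimize <- function(objective, bounds, config = sahs_config(),
                          dim = NULL) {
  stopifnot(inherits(config, "sahs_config"))
  if (is.null(dim(bounds))) {
    stopifnot(length(bounds) == 2L, !is.null(dim))
    bounds <- matrix(rep(as.numeric(bounds), each = dim), ncol = 2L)
  }
  D <- nrow(bounds)
  lower <- bounds[, 1L]; upper <- bounds[, 2L]
  stopifnot(D >= 1L, all(is.finite(lower)), all(is.finite(upper)),
            all(lower <= upper))
  evaluate <- function(x) {
    f <- objective(x)
    if (!is.finite(f)) {
      stop("objective returned a non-finite value at x = (",
           paste(signif(x, 6), collapse = ", "), ")")
    }
    f
  }
  with_seed(config$seed, {
    hm <- matrix(runif(config$hms * D, min = rep(lower, each = config$hms),
                       max = rep(upper, each = config$hms)),
                 nrow = config$hms, ncol = D)
    fitness <- apply(hm, 1L, evaluate)
    history <- numeric(config$max_evals)
    history[seq_len(config$hms)] <- cummin(fitness)
    best_idx <- which.min(fitness)
    best <- hm[best_idx, ]; best_fit <- fitness[best_idx]
    n_eval <- config$hms
    while (n_eval < config$max_evals) {
      new <- numeric(D)
      use_mem <- runif(D) < config$hmcr
      mem_row <- sample.int(config$hms, D, replace = TRUE)
      for (j in seq_len(D)) {
        if (use_mem[j]) {
          x <- hm[mem_row[j], j]
          if (runif(1) < config$par) {
            if (runif(1) < 0.5) {
              x <- x + runif(1) * (max(hm[, j]) - x)
            } else {
              x <- x - runif(1) * (x - min(hm[, j]))
            }
          }
          new[j] <- x
        } else {
          new[j] <- runif(1, lower[j], upper[j])
        }
      }
      f <- evaluate(new)
      n_eval <- n_eval + 1L
      worst <- which.max(fitness)
      if (f < fitness[worst]) {
        hm[worst, ] <- new
        fitness[worst] <- f
      }
      if (f < best_fit) {
        best_fit <- f
        best <- new
      }
      history[n_eval] <- best_fit
    }
    list(best = best, best_fitness = best_fit, history = history)
  })
}
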