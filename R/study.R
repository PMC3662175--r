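#' Planting probabilities for the benchmark planted-motif study
#'
#' A fixed subset of the packaged patterns acts as the informative signal;
#' all remaining patterns are pure noise attributes (their motifs occur only
#' by chance in both classes). Uniframe patterns near the splice junction
#' are planted densely over their short 5-position regions. The multiframe
#' signal is deliberately sparse and rare: the planted 3-mers (GGG, AAA)
#' are nearly absent from the pyrimidine-rich background (see
#' [planted_motif_study()]), so a handful of planted copies is a clean but
#' weak per-attribute signal, while the T/C-rich multiframe patterns rack
#' up large, label-independent background counts. A plain Euclidean k-NN
#' dilutes the weak signal across those many high-variance noise
#' dimensions; an attribute-weighted distance recovers it.
#'
#' @param ufp,mfp pattern tables (defaults: the packaged tables).
#' @return numeric vector of per-pattern planting probabilities aligned to
#'   `rbind(ufp, mfp)`.
#' @export
planted_enrichment <- function(ufp = packaged_patterns("UFP"),
                               mfp = packaged_patterns("MFP")) {
  pats <- rbind(ufp, mfp)
  key <- paste(pats$category, pats$signal, pats$expression, pats$location)
  enrich <- setNames(rep(0, nrow(pats)), key)
  planted <- c(
    "UFP 5SS AAG 1"  = 0.40,   # donor-side uniframe signal
    "UFP 5SS GTA 1"  = 0.40,
    "UFP 3SS CAG 1"  = 0.40,   # acceptor-side uniframe signal
    "MFP 5SS GGG 25" = 0.035,  # sparse rare-motif plants over long regions
    "MFP 3SS AAA 22" = 0.055)
  enrich[names(planted)] <- planted
  unname(enrich)
}

#' Background base composition of the benchmark study
#'
#' Pyrimidine-rich and G-poor (A 0.15, C 0.30, G 0.10, T 0.45), emulating
#' the C/T-biased composition of intron interiors near the acceptor site.
#' Under this background the T/C-rich multiframe patterns accumulate large
#' chance occurrence counts while GGG and AAA almost never occur by chance.
#'
#' @return numeric vector of four probabilities (A, C, G, T).
#' @export
study_background <- function() c(A = 0.15, C = 0.30, G = 0.10, T = 0.45)

#' Benchmark experiment configuration: planted motifs plus noise attributes
#'
#' The canonical synthetic study used throughout the package documentation:
#' `n_per_class` positives and negatives of 101-bp [study_background()]
#' sequence, the [planted_enrichment()] motifs planted in positives, and
#' desk-scale network settings (small hidden layers, a few hundred
#' harmony-search evaluations, 2000 back-propagation epochs per fold)
#' chosen so a full 10-fold run completes in well under a minute while
#' training the sensitivity networks close to convergence, which is what
#' makes the derived weights concentrate on the informative attributes.
#'
#' @param seed master seed.
#' @param n_per_class positives and negatives (default 200, i.e. n = 400).
#' @param k_values neighbor counts (default 3 only; pass
#'   `c(1, 3, 5, 10)` for the full sweep).
#' @return an [experiment_config()].
#' @export
planted_motif_study <- function(seed = 1L, n_per_class = 200L,
                                k_values = 3L) {
  ufp <- packaged_patterns("UFP")
  mfp <- packaged_patterns("MFP")
  gen <- generator_config(n_per_class, n_per_class,
                          background_freqs = study_background(),
                          enrichment = planted_enrichment(ufp, mfp),
                          seed = seed)
  experiment_config(generator = gen, ufp = ufp, mfp = mfp,
                    k_values = k_values, n_folds = 10L,
                    n_hidden_ufp = 4L, n_hidden_mfp = 6L,
                    sahs = sahs_config(hms = 20L, max_evals = 400L),
                    learning_rate = 0.5, epochs = 2000L,
                    d = 0.1, seed = seed)
}

# Fixed multimodal toy problem: a two-bump indicator of a 1-D input, which a
# small sigmoid network can fit in several distinct ways (one basin per
# assignment of hidden units to bump edges), making the loss surface
# multimodal.
two_bump_toy <- function(n = 40L) {
  x <- seq(0, 1, length.out = n)
  y <- as.integer((x >= 0.2 & x <= 0.4) | (x >= 0.6 & x <= 0.8))
  list(X = matrix(x, ncol = 1L), y = y)
}

#' Compare hybrid-initialized and randomly initialized back-propagation
#'
#' Trains the same small network on the fixed two-bump toy problem under
#' two initialization schemes -- the harmony-search initializer and a plain
#' uniform random draw from the same weight box -- with an identical
#' back-propagation budget, once per seed.
#'
#' @param seeds integer vector of seeds (one paired comparison each).
#' @param n_hidden hidden units.
#' @param weight_bounds initial-weight box for both schemes.
#' @param sahs_evals harmony-search evaluation budget.
#' @param learning_rate,epochs back-propagation settings.
#' @return data frame with one row per seed: `hybrid_mse`, `random_mse`
#'   (final training MSE under each scheme).
#' @export
hybrid_vs_random_bp <- function(seeds = 1:20, n_hidden = 3L,
                                weight_bounds = c(-6, 6),
                                sahs_evals = 600L,
                                learning_rate = 0.5, epochs = 800L) {
  toy <- two_bump_toy()
  out <- lapply(seeds, function(s) {
    hybrid <- train_hybrid(toy$X, toy$y, n_hidden = n_hidden,
                           weight_bounds = weight_bounds,
                           sahs = sahs_config(hms = 15L,
                                              max_evals = sahs_evals,
                                              seed = s),
                           learning_rate = learning_rate, epochs = epochs)
    template <- network_params(1L, n_hidden)
    theta0 <- with_seed(s, runif(n_params(template), weight_bounds[1L],
                                 weight_bounds[2L]))
    random <- bp_train(unflatten_params(template, theta0), toy$X, toy$y,
                       learning_rate = learning_rate, epochs = epochs)
    data.frame(seed = s, hybrid_mse = attr(hybrid, "final_mse"),
               random_mse = nn_mse(random, toy$X, toy$y))
  })
  do.call(rbind, out)
}
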