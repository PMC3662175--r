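#' Configuration for the synthetic splice-window generator
#'
#' The generator emulates labeled 101-bp windows around the 5' and 3' splice
#' sites of an intron. Every instance carries both windows; positives (label
#' 1, "intron") have the configured 3-mer patterns planted inside their
#' `[location, location + range - 1]` regions, negatives (label 0) are pure
#' background sequence drawn from `background_freqs`.
#'
#' @param n_positive,n_negative numbers of positive / negative records.
#' @param background_freqs probabilities for A, C, G, T; must sum to 1.
#' @param enrichment per-pattern planting probability: the chance that each
#'   eligible start position of a pattern receives a planted copy of its
#'   3-mer in a positive record. A single number (recycled over all patterns)
#'   or a vector with one entry per pattern row.
#' @param seed integer seed making generation deterministic.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_positive, n_negative,
                             background_freqs = rep(0.25, 4),
                             enrichment = 0, seed = 1L) {
  stopifnot(n_positive >= 0L, n_negative >= 0L)
  if (length(background_freqs) != 4L ||
      abs(sum(background_freqs) - 1) > 1e-12 ||
      any(background_freqs < 0) || any(background_freqs > 1)) {
    stop("background_freqs must be 4 probabilities summing to 1")
  }
  if (any(enrichment < 0) || any(enrichment > 1)) {
    stop("enrichment probabilities must lie in [0, 1]")
  }
  structure(list(n_positive = as.integer(n_positive),
                 n_negative = as.integer(n_negative),
                 background_freqs = as.numeric(background_freqs),
                 enrichment = as.numeric(enrichment),
                 seed = as.integer(seed)),
            class = "generator_config")
}

random_window <- function(freqs) {
  paste(sample(DNA_ALPHABET, WINDOW_LEN, replace = TRUE, prob = freqs),
        collapse = "")
}

# Plant pattern 3-mers into one window, in pattern-row order; each eligible
# start receives a copy with probability `prob[j]`, later writes overwriting
# earlier ones.
plant_patterns <- function(window, patterns, prob) {
  chars <- strsplit(window, "", fixed = TRUE)[[1]]
  for (j in seq_len(nrow(patterns))) {
    if (prob[j] <= 0) next
    starts <- eligible_starts(patterns$location[j], patterns$range[j])
    hit <- starts[runif(length(starts)) < prob[j]]
    for (s in hit) {
      chars[s:(s + 2L)] <- strsplit(patterns$expression[j], "")[[1]]
    }
  }
  paste(chars, collapse = "")
}

#' Generate a labeled synthetic data set of splice-site windows
#'
#' Draws background windows base-by-base from `config$background_freqs` and,
#' for positives only, plants each pattern's 3-mer at its eligible start
#' positions with the configured planting probability. Patterns with signal
#' `"5SS"` are planted on `window_5ss`, `"3SS"` patterns on `window_3ss`.
#' Negatives run through the same code path with planting probability zero,
#' so the two classes differ only by the planted motifs.
#'
#' @param config a [generator_config()].
#' @param patterns pattern table (both categories allowed); planting regions
#'   must fit in the 101-bp window.
#' @return data frame with columns `record_id`, `window_5ss`, `window_3ss`,
#'   `label` (1 = intron, 0 = non-intron).
#' @examples
#' pats <- packaged_patterns("UFP")
#' cfg <- generator_config(5, 5, enrichment = 0.5, seed = 7)
#' d <- generate_dataset(cfg, pats)
#' table(d$label)
#' @export
generate_dataset <- function(config, patterns) {
  stopifnot(inherits(config, "generator_config"))
  validate_patterns(patterns)
  prob <- rep_len(config$enrichment, nrow(patterns))
  n <- config$n_positive + config$n_negative
  if (n == 0L) {
    return(data.frame(record_id = character(0), window_5ss = character(0),
                      window_3ss = character(0), label = integer(0),
                      stringsAsFactors = FALSE))
  }
  labels <- rep(c(1L, 0L), c(config$n_positive, config$n_negative))
  with_seed(config$seed, {
    recs <- lapply(seq_len(n), function(i) {
      w5 <- random_window(config$background_freqs)
      w3 <- random_window(config$background_freqs)
      p <- if (labels[i] == 1L) prob else rep(0, nrow(patterns))
      w5 <- plant_patterns(w5, patterns[patterns$signal == "5SS", ,
                                        drop = FALSE],
                           p[patterns$signal == "5SS"])
      w3 <- plant_patterns(w3, patterns[patterns$signal == "3SS", ,
                                        drop = FALSE],
                           p[patterns$signal == "3SS"])
      list(w5 = w5, w3 = w3)
    })
    data.frame(record_id = sprintf("rec%04d", seq_len(n)),
               window_5ss = vapply(recs, `[[`, character(1), "w5"),
               window_3ss = vapply(recs, `[[`, character(1), "w3"),
               label = labels, stringsAsFactors = FALSE)
  })
}

#' Validate a data frame of sequence records
#'
#' Checks that both windows of every record are exactly 101 bp of ACGT and
#' that labels are 0/1.
#'
#' @param records data frame with `record_id`, `window_5ss`, `window_3ss`,
#'   `label`.
#' @return the records, invisibly.
#' @export
validate_records <- function(records) {
  for (col in c("window_5ss", "window_3ss")) {
    w <- records[[col]]
    if (any(nchar(w) != WINDOW_LEN)) {
      stop(col, " must be exactly ", WINDOW_LEN, " bp")
    }
    if (any(grepl("[^ACGT]", w))) {
      stop(col, " contains characters outside ACGT")
    }
  }
  if (!all(records$label %in% c(0L, 1L))) stop("label must be 0 or 1")
  invisible(records)
}
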