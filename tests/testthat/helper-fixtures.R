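# Shared fixtures built in code.

# A minimal valid pattern table.
make_patterns <- function(expression = "TTT", location = 25L, range = 68L,
                          signal = "5SS", category = "MFP", weight = 1,
                          id = seq_along(expression)) {
  data.frame(id = id, weight = weight, expression = expression,
             location = location, range = range, signal = signal,
             category = category, stringsAsFactors = FALSE)
}

random_window <- function(len = 101L, freqs = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = freqs),
        collapse = "")
}

make_records <- function(w5, w3 = w5, label = 1L) {
  data.frame(record_id = sprintf("r%03d", seq_along(w5)),
             window_5ss = w5, window_3ss = w3,
             label = rep_len(label, length(w5)), stringsAsFactors = FALSE)
}

# Independent brute-force occurrence count: scan every start position with
# substr, no shared code with encode_record().
brute_count <- function(window, kmer, location, range) {
  n <- 0L
  for (s in seq(location, location + range - 1L)) {
    if (s + nchar(kmer) - 1L > nchar(window)) next
    if (substr(window, s, s + nchar(kmer) - 1L) == kmer) n <- n + 1L
  }
  n
}

# Central finite-difference gradient of the training MSE. The step balances
# truncation (~h^2) against roundoff (~eps/h).
fd_gradient <- function(net, X, y, h = 1e-5) {
  theta <- flatten_params(net)
  vapply(seq_along(theta), function(i) {
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    (mean((nn_forward(unflatten_params(net, tp), X) - y)^2) -
       mean((nn_forward(unflatten_params(net, tm), X) - y)^2)) / (2 * h)
  }, numeric(1))
}
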