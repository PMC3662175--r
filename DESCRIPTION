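Package: spliceweights
Title: Weighted Codon Patterns for Intron Splice-Site Windows
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Derives relative-importance weights for codon (3-mer) patterns in
    101-bp windows flanking 5' and 3' splice sites, and evaluates them with a
    weighted nearest-neighbor classifier. A feed-forward network is trained on
    per-pattern occurrence counts using back-propagation initialized by a
    self-adaptive harmony search; per-attribute weights are then obtained from
    a disturbance-based relative-sensitivity analysis of the trained network.
    The weights drive a two-layered lazy classifier (a uniframe-pattern filter
    followed by a multiframe-pattern decision) assessed by stratified 10-fold
    cross-validation with paired t-tests. Includes a synthetic-window generator
    with planted motifs, FASTA input/output, and packaged weighted-pattern
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    withr
Suggests: testthat (>= 3.0.0), jsonlite, knitr, rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
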