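#' Write sequence records to FASTA
#'
#' Each record produces two FASTA entries, one per splice-site window, with
#' headers of the form `record_id|5SS|label` and `record_id|3SS|label`.
#'
#' @param records data frame of sequence records (see [generate_dataset()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  validate_records(records)
  seqs <- c(rbind(records$window_5ss, records$window_3ss))
  names(seqs) <- c(rbind(paste(records$record_id, "5SS", records$label,
                               sep = "|"),
                         paste(records$record_id, "3SS", records$label,
                               sep = "|")))
  dna <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(dna, filepath = path, width = WINDOW_LEN)
  invisible(path)
}

#' Read sequence records from FASTA
#'
#' Expects the header layout written by [write_fasta()]: `record_id|signal|
#' label` with `signal` in `{5SS, 3SS}` and `label` in `{0, 1}`, and both
#' signals present for every record id. Windows must be 101 bp of ACGT.
#'
#' @param path FASTA file path.
#' @return data frame of sequence records.
#' @export
read_fasta <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  headers <- names(dna)
  tokens <- strsplit(headers, "|", fixed = TRUE)
  if (any(lengths(tokens) != 3L)) {
    stop("FASTA header must be \"record_id|signal|label\"; offending entry: ",
         headers[which(lengths(tokens) != 3L)[1L]])
  }
  ids <- vapply(tokens, `[`, character(1), 1L)
  signals <- vapply(tokens, `[`, character(1), 2L)
  labels <- vapply(tokens, `[`, character(1), 3L)
  if (!all(signals %in% c("5SS", "3SS"))) {
    stop("FASTA header signal token must be 5SS or 3SS")
  }
  if (!all(labels %in% c("0", "1"))) {
    stop("FASTA header label token must be 0 or 1")
  }
  if (any(Biostrings::width(dna) != WINDOW_LEN)) {
    stop("every window must be exactly ", WINDOW_LEN, " bp")
  }
  seqs <- as.character(dna)
  uids <- unique(ids)
  w5 <- seqs[match(paste(uids, "5SS"), paste(ids, signals))]
  w3 <- seqs[match(paste(uids, "3SS"), paste(ids, signals))]
  if (anyNA(w5) || anyNA(w3)) {
    stop("each record_id must appear with both a 5SS and a 3SS entry")
  }
  lab5 <- labels[match(paste(uids, "5SS"), paste(ids, signals))]
  lab3 <- labels[match(paste(uids, "3SS"), paste(ids, signals))]
  if (!identical(lab5, lab3)) {
    stop("5SS and 3SS entries of a record must carry the same label")
  }
  records <- data.frame(record_id = uids, window_5ss = unname(w5),
                        window_3ss = unname(w3),
                        label = as.integer(lab5),
                        stringsAsFactors = FALSE)
  validate_records(records)
  records
}
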