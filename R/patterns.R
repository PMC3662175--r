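#' Validate a table of weighted pattern specifications
#'
#' A pattern table is a data frame with one row per weighted pattern and
#' columns `id`, `weight`, `expression`, `location`, `range`, `signal`,
#' `category`. `expression` is a 3-mer over ACGT; `location` is the 1-based
#' start of the region the pattern may occupy; `range` is the number of
#' eligible start positions, so occurrences may begin anywhere in
#' `[location, location + range - 1]` (the 3-mer itself may extend up to
#' 2 bp past the region, but never past the 101-bp window). `signal` says
#' which window the pattern is read on (`"5SS"` or `"3SS"`); `category`
#' separates uniframe (`"UFP"`) from multiframe (`"MFP"`) patterns.
#'
#' @param patterns data frame of pattern rows.
#' @return The validated data frame, invisibly unchanged.
#' @export
validate_patterns <- function(patterns) {
  required <- c("id", "weight", "expression", "location", "range",
                "signal", "category")
  missing <- setdiff(required, names(patterns))
  if (length(missing) > 0L) {
    stop("pattern table is missing column(s): ", paste(missing, collapse = ", "))
  }
  bad_expr <- !grepl("^[ACGT]{3}$", patterns$expression)
  if (any(bad_expr)) {
    stop("pattern expression must be a 3-mer over ACGT; offending row(s): ",
         paste(which(bad_expr), collapse = ", "))
  }
  if (any(patterns$location < 1L)) stop("pattern location must be >= 1")
  if (any(patterns$range < 1L)) stop("pattern range must be >= 1")
  over <- patterns$location + patterns$range - 1L > WINDOW_LEN
  if (any(over)) {
    stop("pattern region exceeds the ", WINDOW_LEN, "-bp window for id(s): ",
         paste(patterns$id[over], collapse = ", "))
  }
  if (any(patterns$weight <= 0)) stop("pattern weight must be > 0")
  if (!all(patterns$signal %in% c("5SS", "3SS"))) {
    stop("pattern signal must be \"5SS\" or \"3SS\"")
  }
  if (!all(patterns$category %in% c("UFP", "MFP"))) {
    stop("pattern category must be \"UFP\" or \"MFP\"")
  }
  invisible(patterns)
}

#' Load a weighted pattern table from TSV
#'
#' Reads a tab-separated pattern table with header
#' `id  weight  expression  location  range  signal  category` and returns the
#' rows in file order. Duplicate ids are kept verbatim (with a warning), since
#' published tables occasionally repeat an id.
#'
#' @param path path to a TSV file.
#' @return data frame of pattern rows (see [validate_patterns()]).
#' @seealso [packaged_patterns()] for the tables shipped with the package.
#' @export
load_pattern_table <- function(path) {
  if (!file.exists(path)) stop("pattern table not found: ", path)
  tab <- read.delim(path, sep = "\t", header = TRUE,
                    colClasses = c(id = "integer", weight = "numeric",
                                   expression = "character",
                                   location = "integer", range = "integer",
                                   signal = "character",
                                   category = "character"),
                    stringsAsFactors = FALSE)
  bad <- !stats::complete.cases(tab)
  if (any(bad)) {
    stop("malformed pattern row at line ", which(bad)[1L] + 1L, " of ", path)
  }
  validate_patterns(tab)
  dup <- duplicated(paste(tab$category, tab$id))
  if (any(dup)) {
    warning("duplicate pattern id(s) kept verbatim: ",
            paste(unique(tab$id[dup]), collapse = ", "))
  }
  tab
}

#' Packaged weighted pattern tables
#'
#' Returns the uniframe (UFP) or multiframe (MFP) weighted pattern table
#' shipped with the package: 12 UFP rows and 45 MFP rows covering both the
#' 5SS and 3SS windows, each with its published relative-importance weight.
#' The MFP table contains a repeated id 25 (and no id 26), preserved as-is.
#'
#' @param category `"UFP"` or `"MFP"`.
#' @return data frame of pattern rows.
#' @examples
#' ufp <- packaged_patterns("UFP")
#' nrow(ufp)        # 12
#' min(ufp$weight)  # 1.00
#' @export
packaged_patterns <- function(category = c("UFP", "MFP")) {
  category <- match.arg(category)
  fname <- if (category == "UFP") "ufp_table.tsv" else "mfp_table.tsv"
  path <- system.file("extdata", fname, package = "spliceweights",
                      mustWork = TRUE)
  suppressWarnings(load_pattern_table(path))
}

# Eligible start positions for one pattern row: starts within
# [location, location + range - 1] whose 3-mer still fits in the window.
eligible_starts <- function(location, range, window_len = WINDOW_LEN) {
  first <- location
  last <- min(location + range - 1L, window_len - 2L)
  if (last < first) integer(0) else seq.int(first, last)
}

count_occurrences <- function(window, expression, location, range) {
  starts <- eligible_starts(location, range, nchar(window))
  if (length(starts) == 0L) return(0L)
  kmers <- substring(window, starts, starts + 2L)
  sum(kmers == expression)
}

#' Encode a sequence record as per-pattern occurrence counts
#'
#' For each pattern row, counts the (possibly overlapping) occurrences of its
#' 3-mer starting inside `[location, location + range - 1]` on the window
#' named by the pattern's `signal` column. Counting is overlapping: every
#' eligible start position contributes independently, so a run of identical
#' bases yields one count per start.
#'
#' @param record one-row data frame (or list) with `record_id`, `window_5ss`,
#'   `window_3ss`.
#' @param patterns pattern table, all rows of the same `category`.
#' @param binary if `TRUE`, counts are reduced to 0/1 presence indicators.
#' @return named integer vector, one count per pattern row, in table order.
#' @export
encode_record <- function(record, patterns, binary = FALSE) {
  validate_patterns(patterns)
  if (length(unique(patterns$category)) > 1L) {
    stop("encode_record expects patterns of a single category")
  }
  windows <- c(`5SS` = record$window_5ss, `3SS` = record$window_3ss)
  counts <- vapply(seq_len(nrow(patterns)), function(j) {
    count_occurrences(windows[[patterns$signal[j]]], patterns$expression[j],
                      patterns$location[j], patterns$range[j])
  }, integer(1))
  if (binary) counts <- as.integer(counts > 0L)
  names(counts) <- paste0(patterns$category, "_", patterns$id, "_",
                          patterns$expression)
  counts
}

#' Encode a set of records into a feature matrix
#'
#' @param records data frame of sequence records (see [generate_dataset()]).
#' @param patterns pattern table, single category.
#' @inheritParams encode_record
#' @return integer matrix, one row per record (rownames `record_id`), one
#'   column per pattern row.
#' @export
encode_dataset <- function(records, patterns, binary = FALSE) {
  validate_patterns(patterns)
  rows <- lapply(seq_len(nrow(records)), function(i) {
    encode_record(records[i, ], patterns, binary = binary)
  })
  mat <- matrix(unlist(rows), nrow = nrow(records), ncol = nrow(patterns),
                byrow = TRUE)
  colnames(mat) <- paste0(patterns$category, "_", patterns$id, "_",
                          patterns$expression)
  rownames(mat) <- records$record_id
  mat
}
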