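#' Read and write epiallele pattern-count tables
#'
#' The portable on-disk format for per-sample epiallele pattern counts is
#' a TSV with the fixed header `sample  locus  pattern  count`, where
#' `pattern` is the 4-character '0'/'1' string (leftmost = lowest
#' genomic coordinate) and `count` a non-negative integer. In memory the
#' table is a `data.table` with `pattern` as the integer code 0-15.
#'
#' @param path file path.
#' @return `read_pattern_table` returns a `data.table` with columns
#'   `sample`, `locus`, `pattern` (integer 0-15), `count` (integer).
#' @examples
#' tab <- data.table::data.table(sample = "S1", locus = "chr1:1-10",
#'                               pattern = c(0L, 15L), count = c(3L, 7L))
#' f <- tempfile(fileext = ".tsv")
#' write_pattern_table(tab, f)
#' identical(read_pattern_table(f), tab)
#' @export
read_pattern_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  expected <- c("sample", "locus", "pattern", "count")
  first <- readLines(path, n = 1L)
  hdr <- if (length(first)) strsplit(first, "\t", fixed = TRUE)[[1L]] else character()
  if (!identical(hdr, expected)) {
    stop("pattern table must have header: ", paste(expected, collapse = ", "))
  }
  dt <- fread(path, sep = "\t", header = TRUE,
              colClasses = list(character = c("sample", "locus", "pattern")))
  if (nrow(dt) == 0L) {
    return(data.table(sample = character(), locus = character(),
                      pattern = integer(), count = integer()))
  }
  if (any(!grepl("^[01]{4}$", dt$pattern))) {
    stop("pattern outside the 16 4-CpG patterns")
  }
  cnt <- suppressWarnings(as.numeric(dt$count))
  if (any(is.na(cnt)) || any(cnt < 0) || any(cnt != round(cnt))) {
    stop("count must be a non-negative integer")
  }
  out <- data.table(sample = dt$sample, locus = dt$locus,
                    pattern = pattern_code(dt$pattern),
                    count = as.integer(cnt))
  if (anyDuplicated(out[, .(sample, locus, pattern)])) {
    stop("duplicate (sample, locus, pattern) rows")
  }
  out[]
}

#' @rdname read_pattern_table
#' @param table pattern-count `data.table` as returned by
#'   \code{\link{count_patterns}} or \code{\link{read_pattern_table}}.
#' @export
write_pattern_table <- function(table, path) {
  table <- .as_pattern_table(table)
  out <- data.table(sample = table$sample, locus = table$locus,
                    pattern = pattern_string(table$pattern),
                    count = table$count)
  fwrite(out, path, sep = "\t")
  invisible(path)
}

## Validate / coerce an in-memory pattern table.
.as_pattern_table <- function(table) {
  table <- as.data.table(table)
  need <- c("sample", "locus", "pattern", "count")
  if (!all(need %in% names(table))) {
    stop("pattern table needs columns: ", paste(need, collapse = ", "))
  }
  if (nrow(table) && (any(!table$pattern %in% 0:15) ||
                      any(table$count < 0) ||
                      any(table$count != round(table$count)))) {
    stop("invalid pattern table: pattern must be 0-15, count a non-negative integer")
  }
  table
}

#' Per-sample, per-locus read depth
#'
#' @inheritParams write_pattern_table
#' @return `data.table` with columns `sample`, `locus`, `depth`.
#' @export
locus_depths <- function(table) {
  table <- .as_pattern_table(table)
  table[, .(depth = sum(count)), by = .(sample, locus)]
}
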