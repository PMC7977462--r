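#' Convert between 4-character pattern strings and pattern codes
#'
#' Epiallele patterns are binary strings over the four CpGs of a locus,
#' leftmost character = lowest genomic coordinate ('0' unmethylated,
#' '1' methylated). Codes are the integers 0-15 with the leftmost
#' character as the most significant bit, so "0111" is code 7.
#'
#' @param pattern character vector of 4-character '0'/'1' strings.
#' @param code integer vector in 0..15.
#' @return `pattern_code` returns integer codes; `pattern_string` returns
#'   4-character strings; `pattern_bitcount` the number of methylated CpGs.
#' @examples
#' pattern_code("0111")     # 7
#' pattern_string(15)       # "1111"
#' pattern_bitcount(0:15)
#' @export
pattern_code <- function(pattern) {
  stopifnot(is.character(pattern))
  bad <- !grepl("^[01]{4}$", pattern)
  if (any(bad)) {
    stop("invalid pattern string(s): ", paste(unique(pattern[bad]), collapse = ", "))
  }
  m <- matrix(as.integer(unlist(strsplit(pattern, ""), use.names = FALSE)),
              ncol = 4L, byrow = TRUE)
  as.integer(m %*% c(8L, 4L, 2L, 1L))
}

#' @rdname pattern_code
#' @export
pattern_string <- function(code) {
  stopifnot(all(code %in% 0:15))
  bits <- sapply(c(8L, 4L, 2L, 1L), function(b) as.integer(bitwAnd(code, b) > 0))
  if (length(code) == 1L) bits <- matrix(bits, nrow = 1L)
  apply(bits, 1L, paste, collapse = "")
}

#' @rdname pattern_code
#' @export
pattern_bitcount <- function(code) {
  stopifnot(all(code %in% 0:15))
  bc <- c(0L, 1L, 1L, 2L, 1L, 2L, 2L, 3L, 1L, 2L, 2L, 3L, 2L, 3L, 3L, 4L)
  bc[code + 1L]
}

## 1-based inclusive locus id over the span of the four CG dinucleotides,
## from 0-based first-C and last-C coordinates.
.locus_id <- function(chrom, first0, last0) {
  sprintf("%s:%d-%d", chrom, first0 + 1L, last0 + 2L)
}

.is_count_vector16 <- function(x) {
  is.numeric(x) && length(x) == 16L && all(is.finite(x)) &&
    all(x >= 0) && all(x == round(x))
}
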