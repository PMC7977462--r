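#' Count 16 methylation patterns per locus from read profiles
#'
#' A fragment contributes to a locus if and only if it carries a known
#' (non-`NA`) call at all four CpG positions of the locus; its 4-bit
#' pattern (leftmost bit = lowest coordinate) then increments exactly one
#' of the 16 counters. Fragments covering fewer than four of the
#' positions, or with an unknown call at any of them, contribute nothing.
#'
#' @param profiles read profile `data.table` from
#'   \code{\link{extract_read_profiles}}.
#' @param loci loci table from \code{\link{enumerate_loci}}.
#' @param sample_id sample name recorded in the output.
#' @return pattern-count `data.table` (`sample`, `locus`, `pattern`,
#'   `count`); only observed (locus, pattern) combinations are listed.
#' @export
count_patterns <- function(profiles, loci, sample_id) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  empty <- data.table(sample = character(), locus = character(),
                      pattern = integer(), count = integer())
  if (!nrow(profiles) || !nrow(loci)) return(empty)
  ## long form: one row per (locus, CpG slot)
  long <- melt(as.data.table(loci), id.vars = c("locus", "chrom"),
               measure.vars = c("pos1", "pos2", "pos3", "pos4"),
               variable.name = "slot", value.name = "pos")
  long[, slot := as.integer(slot)]
  hits <- merge(long, profiles, by = c("chrom", "pos"),
                allow.cartesian = TRUE)
  if (!nrow(hits)) return(empty)
  pats <- hits[, .(
    n_known = sum(!is.na(state)),
    pat = sum(state * c(8L, 4L, 2L, 1L)[slot])
  ), by = .(locus, fragment)]
  pats <- pats[n_known == 4L]
  if (!nrow(pats)) return(empty)
  counts <- pats[, .(count = .N), by = .(locus, pat)]
  out <- data.table(sample = sample_id, locus = counts$locus,
                    pattern = as.integer(counts$pat),
                    count = as.integer(counts$count))
  setkey(out, locus, pattern)
  out[]
}

#' Coverage filter: keep loci covered by at least `min_reads` in every sample
#'
#' A locus survives iff its depth (sum of pattern counts) is at least
#' `min_reads` in all of the listed samples; the comparison is inclusive
#' (depth 10 passes the default filter).
#'
#' @inheritParams write_pattern_table
#' @param min_reads minimum read depth per sample (default 10).
#' @param samples samples required to pass; default all samples in the
#'   table.
#' @return the filtered pattern table (rows of surviving loci only, for
#'   the listed samples).
#' @export
filter_coverage <- function(table, min_reads = 10L, samples = NULL) {
  if (!is.numeric(min_reads) || length(min_reads) != 1L || min_reads < 1) {
    stop("min_reads must be >= 1")
  }
  table <- .as_pattern_table(table)
  if (is.null(samples)) samples <- unique(table$sample)
  if (!length(samples)) stop("need at least one sample")
  table <- table[sample %in% samples]
  dep <- locus_depths(table)
  ok <- dep[depth >= min_reads, .N, by = locus][N == length(samples), locus]
  table[locus %in% ok]
}

#' Loci present in all samples of a table
#'
#' The set intersection of the loci observed (post-filter) in each of the
#' given samples — the "background" loci all downstream comparisons use.
#'
#' @inheritParams filter_coverage
#' @return character vector of locus ids.
#' @export
shared_loci <- function(table, samples = NULL) {
  table <- .as_pattern_table(table)
  if (is.null(samples)) samples <- unique(table$sample)
  if (length(samples) < 2L) stop("need at least 2 samples")
  per <- lapply(samples, function(s) unique(table[sample == s, locus]))
  Reduce(intersect, per)
}

#' Dense 16-pattern count vector for one sample at one locus
#'
#' @inheritParams write_pattern_table
#' @param sample_id,locus_id the sample and locus to extract.
#' @return integer vector of length 16 (named by pattern string).
#' @export
pattern_counts <- function(table, sample_id, locus_id) {
  table <- .as_pattern_table(table)
  rows <- table[sample == sample_id & locus == locus_id]
  v <- integer(16L)
  v[rows$pattern + 1L] <- rows$count
  names(v) <- pattern_string(0:15)
  v
}
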