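#' Enumerate 4-CpG epiallele loci from a CpG index
#'
#' An epiallele locus is a window of four consecutive CpG sites (no CpG
#' between them). By default all sliding windows are produced
#' (overlapping allowed); `disjoint = TRUE` tiles the index into
#' non-overlapping consecutive quadruples instead. Chromosomes with
#' fewer than 4 CpGs yield no loci.
#'
#' Locus ids are rendered 1-based inclusive over the span of the four CG
#' dinucleotides, e.g. `"chr6:155314465-155314568"`.
#'
#' @param index CpG index from \code{\link{index_cpg_sites}}.
#' @param disjoint if TRUE, non-overlapping tiling instead of sliding
#'   windows.
#' @return `data.table` with columns `locus`, `chrom`, `pos1`..`pos4`
#'   (0-based CpG C coordinates, ascending).
#' @examples
#' enumerate_loci(index_cpg_sites(c(chr1 = "CGCGCGCGCG")))
#' @export
enumerate_loci <- function(index, disjoint = FALSE) {
  out <- lapply(names(index), function(chrom) {
    p <- index[[chrom]]
    n <- length(p)
    if (n < 4L) return(NULL)
    first <- if (disjoint) seq(1L, n - 3L, by = 4L) else seq_len(n - 3L)
    data.table(
      locus = .locus_id(chrom, p[first], p[first + 3L]),
      chrom = chrom,
      pos1 = p[first], pos2 = p[first + 1L],
      pos3 = p[first + 2L], pos4 = p[first + 3L]
    )
  })
  res <- rbindlist(out)
  if (!nrow(res)) {
    res <- data.table(locus = character(), chrom = character(),
                      pos1 = integer(), pos2 = integer(),
                      pos3 = integer(), pos4 = integer())
  }
  res[]
}

#' Write epiallele loci as BED
#'
#' BED is 0-based half-open, so a locus spanning CpG Cs at `pos1..pos4`
#' covers `[pos1, pos4 + 2)` (through the G of the last dinucleotide).
#'
#' @param loci loci table from \code{\link{enumerate_loci}}.
#' @param path output file.
#' @export
write_loci_bed <- function(loci, path) {
  stopifnot(all(c("locus", "chrom", "pos1", "pos4") %in% names(loci)))
  bed <- data.table(chrom = loci$chrom, start = loci$pos1,
                    end = loci$pos4 + 2L, name = loci$locus)
  fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
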