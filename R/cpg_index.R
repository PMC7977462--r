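#' Index forward-strand CpG sites of a reference
#'
#' Scans each reference sequence for CG dinucleotides and records the
#' 0-based coordinate of the C. This coordinate system is shared by all
#' downstream loci: reads informing the G on the reverse strand are
#' mapped back to the same forward-strand C (CpG symmetry), so both
#' strands contribute to one site. Dinucleotides containing N are not
#' CpGs and are excluded.
#'
#' @param reference a `Biostrings::DNAStringSet`, a named character vector
#'   of sequences, or the path to a FASTA file.
#' @return named list (one element per sequence) of strictly increasing
#'   integer vectors of 0-based CpG C positions.
#' @examples
#' index_cpg_sites(c(chr1 = "ACGTCGCG"))  # list(chr1 = c(1, 4, 6))
#' @export
index_cpg_sites <- function(reference) {
  seqs <- .as_dnastringset(reference)
  hits <- Biostrings::vmatchPattern("CG", seqs, fixed = TRUE)
  starts <- Biostrings::startIndex(hits)
  idx <- lapply(starts, function(s) if (is.null(s)) integer() else as.integer(s) - 1L)
  names(idx) <- names(seqs)
  idx
}

.as_dnastringset <- function(reference) {
  if (methods::is(reference, "DNAStringSet")) return(reference)
  if (is.character(reference) && length(reference) == 1L && file.exists(reference)) {
    seqs <- tryCatch(Biostrings::readDNAStringSet(reference),
                     error = function(e) stop("malformed FASTA: ", conditionMessage(e)))
    ## FASTA headers may carry descriptions after the sequence name
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    return(seqs)
  }
  if (is.character(reference)) {
    if (is.null(names(reference))) stop("reference sequences must be named")
    bad <- grepl("[^ACGTNacgtn]", reference)
    if (any(bad)) stop("reference sequences must be A/C/G/T/N text")
    return(Biostrings::DNAStringSet(toupper(reference)))
  }
  stop("reference must be a DNAStringSet, named character vector, or FASTA path")
}
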