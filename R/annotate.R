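#' Classify epiallele loci by gene context
#'
#' Assigns each locus one gene-context label by its midpoint:
#' `promoter` if the midpoint falls within TSS-1500 to TSS+500
#' (strand-adjusted, the downstream bound exclusive); otherwise
#' `five_prime_utr` / `exon` / `intron` by overlap with gene structure;
#' otherwise `intergenic`. Precedence is promoter > 5'UTR > exon >
#' intron across all overlapping genes, with nearest TSS breaking ties
#' within a class. Membership is decided by the locus midpoint, not span
#' overlap, so every locus gets exactly one label.
#'
#' @param loci loci table from \code{\link{enumerate_loci}} (columns
#'   `locus`, `chrom`, `pos1`, `pos4`).
#' @param genes gene models: a data.frame with columns `gene_id`,
#'   `chrom`, `strand` (`"+"`/`"-"`), `tx_start`, `tx_end`, `cds_start`,
#'   `cds_end` (0-based half-open), `exon_starts`, `exon_ends`
#'   (comma-separated 0-based half-open lists), as in
#'   \code{\link{read_gene_models}}.
#' @param promoter_upstream,promoter_downstream promoter window around
#'   the TSS in bp (defaults 1500 upstream, 500 downstream).
#' @return character vector of labels, one per locus.
#' @export
classify_gene_context <- function(loci, genes,
                                  promoter_upstream = 1500L,
                                  promoter_downstream = 500L) {
  genes <- copy(as.data.table(genes))
  mid <- .locus_midpoints(loci)
  labels <- rep("intergenic", nrow(loci))
  if (!nrow(genes)) return(labels)
  stopifnot(all(genes$strand %in% c("+", "-")))
  genes[, tss := ifelse(strand == "+", tx_start, tx_end - 1L)]
  for (i in seq_len(nrow(loci))) {
    g <- genes[chrom == loci$chrom[i]]
    if (!nrow(g)) next
    m <- mid[i]
    best_rank <- 5L; best_dist <- Inf
    for (j in seq_len(nrow(g))) {
      rank <- .gene_rank(m, g[j], promoter_upstream, promoter_downstream)
      if (is.na(rank)) next
      d <- abs(m - g$tss[j])
      if (rank < best_rank || (rank == best_rank && d < best_dist)) {
        best_rank <- rank; best_dist <- d
      }
    }
    labels[i] <- c("promoter", "five_prime_utr", "exon", "intron",
                   "intergenic")[best_rank]
  }
  labels
}

## Context rank of midpoint m for one gene row:
## 1 promoter, 2 five_prime_utr, 3 exon, 4 intron, NA outside the gene.
.gene_rank <- function(m, g, up, down) {
  d <- if (g$strand == "+") m - g$tss else g$tss - m
  if (d >= -up && d < down) return(1L)
  if (m < g$tx_start || m >= g$tx_end) return(NA_integer_)
  ex_s <- as.integer(strsplit(g$exon_starts, ",")[[1L]])
  ex_e <- as.integer(strsplit(g$exon_ends, ",")[[1L]])
  in_exon <- any(m >= ex_s & m < ex_e)
  if (in_exon && g$cds_start < g$cds_end) {
    before_cds <- if (g$strand == "+") m < g$cds_start else m >= g$cds_end
    if (before_cds) return(2L)
  }
  if (in_exon) 3L else 4L
}

#' Classify epiallele loci by CpG-density context
#'
#' Labels each locus midpoint as `island` (within a CpG island),
#' `shore` (within the 2 kb flanks of an island, islands removed),
#' `shelf` (within the next 2 kb beyond the shores, islands and shores
#' removed), or `opensea` (everything else). The four classes partition
#' the genome for any island set.
#'
#' @inheritParams classify_gene_context
#' @param cgis CpG islands: a data.frame with columns `chrom`, `start`,
#'   `end` (0-based half-open), e.g. from \code{\link{read_bed3}};
#'   overlapping islands are merged first.
#' @param flank width in bp of each flank tier (default 2000).
#' @return character vector of labels, one per locus.
#' @export
classify_cpg_context <- function(loci, cgis, flank = 2000L) {
  cgis <- as.data.table(cgis)
  mid <- .locus_midpoints(loci)
  labels <- rep("opensea", nrow(loci))
  if (!nrow(cgis)) return(labels)
  for (ch in unique(loci$chrom)) {
    sel <- which(loci$chrom == ch)
    cg <- cgis[chrom == ch]
    if (!nrow(cg) || !length(sel)) next
    ir <- IRanges::reduce(IRanges::IRanges(start = cg$start + 1L, end = cg$end))
    pts <- IRanges::IRanges(start = mid[sel] + 1L, width = 1L)
    dmin <- suppressWarnings(
      do.call(pmin, lapply(seq_along(ir), function(k)
        IRanges::distance(pts, rep(ir[k], length(pts))))))
    on_island <- IRanges::overlapsAny(pts, ir)
    labels[sel] <- ifelse(on_island, "island",
                   ifelse(dmin < flank, "shore",
                   ifelse(dmin < 2L * flank, "shelf", "opensea")))
  }
  labels
}

#' Annotate epiallele loci with gene and CpG-density context
#'
#' @inheritParams classify_gene_context
#' @inheritParams classify_cpg_context
#' @return the loci table with added `midpoint`, and `gene_context` /
#'   `cpg_context` columns for whichever annotation sets are supplied.
#' @export
annotate_loci <- function(loci, genes = NULL, cgis = NULL) {
  out <- as.data.table(loci)
  out[, midpoint := .locus_midpoints(loci)]
  if (!is.null(genes)) out[, gene_context := classify_gene_context(loci, genes)]
  if (!is.null(cgis)) out[, cpg_context := classify_cpg_context(loci, cgis)]
  out[]
}

## 0-based midpoint of the locus span [pos1, pos4 + 2).
.locus_midpoints <- function(loci) {
  stopifnot(all(c("chrom", "pos1", "pos4") %in% names(loci)))
  as.integer(floor((loci$pos1 + loci$pos4 + 2L) / 2))
}

#' Read a 3+ column BED file (e.g. CpG islands)
#'
#' @param path BED file; only the first three columns are used.
#' @return `data.table` with columns `chrom`, `start`, `end` (0-based
#'   half-open).
#' @export
read_bed3 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- fread(path, header = FALSE, select = 1:3,
              col.names = c("chrom", "start", "end"))
  if (nrow(dt) && (!is.numeric(dt$start) || !is.numeric(dt$end) ||
                   any(dt$end < dt$start))) {
    stop("malformed BED intervals")
  }
  dt[]
}

#' Read gene models from a genePred-like TSV
#'
#' Expected columns (tab-separated, with header): `gene_id`, `chrom`,
#' `strand`, `tx_start`, `tx_end`, `cds_start`, `cds_end`,
#' `exon_starts`, `exon_ends`; coordinates 0-based half-open, exon lists
#' comma-separated. Non-coding transcripts have `cds_start == cds_end`.
#'
#' @param path file path.
#' @return `data.table` of gene models.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  need <- c("gene_id", "chrom", "strand", "tx_start", "tx_end",
            "cds_start", "cds_end", "exon_starts", "exon_ends")
  dt <- fread(path, header = TRUE,
              colClasses = list(character = c("exon_starts", "exon_ends")))
  if (!all(need %in% names(dt))) {
    stop("gene model table needs columns: ", paste(need, collapse = ", "))
  }
  dt[]
}
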