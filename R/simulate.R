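#' Simulate a multi-region RRBS epiallele cohort with ground truth
#'
#' Emulates the study design the detection methods target: one tumor
#' core plus `n_peripheries` tumor periphery samples sharing a common
#' set of 4-CpG loci, with reads drawn i.i.d. multinomially from each
#' sample's per-locus 16-pattern mixture at a fixed depth. Null loci
#' share a single mixture across all samples; differential loci follow
#' the chosen effect model:
#' \describe{
#'   \item{`"core_vs_periphery"`}{the core is a uniform 16-pattern
#'     mixture while every periphery is a fully-methylated (`"1111"`)
#'     point mass — a maximal disorder contrast.}
#'   \item{`"sample_specific"`}{one sample (the assigned sample) gets the
#'     uniform mixture while all others share the null mixture.}
#' }
#'
#' Null mixtures emulate the bimodal methylation landscape of RRBS: a
#' per-locus methylation level drawn from Beta(0.4, 0.4), patterns
#' formed as independent products over the four sites, mixed with a
#' small uniform "disorder" component.
#'
#' @param n_null number of null (shared-mixture) loci.
#' @param n_differential number of differential loci.
#' @param n_peripheries number of periphery samples (default 4).
#' @param depth reads per locus per sample (default 25).
#' @param effect effect model for differential loci (see Details).
#' @param specific_sample for `"sample_specific"`: the sample the
#'   differential loci are specific to; default the core.
#' @param disorder weight of the uniform component in null mixtures.
#' @param core_name name of the core sample.
#' @param seed optional integer seed; identical seeds give identical
#'   cohorts.
#' @return list with `table` (pattern-count `data.table` for all
#'   samples), `truth` (`data.table`: `locus`, `is_differential`,
#'   `assigned_sample`), `loci` (locus table with coordinates on the
#'   synthetic chromosome `sim1`), `samples` (named vector of roles),
#'   and `mixtures` (per-locus generating distributions, per sample
#'   group).
#' @export
simulate_cohort <- function(n_null = 500L, n_differential = 20L,
                            n_peripheries = 4L, depth = 25L,
                            effect = c("core_vs_periphery", "sample_specific"),
                            specific_sample = NULL, disorder = 0.05,
                            core_name = "C1", seed = NULL) {
  effect <- match.arg(effect)
  stopifnot(n_null >= 0, n_differential >= 0, n_null + n_differential >= 1,
            n_peripheries >= 1, depth >= 1, disorder >= 0, disorder <= 1)
  if (!is.null(seed)) set.seed(seed)
  n_loci <- n_null + n_differential
  loci <- .sim_layout(n_loci)
  samples <- c(core_name, paste0("P", seq_len(n_peripheries)))
  roles <- setNames(c("core", rep("periphery", n_peripheries)), samples)
  if (is.null(specific_sample)) specific_sample <- core_name
  stopifnot(specific_sample %in% samples)

  is_diff <- rep(FALSE, n_loci)
  if (n_differential > 0) {
    is_diff[sample.int(n_loci, n_differential)] <- TRUE
  }
  uniform16 <- rep(1 / 16, 16L)
  point1111 <- c(rep(0, 15L), 1)

  mixtures <- vector("list", n_loci)
  rows <- vector("list", n_loci)
  for (l in seq_len(n_loci)) {
    if (!is_diff[l]) {
      p <- .null_mixture(disorder)
      per_sample <- rep(list(p), length(samples))
    } else if (effect == "core_vs_periphery") {
      per_sample <- lapply(samples, function(s)
        if (s == core_name) uniform16 else point1111)
    } else {
      p0 <- .null_mixture(disorder)
      per_sample <- lapply(samples, function(s)
        if (s == specific_sample) uniform16 else p0)
    }
    names(per_sample) <- samples
    mixtures[[l]] <- per_sample
    cnts <- lapply(samples, function(s)
      as.integer(rmultinom(1L, depth, per_sample[[s]])))
    sub <- rbindlist(lapply(seq_along(samples), function(si) {
      cv <- cnts[[si]]
      nz <- which(cv > 0L)
      data.table(sample = samples[si], locus = loci$locus[l],
                 pattern = nz - 1L, count = cv[nz])
    }))
    rows[[l]] <- sub
  }
  table <- rbindlist(rows)
  setkey(table, sample, locus, pattern)
  truth <- data.table(
    locus = loci$locus, is_differential = is_diff,
    assigned_sample = ifelse(is_diff,
      if (effect == "core_vs_periphery") core_name else specific_sample,
      NA_character_))
  names(mixtures) <- loci$locus
  list(table = table[], truth = truth, loci = loci,
       samples = roles, mixtures = mixtures)
}

## Deterministic layout: locus j occupies a 60 bp block on "sim1" with
## CpG Cs at block + 10/18/26/34; all other bases are T, so the block
## layout introduces no CpGs beyond the intended ones.
.sim_layout <- function(n_loci, chrom = "sim1") {
  base <- (seq_len(n_loci) - 1L) * 60L
  p1 <- base + 10L; p2 <- base + 18L; p3 <- base + 26L; p4 <- base + 34L
  data.table(locus = .locus_id(chrom, p1, p4), chrom = chrom,
             pos1 = p1, pos2 = p2, pos3 = p3, pos4 = p4)
}

## Bimodal null pattern mixture: independent-site product at a
## Beta(0.4, 0.4) methylation level, plus a uniform disorder component.
.null_mixture <- function(disorder) {
  m <- rbeta(1L, 0.4, 0.4)
  bits <- pattern_bitcount(0:15)
  p <- m^bits * (1 - m)^(4L - bits)
  (1 - disorder) * p + disorder / 16
}

#' Emit simulated alignments (SAM) and reference (FASTA) for a cohort
#'
#' Writes a Bismark-style alignment file per sample: one forward-strand
#' record per simulated fragment, exactly covering its locus, with a SEQ
#' consistent with the bisulfite-converted pattern (C at methylated
#' CpGs, T at unmethylated CpGs) and an XM methylation-call tag (Z/z at
#' the CpG positions). Round-tripping these files through
#' \code{\link{extract_read_profiles}} and \code{\link{count_patterns}}
#' reproduces the input pattern table exactly.
#'
#' @param table pattern-count table (all samples) as produced by
#'   \code{\link{simulate_cohort}}.
#' @param loci locus table with coordinates (`simulate_cohort()$loci`).
#' @param dir output directory (created if needed).
#' @return list with `fasta` (reference path) and `sam` (named vector of
#'   per-sample SAM paths).
#' @export
emit_reads <- function(table, loci, dir) {
  table <- .as_pattern_table(table)
  loci <- as.data.table(loci)
  if (!all(table$locus %in% loci$locus)) {
    stop("table contains loci not representable on the generated reference")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  chrom <- unique(loci$chrom)
  stopifnot(length(chrom) == 1L)
  ref_len <- max(loci$pos4) + 20L
  ref <- rep("T", ref_len)
  for (col in c("pos1", "pos2", "pos3", "pos4")) {
    ref[loci[[col]] + 1L] <- "C"
    ref[loci[[col]] + 2L] <- "G"
  }
  ref_str <- paste(ref, collapse = "")
  fasta <- file.path(dir, "reference.fa")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(ref_str, chrom)), fasta)

  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", chrom, ref_len))
  sams <- character(0)
  tab <- merge(table, loci, by = "locus")
  for (s in unique(tab$sample)) {
    st <- tab[sample == s]
    lines <- character(0)
    for (i in seq_len(nrow(st))) {
      r <- st[i]
      lines <- c(lines, .sim_sam_records(r, ref, chrom))
    }
    path <- file.path(dir, paste0(s, ".sam"))
    writeLines(c(header, lines), path)
    sams[s] <- path
  }
  list(fasta = fasta, sam = sams)
}

## SAM records for one (sample, locus, pattern, count) row.
.sim_sam_records <- function(r, ref, chrom) {
  start0 <- r$pos1
  end0 <- r$pos4 + 1L                       # cover through the last G
  len <- end0 - start0 + 1L
  offs <- c(r$pos1, r$pos2, r$pos3, r$pos4) - start0 + 1L
  bits <- as.integer(intToBits(r$pattern))[4:1]   # leftmost = lowest coord
  seq_chars <- ref[(start0 + 1L):(end0 + 1L)]
  seq_chars[offs] <- ifelse(bits == 1L, "C", "T")
  xm <- rep(".", len)
  xm[offs] <- ifelse(bits == 1L, "Z", "z")
  qname <- sprintf("%s_%s_p%02d_%d", r$sample, gsub("[:\\-]", "_", r$locus),
                   r$pattern, seq_len(r$count))
  sprintf("%s\t0\t%s\t%d\t42\t%dM\t*\t0\t0\t%s\t*\tXM:Z:%s",
          qname, chrom, start0 + 1L, len,
          paste(seq_chars, collapse = ""), paste(xm, collapse = ""))
}
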