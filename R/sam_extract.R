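#' Extract per-fragment CpG methylation calls from bisulfite alignments
#'
#' Reduces Bismark-style SAM/BAM alignments to read-level binary
#' methylation calls at indexed CpG sites. In `"tag"` mode (default) the
#' per-base methylation-call string (XM tag; `Z` = methylated CpG, `z` =
#' unmethylated CpG) is used; in `"reference"` mode calls are made by
#' comparing the read base with the reference at CpG positions (C/T on
#' forward-strand reads, G/A on reverse-strand reads). Either way a call
#' is recorded at the forward-strand C coordinate of its CpG, so both
#' strands contribute to one site.
#'
#' Unmapped, secondary and supplementary records are skipped. Records
#' lacking the XM tag in tag mode are skipped and counted (attribute
#' `n_skipped`). When `merge_mates = TRUE` the two mates of a pair are
#' merged into one fragment; a position where the mates disagree becomes
#' an unknown call (`NA`).
#'
#' @param path SAM or BAM file (SAM text is converted on the fly).
#' @param index CpG index from \code{\link{index_cpg_sites}}.
#' @param mode `"tag"` (Bismark XM string) or `"reference"` (base
#'   comparison; requires `reference`).
#' @param reference reference sequences (FASTA path, named character
#'   vector, or `DNAStringSet`); required for `mode = "reference"`.
#' @param merge_mates merge paired mates into one fragment (default TRUE);
#'   if FALSE each record is its own fragment.
#' @return `data.table` with columns `fragment`, `chrom`, `pos` (0-based
#'   forward-strand C coordinate), `state` (1 methylated, 0 unmethylated,
#'   `NA` unknown/conflicting), one row per fragment x position; attribute
#'   `n_skipped` counts records dropped for missing tags or CIGAR/position
#'   inconsistencies.
#' @export
extract_read_profiles <- function(path, index,
                                  mode = c("tag", "reference"),
                                  reference = NULL,
                                  merge_mates = TRUE) {
  mode <- match.arg(mode)
  if (mode == "reference") {
    if (is.null(reference)) stop("mode = 'reference' requires a reference")
    refseqs <- .as_dnastringset(reference)
  }
  bam <- .ensure_bam(path)
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq"),
    tag = "XM", flag = flags)
  rec <- Rsamtools::scanBam(bam, param = param)[[1L]]
  n <- length(rec$qname)
  n_skipped <- 0L
  rows <- vector("list", n)
  xm_all <- rec$tag$XM
  if (is.null(xm_all)) xm_all <- rep(NA_character_, n)
  seq_all <- as.character(rec$seq)
  for (i in seq_len(n)) {
    chrom <- as.character(rec$rname[i])
    sites <- index[[chrom]]
    if (is.null(sites)) next
    map <- .cigar_ref_query(rec$cigar[i], rec$pos[i] - 1L)
    if (is.null(map)) { n_skipped <- n_skipped + 1L; next }
    if (mode == "tag") {
      xm <- xm_all[i]
      if (is.na(xm)) { n_skipped <- n_skipped + 1L; next }
      if (nchar(xm) != nchar(seq_all[i])) { n_skipped <- n_skipped + 1L; next }
      ch <- strsplit(xm, "")[[1L]][map$qidx]
      is_call <- ch %in% c("Z", "z")
      if (!any(is_call)) next
      rpos <- map$rpos[is_call]
      st <- as.integer(ch[is_call] == "Z")
      ## assign to the forward C: either the call is at the C itself, or
      ## at the G of the dinucleotide (reverse-strand read)
      at_c <- rpos %in% sites
      at_g <- !at_c & (rpos - 1L) %in% sites
      keep <- at_c | at_g
      if (!any(keep)) next
      cpos <- ifelse(at_c[keep], rpos[keep], rpos[keep] - 1L)
      st <- st[keep]
    } else {
      base <- strsplit(seq_all[i], "")[[1L]][map$qidx]
      rev_read <- bitwAnd(rec$flag[i], 16L) > 0L
      if (!rev_read) {
        keep <- map$rpos %in% sites
        if (!any(keep)) next
        cpos <- map$rpos[keep]
        b <- base[keep]
        st <- ifelse(b == "C", 1L, ifelse(b == "T", 0L, NA_integer_))
      } else {
        keep <- (map$rpos - 1L) %in% sites
        if (!any(keep)) next
        cpos <- map$rpos[keep] - 1L
        b <- base[keep]
        st <- ifelse(b == "G", 1L, ifelse(b == "A", 0L, NA_integer_))
      }
    }
    frag <- if (merge_mates) rec$qname[i] else paste0(rec$qname[i], "/", i)
    rows[[i]] <- data.table(fragment = frag, chrom = chrom,
                            pos = as.integer(cpos), state = st)
  }
  prof <- rbindlist(rows)
  if (nrow(prof)) {
    ## merge duplicate observations of one position within a fragment;
    ## conflicting mate calls become unknown
    prof <- prof[, .(state = {
      s <- unique(state[!is.na(state)])
      if (length(s) == 1L) s else NA_integer_
    }), by = .(fragment, chrom, pos)]
  } else {
    prof <- data.table(fragment = character(), chrom = character(),
                       pos = integer(), state = integer())
  }
  setkey(prof, chrom, fragment, pos)
  setattr(prof, "n_skipped", n_skipped)
  prof
}

## SAM text is converted to a temporary BAM; BAM is used as is.
.ensure_bam <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.bam$", path, ignore.case = TRUE)) return(path)
  dest <- tempfile(fileext = "")
  Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = TRUE)
}

## Map a CIGAR onto (0-based reference position, 1-based query index)
## for aligned bases (M/=/X). Returns NULL on a malformed CIGAR.
.cigar_ref_query <- function(cigar, pos0) {
  if (is.na(cigar) || cigar == "*") return(NULL)
  m <- gregexpr("(\\d+)([MIDNSHP=X])", cigar)[[1L]]
  if (m[1L] == -1L) return(NULL)
  toks <- regmatches(cigar, gregexpr("\\d+|[MIDNSHP=X]", cigar))[[1L]]
  if (length(toks) %% 2L != 0L) return(NULL)
  lens <- as.integer(toks[seq(1L, length(toks), by = 2L)])
  ops <- toks[seq(2L, length(toks), by = 2L)]
  if (any(is.na(lens))) return(NULL)
  rpos <- integer(0); qidx <- integer(0)
  r <- pos0; q <- 0L
  for (k in seq_along(ops)) {
    len <- lens[k]
    op <- ops[k]
    if (op %in% c("M", "=", "X")) {
      rpos <- c(rpos, r + seq_len(len) - 1L)
      qidx <- c(qidx, q + seq_len(len))
      r <- r + len; q <- q + len
    } else if (op %in% c("I", "S")) {
      q <- q + len
    } else if (op %in% c("D", "N")) {
      r <- r + len
    } ## H, P consume nothing we track
  }
  list(rpos = rpos, qidx = qidx)
}
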