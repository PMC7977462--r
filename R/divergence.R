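#' Pattern probability distribution from counts
#'
#' Converts the 16 pattern counts of one epiallele locus into a
#' probability distribution. A pseudocount `epsilon` is added to the
#' probabilities (not the counts) and the vector renormalized, so the
#' result sums to exactly 1 for any `epsilon >= 0`:
#' \deqn{p'_i = (p_i + \epsilon) / (1 + 16\epsilon), \quad p_i = n_i / N.}
#' The pseudocount keeps every antilogarithm strictly positive so entropy
#' terms are finite even for patterns with zero observed reads.
#'
#' @param counts numeric vector of 16 non-negative integer pattern counts.
#' @param epsilon non-negative pseudocount added to each probability;
#'   default `6.25e-3`.
#' @return numeric vector of 16 probabilities summing to 1, with
#'   attribute `source_depth` (the total read count).
#' @examples
#' pattern_distribution(c(5, 5, rep(0, 14)), epsilon = 0)
#' @export
pattern_distribution <- function(counts, epsilon = 6.25e-3) {
  if (!.is_count_vector16(counts)) {
    stop("counts must be 16 non-negative integers")
  }
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon < 0) {
    stop("epsilon must be a single non-negative number")
  }
  depth <- sum(counts)
  if (depth < 1) stop("undefined distribution: locus depth is 0")
  p <- counts / depth
  p <- (p + epsilon) / (1 + 16 * epsilon)
  structure(p, source_depth = depth)
}

#' Shannon entropy of a pattern distribution, in bits
#'
#' \eqn{H(p) = -\sum_i p_i \log_2 p_i} with the convention
#' \eqn{0 \log 0 = 0}. For a 16-pattern epiallele distribution,
#' \eqn{0 \le H \le 4} bits.
#'
#' @param p numeric probability vector (must sum to 1 within 1e-9).
#' @return entropy in bits.
#' @examples
#' entropy(rep(1/16, 16))  # 4 bits
#' @export
entropy <- function(p) {
  if (!is.numeric(p) || any(p < 0)) stop("p must be a non-negative numeric vector")
  if (abs(sum(p) - 1) > 1e-9) stop("p is not normalized (sum differs from 1 by > 1e-9)")
  nz <- p > 0
  -sum(p[nz] * log2(p[nz]))
}

#' Jensen-Shannon divergence of two pattern distributions
#'
#' \eqn{JS(p, q) = H((p+q)/2) - (H(p) + H(q))/2} with entropies in bits,
#' so that \eqn{JS \in [0, 1]} for any two distributions; 0 iff
#' \eqn{p = q}, 1 iff the supports are disjoint. Symmetric in its
#' arguments. The result is clamped to \[0, 1\] to absorb floating-point
#' round-off (JS can come out as -1e-17 numerically).
#'
#' @param p,q probability vectors of equal length, each summing to 1.
#' @return the divergence, in \[0, 1\].
#' @examples
#' js_divergence(c(0.5, 0.5, rep(0, 14)), c(1, rep(0, 15)))
#' @export
js_divergence <- function(p, q) {
  if (length(p) != length(q)) stop("p and q must have the same length")
  h <- entropy((p + q) / 2) - (entropy(p) + entropy(q)) / 2
  min(max(h, 0), 1)
}

#' Jensen-Shannon dissimilarity (JSD) of two epiallele count vectors
#'
#' The dissimilarity between two samples at one epiallele locus: the
#' square root of the Jensen-Shannon divergence between their
#' pseudocount-adjusted 16-pattern distributions. By the theorem of
#' Fuglede and Topsoe the square root of JS is a metric, so `jsd`
#' satisfies the triangle inequality and is bounded in \[0, 1\].
#'
#' @param counts_a,counts_b numeric vectors of 16 non-negative pattern
#'   counts, each with depth >= 1.
#' @inheritParams pattern_distribution
#' @return the JSD, in \[0, 1\]; 0 iff the two adjusted distributions are
#'   identical.
#' @examples
#' a <- c(100, rep(0, 15)); b <- c(rep(0, 15), 100)
#' jsd(a, b, epsilon = 0)  # 1: disjoint point masses
#' @export
jsd <- function(counts_a, counts_b, epsilon = 6.25e-3) {
  p <- pattern_distribution(counts_a, epsilon)
  q <- pattern_distribution(counts_b, epsilon)
  sqrt(js_divergence(p, q))
}

## Vectorized row-wise JSD between two L x 16 count matrices.
## Same math as jsd(); used by the per-locus comparison tables.
.jsd_rows <- function(A, B, epsilon) {
  stopifnot(ncol(A) == 16L, ncol(B) == 16L, nrow(A) == nrow(B))
  da <- rowSums(A)
  db <- rowSums(B)
  if (any(da < 1) || any(db < 1)) stop("undefined distribution: zero-depth locus")
  P <- (A / da + epsilon) / (1 + 16 * epsilon)
  Q <- (B / db + epsilon) / (1 + 16 * epsilon)
  hrow <- function(M) {
    X <- ifelse(M > 0, M * log2(M), 0)
    -rowSums(X)
  }
  js <- hrow((P + Q) / 2) - (hrow(P) + hrow(Q)) / 2
  sqrt(pmin(pmax(js, 0), 1))
}

#' Per-locus JSD table between sample pairs
#'
#' Computes the JSD at every locus shared by each requested pair of
#' samples in a pattern-count table.
#'
#' @param table a pattern-count `data.table` with columns
#'   `sample`, `locus`, `pattern`, `count` (see
#'   \code{\link{read_pattern_table}}).
#' @param pairs two-column character matrix (or data.frame) of sample
#'   pairs; default all unordered pairs of samples present.
#' @inheritParams pattern_distribution
#' @return `data.table` with columns `locus`, `sample_a`, `sample_b`,
#'   `jsd`, `depth_a`, `depth_b`.
#' @export
jsd_table <- function(table, pairs = NULL, epsilon = 6.25e-3) {
  table <- .as_pattern_table(table)
  samples <- sort(unique(table$sample))
  if (is.null(pairs)) {
    if (length(samples) < 2L) stop("need at least 2 samples")
    pairs <- t(utils::combn(samples, 2L))
  }
  pairs <- as.matrix(pairs)
  mats <- .counts_matrices(table)
  out <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    a <- pairs[k, 1L]; b <- pairs[k, 2L]
    if (!a %in% names(mats) || !b %in% names(mats)) {
      stop("unknown sample in pairs: ", a, " / ", b)
    }
    shared <- intersect(rownames(mats[[a]]), rownames(mats[[b]]))
    if (!length(shared)) next
    A <- mats[[a]][shared, , drop = FALSE]
    B <- mats[[b]][shared, , drop = FALSE]
    out[[k]] <- data.table(
      locus = shared, sample_a = a, sample_b = b,
      jsd = .jsd_rows(A, B, epsilon),
      depth_a = rowSums(A), depth_b = rowSums(B)
    )
  }
  rbindlist(out)
}

## Named list of per-sample L x 16 count matrices, rownames = locus ids.
.counts_matrices <- function(table) {
  table <- .as_pattern_table(table)
  split_tabs <- split(table, by = "sample")
  lapply(split_tabs, function(tt) {
    loci <- sort(unique(tt$locus))
    M <- matrix(0, nrow = length(loci), ncol = 16L,
                dimnames = list(loci, pattern_string(0:15)))
    M[cbind(match(tt$locus, loci), tt$pattern + 1L)] <- tt$count
    M
  })
}
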