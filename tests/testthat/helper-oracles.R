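## Independent brute-force JSD oracle: term-by-term evaluation of
## H(M) - (H(P) + H(Q))/2 with plain loops and natural-log arithmetic,
## sharing no code with the package implementation.
oracle_jsd <- function(a, b, epsilon = 0) {
  to_prob <- function(x) {
    p <- numeric(16)
    for (i in 1:16) p[i] <- x[i] / sum(x)
    for (i in 1:16) p[i] <- (p[i] + epsilon) / (1 + 16 * epsilon)
    p
  }
  H <- function(p) {
    h <- 0
    for (i in seq_along(p)) {
      if (p[i] > 0) h <- h - p[i] * log(p[i]) / log(2)
    }
    h
  }
  p <- to_prob(a)
  q <- to_prob(b)
  m <- numeric(16)
  for (i in 1:16) m[i] <- (p[i] + q[i]) / 2
  js <- H(m) - (H(p) + H(q)) / 2
  sqrt(max(js, 0))
}

## Random small-integer 16-pattern count vector with depth >= 1.
random_counts <- function(max_count = 20L) {
  repeat {
    v <- as.integer(sample(0:max_count, 16L, replace = TRUE) *
                      (runif(16) < 0.4))
    if (sum(v) >= 1L) return(v)
  }
}

## Dense 16-vector from a named pattern-string spec, e.g.
## counts_of("0000" = 5, "1111" = 5).
counts_of <- function(...) {
  spec <- c(...)
  v <- integer(16L)
  v[pattern_code(names(spec)) + 1L] <- as.integer(spec)
  v
}

## Minimal Bismark-style SAM file for extraction tests.
## reads: data.frame(qname, flag, pos1 (1-based), cigar, seq, xm);
## xm = NA omits the tag.
write_test_sam <- function(path, reads, chrom = "chr1", ref_len = 1000L) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", chrom, ref_len))
  recs <- vapply(seq_len(nrow(reads)), function(i) {
    r <- reads[i, ]
    base <- sprintf("%s\t%d\t%s\t%d\t42\t%s\t*\t0\t0\t%s\t*",
                    r$qname, r$flag, chrom, r$pos1, r$cigar, r$seq)
    if (is.na(r$xm)) base else paste0(base, "\tXM:Z:", r$xm)
  }, character(1))
  writeLines(c(header, recs), path)
  path
}

## Multi-sample null cohort where every sample draws from the same
## per-locus mixture (wrapper over the package simulator).
null_cohort <- function(n_loci, depth, n_samples = 4L, seed = 1L) {
  simulate_cohort(n_null = n_loci, n_differential = 0L,
                  n_peripheries = n_samples - 1L, depth = depth, seed = seed)
}
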