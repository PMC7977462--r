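#' Epipolymorphism of one epiallele locus
#'
#' \eqn{epipoly = 1 - \sum_i p_i^2} over the raw (no pseudocount)
#' 16-pattern probabilities. 0 for a pure pattern population; maximal at
#' the uniform mixture, \eqn{1 - 16/256 = 15/16 = 0.9375}. Invariant
#' under pattern relabeling.
#'
#' @param counts numeric vector of 16 non-negative pattern counts with
#'   depth >= 1.
#' @return value in \[0, 15/16\].
#' @examples
#' epipolymorphism(c(8, 8, rep(0, 14)))  # 0.5
#' @export
epipolymorphism <- function(counts) {
  if (!.is_count_vector16(counts)) stop("counts must be 16 non-negative integers")
  depth <- sum(counts)
  if (depth < 1) stop("undefined epipolymorphism: depth is 0")
  1 - sum((counts / depth)^2)
}

#' Classify a differential epiallele as drift or adaptation
#'
#' A differential epiallele whose epipolymorphism is higher in the tumor
#' core than in the periphery is a drift epiallele; lower is an
#' adaptation epiallele; exact ties get their own `"unchanged"` label
#' rather than silently joining either class.
#'
#' @param epipoly_core,epipoly_periphery epipolymorphism values in
#'   \[0, 15/16\] (vectorized).
#' @return character vector in `{"drift", "adaptation", "unchanged"}`.
#' @export
classify_drift <- function(epipoly_core, epipoly_periphery) {
  stopifnot(all(epipoly_core >= 0 & epipoly_core <= 15 / 16),
            all(epipoly_periphery >= 0 & epipoly_periphery <= 15 / 16))
  ifelse(epipoly_core > epipoly_periphery, "drift",
         ifelse(epipoly_core < epipoly_periphery, "adaptation", "unchanged"))
}

#' Methylation level of one epiallele locus
#'
#' The average methylation of the four CpG sites across all reads:
#' \eqn{\sum_i n_i \cdot \mathrm{bits}(i) / (4N)}.
#'
#' @inheritParams epipolymorphism
#' @return value in \[0, 1\].
#' @examples
#' cnt <- integer(16); cnt[pattern_code("0111") + 1] <- 4
#' epiallele_methylation(cnt)  # 0.75
#' @export
epiallele_methylation <- function(counts) {
  if (!.is_count_vector16(counts)) stop("counts must be 16 non-negative integers")
  depth <- sum(counts)
  if (depth < 1) stop("undefined methylation level: depth is 0")
  sum(counts * pattern_bitcount(0:15)) / (4 * depth)
}

#' Jaccard similarity of methylation state at two adjacent CpG sites
#'
#' Over the fragments carrying known calls at both sites,
#' \eqn{J = n_{11} / (n_{11} + n_{10} + n_{01})}: the fraction of
#' fragments methylated at either site that are methylated at both.
#' When no fragment is methylated at either site (all (0,0)), J is
#' defined as 1 (the states agree perfectly).
#'
#' @param profiles read profiles from \code{\link{extract_read_profiles}}.
#' @param chrom chromosome of the two sites.
#' @param site_a,site_b 0-based CpG positions.
#' @return value in \[0, 1\].
#' @export
adjacent_cpg_jaccard <- function(profiles, chrom, site_a, site_b) {
  ch <- chrom
  a <- profiles[chrom == ch & pos == site_a, .(fragment, sa = state)]
  b <- profiles[chrom == ch & pos == site_b, .(fragment, sb = state)]
  both <- merge(a, b, by = "fragment")
  both <- both[!is.na(sa) & !is.na(sb)]
  if (!nrow(both)) stop("no fragment covers both sites with known calls")
  n11 <- sum(both$sa == 1 & both$sb == 1)
  n10 <- sum(both$sa == 1 & both$sb == 0)
  n01 <- sum(both$sa == 0 & both$sb == 1)
  if (n11 + n10 + n01 == 0L) return(1)
  n11 / (n11 + n10 + n01)
}

#' Binned methylation-heterogeneity AUC
#'
#' Summarizes one sample's differential epialleles: their methylation
#' levels (in percent) are divided into 21 bins — the first
#' \eqn{[0, 2.5]}, the last \eqn{(97.5, 100]}, the rest of width 5 — and
#' the AUC is the sum over bins of bin width times the bin's median
#' epipolymorphism (an empty bin contributes 0). Bin widths sum to 100,
#' so the AUC ranges from 0 to 100. Exact methylation 0 falls in the
#' first bin, 100 in the last.
#'
#' @param methylation_percent numeric vector of per-locus methylation
#'   levels in percent (0-100).
#' @param epipoly numeric vector (same length) of per-locus
#'   epipolymorphism values in \[0, 15/16\].
#' @return the AUC, in \[0, 100\]; 0 for empty input.
#' @examples
#' heterogeneity_auc(c(1, 50, 99), c(0.2, 0.9, 0.1))
#' @export
heterogeneity_auc <- function(methylation_percent, epipoly) {
  if (length(methylation_percent) != length(epipoly)) {
    stop("methylation and epipolymorphism vectors must have the same length")
  }
  if (!length(epipoly)) return(0)
  stopifnot(all(methylation_percent >= 0 & methylation_percent <= 100),
            all(epipoly >= 0 & epipoly <= 15 / 16))
  breaks <- c(0, 2.5, seq(7.5, 97.5, by = 5), 100)
  widths <- diff(breaks)
  bin <- cut(methylation_percent, breaks = breaks, include.lowest = TRUE,
             right = TRUE, labels = FALSE)
  med <- numeric(length(widths))
  agg <- tapply(epipoly, bin, median)
  med[as.integer(names(agg))] <- agg
  sum(widths * med)
}

#' Per-sample heterogeneity summary over a set of differential epialleles
#'
#' Convenience wrapper computing, for one (core, periphery) pair and a
#' set of loci (typically that pair's CPDEs), the per-locus
#' epipolymorphism and methylation in both samples, the drift label, and
#' the per-sample AUC and drift fraction.
#'
#' @inheritParams filter_coverage
#' @param core,periphery the two sample names.
#' @param loci character vector of locus ids to summarize.
#' @return list with `per_locus` (`data.table`: `locus`, `epipoly_core`,
#'   `epipoly_periphery`, `meth_core`, `meth_periphery`, `drift_label`)
#'   and `summary` (`data.table`: `sample`, `auc`, `drift_fraction`,
#'   `adaptation_fraction`, `unchanged_fraction`).
#' @export
heterogeneity_summary <- function(table, core, periphery, loci) {
  table <- .as_pattern_table(table)
  mats <- .counts_matrices(table[sample %in% c(core, periphery)])
  loci <- intersect(loci, intersect(rownames(mats[[core]]),
                                    rownames(mats[[periphery]])))
  if (!length(loci)) stop("no loci to summarize")
  A <- mats[[core]][loci, , drop = FALSE]
  B <- mats[[periphery]][loci, , drop = FALSE]
  ep <- function(M) 1 - rowSums((M / rowSums(M))^2)
  ml <- function(M) as.vector(M %*% pattern_bitcount(0:15)) / (4 * rowSums(M))
  per_locus <- data.table(
    locus = loci,
    epipoly_core = ep(A), epipoly_periphery = ep(B),
    meth_core = ml(A), meth_periphery = ml(B))
  per_locus[, drift_label := classify_drift(epipoly_core, epipoly_periphery)]
  frac <- function(lbl) mean(per_locus$drift_label == lbl)
  summary <- data.table(
    sample = c(core, periphery),
    auc = c(heterogeneity_auc(per_locus$meth_core * 100, per_locus$epipoly_core),
            heterogeneity_auc(per_locus$meth_periphery * 100, per_locus$epipoly_periphery)),
    drift_fraction = frac("drift"),
    adaptation_fraction = frac("adaptation"),
    unchanged_fraction = frac("unchanged"))
  list(per_locus = per_locus[], summary = summary)
}
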