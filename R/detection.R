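#' Fit a one-tailed normal null threshold to a score distribution
#'
#' The empirical score distribution (pairwise JSDs, or composite
#' specificity indices) is approximated by a normal fitted by moment
#' estimation; the decision threshold is the upper one-tailed quantile
#' \eqn{\mu + z_{1-\alpha}\,\sigma}. With `robust = TRUE` the location
#' and scale are the median and MAD instead.
#'
#' @param scores numeric vector of at least 30 finite scores.
#' @param alpha one-tailed significance level (default 0.05).
#' @param robust use median/MAD instead of moment estimates.
#' @return object of class `epijsd_null`: list with `mu`, `sigma`,
#'   `alpha`, `threshold`.
#' @examples
#' fit_null_threshold(rnorm(1000, 0.1, 0.05))
#' @export
fit_null_threshold <- function(scores, alpha = 0.05, robust = FALSE) {
  scores <- as.numeric(scores)
  if (length(scores) < 30L) stop("need at least 30 scores to fit a null")
  if (any(!is.finite(scores))) stop("scores must be finite")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)")
  }
  if (robust) {
    mu <- median(scores)
    sigma <- mad(scores)
  } else {
    mu <- mean(scores)
    sigma <- sqrt(mean((scores - mu)^2))
  }
  if (sigma == 0) stop("degenerate null: score distribution has zero spread")
  structure(
    list(mu = mu, sigma = sigma, alpha = alpha,
         threshold = mu + qnorm(1 - alpha) * sigma),
    class = "epijsd_null")
}

#' @export
print.epijsd_null <- function(x, ...) {
  cat(sprintf("normal null: mu = %.4g, sigma = %.4g, alpha = %.3g, threshold = %.4g\n",
              x$mu, x$sigma, x$alpha, x$threshold))
  invisible(x)
}

#' Composite specificity index (CSI) of a score set
#'
#' The CSI contrasts the largest element of a set of JSD-derived scores
#' against the remaining ones: \eqn{CSI = \max(S) - \mathrm{mean}(S
#' \setminus \max)}. A higher CSI indicates that one comparison stands
#' out from the rest — e.g. a larger core-periphery discrepancy relative
#' to the periphery-periphery discrepancies. The algebra is isolated
#' here so an alternative contrast (such as max minus second max) can be
#' swapped in one place.
#'
#' @param s numeric vector of at least 2 scores.
#' @return list with `csi`, `argmax` (index of the first maximum), and
#'   `unique_max` (whether the maximum is attained exactly once — callers
#'   treat ties as ineligible).
#' @examples
#' csi_index(c(0.6, 0.10, 0.20, 0.15))  # csi = 0.45, argmax = 1
#' @export
csi_index <- function(s) {
  if (length(s) < 2L) stop("CSI needs at least 2 scores")
  i <- which.max(s)
  mx <- s[i]
  list(csi = mx - mean(s[-i]), argmax = i,
       unique_max = sum(s == mx) == 1L)
}

## Pairwise JSD array for a sample set: L x K x K symmetric slices,
## restricted to loci shared by all samples.
.jsd_array <- function(table, samples, epsilon) {
  shared <- shared_loci(table, samples)
  if (!length(shared)) stop("no loci shared by all samples")
  shared <- sort(shared)
  mats <- .counts_matrices(table[sample %in% samples])
  mats <- lapply(mats[samples], function(M) M[shared, , drop = FALSE])
  K <- length(samples)
  L <- length(shared)
  arr <- array(0, dim = c(L, K, K), dimnames = list(shared, samples, samples))
  for (a in seq_len(K - 1L)) {
    for (b in (a + 1L):K) {
      v <- .jsd_rows(mats[[a]], mats[[b]], epsilon)
      arr[, a, b] <- v
      arr[, b, a] <- v
    }
  }
  arr
}

#' Detect periphery-periphery differential epialleles (PPDEs)
#'
#' For every pair of periphery samples and every locus shared by all of
#' them, the JSD is computed; the detection threshold \eqn{\delta} is
#' fitted once to the pooled distribution of all pair JSDs
#' (\code{\link{fit_null_threshold}}), and a pair-locus is called a PPDE
#' iff its JSD exceeds \eqn{\delta}.
#'
#' @inheritParams filter_coverage
#' @param samples the periphery sample names (>= 2); default all samples
#'   in the table.
#' @param alpha one-tailed significance level for the fitted null.
#' @param epsilon pseudocount for pattern distributions.
#' @param robust robust null fitting (median/MAD).
#' @return list with `records` (`data.table`: `locus`, `sample_a`,
#'   `sample_b`, `jsd`, `call`) and `null` (the fitted `epijsd_null`,
#'   whose `threshold` is \eqn{\delta}).
#' @export
detect_ppde <- function(table, samples = NULL, alpha = 0.05,
                        epsilon = 6.25e-3, robust = FALSE) {
  table <- .as_pattern_table(table)
  if (is.null(samples)) samples <- sort(unique(table$sample))
  if (length(samples) < 2L) stop("need at least 2 periphery samples")
  pairs <- t(utils::combn(samples, 2L))
  rec <- jsd_table(table, pairs, epsilon)
  null <- fit_null_threshold(rec$jsd, alpha, robust)
  rec[, call := jsd > null$threshold]
  list(records = rec[, .(locus, sample_a, sample_b, jsd, call)], null = null)
}

#' Detect core-periphery differential epialleles (CPDEs)
#'
#' For each periphery sample \eqn{P_i} and each locus shared by all
#' samples, the composite specificity index contrasts the set \eqn{S_i}
#' of the JSDs between \eqn{P_i} and the other tumor samples (the core
#' and the remaining peripheries): \eqn{CSI = \max(S_i) -
#' \mathrm{mean}(S_i \setminus \max)}. Consistent loci whose JSDs are all
#' zero are removed first; a per-pair threshold `Thres1` is then fitted
#' to that pair's CSI distribution. A locus is called a CPDE for the pair
#' (core, \eqn{P_i}) iff
#' (i) \eqn{JSD(core, P_i) > \gamma},
#' (ii) the unique maximum of \eqn{S_i} is the core comparison, and
#' (iii) \eqn{CSI > Thres1}.
#'
#' @inheritParams detect_ppde
#' @param core name of the single core sample.
#' @param peripheries names of the periphery samples (>= 2; the study
#'   design uses 4).
#' @param gamma minimum core-periphery JSD (default 0.3).
#' @return list with `records` (`data.table`: `locus`, `periphery`,
#'   `jsd_core`, `csi`, `argmax_is_core`, `threshold`, `call`), `nulls`
#'   (per-periphery fitted nulls), and `summary` (per-pair call counts
#'   plus the union and intersection sizes across pairs).
#' @export
detect_cpde <- function(table, core, peripheries, gamma = 0.3,
                        alpha = 0.05, epsilon = 6.25e-3, robust = FALSE) {
  table <- .as_pattern_table(table)
  if (length(core) != 1L || !core %in% table$sample) {
    stop("exactly one core sample present in the table is required")
  }
  if (length(peripheries) < 2L) stop("need at least 2 periphery samples")
  if (core %in% peripheries) stop("core cannot also be a periphery")
  samples <- c(core, peripheries)
  arr <- .jsd_array(table, samples, epsilon)
  loci <- dimnames(arr)[[1L]]
  nulls <- list()
  recs <- vector("list", length(peripheries))
  for (pi in seq_along(peripheries)) {
    p <- peripheries[pi]
    others <- setdiff(samples, p)             # core first
    S <- arr[, p, others, drop = FALSE]
    dim(S) <- c(length(loci), length(others))
    keep <- rowSums(S != 0) > 0               # drop all-zero (consistent) loci
    Sk <- S[keep, , drop = FALSE]
    lk <- loci[keep]
    cs <- apply(Sk, 1L, csi_index)
    csi_v <- vapply(cs, `[[`, numeric(1), "csi")
    amax_core <- vapply(cs, function(z) z$unique_max && z$argmax == 1L, logical(1))
    null <- fit_null_threshold(csi_v, alpha, robust)
    nulls[[p]] <- null
    jsd_core <- Sk[, 1L]
    recs[[pi]] <- data.table(
      locus = lk, periphery = p, jsd_core = jsd_core, csi = csi_v,
      argmax_is_core = amax_core, threshold = null$threshold,
      call = jsd_core > gamma & amax_core & csi_v > null$threshold)
  }
  records <- rbindlist(recs)
  called <- records[call == TRUE]
  per_pair <- called[, .N, by = periphery]
  union_loci <- unique(called$locus)
  inter_loci <- if (nrow(called)) {
    called[, .(npairs = uniqueN(periphery)), by = locus][
      npairs == length(peripheries), locus]
  } else character()
  list(records = records, nulls = nulls,
       summary = list(per_pair = per_pair,
                      union = union_loci, intersection = inter_loci))
}

#' Detect local-specific epialleles across tumor samples
#'
#' For each sample \eqn{i} at each shared locus, \eqn{m_i} is the mean
#' JSD between sample \eqn{i} and the other tumor samples; over the set
#' \eqn{M = \{m_i\}}, \eqn{CSI = \max(M) - \mathrm{mean}(M \setminus
#' \max)} and the argmax sample is the candidate the epiallele is
#' specific to. Loci with all-zero \eqn{M}, or a tie at the maximum, are
#' ineligible. `Thres2` is fitted once to all eligible CSI values; a
#' locus is called specific to its argmax sample iff
#' (i) \eqn{\max(M) > \gamma}, (ii) the argmax is unique, and
#' (iii) \eqn{CSI > Thres2}.
#'
#' @inheritParams detect_cpde
#' @param samples the tumor sample names (>= 3); default all in the table.
#' @return list with `records` (`data.table`: `locus`, `assigned_sample`,
#'   `max_mean_jsd`, `csi`, `threshold`, `call`) and `null` (the fitted
#'   `epijsd_null` for `Thres2`).
#' @export
detect_local_specific <- function(table, samples = NULL, gamma = 0.3,
                                  alpha = 0.05, epsilon = 6.25e-3,
                                  robust = FALSE) {
  table <- .as_pattern_table(table)
  if (is.null(samples)) samples <- sort(unique(table$sample))
  if (length(samples) < 3L) stop("need at least 3 tumor samples")
  arr <- .jsd_array(table, samples, epsilon)
  loci <- dimnames(arr)[[1L]]
  K <- length(samples)
  ## m_i: mean JSD of sample i to the other samples, per locus
  M <- sapply(seq_len(K), function(i) rowSums(arr[, i, -i, drop = FALSE]) / (K - 1L))
  if (is.null(dim(M))) M <- matrix(M, nrow = 1L)
  eligible <- rowSums(M != 0) > 0
  cs <- apply(M[eligible, , drop = FALSE], 1L, csi_index)
  csi_v <- vapply(cs, `[[`, numeric(1), "csi")
  uniq <- vapply(cs, `[[`, logical(1), "unique_max")
  amax <- samples[vapply(cs, `[[`, integer(1), "argmax")]
  keep <- uniq                                 # ties at the max are ineligible
  if (sum(keep) < 30L) stop("too few eligible loci to fit the specificity null")
  null <- fit_null_threshold(csi_v[keep], alpha, robust)
  mmax <- apply(M[eligible, , drop = FALSE], 1L, max)
  records <- data.table(
    locus = loci[eligible], assigned_sample = amax,
    max_mean_jsd = mmax, csi = csi_v, unique_max = uniq,
    threshold = null$threshold,
    call = uniq & mmax > gamma & csi_v > null$threshold)
  list(records = records, null = null)
}
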