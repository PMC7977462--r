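test_that("epipolymorphism matches closed forms and is relabel-invariant", {
  expect_equal(epipolymorphism(counts_of("1111" = 12)), 0)
  expect_equal(epipolymorphism(rep(1L, 16)), 0.9375)
  expect_equal(epipolymorphism(counts_of("0000" = 8, "1111" = 8)), 0.5)
  expect_error(epipolymorphism(integer(16)), "depth")
  set.seed(3)
  for (i in 1:50) {
    v <- random_counts()
    expect_equal(epipolymorphism(v), epipolymorphism(v[sample(16)]))
    expect_lte(epipolymorphism(v), 0.9375)
  }
  ## uniform maximizes over all 2-pattern and 4-pattern splits of 16 reads
  best <- max(sapply(1:15, function(k)
    epipolymorphism(counts_of("0000" = k, "1111" = 16L - k))))
  expect_lt(best, epipolymorphism(rep(1L, 16)))
})

test_that("drift classification compares core vs periphery epipolymorphism", {
  expect_equal(classify_drift(0.6, 0.4), "drift")
  expect_equal(classify_drift(0.2, 0.5), "adaptation")
  expect_equal(classify_drift(0.3, 0.3), "unchanged")
  expect_equal(classify_drift(c(0.6, 0.2, 0.3), c(0.4, 0.5, 0.3)),
               c("drift", "adaptation", "unchanged"))
})

test_that("epiallele methylation is the mean of the four CpGs over reads", {
  expect_equal(epiallele_methylation(counts_of("1111" = 5, "0000" = 5)), 0.5)
  expect_equal(epiallele_methylation(counts_of("0111" = 9)), 0.75)
  expect_equal(epiallele_methylation(counts_of("1011" = 3, "0000" = 1)), 0.5625)
  expect_error(epiallele_methylation(integer(16)), "depth")
})

test_that("adjacent-CpG Jaccard follows the n11/(n11+n10+n01) convention", {
  mk <- function(sa, sb) {
    n <- length(sa)
    data.table::data.table(
      fragment = rep(paste0("f", seq_len(n)), 2), chrom = "chr1",
      pos = rep(c(10L, 20L), each = n), state = c(sa, sb))
  }
  prof <- mk(c(rep(1L, 8), 1L, 0L, rep(0L, 10)),
             c(rep(1L, 8), 0L, 1L, rep(0L, 10)))
  expect_equal(adjacent_cpg_jaccard(prof, "chr1", 10L, 20L), 0.8)
  expect_equal(adjacent_cpg_jaccard(mk(c(1L, 1L), c(1L, 1L)), "chr1", 10L, 20L), 1)
  expect_equal(adjacent_cpg_jaccard(mk(c(1L, 1L), c(0L, 0L)), "chr1", 10L, 20L), 0)
  ## all (0,0) pairs: defined as 1
  expect_equal(adjacent_cpg_jaccard(mk(c(0L, 0L), c(0L, 0L)), "chr1", 10L, 20L), 1)
  expect_error(adjacent_cpg_jaccard(mk(NA_integer_, NA_integer_),
                                    "chr1", 10L, 20L), "no fragment")
})

test_that("heterogeneity AUC bins methylation and sums width x median", {
  ## every bin's median at 0.5 -> AUC 50
  centers <- c(1.25, seq(5, 95, by = 5), 98.75)
  expect_equal(heterogeneity_auc(centers, rep(0.5, 21)), 50)
  expect_equal(heterogeneity_auc(numeric(0), numeric(0)), 0)
  ## maximal epipolymorphism everywhere stays within the 0-100 contract
  expect_equal(heterogeneity_auc(centers, rep(0.9375, 21)), 93.75)
  expect_lte(heterogeneity_auc(centers, rep(0.9375, 21)), 100)
  ## boundary values 0 and 100 land in the first and last bins
  expect_equal(heterogeneity_auc(c(0, 100), c(0.8, 0.8)), (2.5 + 2.5) * 0.8)
  ## empty bins contribute zero
  expect_equal(heterogeneity_auc(50, 0.9), 5 * 0.9)
  ## monotone in any bin median; bounded on adversarial inputs
  set.seed(9)
  for (i in 1:20) {
    n <- sample(1:50, 1)
    m <- runif(n, 0, 100)
    e <- runif(n, 0, 0.9375)
    a0 <- heterogeneity_auc(m, e)
    expect_gte(a0, 0); expect_lte(a0, 100)
    e2 <- pmin(e + runif(n, 0, 0.9375 - max(e)), 0.9375)
    expect_gte(heterogeneity_auc(m, e2), a0)
  }
})

test_that("heterogeneity_summary ties the per-locus measures together", {
  sim <- simulate_cohort(n_null = 100, n_differential = 20, depth = 30,
                         seed = 13)
  peri <- names(sim$samples)[sim$samples == "periphery"]
  res <- detect_cpde(sim$table, "C1", peri)
  called <- res$records[call == TRUE & periphery == "P1", locus]
  hs <- heterogeneity_summary(sim$table, "C1", "P1", called)
  expect_equal(nrow(hs$per_locus), length(called))
  fr <- hs$summary[1, .(drift_fraction, adaptation_fraction, unchanged_fraction)]
  expect_equal(sum(unlist(fr)), 1)
  ## injected loci: core uniform (epipoly ~15/16) vs periphery point mass
  expect_gte(hs$summary$auc[1], hs$summary$auc[2])
  expect_gte(fr$drift_fraction, 0.9)
})

test_that("CPDE |methylation difference| correlates positively with JSD", {
  sim <- simulate_cohort(n_null = 400, n_differential = 20, depth = 30,
                         seed = 19)
  rec <- jsd_table(sim$table, pairs = cbind("C1", "P1"))
  meth <- sapply(rec$locus, function(l) {
    abs(epiallele_methylation(pattern_counts(sim$table, "C1", l)) -
          epiallele_methylation(pattern_counts(sim$table, "P1", l)))
  })
  rho <- suppressWarnings(cor(rec$jsd, meth, method = "spearman"))
  expect_gt(rho, 0)
})
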