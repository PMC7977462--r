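## scores rescaled so the moment estimates are exact
scores_with_moments <- function(n, mu, sigma, seed = 5) {
  set.seed(seed)
  x <- rnorm(n)
  mu + (x - mean(x)) / sqrt(mean((x - mean(x))^2)) * sigma
}

test_that("fit_null_threshold places the one-tailed normal quantile", {
  s <- scores_with_moments(1000, 0.10, 0.05)
  nm <- fit_null_threshold(s, alpha = 0.05)
  expect_equal(nm$threshold, 0.10 + qnorm(0.95) * 0.05, tolerance = 1e-9)
  expect_equal(nm$threshold, 0.18224, tolerance = 1e-4)
  expect_equal(fit_null_threshold(s, alpha = 0.5)$threshold, nm$mu,
               tolerance = 1e-12)
  expect_error(fit_null_threshold(rep(0.3, 100)), "degenerate")
  expect_error(fit_null_threshold(c(1, 2)), "at least 30")
  expect_error(fit_null_threshold(c(rnorm(50), Inf)), "finite")
})

test_that("threshold exceedance on truly normal scores is calibrated to alpha", {
  set.seed(202)
  n <- 20000
  for (alpha in c(0.05, 0.01)) {
    x <- rnorm(n, 0.3, 0.05)
    thr <- fit_null_threshold(x, alpha)$threshold
    expect_lt(abs(mean(x > thr) - alpha), 3 * sqrt(alpha * (1 - alpha) / n))
  }
})

test_that("csi_index contrasts the max against the mean of the rest", {
  r <- csi_index(c(0.6, 0.10, 0.20, 0.15))
  expect_equal(r$csi, 0.45)
  expect_equal(r$argmax, 1L)
  expect_true(r$unique_max)
  r2 <- csi_index(c(0.2, 0.6, 0.1, 0.1))
  expect_equal(r2$argmax, 2L)               # core not the argmax -> ineligible
  r3 <- csi_index(c(0.5, 0.5, 0.1, 0.1))
  expect_false(r3$unique_max)               # tie at the max
  ## Eq-6 style set over 5 samples
  r4 <- csi_index(c(0.5, 0.1, 0.1, 0.1, 0.1))
  expect_equal(r4$csi, 0.4)
})

test_that("detect_ppde calls ~alpha on a null cohort and finds spiked loci", {
  sim <- null_cohort(n_loci = 1000, depth = 30, n_samples = 4, seed = 17)
  peri <- names(sim$samples)[sim$samples == "periphery"]
  res <- detect_ppde(sim$table, peri, epsilon = 0)
  rate <- mean(res$records$call)
  expect_gt(rate, 0.01)
  expect_lt(rate, 0.09)                     # near the 5% design level
  ## spike two samples with disjoint point masses at 10 loci
  tab <- data.table::copy(sim$table)
  spike <- sim$truth$locus[1:10]
  tab <- tab[!(locus %in% spike & sample %in% peri[1:2])]
  tab <- rbind(tab,
    data.table::data.table(sample = peri[1], locus = spike, pattern = 0L,
                           count = 30L),
    data.table::data.table(sample = peri[2], locus = spike, pattern = 15L,
                           count = 30L))
  res2 <- detect_ppde(tab, peri, epsilon = 0)
  spiked <- res2$records[locus %in% spike & sample_a == peri[1] &
                           sample_b == peri[2]]
  expect_true(all(spiked$call))             # JSD ~ 1 >> delta
  ## a locus absent from one sample is not tested
  tab2 <- sim$table[!(sample == peri[1] & locus == sim$truth$locus[20])]
  res3 <- detect_ppde(tab2, peri, epsilon = 0)
  expect_false(any(res3$records$locus == sim$truth$locus[20] &
                     res3$records$sample_a == peri[1]))
})

test_that("detect_cpde recovers injected loci and stays calibrated on nulls", {
  sim <- simulate_cohort(n_null = 500, n_differential = 20, depth = 30,
                         seed = 23)
  peri <- names(sim$samples)[sim$samples == "periphery"]
  res <- detect_cpde(sim$table, "C1", peri)
  inj <- sim$truth[is_differential == TRUE, locus]
  ## power: every pair recovers at least 18 of the 20 injected loci
  per_pair <- res$records[call == TRUE, .N, by = periphery]
  expect_true(all(per_pair$N >= 18))
  expect_gte(length(intersect(res$summary$union, inj)), 18)
  ## null loci called at most at the alpha level, per pair
  null_rate <- res$records[!locus %in% inj, mean(call)]
  expect_lte(null_rate, 0.05)
  ## gamma = 1 forbids any call since JSD <= 1
  res_g1 <- detect_cpde(sim$table, "C1", peri, gamma = 1)
  expect_equal(sum(res_g1$records$call), 0L)
  ## eligibility bookkeeping is stored with each record
  called <- res$records[call == TRUE]
  expect_true(all(called$jsd_core > 0.3))
  expect_true(all(called$argmax_is_core))
  expect_true(all(called$csi > called$threshold))
})

test_that("a pure null cohort yields few CPDEs and none in all pairs", {
  sim <- null_cohort(n_loci = 500, depth = 30, n_samples = 5, seed = 29)
  peri <- names(sim$samples)[sim$samples == "periphery"]
  res <- detect_cpde(sim$table, "C1", peri)
  ## no more calls than the alpha-level expectation per pair
  expect_lte(nrow(res$records[call == TRUE]),
             ceiling(0.05 * nrow(res$records)))
  expect_length(res$summary$intersection, 0L)
})

test_that("raising gamma or lowering alpha never increases CPDE calls", {
  sim <- simulate_cohort(n_null = 200, n_differential = 10, depth = 25,
                         seed = 37)
  peri <- names(sim$samples)[sim$samples == "periphery"]
  n_calls <- function(gamma, alpha)
    sum(detect_cpde(sim$table, "C1", peri, gamma = gamma,
                    alpha = alpha)$records$call)
  base <- n_calls(0.3, 0.05)
  expect_lte(n_calls(0.5, 0.05), base)
  expect_lte(n_calls(0.3, 0.01), base)
})

test_that("relabeling peripheries permutes but preserves the CPDE union", {
  sim <- simulate_cohort(n_null = 200, n_differential = 10, depth = 25,
                         seed = 41)
  peri <- names(sim$samples)[sim$samples == "periphery"]
  res1 <- detect_cpde(sim$table, "C1", peri)
  res2 <- detect_cpde(sim$table, "C1", rev(peri))
  expect_setequal(res1$summary$union, res2$summary$union)
  ## determinism: identical inputs give identical call tables
  res3 <- detect_cpde(sim$table, "C1", peri)
  expect_identical(res1$records, res3$records)
})

test_that("detect_local_specific assigns divergent loci to the right sample", {
  sim <- simulate_cohort(n_null = 300, n_differential = 10, depth = 30,
                         effect = "sample_specific", specific_sample = "P2",
                         seed = 43)
  res <- detect_local_specific(sim$table)
  inj <- sim$truth[is_differential == TRUE, locus]
  hits <- res$records[call == TRUE & locus %in% inj]
  expect_gte(nrow(hits), 8)
  expect_true(all(hits$assigned_sample == "P2"))
  ## null calibration: fraction of eligible null loci called stays small
  null_rate <- res$records[!locus %in% inj, mean(call)]
  expect_lte(null_rate, 0.05)
  expect_error(detect_local_specific(sim$table, samples = c("C1", "P1")),
               "at least 3")
})

test_that("core-divergent loci are both CPDEs in all pairs and core-specific", {
  sim <- simulate_cohort(n_null = 300, n_differential = 10, depth = 30,
                         seed = 47)
  peri <- names(sim$samples)[sim$samples == "periphery"]
  inj <- sim$truth[is_differential == TRUE, locus]
  cp <- detect_cpde(sim$table, "C1", peri)
  sp <- detect_local_specific(sim$table)
  core_specific <- sp$records[call == TRUE & assigned_sample == "C1", locus]
  expect_gte(length(intersect(inj, cp$summary$intersection)), 8)
  expect_gte(length(intersect(inj, core_specific)), 8)
  expect_gte(length(intersect(core_specific, cp$summary$union)), 8)
})
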