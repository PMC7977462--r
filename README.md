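# epiJSD

Read-level DNA methylation heterogeneity for multi-region bisulfite
sequencing (RRBS/WGBS), built around **epialleles**: windows of four
consecutive CpG sites observed on a single sequenced fragment. Each
fragment realizes one of the 16 binary methylation patterns of its
window, so a locus in a cell population is summarized not by one average
methylation value but by a 16-pattern probability distribution — a
read-out of the mixture of epigenetic subclones at that locus.

The package is aimed at analyses that compare a tumor **core** sample
against several tumor **periphery** samples (or any small multi-region
design) and ask which loci differ in their subclonal methylation
composition, which sample a divergent locus is specific to, and how
disordered each sample's methylation patterns are overall.

## Method

For one locus in one sample, pattern probabilities are estimated from
the read counts with a pseudocount `ε` (default `6.25e-3`) applied to
the probabilities and renormalized:

    p'_i = (n_i / N + ε) / (1 + 16ε),   i = 1..16

Two samples are compared with the Jensen–Shannon dissimilarity,

    JS(P, Q) = H((P + Q)/2) − (H(P) + H(Q))/2,   JSD = sqrt(JS)

with entropies `H` in bits (log base 2), so `JS ∈ [0, 1]`; the square
root of JS is a metric (Fuglede–Topsøe), hence JSD is a bounded distance
between pattern distributions.

Calling proceeds against empirical normal nulls (moment fit, one-tailed
threshold `μ + z₀.₉₅ σ`):

* **PPDE** (periphery–periphery differential epiallele): `JSD > δ`,
  with `δ` fitted to the pooled periphery-pair JSD distribution.
* **CPDE** (core–periphery differential epiallele): with `S_i` the set
  of JSDs between periphery `P_i` and the other tumor samples, the
  composite specificity index is `CSI = max(S_i) − mean(S_i \ max)`.
  A locus is a CPDE for (core, `P_i`) iff `JSD(core, P_i) > γ`
  (default `γ = 0.3`), the unique maximum of `S_i` is the core
  comparison, and `CSI > Thres1` (fitted per pair).
* **Local-specific epiallele**: the same CSI contrast applied to the
  per-sample mean JSDs `m_i`; the argmax sample is the one the locus is
  specific to.

Per-sample heterogeneity is summarized by the epipolymorphism
`1 − Σ p_i²` (0 for a pure population, 15/16 for the uniform mixture),
drift/adaptation labels (epipolymorphism higher/lower in the core than
in the periphery), and a methylation-heterogeneity AUC: methylation
levels are split into 21 bins — (0, 2.5], then width-5 bins, then
(97.5, 100] — and the AUC is the sum of bin width × median
epipolymorphism, ranging 0–100.

## Worked example

Simulate the default study design (1 core + 4 peripheries, 500 shared
null loci plus 20 loci where the core is a uniform 16-pattern mixture
and the peripheries are fully methylated, depth 30) and call CPDEs:

```r
library(epiJSD)

sim  <- simulate_cohort(n_null = 500, n_differential = 20, depth = 30, seed = 42)
peri <- names(sim$samples)[sim$samples == "periphery"]
res  <- detect_cpde(sim$table, "C1", peri)

res$nulls[["P1"]]
#> normal null: mu = 0.09586, sigma = 0.1474, alpha = 0.05, threshold = 0.3383

res$summary$per_pair
#>    periphery     N
#> 1:        P1    20
#> 2:        P2    20
#> 3:        P3    20
#> 4:        P4    20

head(res$records[res$records$call == TRUE], 3)
#>               locus periphery  jsd_core       csi argmax_is_core threshold  call
#> 1:   sim1:1151-1176        P1 0.7917782 0.7917782           TRUE 0.3383399  TRUE
#> 2: sim1:13631-13656        P1 0.8799806 0.8799806           TRUE 0.3383399  TRUE
#> 3:   sim1:1391-1416        P1 0.8341306 0.8341306           TRUE 0.3383399  TRUE
```

Each pair calls exactly the 20 injected loci: the fitted `Thres1`
(0.338 for P1) sits above the null CSI noise, and the injected loci have
core–periphery JSDs around 0.8–0.9. Summarizing heterogeneity for the
P1 calls:

```r
hs <- heterogeneity_summary(sim$table, "C1", "P1",
        res$records[res$records$call & res$records$periphery == "P1", ]$locus)
hs$summary
#>    sample      auc drift_fraction adaptation_fraction unchanged_fraction
#> 1:     C1 18.19444              1                   0                  0
#> 2:     P1  0.00000              1                   0                  0
```

All 20 called loci are drift epialleles (core more disordered than the
periphery), and the core's methylation-heterogeneity AUC (18.2) exceeds
the periphery's (0) — the designed contrast.

The same pipeline runs from the shell via the installed `epijsd`
script: `epijsd simulate --seed 42 --out sim/`, then
`epijsd cpde --manifest sim/manifest.tsv --out calls/`; every run writes
a `params.json` with all fitted thresholds.

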