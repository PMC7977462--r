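---
title: "Quantifying read-level methylation heterogeneity with epiJSD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying read-level methylation heterogeneity with epiJSD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiJSD)
library(data.table)
```

## The model

Bulk bisulfite sequencing averages methylation over cells, but each
aligned fragment reports the joint methylation state of the CpGs it
covers — a single-molecule observation. epiJSD treats every window of
four consecutive CpG sites covered by one fragment as an **epiallele**
with 16 possible binary patterns (leftmost bit = lowest genomic
coordinate), and models a locus in a sample as a multinomial over those
16 patterns. Differences in the pattern distribution between samples
reveal differences in subclonal composition that the average methylation
level can hide: two samples can share a methylation level of 0.5 as a
50/50 mixture of `0000`/`1111` or as a pure `0011` population.

The assumptions this rests on: fragments are independent draws from the
cell population (duplicates should be removed upstream); the four CpGs
of a window are covered by the same molecule, so patterns are phased
observations, not reconstructions; and CpG methylation is symmetric
across strands, so calls on either strand inform the same forward-strand
C coordinate.

### Dissimilarity

For counts $n_i$ with depth $N$, probabilities are pseudocount-adjusted,

$$p'_i = \frac{n_i/N + \varepsilon}{1 + 16\varepsilon},$$

which keeps $\sum_i p'_i = 1$ exactly for any $\varepsilon \ge 0$ and
every antilogarithm strictly positive. Two distributions are compared
with the Jensen–Shannon divergence in bits,

$$JS(P,Q) = H\!\left(\tfrac{P+Q}{2}\right) - \tfrac{H(P)+H(Q)}{2},
\qquad H(P) = -\sum_i p_i \log_2 p_i,$$

so $JS \in [0,1]$, and the dissimilarity is $JSD = \sqrt{JS}$, a metric
bounded in $[0,1]$ (Fuglede–Topsøe). $JSD = 0$ iff the adjusted
distributions coincide; $JSD = 1$ iff the supports are disjoint (at
$\varepsilon = 0$).

### Calling differential and specific epialleles

All callers share one thresholding device
(`fit_null_threshold()`): a normal is fitted to the observed score
distribution by moment estimation and the decision threshold is the
one-tailed quantile $\mu + z_{1-\alpha}\sigma$ with $\alpha = 0.05$.
This is an empirical-null argument — the bulk of loci are assumed
undisturbed, so the score distribution itself estimates the null — not a
parametric model of JSD sampling noise. A `robust = TRUE` flag
substitutes median/MAD when outlying scores are expected to distort the
moments.

* **PPDE**: a locus is differential between two periphery samples iff
  its JSD exceeds $\delta$, fitted to the pooled distribution of all
  periphery-pair JSDs.
* **CPDE**: for periphery $P_i$, let $S_i$ be the JSDs between $P_i$
  and the other tumor samples (core first). The composite specificity
  index is $CSI = \max(S_i) - \mathrm{mean}(S_i \setminus \max)$: large
  when the core comparison stands out from the periphery–periphery
  background. After removing consistent loci (all JSDs zero), a
  per-pair threshold $Thres_1$ is fitted to the CSI distribution, and a
  CPDE must satisfy (i) $JSD(\mathrm{core}, P_i) > \gamma$, (ii) the
  unique maximum of $S_i$ is the core comparison, (iii) $CSI > Thres_1$.
* **Local-specific epialleles**: the same contrast over the per-sample
  mean JSDs $m_i$ to the other tumor samples; the argmax sample is the
  one the locus is assigned to, with a single global $Thres_2$.

### Heterogeneity summaries

Per locus: epipolymorphism $1 - \sum_i p_i^2$ on the **raw**
probabilities (no pseudocount — the statistic needs no logarithm), and
the methylation level as the read-weighted mean over the four CpGs.
Differential loci with higher core epipolymorphism are **drift**
epialleles, lower are **adaptation**; exact ties are labeled
`unchanged` rather than silently joining either class. Per sample: the
methylation-heterogeneity AUC bins methylation percent into 21 bins —
$(0, 2.5]$, eighteen width-5 bins, $(97.5, 100]$ — and sums bin width ×
median epipolymorphism, giving a 0–100 score of how disordered the
sample's patterns are across the methylation range.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `epsilon` | 6.25e-3 | probability | pseudocount per pattern; keeps entropies finite. The analysis is insensitive to its exact magnitude (JSD is continuous in `epsilon`), but it must be well below 1/16 so it never dominates observed patterns. |
| `min_reads` | 10 | reads | per-sample locus depth filter; below ~10 reads the 16-bin multinomial is too noisy to compare. |
| `gamma` | 0.3 | JSD | minimum effect size for CPDE/specific calls; chosen where the core–periphery JSD distribution separates from the periphery–periphery one. |
| `alpha` | 0.05 | — | one-tailed level of every fitted null. No multiplicity correction is applied beyond it; the callers are screening tools, not inference on individual loci. |
| `depth` (simulator) | 25 | reads/locus | matches a typical RRBS design (~25× per covered CpG). |

## The synthetic-data generator

`simulate_cohort()` emulates the multi-region design the callers
target: 1 core + 4 peripheries over a shared set of 4-CpG loci, reads
drawn i.i.d. multinomially at fixed depth. Null loci share one mixture
across samples, built as an independent-site product at a per-locus
methylation level drawn from Beta(0.4, 0.4) — the U-shaped,
mostly-all-or-nothing landscape typical of RRBS — mixed with a 5%
uniform disorder component so null pattern distributions are not pure
point masses. Differential loci contrast a uniform 16-pattern core
mixture against fully methylated peripheries (or, for the
sample-specific model, one divergent sample against a shared null
mixture). `emit_reads()` materializes a cohort as Bismark-style SAM plus
a FASTA reference in which fragments exactly cover their locus, so the
alignment-parsing path can be tested round-trip.

What the generator does **not** emulate: sequencing and bisulfite
conversion errors, read-length and fragment-position variation,
coverage heterogeneity across loci, linkage between neighboring loci,
and biological effect sizes subtler than the designed contrasts. Tests
passing on simulated cohorts therefore demonstrate the correctness and
calibration of the machinery under the stated sampling model, not
performance on real tumors, where effect sizes, depth variation and
mapping artifacts will reduce power.

Test and acceptance runs use cohorts of 500 null + 20 differential loci
at depth 30 with 5 samples — large enough for stable null fits
(thousands of CSI values per pair) while keeping the whole suite under a
minute of compute.

## Numerical and design choices

* **Logarithm base 2** throughout, so JS and JSD live in $[0, 1]$;
  floating-point round-off is clamped (JS can evaluate to $-10^{-17}$
  for identical inputs).
* **Pseudocount on probabilities, then renormalize** — not on counts —
  so $\sum p' = 1$ holds exactly regardless of depth.
* **CSI algebra**: the contrast max − mean(rest) is one reasonable
  realization of "the largest discrepancy against the remaining ones";
  it is isolated in `csi_index()` so an alternative such as
  max − second-max can be swapped in one place. Ties at the maximum
  make a locus ineligible rather than guessing a winner.
* **Sliding 4-CpG windows** (overlap allowed) are the default locus
  set, maximizing recovery; `disjoint = TRUE` tiles instead. Loci are
  identified by their 1-based inclusive span over the CG dinucleotides.
* **Fragments, not reads**: overlapping mates are merged and counted
  once, and a position where mates disagree becomes an unknown call.
  Any locus pattern containing an unknown is discarded for that
  fragment — no imputation. Both behaviors are flags
  (`merge_mates`), since upstream pipelines differ.
* **Degenerate inputs**: zero-depth loci raise errors rather than
  returning NaN; a constant score vector is a degenerate null; empty
  AUC input returns 0; empty bins contribute 0 (their median is
  undefined otherwise); methylation exactly 0%/100% is assigned to the
  first/last AUC bin, whose open lower/upper bounds would otherwise
  leave the boundary homeless.
* **Annotation by midpoint**: a locus gets exactly one gene-context and
  one CpG-context label, decided by its midpoint, with precedence
  promoter > 5'UTR > exon > intron and nearest-TSS tie-breaks; islands,
  2 kb shores, 2 kb shelves and opensea partition the genome after
  merging overlapping islands.

## Worked example

```{r example}
sim  <- simulate_cohort(n_null = 500, n_differential = 20, depth = 30, seed = 42)
peri <- names(sim$samples)[sim$samples == "periphery"]
res  <- detect_cpde(sim$table, "C1", peri)
res$summary$per_pair
length(intersect(res$summary$union,
                 sim$truth[is_differential == TRUE, locus]))
```

All 20 injected loci are recovered in every pair on this seed, with no
null locus called; the per-pair fitted thresholds are in
`res$nulls`.

```{r heterogeneity}
called <- res$records[call == TRUE & periphery == "P1", locus]
hs <- heterogeneity_summary(sim$table, "C1", "P1", called)
hs$summary
```

## Limitations

Epialleles are fixed at four CpGs; longer haplotypes or scores such as
PDR/MHL are out of scope. The normal null is an approximation to the
empirical score distribution — with strong or abundant signal the
moment fit inflates the threshold (conservative); the robust option
mitigates but does not remove this. JSD weighs all 16 patterns equally
and ignores depth differences between samples beyond the pseudocount,
so very unequal depths make comparisons noisier than the fitted null
assumes. Annotation classifies by midpoint only and does not handle
trans-spliced or overlapping-isoform subtleties.
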