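---
title: "Finding methylation-driven genes in staged tumor cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding methylation-driven genes in staged tumor cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

Promoter CpG methylation can repress transcription. When a tumor loses
methylation at a gene's promoter and that gene is simultaneously
overexpressed — or gains methylation while the gene is silenced — the
methylation change is a plausible driver of the expression change. `mdgpipe`
operationalizes this anticorrelation idea for cohorts with paired
HM450-style beta values and RNA-seq counts stratified by tumor stage
(non-tumor NT plus stages I–IV).

A gene is called a **methylation-driven gene (MDG)** for a contrast
(NT versus one tumor stage) when three conditions hold simultaneously:

1. **Differential expression.** A DESeq-style negative-binomial Wald test
   on median-of-ratios–normalized counts calls the gene `up`
   (log2FC > 2, BH FDR < 0.05) or `down` (log2FC < −2, FDR < 0.05). Both
   inequalities are strict. The fold change uses a pseudocount of 0.5 on
   the group means so all-zero groups stay finite; the dispersion is a
   pooled within-group method-of-moments estimate floored at 1e-8. This is
   deliberately a self-contained reimplementation of the DESeq recipe —
   exact concordance with any DESeq release is a non-goal, and the test is
   validated instead by power and null-calibration simulations.
2. **Differential promoter methylation.** At least one promoter CpG of the
   gene is differentially methylated: |mean beta difference| ≥ 0.15,
   two-sided Wilcoxon rank-sum p < 0.05 (raw, uncorrected — a BH option
   exists but is off by default), and the tumor-group mean beta falls
   outside the (0.4, 0.6) band: above 0.6 for hypermethylation, below 0.4
   for hypomethylation. The Wilcoxon p is exact (via the null rank-sum
   distribution) when both groups have at most 8 samples and no ties, and
   otherwise uses the normal approximation with tie and continuity
   correction.
3. **Anticorrelated promoter median.** The median over all
   (promoter CpG × tumor sample) beta values must be < 0.4 with expression
   `up` (hypomethylated driver) or > 0.6 with expression `down`
   (hypermethylated driver). Medians exactly at a threshold are not
   classified; the two classes are therefore disjoint by construction. The
   tumor group of the contrast supplies the classification samples; the
   NT-side median is also reported for transparency.

Candidates that pass conditions 1–2 but fail condition 3 are dropped.
Disabling the filter (`anticorrelation = FALSE`) can only grow the result —
a monotonicity property the test suite checks.

Calls are intersected across the four NT-versus-stage contrasts
(`stage_sets()`), giving stage-shared and stage-exclusive driver sets and
the full Venn decomposition. The baseline-contrast scheme is the default
because stage-versus-stage contrasts show far fewer differentially
methylated CpGs than any stage-versus-NT contrast — the package retains a
`sequential = TRUE` mode to reproduce exactly that comparison, alongside
`bootstrap_dm_counts()`, which equalizes unbalanced groups by resampling a
fixed number of samples (default: the smallest group size) per phenotype.

# Downstream stages

**Co-expression networks.** For each tumor phenotype, mutual information is
computed between every called driver and every filtered gene
(`infer_network()`), networks are reduced to their top-k edges (defaults
1,000 / 10,000 / 100,000; ties broken lexicographically so results are
order-independent), and a driver's first neighbors are checked for
expression-direction concordance. An optional data-processing-inequality
pruning step (`dpi_prune()`, tolerance 0.15) is available but off by
default, since the core procedure is MI plus top-k filtering.

**MI estimator.** Each vector is discretized into `max(2, floor(n^(1/3)))`
equal-frequency bins on its ranks, and the plug-in estimate is corrected
with the Miller–Madow term and clamped at zero. The rank binning makes the
estimate exactly invariant under strictly monotone transforms (so
normalized counts and log counts give identical networks). The bin count
and correction were chosen because the raw plug-in estimate with
`sqrt(n)` bins is inflated by roughly `(B−1)²/(2n)` — about 0.49 nats at
n = 10,000 — which would swamp weak dependencies; with the cube-root rule
plus correction, the estimator reproduces the Gaussian closed form
`−½·ln(1−ρ²)` within ±15% at ρ ∈ {0.3, 0.8} and stays below 0.05 nats on
permuted data. The price is that the deterministic identity
MI(x, x) = ln(B) holds only up to the small `(B−1)/(2n)` correction term.

**Survival.** For role-bearing drivers (oncogene / tumor-suppressor / both,
joined from a user-supplied catalog), tumor samples are split at the
gene's median expression — strictly above the median is `high`, ties go to
`low` (a deterministic convention) — and compared by Kaplan–Meier curves
and the two-group log-rank test. Both are fitted through the `survival`
package; the test suite independently re-derives the product-limit values
and the pooled `(ΣO−ΣE)²/ΣV` statistic by hand. All tumor stages are
pooled by default. Follow-up times are used in the units supplied (days);
no administrative censoring horizon is imposed.

**Enrichment.** A local hypergeometric over-representation test
(`ora_test()`, upper tail) against GMT gene sets replaces any web service.
The universe defaults to the genes surviving preprocessing; results are
filtered at raw p < 0.01 (BH FDR is reported alongside but not used for
the filter, matching the raw-p convention).

# Preprocessing conventions

* Genes are dropped in this order: not in the annotation; zero counts in
  **more than** 50% of samples; mean count **strictly below** 10 (a mean
  of exactly 10 is retained). The filter is idempotent.
* CpG rows with **any** missing beta value are dropped; nothing is imputed.
  Beta values are M/(M+U); M+U = 0 is reported as missing.
* Each CpG maps to at most one gene (first occurrence wins).
* `within_bin_quantile_normalize()` offers a simplified covariate
  correction: equal-frequency covariate bins, full-quantile mapping of each
  bin onto the pooled per-sample reference, rounded half-to-even back to
  integers so the count models downstream still apply. It is a generic
  one-covariate operation, not a GC/length/biotype model; undersized bins
  are merged with a warning, and a constant covariate reduces to the
  identity. Externally batch-corrected matrices can be supplied directly —
  the pipeline makes no attempt to estimate batch effects itself.

# The synthetic cohort generator

`simulate_cohort()` emulates the study design the package targets:

* **Group sizes** default to 24 NT / 158 stage I / 31 stage II /
  72 stage III / 57 stage IV — the unbalanced five-group layout of the
  motivating cohort.
* **Beta values** are drawn from Beta distributions parameterized by mean
  and precision (default 50), the standard choice for bounded methylation
  data; each null CpG sits at one of two modes (means 0.2 / 0.8), giving
  the bimodal marginal distribution typical of promoter arrays.
* **Counts** are negative binomial (dispersion 0.15) with log-normal
  per-gene baseline means (log-mean log(300), log-sd 0.7) — moderately
  deep RNA-seq after filtering.
* **Planted drivers**: hypomethylated-up genes start at promoter mean 0.8
  in NT and drop by `beta_shift = 0.45` in tumor stages while counts scale
  by 2^3; hypermethylated-down genes mirror this. The default shift makes
  planted tumor medians cross the 0.4/0.6 thresholds with overwhelming
  probability at 5 CpGs per gene, so the planted truth is recoverable in
  principle — sensitivity failures then indicate method defects, not an
  unidentifiable simulation. Effects are planted uniformly across all four
  stages by default (`planted_stages` restricts them).
* **Survival** is exponential (baseline hazard 0.001/day); an optional
  link gene multiplies the hazard above its median expression; censoring
  is independent with probability `censor_rate` at a uniform time before
  the event.
* A single integer seed fully determines every output, byte for byte.

What the generator does **not** emulate: realistic HM450 probe annotation
or probe-type effects, correlated CpGs beyond the shared gene effect,
copy-number or mutational confounding, GC/length biases (counts are
unbiased by construction), or batch structure. Passing tests therefore
demonstrate that the statistical machinery behaves as specified under its
own assumptions — not that those assumptions capture every property of
real tumor data.

# Numerical conventions and degenerate inputs

* Strict inequalities at every published threshold (log2FC 2, FDR 0.05,
  mean-diff 0.15, p 0.05, beta 0.4/0.6).
* Constant CpGs: Wilcoxon p = 1, status `none`. Constant expression
  vectors: MI = 0; `median_split()` labels everything `low` with a
  warning. All-zero genes in both groups are excluded from DE testing.
* Hierarchical clustering of samples uses Euclidean distance and average
  linkage cut at k = 2 — conventional settings, reported with an NT-purity
  summary (fraction of NT samples in the NT-majority cluster).
* Bootstrap resampling is without replacement when a phenotype has at
  least `group_size` samples, with replacement otherwise.
* All randomness in a pipeline run flows from the single seed recorded in
  the manifest; reruns produce identical output checksums.

# Problem sizes used by the test suite

The packaged checks run on deliberately scaled cohorts chosen to finish in
minutes on one core while leaving the planted effects clearly
identifiable: recovery checks use 200–1,000 genes at 2–5 promoter CpGs and
24 samples per group; null calibration uses 20 replicates of 300–500
genes; Wilcoxon enumeration covers all group sizes up to 6; MI oracles use
n = 10,000; survival power uses 200 replicates of n = 200; the end-to-end
determinism and recovery check runs the full default 342-sample design
twice. The same quantities are recomputed from scratch by
`scripts/acceptance.R`.

# Known limitations

* The DE test has no dispersion shrinkage across genes; at very small
  group sizes its method-of-moments dispersion is noisy and the Wald test
  can be mildly anti-conservative. The published thresholds (|log2FC| > 2)
  dominate calls in practice.
* The promoter-median rule cannot classify genes whose promoter sits
  mid-range (median in the 0.4–0.6 band) regardless of how strong the
  expression change is — by design.
* MI networks rank dependence but their absolute values depend on the
  binning rule; compare edges within a network, not across sample sizes.
* The underexpression rule assumes the symmetric threshold log2FC < −2;
  only the overexpression side of the threshold pair is conventionally
  quoted, and the symmetric reading is adopted here.
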