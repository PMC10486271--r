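# mdgpipe

Integrative discovery of **methylation-driven genes (MDGs)** from paired DNA
methylation and RNA-seq data stratified by tumor progression stage — for
cancer epigenomics analysts who have a CpG×sample beta-value matrix
(HM450-style, β = M/(M+U) ∈ [0,1]), a gene×sample count matrix, and a
clinical table with stages NT (non-tumor adjacent) and I–IV.

The core statistic is an anticorrelation rule evaluated per stage contrast
(NT vs stage). A gene *g* is a hypomethylated driver when

* DE: log2FC(g) > 2 and BH-FDR < 0.05 (negative-binomial Wald test on
  median-of-ratios–normalized counts),
* DM: at least one promoter CpG of *g* has |Δβ̄| ≥ 0.15, Wilcoxon p < 0.05,
  and tumor mean β outside the (0.4, 0.6) band,
* median over all promoter-CpG × tumor-sample β values < 0.4,

and a hypermethylated driver under the mirrored conditions (log2FC < −2,
median β > 0.6). Calls are intersected across the four NT-vs-stage
contrasts (Venn logic), annotated against an oncogene/tumor-suppressor
catalog, and carried into mutual-information co-expression networks
(top-k edges, first-neighbor expression concordance), Kaplan–Meier
median-split survival with log-rank tests, and local hypergeometric
over-representation analysis against GMT gene sets.

A seeded synthetic-cohort generator (`simulate_cohort()`) plants
anticorrelated methylation/expression effects with known truth, so the
whole pipeline is testable without external data. See the vignette in
`vignettes/methylation-driven-genes.Rmd` for the model, parameter
defaults, and design rationale.

## Worked example

```r
library(mdgpipe)

cfg <- simulation_config(group_sizes = c(NT = 24, I = 24), n_genes = 300,
                         n_hypo_planted = 15, n_hyper_planted = 15, seed = 42)
cohort <- simulate_cohort(cfg)
beta   <- clean_cpgs(cohort$beta)
counts <- filter_genes(cohort$counts)

de  <- de_test(counts, cohort$samples, baseline = "NT", target = "I")
dm  <- dm_test(beta, cohort$samples, baseline = "NT", target = "I")
mdg <- call_mdgs(dm, de, beta, cohort$cpg_map, cohort$samples, "NT", "I")

table(mdg$methyl_class)
#> hyper  hypo
#>    15    15

head(mdg[, c("gene_id", "median_beta_tumor", "median_beta_nt",
             "n_dm_cpgs", "expr_status", "methyl_class")], 4)
#>   gene_id median_beta_tumor median_beta_nt n_dm_cpgs expr_status methyl_class
#> 1  G00004         0.6466434      0.2020392         5        down        hyper
#> 2  G00005         0.6527164      0.1818066         5        down        hyper
#> 3  G00020         0.3590635      0.8066807         5          up         hypo
#> 4  G00024         0.3467442      0.7916048         5          up         hypo

truth <- subset(cohort$truth, planted_class != "null")$gene_id
sprintf("sensitivity = %.2f, false discovery proportion = %.2f",
        mean(truth %in% mdg$gene_id), mean(!mdg$gene_id %in% truth))
#> "sensitivity = 1.00, false discovery proportion = 0.00"
```

All 30 planted drivers are recovered with the correct class: the tumor
promoter medians sit outside the 0.4/0.6 band, the NT medians on the
opposite side, every planted gene carries 5 differentially methylated
promoter CpGs, and the expression direction opposes the methylation shift.

For a full multi-stage run, write the cohort to disk and drive the
orchestrator (or use `inst/scripts/run_pipeline.R` with a YAML config):

```r
d <- tempfile(); write_fixtures(simulate_cohort(simulation_config(seed = 1)), d)
cfg <- pipeline_config(counts = file.path(d, "counts.tsv"),
                       beta = file.path(d, "beta.tsv"),
                       cpg_map = file.path(d, "cpg_map.tsv"),
                       samples = file.path(d, "samples.tsv"),
                       roles = file.path(d, "roles.tsv"),
                       gmt = file.path(d, "sets.gmt"), seed = 1)
res <- run_pipeline(cfg, file.path(d, "out"))
```

This writes per-contrast DE/DM/MDG tables, shared and stage-exclusive
driver sets, role annotations, top-k network edge lists, neighbor
concordance, survival summaries, an enrichment table, and a manifest with
output checksums (reruns with the same seed are checksum-identical).

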