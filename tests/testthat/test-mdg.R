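toy_map <- function(genes, cpgs_per_gene = 1, region = "promoter") {
  n <- length(genes) * cpgs_per_gene
  data.frame(cpg_id = sprintf("cg%03d", seq_len(n)), chrom = "chr1",
             pos = 100L * seq_len(n), gene_id = rep(genes, each = cpgs_per_gene),
             region = region, stringsAsFactors = FALSE)
}

test_that("promoter median pools all promoter CpG x sample values", {
  map <- toy_map("gA")
  beta <- matrix(c(0.2, 0.4, 0.6), 1, dimnames = list("cg001", paste0("s", 1:3)))
  expect_equal(promoter_median(beta, map, "gA", paste0("s", 1:3)), 0.4)
  map2 <- toy_map("gB", cpgs_per_gene = 2)
  beta2 <- matrix(c(0.1, 0.2, 0.8, 0.9), 2, byrow = TRUE,
                  dimnames = list(c("cg001", "cg002"), c("s1", "s2")))
  expect_equal(promoter_median(beta2, map2, "gB", c("s1", "s2")), 0.5)
  const <- matrix(0.7, 2, 2, dimnames = list(c("cg001", "cg002"), c("s1", "s2")))
  expect_equal(promoter_median(const, map2, "gB", c("s1", "s2")), 0.7)
  # no promoter CpGs -> NA
  body_map <- toy_map("gC", region = "body")
  expect_true(is.na(promoter_median(beta, body_map, "gC", "s1")))
})

make_contrast_fixture <- function(median_tumor, expr_status, dm_called = TRUE) {
  # one gene, 1 promoter CpG, 4 NT + 4 tumor samples
  ids <- sprintf("s%d", 1:8)
  sam <- data.frame(sample_id = ids, phenotype = rep(c("NT", "I"), each = 4))
  beta <- matrix(c(rep(0.5, 4), rep(median_tumor, 4)), 1,
                 dimnames = list("cg001", ids))
  dm <- data.frame(cpg_id = "cg001", mean_diff = median_tumor - 0.5, pvalue = 0.001,
                   tumor_mean_beta = median_tumor,
                   status = if (dm_called) "hypo" else "none")
  de <- data.frame(gene_id = "gA", log2fc = 3, pvalue = 1e-5, fdr = 1e-4,
                   status = expr_status)
  list(dm = dm, de = de, beta = beta, map = toy_map("gA"), samples = sam)
}

test_that("the anticorrelation rule classifies and drops candidates correctly", {
  # DM CpG + overexpression + tumor median 0.25 -> hypomethylated driver
  f <- make_contrast_fixture(0.25, "up")
  out <- call_mdgs(f$dm, f$de, f$beta, f$map, f$samples, "NT", "I")
  expect_identical(out$methyl_class, "hypo")
  expect_equal(out$median_beta_tumor, 0.25)
  expect_identical(out$n_dm_cpgs, 1L)
  # DM CpGs + underexpression + tumor median 0.75 -> hypermethylated driver
  f <- make_contrast_fixture(0.75, "down")
  out <- call_mdgs(f$dm, f$de, f$beta, f$map, f$samples, "NT", "I")
  expect_identical(out$methyl_class, "hyper")
  # median inside the (0.4, 0.6) band -> dropped
  f <- make_contrast_fixture(0.55, "up")
  expect_identical(nrow(call_mdgs(f$dm, f$de, f$beta, f$map, f$samples, "NT", "I")), 0L)
  # direction mismatch (median low but expression down) -> dropped
  f <- make_contrast_fixture(0.25, "down")
  expect_identical(nrow(call_mdgs(f$dm, f$de, f$beta, f$map, f$samples, "NT", "I")), 0L)
  # no DM CpG -> not even a candidate
  f <- make_contrast_fixture(0.25, "up", dm_called = FALSE)
  expect_identical(nrow(call_mdgs(f$dm, f$de, f$beta, f$map, f$samples, "NT", "I")), 0L)
  # disabling the anticorrelation filter keeps the candidate
  f <- make_contrast_fixture(0.55, "up")
  loose <- call_mdgs(f$dm, f$de, f$beta, f$map, f$samples, "NT", "I",
                     anticorrelation = FALSE)
  expect_identical(nrow(loose), 1L)
  expect_true(is.na(loose$methyl_class))
})

test_that("every MDG record satisfies its class rule, and classes are disjoint", {
  co <- simulate_cohort(small_config(seed = 23))
  beta <- clean_cpgs(co$beta)
  counts <- filter_genes(co$counts)
  de <- de_test(counts, co$samples, "NT", "I")
  dm <- dm_test(beta, co$samples, "NT", "I")
  m <- call_mdgs(dm, de, beta, co$cpg_map, co$samples, "NT", "I")
  expect_gt(nrow(m), 0)
  tum <- co$samples$sample_id[co$samples$phenotype == "I"]
  for (i in seq_len(nrow(m))) {
    med <- promoter_median(beta, co$cpg_map, m$gene_id[i], tum)
    expect_equal(med, m$median_beta_tumor[i])
    if (m$methyl_class[i] == "hypo") {
      expect_lt(med, 0.4); expect_identical(m$expr_status[i], "up")
    } else {
      expect_gt(med, 0.6); expect_identical(m$expr_status[i], "down")
    }
    expect_gte(m$n_dm_cpgs[i], 1L)
  }
  expect_identical(anyDuplicated(m$gene_id), 0L)
})

test_that("planted drivers are recovered with high sensitivity and low FDP", {
  co <- simulate_cohort(small_config(seed = 24, n_genes = 400,
                                     n_hypo_planted = 20, n_hyper_planted = 20))
  beta <- clean_cpgs(co$beta)
  counts <- filter_genes(co$counts)
  de <- de_test(counts, co$samples, "NT", "I")
  dm <- dm_test(beta, co$samples, "NT", "I")
  m <- call_mdgs(dm, de, beta, co$cpg_map, co$samples, "NT", "I")
  truth <- planted_ids(co)
  expect_gte(mean(truth %in% m$gene_id), 0.9)
  expect_lte(mean(!m$gene_id %in% truth), 0.1)
})

test_that("stage set logic enumerates shared, exclusive and Venn cells", {
  mk <- function(genes, cls = "hypo") {
    data.frame(gene_id = genes, contrast = "x", median_beta_tumor = 0.2,
               median_beta_nt = 0.8, n_promoter_cpgs = 1L, n_dm_cpgs = 1L,
               expr_status = "up", methyl_class = cls, stringsAsFactors = FALSE)
  }
  tabs <- list("NT:I" = mk(c("A", "B")), "NT:II" = mk("B"),
               "NT:III" = mk("B"), "NT:IV" = mk("B"))
  s <- stage_sets(tabs)
  expect_identical(s$hypo$shared, "B")
  expect_identical(s$hypo$exclusive[["NT:I"]], "A")
  expect_identical(s$hypo$cells[["NT:I"]], "A")
  expect_identical(s$hypo$cells[["NT:I&NT:II&NT:III&NT:IV"]], "B")
  expect_identical(length(s$hypo$cells), 15L)
  expect_identical(s$hyper$shared, character(0))
  expect_error(stage_sets(tabs[1]), "at least 2")
})

test_that("stage-uniform planting leaves stage-exclusive sets empty", {
  co <- simulate_cohort(simulation_config(
    group_sizes = c(NT = 24, I = 24, II = 24, III = 24, IV = 24),
    n_genes = 150, n_hypo_planted = 8, n_hyper_planted = 8, seed = 25))
  beta <- clean_cpgs(co$beta)
  counts <- filter_genes(co$counts)
  tabs <- list()
  for (st in c("I", "II", "III", "IV")) {
    de <- de_test(counts, co$samples, "NT", st)
    dm <- dm_test(beta, co$samples, "NT", st)
    tabs[[paste0("NT:", st)]] <-
      call_mdgs(dm, de, beta, co$cpg_map, co$samples, "NT", st)
  }
  s <- stage_sets(tabs)
  expect_gte(length(s$hypo$shared) + length(s$hyper$shared), 14)
  expect_lte(sum(lengths(s$hypo$exclusive), lengths(s$hyper$exclusive)), 1)
})

test_that("role annotation joins the catalog with none as default", {
  catalog <- data.frame(
    gene_id = c("ITK", "RAB25", "EHF", "DUAL"),
    role = c("oncogene", "tumor_suppressor", "tumor_suppressor", "both"),
    stringsAsFactors = FALSE)
  shared <- c("ITK", "RAB25", "EHF", "OTHER", "DUAL")
  out <- annotate_roles(shared, catalog)
  expect_identical(out$role, c("oncogene", "tumor_suppressor",
                               "tumor_suppressor", "none", "both"))
  bearing <- out$gene_id[out$role != "none"]
  expect_setequal(bearing, c("ITK", "RAB25", "EHF", "DUAL"))
})
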