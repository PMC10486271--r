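# Shared scaled-down cohort configurations for the test suite.

small_config <- function(seed = 1L, ...) {
  defaults <- list(group_sizes = c(NT = 24, I = 24), n_genes = 200,
                   cpgs_per_gene = 5, n_hypo_planted = 10, n_hyper_planted = 10,
                   seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}

null_config <- function(seed = 1L, ...) {
  small_config(seed = seed, n_hypo_planted = 0, n_hyper_planted = 0,
               n_genes = 300, cpgs_per_gene = 2, ...)
}

planted_ids <- function(cohort, cls = c("hypo", "hyper")) {
  cohort$truth$gene_id[cohort$truth$planted_class %in% cls]
}
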