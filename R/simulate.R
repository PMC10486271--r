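#' Configuration for the synthetic paired cohort generator
#'
#' The defaults describe the study design the package targets: five phenotype
#' groups with unbalanced sizes (24 non-tumor, 158 stage I, 31 stage II,
#' 72 stage III, 57 stage IV), beta values with a bimodal hypo/hyper promoter
#' structure, negative-binomial counts, and a planted set of
#' methylation-driven genes whose promoter methylation and expression shift
#' in opposite directions between non-tumor and tumor groups.
#'
#' Planted hypomethylated genes start near `baseline_beta_high` in non-tumor
#' tissue and drop by `beta_shift` in the planted tumor stages while their
#' counts are scaled by `2^expr_log2fc` (overexpression). Planted
#' hypermethylated genes mirror this (rise by `beta_shift`, counts scaled by
#' `2^-expr_log2fc`). With the default `beta_shift = 0.45` the planted tumor
#' promoter medians cross the 0.4/0.6 classification thresholds.
#'
#' @param group_sizes Named integer vector, phenotype -> sample count.
#' @param n_genes Number of genes.
#' @param cpgs_per_gene Promoter CpGs simulated per gene.
#' @param n_hypo_planted,n_hyper_planted Planted hypo-/hypermethylated gene
#'   counts (hypo pairs with expression up, hyper with down).
#' @param beta_shift Beta-scale effect size applied to planted genes in tumor.
#' @param expr_log2fc Planted absolute log2 fold change in tumor groups.
#' @param nb_dispersion Negative-binomial dispersion (variance = mu + a mu^2).
#' @param baseline_beta_low,baseline_beta_high Means of the two modes of the
#'   bimodal beta distribution, in (0,1).
#' @param beta_precision Precision of the Beta distribution used for beta
#'   values (shape1 = mean * precision, shape2 = (1-mean) * precision).
#' @param expr_meanlog,expr_sdlog Log-normal parameters of per-gene baseline
#'   mean counts.
#' @param planted_stages Tumor phenotypes receiving the planted effect
#'   (default: all four stages, i.e. stage-shared planting).
#' @param missing_rate Fraction of beta entries set missing completely at
#'   random (default 0).
#' @param survival_link_gene Optional gene id whose expression drives the
#'   simulated hazard (see [simulate_survival()]).
#' @param hazard_ratio Hazard ratio applied to samples above the link gene's
#'   median expression.
#' @param censor_rate Fraction of samples censored uniformly at random.
#' @param baseline_hazard Exponential baseline hazard per day.
#' @param seed Integer seed; fully determines the generated cohort.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(group_sizes = c(NT = 24, I = 158, II = 31, III = 72, IV = 57),
                              n_genes = 1000,
                              cpgs_per_gene = 5,
                              n_hypo_planted = 50,
                              n_hyper_planted = 50,
                              beta_shift = 0.45,
                              expr_log2fc = 3,
                              nb_dispersion = 0.15,
                              baseline_beta_low = 0.2,
                              baseline_beta_high = 0.8,
                              beta_precision = 50,
                              expr_meanlog = log(300),
                              expr_sdlog = 0.7,
                              planted_stages = NULL,
                              missing_rate = 0,
                              survival_link_gene = NULL,
                              hazard_ratio = 1,
                              censor_rate = 0.3,
                              baseline_hazard = 0.001,
                              seed = 1L) {
  cfg <- list(group_sizes = group_sizes, n_genes = as.integer(n_genes),
              cpgs_per_gene = as.integer(cpgs_per_gene),
              n_hypo_planted = as.integer(n_hypo_planted),
              n_hyper_planted = as.integer(n_hyper_planted),
              beta_shift = beta_shift, expr_log2fc = expr_log2fc,
              nb_dispersion = nb_dispersion,
              baseline_beta_low = baseline_beta_low,
              baseline_beta_high = baseline_beta_high,
              beta_precision = beta_precision,
              expr_meanlog = expr_meanlog, expr_sdlog = expr_sdlog,
              planted_stages = planted_stages, missing_rate = missing_rate,
              survival_link_gene = survival_link_gene,
              hazard_ratio = hazard_ratio, censor_rate = censor_rate,
              baseline_hazard = baseline_hazard, seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

#' @keywords internal
validate_simulation_config <- function(cfg) {
  if (is.null(names(cfg$group_sizes)) || !"NT" %in% names(cfg$group_sizes))
    stop("group_sizes must be named and include an NT group")
  if (any(cfg$group_sizes < 2)) stop("every group needs at least 2 samples")
  if (cfg$n_genes < 1 || cfg$cpgs_per_gene < 1) stop("counts must be positive")
  if (cfg$n_hypo_planted + cfg$n_hyper_planted > cfg$n_genes)
    stop("more planted genes than genes")
  for (m in c(cfg$baseline_beta_low, cfg$baseline_beta_high))
    if (m <= 0 || m >= 1) stop("beta means must lie in (0,1)")
  if (cfg$baseline_beta_high - cfg$beta_shift <= 0 ||
      cfg$baseline_beta_low + cfg$beta_shift >= 1)
    stop("beta_shift pushes planted means outside (0,1)")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) stop("missing_rate in [0,1)")
  if (cfg$hazard_ratio <= 0) stop("hazard_ratio must be positive")
  invisible(cfg)
}

#' Simulate a paired methylation/expression cohort with planted driver genes
#'
#' Draws a seeded cohort: negative-binomial counts with log-normal per-gene
#' baseline means, Beta-distributed promoter beta values with a bimodal
#' hypo/hyper structure, a CpG-to-gene promoter map, a sample table with
#' right-censored survival, and a truth table recording which genes carry a
#' planted anticorrelated methylation/expression shift. The same
#' configuration (including seed) always yields bit-identical output.
#'
#' @param config A [simulation_config()].
#' @return A list of class `mdg_cohort` with elements `beta`, `counts`,
#'   `cpg_map`, `samples`, `truth`, and `config`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  validate_simulation_config(config)
  set.seed(config$seed)
  sizes <- config$group_sizes
  phenos <- names(sizes)
  tumor_phenos <- setdiff(phenos, "NT")
  planted_stages <- if (is.null(config$planted_stages)) tumor_phenos else config$planted_stages
  sample_ids <- unlist(lapply(phenos, function(p) sprintf("%s_%03d", p, seq_len(sizes[[p]]))),
                       use.names = FALSE)
  pheno_of <- rep(phenos, sizes)
  n_samp <- length(sample_ids)
  genes <- sprintf("G%05d", seq_len(config$n_genes))

  nh <- config$n_hypo_planted; ny <- config$n_hyper_planted
  planted <- if (nh + ny > 0) sample(genes, nh + ny) else character(0)
  hypo_genes <- planted[seq_len(nh)]
  hyper_genes <- planted[nh + seq_len(ny)]
  truth <- data.frame(
    gene_id = genes,
    planted_class = ifelse(genes %in% hypo_genes, "hypo",
                           ifelse(genes %in% hyper_genes, "hyper", "null")),
    expr_direction = ifelse(genes %in% hypo_genes, "up",
                            ifelse(genes %in% hyper_genes, "down", "none")),
    stringsAsFactors = FALSE)

  # expression: per-gene log-normal baseline means, planted fold change in tumor
  mu <- stats::rlnorm(config$n_genes, config$expr_meanlog, config$expr_sdlog)
  MU <- matrix(mu, nrow = config$n_genes, ncol = n_samp,
               dimnames = list(genes, sample_ids))
  shifted <- pheno_of %in% planted_stages
  MU[match(hypo_genes, genes), shifted] <- MU[match(hypo_genes, genes), shifted] * 2^config$expr_log2fc
  MU[match(hyper_genes, genes), shifted] <- MU[match(hyper_genes, genes), shifted] * 2^(-config$expr_log2fc)
  counts <- matrix(stats::rnbinom(length(MU), mu = MU, size = 1 / config$nb_dispersion),
                   nrow = config$n_genes, dimnames = dimnames(MU))

  # promoter CpGs: bimodal baseline, planted genes shift in tumor
  k <- config$cpgs_per_gene
  n_cpg <- config$n_genes * k
  gene_of_cpg <- rep(genes, each = k)
  cpg_ids <- sprintf("cg%07d", seq_len(n_cpg))
  gene_idx <- rep(seq_len(config$n_genes), each = k)
  cpg_map <- data.frame(
    cpg_id = cpg_ids,
    chrom = paste0("chr", ((gene_idx - 1L) %% 22L) + 1L),
    pos = 1500L * seq_len(n_cpg),
    gene_id = gene_of_cpg,
    region = "promoter",
    stringsAsFactors = FALSE)

  base_state <- sample(c(config$baseline_beta_low, config$baseline_beta_high),
                       n_cpg, replace = TRUE)
  is_hypo_cpg <- gene_of_cpg %in% hypo_genes
  is_hyper_cpg <- gene_of_cpg %in% hyper_genes
  base_state[is_hypo_cpg] <- config$baseline_beta_high
  base_state[is_hyper_cpg] <- config$baseline_beta_low
  MB <- matrix(base_state, nrow = n_cpg, ncol = n_samp,
               dimnames = list(cpg_ids, sample_ids))
  MB[is_hypo_cpg, shifted] <- config$baseline_beta_high - config$beta_shift
  MB[is_hyper_cpg, shifted] <- config$baseline_beta_low + config$beta_shift
  phi <- config$beta_precision
  beta <- matrix(stats::rbeta(length(MB), MB * phi, (1 - MB) * phi),
                 nrow = n_cpg, dimnames = dimnames(MB))
  if (config$missing_rate > 0) {
    miss <- stats::runif(length(beta)) < config$missing_rate
    beta[miss] <- NA_real_
  }

  samples <- data.frame(sample_id = sample_ids, phenotype = pheno_of,
                        stringsAsFactors = FALSE)
  samples <- simulate_survival(samples, counts,
                               link_gene = config$survival_link_gene,
                               hazard_ratio = config$hazard_ratio,
                               censor_rate = config$censor_rate,
                               baseline_hazard = config$baseline_hazard,
                               seed = NULL)

  structure(list(beta = beta, counts = counts, cpg_map = cpg_map,
                 samples = samples, truth = truth, config = config),
            class = "mdg_cohort")
}

#' Attach simulated right-censored survival to a sample table
#'
#' Event times are exponential with a baseline hazard; samples whose
#' expression of `link_gene` lies strictly above the cohort median have their
#' hazard multiplied by `hazard_ratio` (so `hazard_ratio > 1` makes the
#' high-expression group fare worse). Each sample is independently censored
#' with probability `censor_rate`, at a uniform time before its event.
#'
#' @param sample_table Data.frame with `sample_id` (and any other columns).
#' @param expr Gene-by-sample count matrix covering the table's samples.
#' @param link_gene Gene id driving the hazard, or `NULL` for no covariate
#'   effect.
#' @param hazard_ratio Positive hazard multiplier for the high-expression
#'   group.
#' @param censor_rate Probability of censoring per sample, in \[0,1).
#' @param baseline_hazard Exponential baseline hazard per day.
#' @param seed Integer seed, or `NULL` to draw from the current RNG state.
#' @return `sample_table` with columns `time`, `event` and `vital_status`
#'   replaced/added.
#' @export
simulate_survival <- function(sample_table, expr, link_gene = NULL,
                              hazard_ratio = 1, censor_rate = 0.3,
                              baseline_hazard = 0.001, seed = NULL) {
  if (hazard_ratio <= 0) stop("hazard_ratio must be positive")
  if (censor_rate < 0 || censor_rate >= 1) stop("censor_rate must be in [0,1)")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(sample_table)
  rate <- rep(baseline_hazard, n)
  if (!is.null(link_gene)) {
    if (!link_gene %in% rownames(expr)) stop("link_gene not in expression matrix")
    x <- expr[link_gene, sample_table$sample_id]
    rate[x > stats::median(x)] <- baseline_hazard * hazard_ratio
  }
  t_event <- stats::rexp(n, rate)
  censored <- stats::runif(n) < censor_rate
  u <- stats::runif(n)
  sample_table$time <- ifelse(censored, u * t_event, t_event)
  sample_table$event <- as.integer(!censored)
  sample_table$vital_status <- ifelse(censored, "alive", "dead")
  sample_table
}

#' Write a simulated cohort to a fixture directory
#'
#' Produces the plain-text layout consumed by the pipeline: `counts.tsv`,
#' `beta.tsv`, `cpg_map.tsv`, `samples.tsv`, `truth.tsv`, `roles.tsv`
#' (a small gene-role catalog labeling some planted genes as oncogene /
#' tumor suppressor so the role-annotation and survival stages are
#' exercisable) and `sets.gmt` with the planted hypo/hyper gene sets. All
#' files round-trip through the package readers.
#'
#' @param cohort An `mdg_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_fixtures <- function(cohort, dir) {
  stopifnot(inherits(cohort, "mdg_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_count_matrix(cohort$counts, p("counts.tsv"))
  write_beta_matrix(cohort$beta, p("beta.tsv"))
  write_cpg_map(cohort$cpg_map, p("cpg_map.tsv"))
  write_sample_table(cohort$samples, p("samples.tsv"))
  utils::write.table(cohort$truth, p("truth.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  hypo <- cohort$truth$gene_id[cohort$truth$planted_class == "hypo"]
  hyper <- cohort$truth$gene_id[cohort$truth$planted_class == "hyper"]
  roles <- data.frame(
    gene_id = c(utils::head(hypo, 1L), utils::head(hyper, 2L)),
    role = c(rep("oncogene", length(utils::head(hypo, 1L))),
             rep("tumor_suppressor", length(utils::head(hyper, 2L)))),
    stringsAsFactors = FALSE)
  write_gene_annotation(roles, p("roles.tsv"))
  write_gmt(list(planted_hypo = hypo, planted_hyper = hyper), p("sets.gmt"),
            descriptions = c("planted hypomethylated-overexpressed genes",
                             "planted hypermethylated-underexpressed genes"))
  invisible(c(counts = p("counts.tsv"), beta = p("beta.tsv"),
              cpg_map = p("cpg_map.tsv"), samples = p("samples.tsv"),
              truth = p("truth.tsv"), roles = p("roles.tsv"),
              sets = p("sets.gmt")))
}

#' Read a fixture directory back into an `mdg_cohort`-like list
#'
#' @param dir Directory written by [write_fixtures()].
#' @return List with beta, counts, cpg_map, samples, truth, roles, sets.
#' @export
read_fixtures <- function(dir) {
  p <- function(f) file.path(dir, f)
  list(beta = read_beta_matrix(p("beta.tsv")),
       counts = read_count_matrix(p("counts.tsv")),
       cpg_map = read_cpg_map(p("cpg_map.tsv")),
       samples = read_sample_table(p("samples.tsv")),
       truth = utils::read.delim(p("truth.tsv"), stringsAsFactors = FALSE),
       roles = read_gene_annotation(p("roles.tsv")),
       sets = read_gmt(p("sets.gmt")))
}
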