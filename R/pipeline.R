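#' Configuration for the end-to-end analysis pipeline
#'
#' Collects input paths and every threshold of the analysis. Defaults follow
#' the progression-vs-baseline design: non-tumor (NT) is contrasted against
#' each tumor stage separately; differential expression at |log2FC| > 2 and
#' FDR < 0.05; differential methylation at |mean beta difference| >= 0.15,
#' Wilcoxon p < 0.05 and the 0.4/0.6 tumor beta band; gene classification at
#' promoter-median beta < 0.4 (hypo, with overexpression) or > 0.6 (hyper,
#' with underexpression); enrichment filtered at raw p < 0.01; networks
#' reported at the top 1,000 / 10,000 / 100,000 edges.
#'
#' @param counts,beta,cpg_map,samples Paths to the input TSV files.
#' @param roles Optional path to a gene-role catalog TSV.
#' @param gmt Optional path to a GMT gene-set collection.
#' @param annotation Optional path to a TSV of annotated gene ids (with a
#'   `gene_id` column); `NULL` treats all genes as annotated.
#' @param contrasts List of `c(baseline, target)` pairs; `NULL` uses NT
#'   against every other phenotype present, in phenotype order. Set
#'   `sequential = TRUE` to use the consecutive-stage scheme instead.
#' @param sequential Use consecutive-stage contrasts (NT:I, I:II, ...)
#'   instead of the baseline scheme (default FALSE).
#' @param lfc,fdr DE thresholds (default 2, 0.05).
#' @param mean_diff,dm_p DM thresholds (default 0.15, 0.05).
#' @param beta_low,beta_high Beta band / median classification thresholds
#'   (default 0.4, 0.6).
#' @param enrich_alpha Raw-p enrichment filter (default 0.01).
#' @param top_k Integer vector of edge cutoffs (default
#'   `c(1000, 10000, 100000)`).
#' @param n_boot,boot_group_size Bootstrap DM replicates and per-group
#'   sample count (`NULL` = smallest group); `n_boot = 0` skips the
#'   bootstrap stage.
#' @param anticorrelation Apply the anticorrelation class filter in MDG
#'   calling (default TRUE).
#' @param seed Integer seed for all stochastic stages.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(counts, beta, cpg_map, samples,
                            roles = NULL, gmt = NULL, annotation = NULL,
                            contrasts = NULL, sequential = FALSE,
                            lfc = 2, fdr = 0.05, mean_diff = 0.15, dm_p = 0.05,
                            beta_low = 0.4, beta_high = 0.6,
                            enrich_alpha = 0.01,
                            top_k = c(1000, 10000, 100000),
                            n_boot = 0, boot_group_size = NULL,
                            anticorrelation = TRUE, seed = 1L) {
  stopifnot(lfc > 0, fdr > 0, fdr < 1, mean_diff > 0, mean_diff < 1,
            dm_p > 0, dm_p < 1, beta_low > 0, beta_high < 1,
            beta_low < beta_high, enrich_alpha > 0, all(top_k >= 1))
  cfg <- list(counts = counts, beta = beta, cpg_map = cpg_map,
              samples = samples, roles = roles, gmt = gmt,
              annotation = annotation, contrasts = contrasts,
              sequential = sequential, lfc = lfc, fdr = fdr,
              mean_diff = mean_diff, dm_p = dm_p,
              beta_low = beta_low, beta_high = beta_high,
              enrich_alpha = enrich_alpha, top_k = top_k,
              n_boot = n_boot, boot_group_size = boot_group_size,
              anticorrelation = anticorrelation, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' The YAML keys mirror the arguments of [pipeline_config()]; relative input
#' paths are resolved against the YAML file's directory.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (f in c("counts", "beta", "cpg_map", "samples", "roles", "gmt", "annotation")) {
    if (!is.null(y[[f]]) && !file.exists(y[[f]]))
      y[[f]] <- file.path(base, y[[f]])
  }
  if (!is.null(y$contrasts)) y$contrasts <- lapply(y$contrasts, as.character)
  do.call(pipeline_config, y)
}

#' @keywords internal
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full methylation-driven-gene pipeline
#'
#' Executes preprocess -> differential expression and methylation per
#' contrast -> MDG calling -> stage intersection -> role annotation ->
#' per-phenotype MI networks with first-neighbor concordance -> survival for
#' role-bearing MDGs -> enrichment, writing every intermediate table, a run
#' manifest (config, seed, package version, output checksums) and a
#' plain-text log with per-stage timings. Reruns with the same inputs and
#' seed produce identical output checksums.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "run.log")
  cat("", file = logf)
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    cat(msg, "\n", file = logf, append = TRUE)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    say(sprintf("stage %-14s %.2fs", name, proc.time()[["elapsed"]] - t0))
    out
  }
  set.seed(config$seed)

  inputs <- stage("read", {
    list(counts = read_count_matrix(config$counts),
         beta = read_beta_matrix(config$beta),
         cpg_map = read_cpg_map(config$cpg_map),
         samples = read_sample_table(config$samples),
         roles = if (!is.null(config$roles)) read_gene_annotation(config$roles),
         sets = if (!is.null(config$gmt)) read_gmt(config$gmt),
         annotation = if (!is.null(config$annotation))
           utils::read.delim(config$annotation, stringsAsFactors = FALSE)$gene_id)
  })
  shared <- intersect(colnames(inputs$counts), colnames(inputs$beta))
  if (!length(shared)) stop("no shared sample ids between counts and beta")
  samples <- inputs$samples[inputs$samples$sample_id %in% shared &
                              !is.na(inputs$samples$phenotype), ]

  pre <- stage("preprocess", {
    counts <- filter_genes(inputs$counts[, samples$sample_id, drop = FALSE],
                           annotation = inputs$annotation)
    beta <- clean_cpgs(inputs$beta[, samples$sample_id, drop = FALSE])
    list(counts = counts, beta = beta)
  })
  write_count_matrix(pre$counts, file.path(out_dir, "counts_filtered.tsv"))
  write_beta_matrix(pre$beta, file.path(out_dir, "beta_clean.tsv"))

  phenos <- unique(samples$phenotype)
  contrasts <- config$contrasts
  if (is.null(contrasts)) {
    others <- setdiff(phenos, "NT")
    contrasts <- if (config$sequential) {
      froms <- c("NT", utils::head(others, -1))
      Map(c, froms, others)
    } else {
      lapply(others, function(p) c("NT", p))
    }
  }
  names(contrasts) <- vapply(contrasts, paste, character(1), collapse = ":")

  de_tables <- list(); dm_tables <- list(); mdg_tables <- list()
  for (nm in names(contrasts)) {
    ct <- contrasts[[nm]]
    de_tables[[nm]] <- stage(paste0("de ", nm),
      de_test(pre$counts, samples, ct[1], ct[2],
              lfc_cutoff = config$lfc, fdr_cutoff = config$fdr))
    dm_tables[[nm]] <- stage(paste0("dm ", nm),
      dm_test(pre$beta, samples, ct[1], ct[2],
              mean_diff_cutoff = config$mean_diff, p_cutoff = config$dm_p,
              beta_low = config$beta_low, beta_high = config$beta_high))
    mdg_tables[[nm]] <- stage(paste0("mdg ", nm),
      call_mdgs(dm_tables[[nm]], de_tables[[nm]], pre$beta, inputs$cpg_map,
                samples, ct[1], ct[2], beta_low = config$beta_low,
                beta_high = config$beta_high,
                anticorrelation = config$anticorrelation))
    write_tsv(de_tables[[nm]], file.path(out_dir, paste0("de_", gsub(":", "_", nm), ".tsv")))
    write_tsv(dm_tables[[nm]], file.path(out_dir, paste0("dm_", gsub(":", "_", nm), ".tsv")))
    write_tsv(mdg_tables[[nm]], file.path(out_dir, paste0("mdg_", gsub(":", "_", nm), ".tsv")))
  }

  boot <- NULL
  if (config$n_boot > 0) {
    boot <- stage("bootstrap", bootstrap_dm_counts(
      pre$beta, samples, unname(contrasts), n_boot = config$n_boot,
      group_size = config$boot_group_size, seed = config$seed,
      mean_diff_cutoff = config$mean_diff, p_cutoff = config$dm_p,
      beta_low = config$beta_low, beta_high = config$beta_high))
    write_tsv(boot, file.path(out_dir, "bootstrap_dm_counts.tsv"))
  }

  clust <- stage("cluster", cluster_samples(pre$beta, samples))
  write_tsv(data.frame(sample_id = names(clust$clusters),
                       cluster = unname(clust$clusters)),
            file.path(out_dir, "sample_clusters.tsv"))

  sets <- NULL; roles_tab <- NULL
  if (length(mdg_tables) >= 2) {
    sets <- stage("stage_sets", stage_sets(mdg_tables))
    for (cls in c("hypo", "hyper")) {
      write_tsv(data.frame(gene_id = sets[[cls]]$shared),
                file.path(out_dir, paste0("shared_", cls, ".tsv")))
      excl <- sets[[cls]]$exclusive
      write_tsv(data.frame(contrast = rep(names(excl), lengths(excl)),
                           gene_id = unlist(excl, use.names = FALSE)),
                file.path(out_dir, paste0("exclusive_", cls, ".tsv")))
    }
  }
  shared_genes <- if (!is.null(sets)) unique(c(sets$hypo$shared, sets$hyper$shared))
    else unique(unlist(lapply(mdg_tables, `[[`, "gene_id")))
  if (!is.null(inputs$roles)) {
    roles_tab <- stage("roles", annotate_roles(shared_genes, inputs$roles))
    write_tsv(roles_tab, file.path(out_dir, "shared_roles.tsv"))
  }

  networks <- list(); concordance <- list()
  sf <- size_factors(pre$counts)
  norm <- sweep(pre$counts, 2L, sf, "/")
  role_genes <- if (!is.null(roles_tab)) roles_tab$gene_id[roles_tab$role != "none"]
    else character(0)
  for (nm in names(contrasts)) {
    ct <- contrasts[[nm]]
    mdg_set <- mdg_tables[[nm]]$gene_id
    ids <- samples$sample_id[samples$phenotype == ct[2]]
    if (!length(mdg_set) || length(ids) < 8) next
    net <- stage(paste0("network ", ct[2]),
      infer_network(norm[, ids, drop = FALSE], mdg_set,
                    all_genes = rownames(norm), phenotype = ct[2]))
    for (k in config$top_k) {
      nk <- top_k_edges(net, k)
      write_network(nk, file.path(out_dir, sprintf("network_%s_top%d.tsv", ct[2], k)))
    }
    networks[[nm]] <- top_k_edges(net, max(config$top_k))
    for (g in intersect(role_genes, mdg_set)) {
      sub <- first_neighbors(networks[[nm]], g)
      concordance[[paste(nm, g, sep = "/")]] <- data.frame(
        contrast = nm, gene_id = g, n_neighbors = length(setdiff(sub$nodes, g)),
        concordance = neighbor_concordance(sub, de_tables[[nm]]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(concordance))
    write_tsv(do.call(rbind, concordance), file.path(out_dir, "neighbor_concordance.tsv"))

  surv_tab <- NULL
  if (length(role_genes) && all(c("time", "event") %in% names(samples))) {
    tumor <- samples[samples$phenotype != "NT", ]
    surv_tab <- stage("survival", do.call(rbind, lapply(
      intersect(role_genes, rownames(pre$counts)), function(g) {
        fit <- survival_by_expression(g, pre$counts, tumor)
        data.frame(gene_id = g, statistic = fit$statistic,
                   p_value = fit$p_value, stringsAsFactors = FALSE)
      })))
    if (!is.null(surv_tab)) write_tsv(surv_tab, file.path(out_dir, "survival.tsv"))
  }

  enr <- NULL
  if (!is.null(inputs$sets) && !is.null(sets)) {
    universe <- rownames(pre$counts)
    enr <- stage("enrichment", {
      res <- lapply(c("hypo", "hyper"), function(cls) {
        q <- intersect(sets[[cls]]$shared, universe)
        if (!length(q)) return(NULL)
        tab <- enrich(q, inputs$sets, universe, alpha = config$enrich_alpha)
        if (nrow(tab)) cbind(query = cls, tab) else NULL
      })
      do.call(rbind, res)
    })
    if (!is.null(enr)) write_tsv(enr, file.path(out_dir, "enrichment.tsv"))
  }

  outputs <- setdiff(list.files(out_dir), c("run.log", "manifest.json"))
  manifest <- list(
    package = "mdgpipe",
    version = as.character(utils::packageVersion("mdgpipe")),
    seed = config$seed,
    config = unclass(config),
    contrasts = lapply(contrasts, as.character),
    checksums = as.list(tools::md5sum(file.path(out_dir, sort(outputs)))))
  names(manifest$checksums) <- sort(outputs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  say("done")
  invisible(list(samples = samples, preprocessed = pre, contrasts = contrasts,
                 de = de_tables, dm = dm_tables, mdg = mdg_tables,
                 bootstrap = boot, clustering = clust, stage_sets = sets,
                 roles = roles_tab, networks = networks,
                 concordance = concordance, survival = surv_tab,
                 enrichment = enr, manifest = manifest))
}
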