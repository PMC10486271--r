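#' Median promoter methylation of a gene over a sample subset
#'
#' The median over all (promoter CpG, sample) beta values of the gene,
#' restricted to the given samples. This pooled median over every promoter
#' CpG of the gene is the quantity the hypo/hyper gene classification is
#' applied to.
#'
#' @param beta Cleaned beta matrix.
#' @param cpg_map CpG map (see [read_cpg_map()]).
#' @param gene Gene id.
#' @param sample_ids Character vector of sample ids.
#' @return The median beta, or `NA` if the gene has no promoter CpG in the
#'   matrix.
#' @export
promoter_median <- function(beta, cpg_map, gene, sample_ids) {
  cpgs <- cpg_map$cpg_id[cpg_map$gene_id == gene & cpg_map$region == "promoter"]
  cpgs <- intersect(cpgs, rownames(beta))
  if (!length(cpgs)) return(NA_real_)
  stats::median(beta[cpgs, intersect(sample_ids, colnames(beta)), drop = FALSE])
}

#' Call methylation-driven genes for one contrast
#'
#' A gene is a candidate when at least one of its promoter CpGs is
#' differentially methylated (status not `none` in `dm`) and the gene itself
#' is differentially expressed (status not `none` in `de`). A candidate is a
#' hypomethylated driver when its tumor-group promoter median beta is below
#' `beta_low` and its expression status is `up`; a hypermethylated driver
#' when the median is above `beta_high` and the status is `down`. Candidates
#' satisfying neither rule are dropped — this is the anticorrelation filter
#' linking promoter methylation loss to overexpression and methylation gain
#' to silencing. Strict inequalities: a median exactly at a threshold is not
#' classified.
#'
#' @param dm [dm_test()] output for the contrast.
#' @param de [de_test()] output for the same contrast.
#' @param beta Cleaned beta matrix.
#' @param cpg_map CpG map.
#' @param samples Sample table.
#' @param baseline,target Phenotype labels of the contrast (`target` is the
#'   tumor group supplying the classification medians).
#' @param beta_low,beta_high Median-beta thresholds (defaults 0.4 / 0.6).
#' @param anticorrelation Apply the class rules (default TRUE); with FALSE
#'   all candidates are returned with `methyl_class = NA` (debugging aid:
#'   disabling the filter can only grow the gene set).
#' @return Data.frame: gene_id, contrast, median_beta_tumor, median_beta_nt,
#'   n_promoter_cpgs, n_dm_cpgs, expr_status, methyl_class.
#' @export
call_mdgs <- function(dm, de, beta, cpg_map, samples, baseline, target,
                      beta_low = 0.4, beta_high = 0.6, anticorrelation = TRUE) {
  contrast <- paste0(baseline, ":", target)
  prom <- cpg_map[cpg_map$region == "promoter" & cpg_map$cpg_id %in% rownames(beta), ]
  dm_status <- stats::setNames(dm$status, dm$cpg_id)
  de_status <- stats::setNames(de$status, de$gene_id)
  prom$dm <- dm_status[prom$cpg_id]
  if (anyNA(prom$dm)) stop("dm table does not cover all promoter CpGs; contrast mismatch?")
  n_prom <- table(prom$gene_id)
  n_dm <- tapply(prom$dm != "none", prom$gene_id, sum)
  cand <- names(n_dm)[n_dm >= 1L]
  cand <- cand[cand %in% names(de_status) & de_status[cand] != "none"]
  if (!length(cand)) {
    return(data.frame(gene_id = character(0), contrast = character(0),
                      median_beta_tumor = numeric(0), median_beta_nt = numeric(0),
                      n_promoter_cpgs = integer(0), n_dm_cpgs = integer(0),
                      expr_status = character(0), methyl_class = character(0),
                      stringsAsFactors = FALSE))
  }
  tum <- samples$sample_id[samples$phenotype == target]
  nt <- samples$sample_id[samples$phenotype == baseline]
  med_t <- vapply(cand, function(g) promoter_median(beta, prom, g, tum), numeric(1))
  med_n <- vapply(cand, function(g) promoter_median(beta, prom, g, nt), numeric(1))
  out <- data.frame(gene_id = cand, contrast = contrast,
                    median_beta_tumor = med_t, median_beta_nt = med_n,
                    n_promoter_cpgs = as.integer(n_prom[cand]),
                    n_dm_cpgs = as.integer(n_dm[cand]),
                    expr_status = unname(de_status[cand]),
                    methyl_class = NA_character_,
                    stringsAsFactors = FALSE, row.names = NULL)
  hypo <- out$median_beta_tumor < beta_low & out$expr_status == "up"
  hyper <- out$median_beta_tumor > beta_high & out$expr_status == "down"
  out$methyl_class[hypo] <- "hypo"
  out$methyl_class[hyper] <- "hyper"
  if (anticorrelation) out <- out[!is.na(out$methyl_class), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Shared and stage-exclusive methylation-driven gene sets across contrasts
#'
#' Computes, per methylation class, the intersection of the gene sets across
#' every contrast (the stage-shared drivers), each contrast's exclusive set,
#' and all nonempty Venn cells. Venn logic runs on gene ids; a gene may carry
#' different medians in different contrasts.
#'
#' @param mdg_tables Named list of [call_mdgs()] outputs, one per contrast.
#' @return List with per-class elements `hypo` and `hyper`, each containing
#'   `sets` (per-contrast gene ids), `shared`, `exclusive` (named list) and
#'   `cells` (named list over contrast combinations).
#' @export
stage_sets <- function(mdg_tables) {
  if (length(mdg_tables) < 2) stop("need at least 2 contrasts")
  if (is.null(names(mdg_tables))) stop("mdg_tables must be named by contrast")
  per_class <- function(cls) {
    sets <- lapply(mdg_tables, function(t) unique(t$gene_id[t$methyl_class == cls]))
    shared <- Reduce(intersect, sets)
    exclusive <- lapply(seq_along(sets), function(i) {
      setdiff(sets[[i]], unique(unlist(sets[-i])))
    })
    names(exclusive) <- names(sets)
    nm <- names(sets)
    cells <- list()
    for (mask in seq_len(2^length(sets) - 1L)) {
      inside <- nm[bitwAnd(mask, 2^(seq_along(nm) - 1L)) > 0]
      outside <- setdiff(nm, inside)
      cell <- Reduce(intersect, sets[inside])
      if (length(outside)) cell <- setdiff(cell, unique(unlist(sets[outside])))
      cells[[paste(inside, collapse = "&")]] <- cell
    }
    list(sets = sets, shared = shared, exclusive = exclusive, cells = cells)
  }
  list(hypo = per_class("hypo"), hyper = per_class("hyper"))
}

#' Label genes with their cancer role from a catalog
#'
#' Joins a gene set against a gene-role catalog; genes absent from the
#' catalog get role `none`. Genes catalogued as both oncogene and tumor
#' suppressor should carry the role `both` in the catalog.
#'
#' @param genes Character vector of gene ids.
#' @param catalog Data.frame with `gene_id` and `role` (see
#'   [read_gene_annotation()]).
#' @return Data.frame: gene_id, role.
#' @export
annotate_roles <- function(genes, catalog) {
  role <- catalog$role[match(genes, catalog$gene_id)]
  role[is.na(role)] <- "none"
  data.frame(gene_id = genes, role = role, stringsAsFactors = FALSE)
}
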