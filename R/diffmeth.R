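#' @keywords internal
#' Two-sided Wilcoxon rank-sum p-value for x vs y.
#' Exact (via the null rank-sum distribution) when both groups have <= `exact_max`
#' observations and there are no ties; otherwise the normal approximation with
#' tie and continuity correction, matching `stats::wilcox.test(correct = TRUE)`.
rank_sum_p <- function(x, y, exact_max = 8L) {
  n1 <- length(x); n2 <- length(y)
  v <- c(x, y)
  if (length(unique(v)) == 1L) return(1)
  r <- rank(v)
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(v))
  if (!ties && n1 <= exact_max && n2 <= exact_max) {
    if (W > n1 * n2 / 2) {
      p <- 2 * stats::pwilcox(W - 1, n1, n2, lower.tail = FALSE)
    } else {
      p <- 2 * stats::pwilcox(W, n1, n2)
    }
    return(min(p, 1))
  }
  nt <- table(r)
  sigma2 <- (n1 * n2 / 12) * ((n1 + n2 + 1) -
    sum(nt^3 - nt) / ((n1 + n2) * (n1 + n2 - 1)))
  if (sigma2 == 0) return(1)
  z <- W - n1 * n2 / 2
  z <- sign(z) * max(abs(z) - 0.5, 0) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Per-CpG differential methylation between two phenotypes
#'
#' For each CpG the mean beta difference (target minus baseline) and a
#' two-sided Wilcoxon rank-sum p-value are computed (exact when both groups
#' have at most 8 samples and no ties, normal approximation with tie and
#' continuity correction otherwise). A CpG is called `hyper` when
#' `mean_diff >= mean_diff_cutoff`, `p < p_cutoff` and the tumor-group mean
#' beta lies above `beta_high`; `hypo` when `mean_diff <= -mean_diff_cutoff`,
#' `p < p_cutoff` and the tumor mean lies below `beta_low`; otherwise `none`.
#' Set `band = FALSE` to drop the beta-band requirement (mean-diff +
#' p-value only). A CpG constant across both groups gets p = 1.
#'
#' @param beta Cleaned CpG-by-sample beta matrix (no missing values).
#' @param samples Sample table with `sample_id` and `phenotype`.
#' @param baseline,target Phenotype labels; `target` is the tumor side.
#' @param mean_diff_cutoff Minimum absolute mean beta difference (default 0.15).
#' @param p_cutoff Raw p-value threshold (default 0.05).
#' @param beta_low,beta_high Tumor-mean beta thresholds for hypo/hyper calls
#'   (defaults 0.4 and 0.6).
#' @param band Apply the beta-band requirement (default TRUE).
#' @param adjust Multiple-testing adjustment for the p-values used in the
#'   status call; `"none"` (default, raw p as in the mean-diff + Wilcoxon
#'   rule) or any `stats::p.adjust` method.
#' @return Data.frame: cpg_id, mean_diff, pvalue, tumor_mean_beta, status.
#' @export
dm_test <- function(beta, samples, baseline, target,
                    mean_diff_cutoff = 0.15, p_cutoff = 0.05,
                    beta_low = 0.4, beta_high = 0.6, band = TRUE,
                    adjust = "none") {
  i0 <- intersect(samples$sample_id[samples$phenotype == baseline], colnames(beta))
  i1 <- intersect(samples$sample_id[samples$phenotype == target], colnames(beta))
  if (length(i0) < 2 || length(i1) < 2) stop("each group needs >= 2 samples")
  if (anyNA(beta[, c(i0, i1)])) stop("beta matrix has missing values; run clean_cpgs() first")
  b0 <- beta[, i0, drop = FALSE]; b1 <- beta[, i1, drop = FALSE]
  mean_diff <- rowMeans(b1) - rowMeans(b0)
  tumor_mean <- rowMeans(b1)
  pvalue <- vapply(seq_len(nrow(beta)),
                   function(i) rank_sum_p(b1[i, ], b0[i, ]), numeric(1))
  p_used <- if (identical(adjust, "none")) pvalue else stats::p.adjust(pvalue, method = adjust)
  status <- rep("none", nrow(beta))
  sig <- p_used < p_cutoff
  hyper <- sig & mean_diff >= mean_diff_cutoff
  hypo <- sig & mean_diff <= -mean_diff_cutoff
  if (band) {
    hyper <- hyper & tumor_mean > beta_high
    hypo <- hypo & tumor_mean < beta_low
  }
  status[hyper] <- "hyper"
  status[hypo] <- "hypo"
  data.frame(cpg_id = rownames(beta), mean_diff = mean_diff, pvalue = pvalue,
             tumor_mean_beta = tumor_mean, status = status,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Bootstrap differentially-methylated CpG counts at equalized group sizes
#'
#' To mitigate unbalanced phenotype groups, each bootstrap replicate draws
#' `group_size` samples per phenotype (default: the smallest group size,
#' matching a scale-down-to-smallest design), runs [dm_test()] for every
#' contrast and counts hyper- and hypomethylated CpGs. Sampling is without
#' replacement when a group is at least `group_size` large, with replacement
#' otherwise.
#'
#' @param beta Cleaned beta matrix.
#' @param samples Sample table.
#' @param contrasts List of `c(baseline, target)` phenotype pairs.
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param group_size Samples drawn per phenotype; default `NULL` uses the
#'   smallest group involved in any contrast.
#' @param seed Integer seed.
#' @param conf Width of the reported percentile interval (default 0.95).
#' @param ... Passed to [dm_test()] (thresholds, `band`, ...).
#' @return Data.frame with one row per contrast: baseline, target,
#'   mean/lo/hi of hyper and hypo counts, n_boot, group_size.
#' @export
bootstrap_dm_counts <- function(beta, samples, contrasts, n_boot = 1000,
                                group_size = NULL, seed = 1L, conf = 0.95, ...) {
  if (n_boot < 1) stop("n_boot must be >= 1")
  set.seed(seed)
  phenos <- unique(unlist(contrasts))
  sizes <- vapply(phenos, function(p) sum(samples$phenotype == p), integer(1))
  if (is.null(group_size)) group_size <- min(sizes)
  counts <- array(NA_real_, dim = c(length(contrasts), n_boot, 2L),
                  dimnames = list(NULL, NULL, c("hyper", "hypo")))
  for (b in seq_len(n_boot)) {
    picked <- lapply(phenos, function(p) {
      ids <- samples$sample_id[samples$phenotype == p]
      sample(ids, group_size, replace = length(ids) < group_size)
    })
    names(picked) <- phenos
    for (ci in seq_along(contrasts)) {
      ct <- contrasts[[ci]]
      ids <- c(picked[[ct[1L]]], picked[[ct[2L]]])
      sub_samples <- data.frame(
        sample_id = ids,
        phenotype = rep(ct, each = group_size),
        stringsAsFactors = FALSE)
      # resampling with replacement can duplicate column ids; subset keeps them
      sub_beta <- beta[, ids, drop = FALSE]
      colnames(sub_beta) <- sub_samples$sample_id <- sprintf("bs%04d", seq_along(ids))
      dm <- dm_test(sub_beta, sub_samples, ct[1L], ct[2L], ...)
      counts[ci, b, "hyper"] <- sum(dm$status == "hyper")
      counts[ci, b, "hypo"] <- sum(dm$status == "hypo")
    }
  }
  a <- (1 - conf) / 2
  out <- do.call(rbind, lapply(seq_along(contrasts), function(ci) {
    data.frame(baseline = contrasts[[ci]][1L], target = contrasts[[ci]][2L],
               hyper_mean = mean(counts[ci, , "hyper"]),
               hyper_lo = stats::quantile(counts[ci, , "hyper"], a, names = FALSE),
               hyper_hi = stats::quantile(counts[ci, , "hyper"], 1 - a, names = FALSE),
               hypo_mean = mean(counts[ci, , "hypo"]),
               hypo_lo = stats::quantile(counts[ci, , "hypo"], a, names = FALSE),
               hypo_hi = stats::quantile(counts[ci, , "hypo"], 1 - a, names = FALSE),
               n_boot = n_boot, group_size = group_size,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Hierarchical clustering of samples on their methylation profiles
#'
#' Samples are clustered with Euclidean distance on beta columns and average
#' linkage, then cut into `k` flat clusters. The non-tumor (NT) purity is the
#' fraction of NT samples falling in the cluster that contains the majority
#' of NT samples; a value near 1 reproduces the well-separated NT cluster
#' seen in tumor methylation data.
#'
#' @param beta Cleaned beta matrix.
#' @param samples Sample table.
#' @param k Number of flat clusters (default 2).
#' @return List: `hclust` (the dendrogram), `clusters` (named integer
#'   vector), `nt_purity`.
#' @export
cluster_samples <- function(beta, samples, k = 2L) {
  ids <- intersect(samples$sample_id, colnames(beta))
  if (length(ids) < 3) stop("need at least 3 samples to cluster")
  if (length(ids) < k) stop("fewer samples than clusters requested")
  hc <- stats::hclust(stats::dist(t(beta[, ids, drop = FALSE])), method = "average")
  cl <- stats::cutree(hc, k = k)
  nt <- samples$sample_id[samples$phenotype == "NT"]
  nt <- intersect(nt, ids)
  purity <- if (length(nt)) max(table(cl[nt])) / length(nt) else NA_real_
  list(hclust = hc, clusters = cl, nt_purity = purity)
}
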