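#' Median-of-ratios size factors
#'
#' For every gene with nonzero counts in all samples, the per-sample count is
#' divided by the gene's geometric mean across samples; the size factor of a
#' sample is the median of these ratios, rescaled so the factors have
#' geometric mean 1.
#'
#' @param counts Gene-by-sample count matrix.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  pos <- rowSums(counts == 0) == 0L
  if (!any(pos)) stop("no gene has nonzero counts in every sample")
  lc <- log(counts[pos, , drop = FALSE])
  lgm <- rowMeans(lc)
  sf <- apply(lc, 2L, function(x) exp(stats::median(x - lgm)))
  sf <- sf / exp(mean(log(sf)))
  sf
}

#' @keywords internal
de_status <- function(log2fc, fdr, lfc_cutoff = 2, fdr_cutoff = 0.05) {
  status <- rep("none", length(log2fc))
  ok <- !is.na(log2fc) & !is.na(fdr)
  status[ok & log2fc > lfc_cutoff & fdr < fdr_cutoff] <- "up"
  status[ok & log2fc < -lfc_cutoff & fdr < fdr_cutoff] <- "down"
  status
}

#' Two-group negative-binomial differential expression
#'
#' A DESeq-style test: counts are normalized by median-of-ratios size
#' factors; per gene the log2 fold change is
#' `log2((mean_target + pc) / (mean_baseline + pc))` with pseudocount `pc`;
#' the p-value comes from a Wald test on the log ratio with a
#' method-of-moments negative-binomial dispersion (pooled within-group,
#' floored at 1e-8) and delta-method standard error; FDR is
#' Benjamini-Hochberg across all tested genes. A gene is `up` when
#' `log2fc > lfc_cutoff` and `fdr < fdr_cutoff` (strict inequalities),
#' `down` symmetrically, `none` otherwise. Genes with all-zero counts in
#' both groups are excluded from testing (status `none`, NA statistics).
#'
#' @param counts Gene-by-sample count matrix.
#' @param samples Sample table with `sample_id` and `phenotype`.
#' @param baseline,target Phenotype labels of the two groups.
#' @param lfc_cutoff Log2 fold-change threshold (default 2).
#' @param fdr_cutoff FDR threshold (default 0.05).
#' @param pseudocount Added to group means before the ratio (default 0.5).
#' @return Data.frame: gene_id, log2fc, pvalue, fdr, status.
#' @export
de_test <- function(counts, samples, baseline, target,
                    lfc_cutoff = 2, fdr_cutoff = 0.05, pseudocount = 0.5) {
  i0 <- samples$sample_id[samples$phenotype == baseline]
  i1 <- samples$sample_id[samples$phenotype == target]
  i0 <- intersect(i0, colnames(counts)); i1 <- intersect(i1, colnames(counts))
  if (length(i0) < 2 || length(i1) < 2) stop("each group needs >= 2 samples")
  sf <- size_factors(counts[, c(i0, i1), drop = FALSE])
  q <- sweep(counts[, c(i0, i1), drop = FALSE], 2L, sf, "/")
  q0 <- q[, i0, drop = FALSE]; q1 <- q[, i1, drop = FALSE]
  n0 <- length(i0); n1 <- length(i1)
  m0 <- rowMeans(q0); m1 <- rowMeans(q1)
  v0 <- rowSums((q0 - m0)^2) / (n0 - 1)
  v1 <- rowSums((q1 - m1)^2) / (n1 - 1)
  # method-of-moments dispersion pooled over groups, floored
  a0 <- ifelse(m0 > 0, (v0 - m0) / m0^2, NA_real_)
  a1 <- ifelse(m1 > 0, (v1 - m1) / m1^2, NA_real_)
  w0 <- ifelse(is.na(a0), 0, n0 - 1); w1 <- ifelse(is.na(a1), 0, n1 - 1)
  alpha <- (ifelse(is.na(a0), 0, a0) * w0 + ifelse(is.na(a1), 0, a1) * w1) /
    pmax(w0 + w1, 1)
  alpha <- pmax(alpha, 1e-8)
  pc <- pseudocount
  log2fc <- log2((m1 + pc) / (m0 + pc))
  se2 <- (m0 + alpha * m0^2) / (n0 * (m0 + pc)^2) +
         (m1 + alpha * m1^2) / (n1 * (m1 + pc)^2)
  wald <- (log(m1 + pc) - log(m0 + pc)) / sqrt(se2)
  pvalue <- 2 * stats::pnorm(-abs(wald))
  degenerate <- m0 == 0 & m1 == 0
  log2fc[degenerate] <- NA_real_
  pvalue[degenerate] <- NA_real_
  fdr <- rep(NA_real_, length(pvalue))
  fdr[!degenerate] <- stats::p.adjust(pvalue[!degenerate], method = "BH")
  data.frame(gene_id = rownames(counts),
             log2fc = log2fc, pvalue = pvalue, fdr = fdr,
             status = de_status(log2fc, fdr, lfc_cutoff, fdr_cutoff),
             stringsAsFactors = FALSE, row.names = NULL)
}
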