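#' Beta value from methylated/unmethylated array intensities
#'
#' The methylation level of a CpG is beta = M / (M + U), where M is the
#' methylated and U the unmethylated probe intensity. When M + U = 0 the
#' value is undefined and reported as `NA` (a missing beta, later removed by
#' [clean_cpgs()]).
#'
#' @param M Nonnegative methylated intensity (vectorized).
#' @param U Nonnegative unmethylated intensity (vectorized).
#' @return Numeric vector of beta values in \[0,1\], `NA` where M + U = 0.
#' @export
beta_from_intensities <- function(M, U) {
  if (any(M < 0, na.rm = TRUE) || any(U < 0, na.rm = TRUE))
    stop("intensities must be nonnegative")
  tot <- M + U
  out <- M / tot
  out[tot == 0] <- NA_real_
  out
}

#' Filter a count matrix by annotation, zero fraction and mean expression
#'
#' Applies, in order: (1) drop genes not present in the annotation,
#' (2) drop genes with zero counts in more than `max_zero_fraction` of the
#' samples (strictly more), (3) drop genes whose mean count across samples is
#' strictly below `min_mean`. A gene whose mean is exactly `min_mean` is
#' retained. Surviving genes keep their input order; the filter is idempotent.
#'
#' @param counts Gene-by-sample count matrix.
#' @param annotation Character vector of annotated gene ids, or a data.frame
#'   with a `gene_id` column, or `NULL` to treat every gene as annotated.
#' @param max_zero_fraction Maximum tolerated fraction of zero-count samples
#'   per gene (default 0.5).
#' @param min_mean Minimum mean count per gene (default 10).
#' @return Filtered count matrix (possibly with zero rows, with a warning).
#' @export
filter_genes <- function(counts, annotation = NULL, max_zero_fraction = 0.5,
                         min_mean = 10) {
  if (!is.null(annotation)) {
    ids <- if (is.data.frame(annotation)) annotation$gene_id else annotation
    counts <- counts[rownames(counts) %in% ids, , drop = FALSE]
  }
  zf <- rowMeans(counts == 0)
  counts <- counts[zf <= max_zero_fraction, , drop = FALSE]
  counts <- counts[rowMeans(counts) >= min_mean, , drop = FALSE]
  if (nrow(counts) == 0L) warning("no genes survive filtering")
  counts
}

#' Drop CpGs with any missing beta value
#'
#' A CpG row containing at least one missing value is removed entirely; no
#' imputation is attempted.
#'
#' @param beta CpG-by-sample beta matrix.
#' @return Beta matrix with complete rows only.
#' @export
clean_cpgs <- function(beta) {
  keep <- stats::complete.cases(beta)
  out <- beta[keep, , drop = FALSE]
  if (nrow(out) == 0L && nrow(beta) > 0L)
    warning("all CpGs had missing values; result is empty")
  out
}

#' Within-bin full-quantile normalization against a per-gene covariate
#'
#' Removes a systematic dependence of counts on a per-gene covariate (e.g. GC
#' content or gene length). Genes are split into `n_bins` equal-frequency
#' covariate bins; within each sample, the counts of each bin are
#' full-quantile mapped onto the quantiles of all genes in that sample (the
#' pooled across-bin reference). Output is rounded half-to-even back to
#' integers so downstream count models still apply. A constant covariate
#' collapses to a single bin, which leaves the matrix unchanged up to
#' rounding.
#'
#' @param counts Gene-by-sample count matrix.
#' @param covariate Numeric vector, one value per gene (same order as rows).
#' @param n_bins Number of equal-frequency bins (>= 2).
#' @return Normalized integer count matrix, same dimnames as the input.
#' @export
within_bin_quantile_normalize <- function(counts, covariate, n_bins = 10) {
  if (length(covariate) != nrow(counts))
    stop("covariate must have one value per gene")
  if (any(is.na(covariate))) stop("covariate must be known for all genes")
  if (n_bins < 2) stop("n_bins must be >= 2")
  G <- nrow(counts)
  if (length(unique(covariate)) == 1L) {
    bins <- rep(1L, G)
  } else {
    ord <- order(covariate, rownames(counts))
    bins <- integer(G)
    bins[ord] <- ceiling(seq_len(G) * n_bins / G)
  }
  # merge undersized bins with their lower neighbor
  repeat {
    sz <- table(bins)
    small <- names(sz)[sz < 2L]
    if (!length(small) || length(sz) == 1L) break
    b <- as.integer(small[1L])
    ids <- sort(unique(bins))
    nb <- if (b == min(ids)) ids[ids > b][1L] else max(ids[ids < b])
    warning("bin with fewer than 2 genes merged with neighbor")
    bins[bins == b] <- nb
  }
  out <- counts
  bin_idx <- split(seq_len(G), bins)
  for (j in seq_len(ncol(counts))) {
    v <- sort(counts[, j])
    for (idx in bin_idx) {
      x <- counts[idx, j]
      m <- length(x)
      pr <- if (m == 1L) 0.5 else (rank(x, ties.method = "average") - 1) / (m - 1)
      out[idx, j] <- stats::quantile(v, pr, type = 7, names = FALSE)
    }
  }
  round(out)
}
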