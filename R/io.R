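#' @keywords internal
read_id_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("matrix file needs an id column plus at least one sample column: ", path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate row ids in ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- ids
  m
}

#' @keywords internal
write_id_matrix <- function(x, path, id_name) {
  df <- data.frame(id = rownames(x), x, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- id_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write a gene-by-sample count matrix
#'
#' Counts are stored as TSV with gene ids in the first column (`gene_id`) and
#' one column per sample. All entries must be nonnegative; duplicated gene or
#' sample ids are an error.
#'
#' @param path Path to a tab-delimited file.
#' @return A numeric matrix with gene rownames and sample colnames.
#' @export
read_count_matrix <- function(path) {
  m <- read_id_matrix(path)
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids in ", path)
  if (any(m < 0, na.rm = TRUE)) stop("negative counts in ", path)
  m
}

#' @rdname read_count_matrix
#' @param x Matrix to write.
#' @export
write_count_matrix <- function(x, path) write_id_matrix(x, path, "gene_id")

#' Read or write a CpG-by-sample beta-value matrix
#'
#' Beta values are methylation levels M/(M+U) in \[0,1\]; missing entries are
#' permitted on input (see [clean_cpgs()]).
#'
#' @param path Path to a tab-delimited file, CpG ids in the first column.
#' @return Numeric matrix with CpG rownames and sample colnames.
#' @export
read_beta_matrix <- function(path) {
  m <- read_id_matrix(path)
  rng <- range(m, na.rm = TRUE)
  if (rng[1L] < 0 || rng[2L] > 1) stop("beta values outside [0,1] in ", path)
  m
}

#' @rdname read_beta_matrix
#' @param x Matrix to write.
#' @export
write_beta_matrix <- function(x, path) write_id_matrix(x, path, "cpg_id")

#' Read or write the CpG-to-gene map
#'
#' BED-like TSV with columns `cpg_id`, `chrom`, `pos` (0-based), `gene_id`,
#' `region` (promoter / body / other). Each CpG maps to at most one gene;
#' when a CpG id occurs more than once only its first occurrence is kept.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with one row per CpG.
#' @export
read_cpg_map <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("cpg_id", "chrom", "pos", "gene_id", "region")
  if (!all(need %in% names(df))) stop("cpg map must have columns: ", paste(need, collapse = ", "))
  df <- df[!duplicated(df$cpg_id), need, drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @rdname read_cpg_map
#' @param x CpG map data.frame to write.
#' @export
write_cpg_map <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write the sample annotation table
#'
#' TSV with columns `sample_id`, `phenotype` (NT, I, II, III, IV),
#' `vital_status`, `time` (days of follow-up) and `event` (1 = death observed,
#' 0 = censored).
#'
#' @param path Path to the TSV file.
#' @return A data.frame with one row per sample.
#' @export
read_sample_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "phenotype")
  if (!all(need %in% names(df))) stop("sample table must have columns sample_id and phenotype")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in ", path)
  df
}

#' @rdname read_sample_table
#' @param x Sample table to write.
#' @export
write_sample_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write a gene-role catalog
#'
#' TSV with columns `gene_id` and `role`; roles are `oncogene`,
#' `tumor_suppressor`, `both` or `none`. Genes absent from the catalog are
#' treated as annotated with role `none` by [annotate_roles()]; a gene listed
#' in both an oncogene and a tumor-suppressor source should already carry the
#' label `both`.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with columns gene_id, role.
#' @export
read_gene_annotation <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(df)) stop("gene annotation must have a gene_id column")
  if (!"role" %in% names(df)) df$role <- "none"
  bad <- setdiff(unique(df$role), c("oncogene", "tumor_suppressor", "both", "none"))
  if (length(bad)) stop("unknown roles: ", paste(bad, collapse = ", "))
  df[, c("gene_id", "role")]
}

#' @rdname read_gene_annotation
#' @param x Annotation data.frame to write.
#' @export
write_gene_annotation <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write gene sets in GMT format
#'
#' One set per line: set name, description, then tab-separated member ids.
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of character vectors (set name -> members).
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @param descriptions Optional character vector of per-set descriptions
#'   (defaults to the set names).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("every gene set must be named")
  if (is.null(descriptions)) descriptions <- names(sets)
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
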