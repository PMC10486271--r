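#' Upper-tail hypergeometric over-representation p-value
#'
#' `p = P(X >= overlap)` where X is the overlap between a random query of
#' the observed size and the gene set, drawn from the universe without
#' replacement. Query and set are restricted to the universe before
#' testing.
#'
#' @param query Character vector of query gene ids.
#' @param geneset Character vector of set member ids.
#' @param universe Character vector of background gene ids.
#' @return The upper-tail hypergeometric p-value.
#' @export
ora_test <- function(query, geneset, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  query <- unique(intersect(query, universe))
  geneset <- unique(intersect(geneset, universe))
  if (!length(query)) stop("empty query (after restriction to the universe)")
  k <- length(intersect(query, geneset))
  stats::phyper(k - 1, length(geneset), length(universe) - length(geneset),
                length(query), lower.tail = FALSE)
}

#' Over-representation analysis of a query against a gene-set collection
#'
#' Runs [ora_test()] for every set, reports Benjamini-Hochberg FDR across
#' sets, and filters at raw `p < alpha` (strict; the default 0.01 matches
#' the conventional stringent cutoff for GO-style results). Sets with no
#' members inside the universe are dropped with a message. Results do not
#' depend on the ordering of gene ids within sets.
#'
#' @param query Character vector of query gene ids.
#' @param collection Named list of gene sets (e.g. from [read_gmt()]).
#' @param universe Background gene ids (typically the genes surviving
#'   preprocessing).
#' @param alpha Raw p-value threshold (default 0.01); use 1 to keep all
#'   sets.
#' @return Data.frame sorted by p: set, overlap, set_size, p, fdr.
#' @export
enrich <- function(query, collection, universe, alpha = 0.01) {
  universe <- unique(universe)
  restricted <- lapply(collection, function(s) unique(intersect(s, universe)))
  empty <- vapply(restricted, length, integer(1)) == 0L
  if (any(empty)) {
    message("dropping ", sum(empty), " set(s) with no members in the universe")
    restricted <- restricted[!empty]
  }
  if (!length(restricted)) {
    return(data.frame(set = character(0), overlap = integer(0),
                      set_size = integer(0), p = numeric(0), fdr = numeric(0),
                      stringsAsFactors = FALSE))
  }
  q <- unique(intersect(query, universe))
  p <- vapply(restricted, function(s) ora_test(q, s, universe), numeric(1))
  out <- data.frame(set = names(restricted),
                    overlap = vapply(restricted, function(s) length(intersect(q, s)), integer(1)),
                    set_size = vapply(restricted, length, integer(1)),
                    p = unname(p), fdr = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$p, out$set), , drop = FALSE]
  if (alpha < 1) out <- out[out$p < alpha, , drop = FALSE]
  rownames(out) <- NULL
  out
}
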