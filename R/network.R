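#' @keywords internal
#' Equal-frequency bin assignment by rank; ties broken by position so a
#' strictly monotone transform of the input yields identical bins.
bin_ranks <- function(x, bins) {
  ceiling(bins * rank(x, ties.method = "first") / length(x))
}

#' @keywords internal
#' Plug-in MI with Miller-Madow bias correction, clamped at 0. The plug-in
#' estimate is biased upward by roughly (Bx-1)(By-1)/(2n); the correction
#' subtracts the occupied-cell version of that term.
mi_from_bins <- function(bx, by, bins) {
  n <- length(bx)
  tab <- tabulate((bx - 1L) * bins + by, nbins = bins * bins)
  cx <- tabulate(bx, nbins = bins)
  cy <- tabulate(by, nbins = bins)
  px <- cx / n
  py <- cy / n
  nz <- which(tab > 0L)
  p <- tab[nz] / n
  i <- ((nz - 1L) %/% bins) + 1L
  j <- ((nz - 1L) %% bins) + 1L
  mi <- sum(p * log(p / (px[i] * py[j])))
  mi <- mi + (sum(cx > 0L) - 1 + sum(cy > 0L) - 1 - (length(nz) - 1)) / (2 * n)
  max(mi, 0)
}

#' Mutual information of two numeric vectors
#'
#' Both vectors are discretized into `bins` equal-frequency bins on their
#' ranks and the plug-in estimate
#' `sum p(a,b) * log(p(a,b) / (p(a) p(b)))` is computed, in nats, with a
#' Miller-Madow bias correction (the raw plug-in estimate is inflated by
#' about `(bins-1)^2 / (2n)`, which would swamp weak dependencies) and a
#' clamp at zero. The default bin count `max(2, floor(n^(1/3)))` keeps both
#' bias and variance small; the rank-based binning makes the estimate
#' invariant under strictly monotone transforms of either input. A constant
#' vector carries no information and returns 0 exactly.
#'
#' @param x,y Numeric vectors of equal length n >= 8.
#' @param bins Number of bins (default `max(2, floor(n^(1/3)))`).
#' @return Nonnegative mutual information in nats.
#' @export
mutual_information <- function(x, y, bins = NULL) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 8) stop("need at least 8 observations")
  if (is.null(bins)) bins <- max(2L, floor(n^(1/3)))
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) return(0)
  mi_from_bins(bin_ranks(x, bins), bin_ranks(y, bins), as.integer(bins))
}

#' Infer a mutual-information co-expression network for one phenotype
#'
#' Computes MI over the expression profiles of every (driver gene, gene)
#' pair with the driver in `mdg_set` and the partner in `all_genes`,
#' excluding self-pairs. Edges are canonicalized (`gene_a < gene_b`
#' lexicographically) and deduplicated, so a pair of two driver genes yields
#' a single edge. For a driver set of size m disjoint from an `all_genes`
#' set of size A this gives m * A edges (e.g. 275 x 16227 = 4462425).
#'
#' @param expr Normalized expression matrix (genes x samples) restricted to
#'   the phenotype's samples (>= 8 samples).
#' @param mdg_set Character vector of driver gene ids (must be rows of
#'   `expr`).
#' @param all_genes Partner gene ids (default: all rows of `expr`). Set this
#'   to `mdg_set` for a driver-only network.
#' @param phenotype Label stored on the network (default `NA`).
#' @param bins MI bin count (default `max(2, floor(n_samples^(1/3)))`).
#' @return Data.frame of class `mi_network`: gene_a, gene_b, mi; attribute
#'   `phenotype`.
#' @export
infer_network <- function(expr, mdg_set, all_genes = rownames(expr),
                          phenotype = NA_character_, bins = NULL) {
  if (!length(mdg_set)) stop("mdg_set is empty")
  missing_g <- setdiff(union(mdg_set, all_genes), rownames(expr))
  if (length(missing_g)) stop("genes absent from expression matrix: ",
                              paste(utils::head(missing_g, 3), collapse = ", "))
  n <- ncol(expr)
  if (n < 8) stop("phenotype needs >= 8 samples")
  if (is.null(bins)) bins <- max(2L, floor(n^(1/3)))
  bins <- as.integer(bins)
  univ <- union(mdg_set, all_genes)
  bm <- t(apply(expr[univ, , drop = FALSE], 1L, bin_ranks, bins = bins))
  const <- apply(expr[univ, , drop = FALSE], 1L, function(r) length(unique(r)) == 1L)
  names(const) <- univ
  ga <- rep(mdg_set, each = length(all_genes))
  gb <- rep(all_genes, times = length(mdg_set))
  keep <- ga != gb
  ga <- ga[keep]; gb <- gb[keep]
  a <- pmin(ga, gb); b <- pmax(ga, gb)
  key <- paste(a, b, sep = "\r")
  first <- !duplicated(key)
  a <- a[first]; b <- b[first]
  mi <- numeric(length(a))
  for (e in seq_along(a)) {
    mi[e] <- if (const[[a[e]]] || const[[b[e]]]) 0 else
      mi_from_bins(bm[a[e], ], bm[b[e], ], bins)
  }
  out <- data.frame(gene_a = a, gene_b = b, mi = mi, stringsAsFactors = FALSE)
  attr(out, "phenotype") <- phenotype
  class(out) <- c("mi_network", class(out))
  out
}

#' Number of unique driver-gene MI pairs
#'
#' The number of edges [infer_network()] evaluates: all (driver, partner)
#' pairs minus self-pairs, counting each unordered driver-driver pair once.
#' For a driver set of size `n_mdg` disjoint from `n_genes` partners this is
#' `n_mdg * n_genes` (e.g. 275 drivers against a 16,227-gene transcriptome
#' give 4,462,425, about 4.5 million pairs).
#'
#' @param n_mdg Driver set size.
#' @param n_genes Partner set size.
#' @param overlap Number of genes in both sets (default 0).
#' @return The unique pair count.
#' @export
pair_count <- function(n_mdg, n_genes, overlap = 0) {
  n_mdg * n_genes - overlap - choose(overlap, 2)
}

#' Keep the k strongest edges of a network
#'
#' Returns exactly `min(k, nrow(network))` edges, the largest by MI; ties at
#' the boundary are broken by lexicographic (gene_a, gene_b) order so the
#' result does not depend on the input edge order.
#'
#' @param network An edge data.frame with columns gene_a, gene_b, mi.
#' @param k Number of edges to keep (>= 1).
#' @return The filtered network, same class and attributes.
#' @export
top_k_edges <- function(network, k) {
  if (k < 1) stop("k must be >= 1")
  ord <- order(-network$mi, network$gene_a, network$gene_b)
  out <- network[utils::head(ord, k), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "phenotype") <- attr(network, "phenotype")
  out
}

#' First neighbors of a seed gene in a network
#'
#' All edges incident to the seed, plus the incident node set. An absent
#' seed yields an empty subnetwork (with a message).
#'
#' @param network Edge data.frame (gene_a, gene_b, mi).
#' @param seed_gene Gene id.
#' @return List: `edges` (data.frame), `nodes` (character, including the
#'   seed when present), `seed`.
#' @export
first_neighbors <- function(network, seed_gene) {
  hit <- network$gene_a == seed_gene | network$gene_b == seed_gene
  edges <- network[hit, , drop = FALSE]
  rownames(edges) <- NULL
  if (!nrow(edges)) message("seed gene not present in network: ", seed_gene)
  nodes <- unique(c(edges$gene_a, edges$gene_b))
  list(edges = edges, nodes = nodes, seed = seed_gene)
}

#' Expression-direction concordance between a seed and its first neighbors
#'
#' The fraction of neighbors (seed excluded) whose differential-expression
#' status equals the seed's, computed over neighbors with a non-missing
#' status available in `de` (`none` counts as a discordant status).
#'
#' @param subnetwork Output of [first_neighbors()].
#' @param de [de_test()] output supplying statuses.
#' @return Fraction in \[0,1\], or `NA` when no neighbor has a usable
#'   status.
#' @export
neighbor_concordance <- function(subnetwork, de) {
  seed <- subnetwork$seed
  st <- stats::setNames(de$status, de$gene_id)
  seed_status <- st[seed]
  if (is.na(seed_status)) return(NA_real_)
  nb <- setdiff(subnetwork$nodes, seed)
  nb_status <- st[nb]
  nb_status <- nb_status[!is.na(nb_status)]
  if (!length(nb_status)) return(NA_real_)
  mean(nb_status == seed_status)
}

#' Data-processing-inequality pruning of an MI network
#'
#' For every triangle, the weakest edge is removed when its MI is below
#' `(1 - tolerance)` times the smaller of the other two edges — the
#' classical indirect-interaction filter for MI networks. Off by default in
#' the pipeline; exposed for exploratory use.
#'
#' @param network Edge data.frame (gene_a, gene_b, mi).
#' @param tolerance Relative tolerance in \[0,1\] (default 0.15).
#' @return The pruned network.
#' @export
dpi_prune <- function(network, tolerance = 0.15) {
  mi_of <- stats::setNames(network$mi, paste(network$gene_a, network$gene_b, sep = "\r"))
  get_mi <- function(u, v) {
    k <- paste(pmin(u, v), pmax(u, v), sep = "\r")
    out <- mi_of[k]
    out[is.na(out)] <- -Inf
    out
  }
  nodes <- unique(c(network$gene_a, network$gene_b))
  adj <- lapply(stats::setNames(nodes, nodes), function(v)
    unique(c(network$gene_b[network$gene_a == v], network$gene_a[network$gene_b == v])))
  drop <- rep(FALSE, nrow(network))
  for (e in seq_len(nrow(network))) {
    u <- network$gene_a[e]; v <- network$gene_b[e]
    common <- intersect(adj[[u]], adj[[v]])
    for (w in common) {
      if (network$mi[e] < (1 - tolerance) * min(get_mi(u, w), get_mi(v, w))) {
        drop[e] <- TRUE
        break
      }
    }
  }
  out <- network[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "phenotype") <- attr(network, "phenotype")
  out
}

#' Write a network as SIF or TSV
#'
#' @param network Edge data.frame.
#' @param path Output path.
#' @param format `"tsv"` (gene_a, gene_b, mi) or `"sif"`
#'   (`geneA mi geneB`).
#' @return Invisibly, the path.
#' @export
write_network <- function(network, path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(network[, c("gene_a", "gene_b", "mi")], path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    writeLines(paste(network$gene_a, "mi", network$gene_b, sep = "\t"), path)
  }
  invisible(path)
}
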