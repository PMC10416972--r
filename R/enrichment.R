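# Over-representation analysis: exact upper-tail hypergeometric test of a
# query gene list against GMT sets within a background universe, with
# Benjamini-Hochberg adjustment. A local, exact replacement for web-based
# enrichment calls; it is a plain hypergeometric ORA, not a rank-corrected
# composite score.

#' Exact one-sided hypergeometric over-representation test
#'
#' With `N` universe genes of which `K` belong to the set, and a query of
#' size `n` overlapping the set in `k` genes, returns
#' `P(X >= k), X ~ Hypergeom(N, K, n)` by exact summation in log space.
#'
#' @param query character vector of query genes (must lie in `universe`)
#' @param gene_set character vector of set members (restricted to `universe`)
#' @param universe character vector, the background
#' @return p-value in (0, 1]; an empty query returns 1 by convention
#' @export
ora_test <- function(query, gene_set, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("empty universe")
  query <- unique(as.character(query))
  if (!all(query %in% universe))
    stop("query contains genes outside the universe: ",
         paste(utils::head(setdiff(query, universe), 5L), collapse = ", "))
  gene_set <- intersect(unique(as.character(gene_set)), universe)
  hyper_tail_p(N = length(universe), K = length(gene_set),
               n = length(query), k = length(intersect(query, gene_set)))
}

# P(X >= k) for X ~ Hypergeom(N, K, n), exact log-space summation.
hyper_tail_p <- function(N, K, n, k) {
  stopifnot(N >= 1L, K >= 0L, K <= N, n >= 0L, n <= N, k >= 0L)
  if (k == 0L) return(1)
  hi <- min(K, n)
  if (k > hi) return(0)
  i <- k:hi
  lp <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  min(exp(logsumexp(lp)), 1)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Step-up adjustment `p_(i) * m / i` followed by a cumulative minimum from
#' the largest rank down, capped at 1, returned in the input order.
#'
#' @param p_values numeric vector of raw p-values in (0, 1]
#' @return adjusted p-values, same length and order
#' @export
bh_adjust <- function(p_values) {
  m <- length(p_values)
  if (m == 0L) return(numeric(0))
  stopifnot(all(is.finite(p_values)), all(p_values > 0), all(p_values <= 1))
  o <- order(p_values, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(p_values[o] * m / (m:1)))
  adj[ro]
}

#' Rank gene sets by over-representation of a query list
#'
#' Tests every set in the collection against the query with [ora_test()],
#' adjusts with [bh_adjust()], and ranks by increasing p-value (ties broken
#' by larger overlap, then set name).
#'
#' @param query character vector of query genes
#' @param collection [gene_set_collection()]
#' @param top_k number of top rows to return; `Inf` (default) keeps all
#' @param universe background; defaults to the collection universe. In the
#'   localization pipeline this is the set of genes that passed the
#'   expression filter, not the whole genome.
#' @return data.frame with columns `set_name`, `overlap_k`, `set_size_K`,
#'   `query_size_n`, `universe_size_N`, `p_value`, `adjusted_p`,
#'   `enrichment_score` (`-log10 p`)
#' @export
enrich <- function(query, collection, top_k = Inf, universe = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (is.null(universe)) universe <- collection$universe
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("empty universe")
  query <- intersect(unique(as.character(query)), universe)
  sets <- lapply(collection$sets, intersect, universe)
  n <- length(query); N <- length(universe)
  K <- vapply(sets, length, integer(1))
  k <- vapply(sets, function(s) length(intersect(query, s)), integer(1))
  p <- vapply(seq_along(sets), function(i) hyper_tail_p(N, K[i], n, k[i]),
              numeric(1))
  out <- data.frame(set_name = names(sets), overlap_k = k, set_size_K = K,
                    query_size_n = n, universe_size_N = N, p_value = p,
                    adjusted_p = bh_adjust(p),
                    enrichment_score = -log10(p),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, -out$overlap_k, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top_k)
}
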