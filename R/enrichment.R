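#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` genes from a
#' universe of `N` containing `K` annotated ones. Computed via the stable
#' distribution-function implementation.
#'
#' @param k Observed overlap.
#' @param K Annotated (gene-set) size within the universe.
#' @param n Query list size.
#' @param N Universe size.
#' @return The p-value `P(X >= k)`.
#' @export
hypergeomUpper <- function(k, K, n, N) {
  if (K < 0 || n < 0 || K > N || n > N) stop("need 0 <= K, n <= N")
  if (k < 0 || k > min(K, n)) stop("need 0 <= k <= min(K, n)")
  if (k == 0) return(1)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation of a gene list against a gene-set collection
#'
#' One row per term with a non-empty universe intersection: upper-tail
#' hypergeometric p on the overlap, BH-adjusted across terms, flagged at
#' `fdr < alpha`. Query genes outside the universe are dropped with a
#' warning.
#'
#' @param genes Query gene list.
#' @param collection Named list of gene sets (e.g. [readGMT()] output).
#' @param universe Background gene universe (default recommendation: all
#'   genes surviving [filterGenes()]).
#' @param alpha Significance level on the FDR.
#' @return Data.frame of `EnrichmentRow`s sorted by p: term, overlap `k`,
#'   set size `K`, list size `n`, universe size `N`, p, fdr, significant,
#'   overlapping genes (comma-joined).
#' @export
overrepresentation <- function(genes, collection, universe, alpha = 0.05) {
  if (length(universe) == 0L) stop("empty universe")
  universe <- unique(universe)
  if (length(genes) == 0L) stop("empty gene list")
  outside <- setdiff(genes, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    genes <- intersect(genes, universe)
    if (length(genes) == 0L) stop("no query genes left within the universe")
  }
  genes <- unique(genes)
  sets <- lapply(collection, intersect, y = universe)
  keep <- vapply(sets, length, 1L) > 0L
  sets <- sets[keep]
  N <- length(universe)
  n <- length(genes)
  rows <- lapply(names(sets), function(term) {
    hit <- intersect(sets[[term]], genes)
    data.frame(term = term, k = length(hit), K = length(sets[[term]]),
               n = n, N = N,
               p = hypergeomUpper(length(hit), length(sets[[term]]), n, N),
               genes = paste(sort(hit), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bhFdr(out$p)
  out$significant <- out$fdr < alpha
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("EnrichmentTable", "data.frame")
  out
}

#' Shared-annotation gene network
#'
#' Nodes are query genes annotated to at least one enriched term; an
#' undirected edge connects two genes annotated to the same enriched term,
#' weighted by the number of terms they share. No self-edges.
#'
#' @param genes Query gene list.
#' @param enriched_terms An `EnrichmentTable` (only rows with
#'   `significant == TRUE` are used unless none are flagged, in which case
#'   all rows are used).
#' @param collection The gene-set collection the terms came from.
#' @return A list with `graph` (an [igraph::igraph] object with `weight`
#'   edge attribute) and `edges` (data.frame gene_a, gene_b, weight).
#' @export
sharedTermNetwork <- function(genes, enriched_terms, collection) {
  if (nrow(enriched_terms) == 0L) stop("no enriched terms")
  terms <- enriched_terms$term[enriched_terms$significant]
  if (length(terms) == 0L) terms <- enriched_terms$term
  member <- vapply(terms, function(tm)
    genes %in% collection[[tm]], logical(length(genes)))
  member <- matrix(member, nrow = length(genes),
                   dimnames = list(genes, terms))
  keep <- rowSums(member) > 0
  member <- member[keep, , drop = FALSE]
  co <- member %*% t(member)   # shared-term counts
  diag(co) <- 0
  idx <- which(upper.tri(co) & co > 0, arr.ind = TRUE)
  edges <- data.frame(gene_a = rownames(co)[idx[, 1]],
                      gene_b = rownames(co)[idx[, 2]],
                      weight = co[idx], stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = rownames(co))
  list(graph = g, edges = edges)
}
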