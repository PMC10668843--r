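#' Hypergeometric over-representation of gene sets
#'
#' For each term, the upper-tail hypergeometric probability P(X >= k) of
#' drawing k term members in a query of size n from a universe of size N
#' containing K term members; BH adjustment is applied across all terms
#' and the table is sorted by adjusted p, then term id. Query genes
#' outside the universe are dropped with a warning; term members are
#' intersected with the universe.
#'
#' @param queryGenes character vector of query gene ids.
#' @param collection named list of term member vectors (see [readGmt()]).
#' @param universe character vector of all eligible gene ids (non-empty).
#' @return data.frame: \code{term}, \code{k}, \code{n}, \code{K},
#'   \code{N}, \code{p}, \code{p_adj}, \code{genes}
#'   (comma-separated overlap).
#' @export
hypergeomEnrich <- function(queryGenes, collection, universe) {
  universe <- unique(universe)
  N <- length(universe)
  if (!N) stop("empty universe", call. = FALSE)
  queryGenes <- unique(queryGenes)
  outside <- setdiff(queryGenes, universe)
  if (length(outside)) {
    warning(sprintf("%d query genes outside the universe dropped",
                    length(outside)))
    queryGenes <- intersect(queryGenes, universe)
  }
  n <- length(queryGenes)
  rows <- lapply(names(collection), function(term) {
    members <- intersect(collection[[term]], universe)
    K <- length(members)
    hit <- intersect(queryGenes, members)
    k <- length(hit)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, k = k, n = n, K = K, N = N, p = p,
               genes = paste(sort(hit), collapse = ","),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$p_adj <- bhAdjust(pmin(tab$p, 1))
  tab <- tab[order(tab$p_adj, tab$term), c("term", "k", "n", "K", "N",
                                           "p", "p_adj", "genes")]
  rownames(tab) <- NULL
  tab
}

#' Nearest genes of a TE set
#'
#' Unique nearest-gene ids (by TSS distance, from [annotateContext()]) of
#' the given TEs, in order of first appearance for stability.
#'
#' @param teIds TE ids to look up.
#' @param context data.frame from [annotateContext()].
#' @return Character vector of gene ids.
#' @export
teSetToGenes <- function(teIds, context) {
  g <- context$nearest_gene[match(teIds, context$te_id)]
  unique(g[!is.na(g)])
}
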