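#' Classify TE-gene correlations into signed regulatory pairs
#'
#' The published rule, preserved literally including its boundary
#' asymmetry: a pair is \code{positive} when p_adj < 0.05 and rho >= 0.3
#' (inclusive), \code{negative} when p_adj < 0.05 and rho < -0.3
#' (exclusive at -0.3); anything else is not a pair (\code{NA}).
#'
#' @param rho Spearman correlations.
#' @param pAdj BH-adjusted p-values.
#' @param pCut adjusted-p threshold (default 0.05).
#' @param rhoCut correlation threshold (default 0.3).
#' @return Character vector: \code{"positive"}, \code{"negative"} or
#'   \code{NA}.
#' @export
classifyPairs <- function(rho, pAdj, pCut = 0.05, rhoCut = 0.3) {
  ifelse(pAdj < pCut & rho >= rhoCut, "positive",
         ifelse(pAdj < pCut & rho < -rhoCut, "negative", NA_character_))
}

#' Signed TE-gene regulatory pairs
#'
#' Candidate pairs are each TE's nearest flanking genes (up to two, from
#' [nearestFlankingGenes()]). Spearman's rho is computed between the TE
#' and gene 27-stage mean profiles (average ranks for ties, two-sided
#' asymptotic p), p-values are BH-adjusted jointly across all tested
#' pairs, and pairs are kept per [classifyPairs()]. Pairs with a constant
#' profile on either side are skipped with a warning.
#'
#' @param teStageMeans TEs x stages matrix of stage-mean FPKM.
#' @param geneStageMeans genes x stages matrix of stage-mean TPM (same
#'   stage columns).
#' @param flanking data.frame from [nearestFlankingGenes()].
#' @param pCut,rhoCut thresholds (defaults 0.05 and 0.3).
#' @return data.frame: \code{te_id}, \code{gene_id}, \code{rho}, \code{p},
#'   \code{p_adj}, \code{sign}; only classified pairs are returned.
#' @export
teGenePairs <- function(teStageMeans, geneStageMeans, flanking,
                        pCut = 0.05, rhoCut = 0.3) {
  stopifnot(identical(colnames(teStageMeans), colnames(geneStageMeans)))
  cand <- rbind(
    data.frame(te_id = flanking$te_id, gene_id = flanking$upstream_gene,
               stringsAsFactors = FALSE),
    data.frame(te_id = flanking$te_id, gene_id = flanking$downstream_gene,
               stringsAsFactors = FALSE)
  )
  cand <- unique(cand[!is.na(cand$gene_id), , drop = FALSE])
  cand <- cand[cand$te_id %in% rownames(teStageMeans) &
               cand$gene_id %in% rownames(geneStageMeans), , drop = FALSE]
  cand <- cand[order(cand$te_id, cand$gene_id), , drop = FALSE]
  if (!nrow(cand))
    return(data.frame(te_id = character(), gene_id = character(),
                      rho = numeric(), p = numeric(), p_adj = numeric(),
                      sign = character()))
  rho <- p <- rep(NA_real_, nrow(cand))
  nConst <- 0L
  for (i in seq_len(nrow(cand))) {
    x <- teStageMeans[cand$te_id[i], ]
    y <- geneStageMeans[cand$gene_id[i], ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) { nConst <- nConst + 1L; next }
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                           exact = FALSE))
    rho[i] <- unname(ct$estimate)
    p[i] <- ct$p.value
  }
  if (nConst) warning(sprintf("skipped %d pairs with a constant profile",
                              nConst))
  ok <- !is.na(rho)
  cand <- cand[ok, , drop = FALSE]; rho <- rho[ok]; p <- p[ok]
  pAdj <- bhAdjust(pmin(pmax(p, .Machine$double.xmin), 1))
  sign <- classifyPairs(rho, pAdj, pCut, rhoCut)
  keep <- !is.na(sign)
  data.frame(te_id = cand$te_id[keep], gene_id = cand$gene_id[keep],
             rho = rho[keep], p = p[keep], p_adj = pAdj[keep],
             sign = sign[keep], stringsAsFactors = FALSE, row.names = NULL)
}

#' Intra-module TE-TE edges from topological overlap
#'
#' Keeps the edge (i, j) iff both TEs carry the same non-grey module label
#' and TOM_ij >= \code{threshold}; the edge weight is TOM_ij.
#'
#' @param tom TOM matrix with TE ids as dimnames.
#' @param labels named module labels covering the TOM's TEs.
#' @param threshold minimum topological overlap (default 0.2).
#' @return data.frame: \code{from}, \code{to}, \code{weight},
#'   \code{module} (from < to lexicographically).
#' @export
teTeEdges <- function(tom, labels, threshold = 0.2) {
  ids <- rownames(tom)
  labels <- labels[ids]
  out <- list()
  for (m in setdiff(unique(labels), "grey")) {
    mi <- which(labels == m)
    if (length(mi) < 2L) next
    sub <- tom[mi, mi, drop = FALSE]
    idx <- which(upper.tri(sub) & sub >= threshold, arr.ind = TRUE)
    if (!nrow(idx)) next
    a <- ids[mi[idx[, 1]]]; b <- ids[mi[idx[, 2]]]
    swap <- a > b
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    out[[m]] <- data.frame(from = a, to = b,
                           weight = sub[idx], module = m,
                           stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(from = character(), to = character(),
                      weight = numeric(), module = character()))
  res <- do.call(rbind, out)
  res <- res[order(res$from, res$to), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Flag hub TEs by Meat-and-Carcass GWAS window overlap
#'
#' A TE is a hub when it overlaps (>= 1 bp) at least one +/- 20 kb window
#' around a Meat-and-Carcass-associated SNP, i.e. when a trait-associated
#' variant could perturb the TE's cis-regulatory activity.
#'
#' @param tes TE \code{GRanges} with \code{te_id}.
#' @param gwasWindows windows from [extendGwasLoci()] on Meat-and-Carcass
#'   SNPs.
#' @return Named logical vector over \code{te_id}.
#' @export
flagHubTEs <- function(tes, gwasWindows) {
  stats::setNames(countOverlaps(tes, gwasWindows, ignore.strand = TRUE) > 0,
                  mcols(tes)$te_id)
}

#' Assemble the GWAS-anchored hub TE-TE-gene network
#'
#' Keeps TE-TE edges with at least one hub endpoint, then TE-gene edges
#' whose TE is a hub or is one kept TE-TE edge away from a hub; isolated
#' nodes are dropped. Each node's connectivity score is its degree within
#' the final network.
#'
#' @param pairs TE-gene pairs from [teGenePairs()].
#' @param edges TE-TE edges from [teTeEdges()].
#' @param hubFlags named logical from [flagHubTEs()].
#' @return A \linkS4class{RegulatoryNetwork}.
#' @export
assembleHubNetwork <- function(pairs, edges, hubFlags) {
  hubs <- names(hubFlags)[hubFlags]
  keptTT <- edges[edges$from %in% hubs | edges$to %in% hubs, , drop = FALSE]
  reach <- union(hubs, c(keptTT$from, keptTT$to))
  keptTG <- pairs[pairs$te_id %in% reach, , drop = FALSE]
  teIds <- sort(unique(c(keptTT$from, keptTT$to, keptTG$te_id)))
  geneIds <- sort(unique(keptTG$gene_id))
  deg <- table(c(keptTT$from, keptTT$to, keptTG$te_id, keptTG$gene_id))
  ids <- c(teIds, geneIds)
  nodes <- S4Vectors::DataFrame(
    id = ids,
    type = c(rep("TE", length(teIds)), rep("gene", length(geneIds))),
    hub = ids %in% hubs,
    score = as.integer(deg[ids])
  )
  RegulatoryNetwork(
    nodes,
    S4Vectors::DataFrame(keptTT[, c("from", "to", "weight"), drop = FALSE],
                         row.names = NULL),
    S4Vectors::DataFrame(keptTG[, c("te_id", "gene_id", "rho", "sign"),
                                drop = FALSE] |>
                           stats::setNames(c("te", "gene", "rho", "sign")),
                         row.names = NULL)
  )
}

#' GWAS-category enrichment of network TEs
#'
#' Runs the genome-shuffle permutation enrichment of the network's TEs
#' against the +/- flank windows of each trait category, BH-adjusting the
#' empirical p-values across categories.
#'
#' @param networkTes \code{GRanges} of the TEs in the network.
#' @param gwas data.frame from [readGwasTable()] (all categories).
#' @param chromSizes named chromosome-length vector.
#' @param nPerm,seed permutation settings.
#' @param flank window half-width (default 20000).
#' @return Named list of \linkS4class{EnrichmentResult}, one per category.
#' @export
networkGwasEnrichment <- function(networkTes, gwas, chromSizes,
                                  nPerm = 1000L, seed = 1L,
                                  flank = 20000L) {
  cats <- sort(unique(gwas$category))
  res <- lapply(seq_along(cats), function(i) {
    g <- gwas[gwas$category == cats[i], , drop = FALSE]
    win <- extendGwasLoci(g$chrom, g$pos, chromSizes, flank)
    permutationEnrichment(networkTes, win, chromSizes, nPerm,
                          seed = seed + i, label = cats[i])
  })
  names(res) <- cats
  pAdj <- bhAdjust(vapply(res, empiricalP, numeric(1)))
  for (i in seq_along(res)) res[[i]]@pAdj <- pAdj[i]
  res
}
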