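#' Average methylation level over genomic regions
#'
#' For each region, the ratio of methylated reads summed across all
#' internal CpG sites to total reads at those sites. Regions containing no
#' CpG are returned as \code{NA} and should be excluded downstream.
#'
#' @param track CpG \code{GRanges} with \code{meth}/\code{total} metadata
#'   (see [readMethylation()]).
#' @param regions \code{GRanges} of regions to summarise.
#' @return Numeric vector in [0, 1] (or \code{NA}), one per region.
#' @export
regionMethylation <- function(track, regions) {
  hits <- findOverlaps(regions, track, ignore.strand = TRUE)
  meth <- rep(NA_real_, length(regions))
  if (length(hits)) {
    q <- queryHits(hits)
    sM <- tapply(mcols(track)$meth[subjectHits(hits)], q, sum)
    sT <- tapply(mcols(track)$total[subjectHits(hits)], q, sum)
    meth[as.integer(names(sM))] <- as.numeric(sM) / as.numeric(sT)
  }
  meth
}

#' Expression tiers within one stage
#'
#' TEs expressed at a stage are ranked ascending by stage-mean FPKM (ties
#' broken by TE id for determinism); with rank percentile r = (rank - 1)/n,
#' tiers are \code{low} (r < 0.3), \code{medium} (0.3 <= r < 0.6) and
#' \code{high} (r >= 0.6).
#'
#' @param stageMeansVec named numeric vector of stage-mean FPKM for the
#'   TEs expressed at the stage.
#' @return data.frame: \code{te_id}, \code{tier}.
#' @export
tierByExpression <- function(stageMeansVec) {
  n <- length(stageMeansVec)
  if (!n) stop("no expressed TEs at this stage", call. = FALSE)
  ord <- order(stageMeansVec, names(stageMeansVec), method = "radix")
  r <- (seq_len(n) - 1) / n
  tier <- ifelse(r < 0.3, "low", ifelse(r < 0.6, "medium", "high"))
  data.frame(te_id = names(stageMeansVec)[ord], tier = tier,
             stringsAsFactors = FALSE)
}

# Flatten a genome onto one coordinate line so interval overlap can be
# tested with a single findInterval per query batch. Features are reduced
# to disjoint sorted intervals first.
.flattenGenome <- function(chromSizes) {
  off <- c(0, cumsum(as.numeric(chromSizes)))[seq_along(chromSizes)]
  names(off) <- names(chromSizes)
  off
}

.globalise <- function(chrom, start, end, off) {
  list(start = off[chrom] + start, end = off[chrom] + end)
}

.mergedFeatures <- function(features, off) {
  red <- reduce(features, ignore.strand = TRUE)
  g <- .globalise(as.character(seqnames(red)), start(red), end(red), off)
  ord <- order(g$start)
  list(start = unname(g$start[ord]), end = unname(g$end[ord]))
}

# TRUE for each query interval overlapping >= 1 merged feature by >= 1 bp
.overlapsMerged <- function(qs, qe, merged) {
  if (!length(merged$start)) return(rep(FALSE, length(qs)))
  idx <- findInterval(qe, merged$start)
  ok <- idx >= 1L
  ok[ok] <- merged$end[idx[ok]] >= qs[ok]
  ok
}

#' Genome-shuffle permutation enrichment
#'
#' Tests whether query intervals (e.g. expressed TEs) overlap a feature set
#' (epigenomic peaks, GWAS windows) more often than expected by chance.
#' The observed statistic is the number of query intervals overlapping at
#' least one feature (>= 1 bp). Each permutation relocates every query
#' interval to a uniform random start on a random chromosome (chosen with
#' probability proportional to chromosome length among chromosomes long
#' enough to hold it), preserving its length and keeping it fully
#' on-chromosome. The empirical p-value uses the add-one estimator
#' (1 + #\{null >= observed\}) / (1 + N), so it is never zero; fold
#' enrichment is observed / mean(null).
#'
#' @param query query \code{GRanges}.
#' @param features feature \code{GRanges} (may overlap each other).
#' @param chromSizes named vector covering every chromosome in use.
#' @param nPerm number of permutations (default 1000).
#' @param seed integer seed; results are deterministic given the seed.
#' @param label optional label stored on the result.
#' @return An \linkS4class{EnrichmentResult}.
#' @export
permutationEnrichment <- function(query, features, chromSizes,
                                  nPerm = 1000L, seed = 1L,
                                  label = NA_character_) {
  chroms <- names(chromSizes)
  qchr <- as.character(seqnames(query))
  if (!all(qchr %in% chroms) ||
      !all(as.character(seqnames(features)) %in% chroms))
    stop("chromSizes must cover all chromosomes in use", call. = FALSE)
  w <- width(query)
  L <- as.numeric(chromSizes)
  if (any(max(L) < w))
    stop("query interval longer than every chromosome", call. = FALSE)
  off <- .flattenGenome(chromSizes)
  merged <- .mergedFeatures(features, off)
  gq <- .globalise(qchr, start(query), end(query), off)
  observed <- sum(.overlapsMerged(gq$start, gq$end, merged))

  nq <- length(query)
  null <- integer(nPerm)
  allFit <- max(w) <= min(L)
  set.seed(seed)
  for (p in seq_len(nPerm)) {
    if (allFit) {
      ci <- sample.int(length(L), nq, replace = TRUE, prob = L)
    } else {
      ci <- vapply(w, function(wi) {
        ok <- which(L >= wi)
        ok[sample.int(length(ok), 1L, prob = L[ok])]
      }, integer(1))
    }
    maxStart <- L[ci] - w + 1
    s <- floor(stats::runif(nq) * maxStart) + 1
    gs <- off[chroms[ci]] + s
    null[p] <- sum(.overlapsMerged(gs, gs + w - 1, merged))
  }
  nullMean <- mean(null)
  fold <- if (nullMean > 0) observed / nullMean else
    (if (observed > 0) Inf else 1)
  pEmp <- (1 + sum(null >= observed)) / (1 + nPerm)
  EnrichmentResult(observed, nPerm, nullMean, stats::sd(null), fold, pEmp,
                   label = label)
}

#' Extend GWAS SNP loci into +/- flank windows
#'
#' Each SNP position p (1-based) becomes the closed window
#' [max(1, p - flank), min(chrom length, p + flank)], clamped to the
#' chromosome; overlapping windows are deliberately not merged so each
#' locus is counted independently.
#'
#' @param chrom chromosome of each SNP.
#' @param pos 1-based SNP positions.
#' @param chromSizes named chromosome-length vector.
#' @param flank half-width in bp (default 20000, reflecting typical
#'   linkage-disequilibrium extent).
#' @return A \code{GRanges} of windows, one per SNP, in input order.
#' @export
extendGwasLoci <- function(chrom, pos, chromSizes, flank = 20000L) {
  chrom <- as.character(chrom)
  if (!all(chrom %in% names(chromSizes)))
    stop("unknown chromosome in GWAS loci", call. = FALSE)
  L <- chromSizes[chrom]
  GRanges(chrom, IRanges(pmax(1L, as.integer(pos - flank)),
                         pmin(as.integer(L), as.integer(pos + flank))))
}

#' Benjamini-Hochberg adjustment with domain validation
#'
#' Step-up FDR adjustment of raw p-values; inputs outside (0, 1] are
#' rejected rather than silently propagated.
#'
#' @param p numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values in the original order.
#' @export
bhAdjust <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}
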