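#' Annotate the genomic context of each TE
#'
#' Assigns each TE one category with precedence promoter > exon > intron >
#' intergenic; any >= 1 bp overlap counts, and a TE touching a promoter
#' window (TSS +/- \code{promoterWindow} bp) is \code{promoter} regardless
#' of other overlaps. When the annotation lacks explicit UTR features, the
#' gene's first and last exons (in transcription order) proxy for the 5'
#' and 3' UTR-bearing exons and are reported as \code{utr5_proxy_exon} /
#' \code{utr3_proxy_exon}. The nearest gene minimises |TE midpoint - TSS|;
#' its signed distance is negative upstream of the TSS on the gene's
#' strand.
#'
#' @param tes TE \code{GRanges} with a \code{te_id} metadata column.
#' @param genes gene \code{GRanges} from [readGtfGenes()] (may be empty:
#'   everything becomes intergenic with nearest gene \code{NA}).
#' @param promoterWindow half-width of the promoter window in bp
#'   (default 3000).
#' @return data.frame: \code{te_id}, \code{category}, \code{nearest_gene},
#'   \code{tss_distance}.
#' @export
annotateContext <- function(tes, genes, promoterWindow = 3000L) {
  n <- length(tes)
  teid <- mcols(tes)$te_id
  cat <- rep("intergenic", n)
  nearest <- rep(NA_character_, n)
  dist <- rep(NA_real_, n)
  if (length(genes)) {
    gstr <- as.character(strand(genes))
    tss <- mcols(genes)$tss
    # nearest gene by TE midpoint to TSS
    mid <- floor((start(tes) + end(tes)) / 2)
    for (i in seq_len(n)) {
      same <- which(as.character(seqnames(genes)) ==
                    as.character(seqnames(tes))[i])
      if (!length(same)) next
      d <- abs(mid[i] - tss[same])
      j <- same[order(d, mcols(genes)$gene_id[same])[1]]
      nearest[i] <- mcols(genes)$gene_id[j]
      dist[i] <- if (gstr[j] == "+") mid[i] - tss[j] else tss[j] - mid[i]
    }
    # intron = gene body overlap not otherwise classified
    ovGene <- countOverlaps(tes, genes, ignore.strand = TRUE) > 0
    cat[ovGene] <- "intron"
    # exon overlaps, with first/last exons proxying UTR-bearing exons
    exons <- mcols(genes)$exons
    allEx <- unlist(exons, use.names = FALSE)
    if (length(allEx)) {
      geneOfEx <- rep(seq_along(genes), lengths(exons))
      rank <- unlist(lapply(seq_along(genes), function(g) {
        k <- lengths(exons)[g]
        if (!k) return(integer())
        ord <- order(start(exons[[g]]))
        r <- integer(k); r[ord] <- seq_len(k)
        if (gstr[g] == "-") r <- k + 1L - r
        r
      }))
      nEx <- lengths(exons)[geneOfEx]
      exCat <- ifelse(nEx == 1L, "exon",
               ifelse(rank == 1L, "utr5_proxy_exon",
               ifelse(rank == nEx, "utr3_proxy_exon", "exon")))
      hits <- findOverlaps(tes, allEx, ignore.strand = TRUE)
      # precedence among exon types is positional: plain exon < UTR proxies
      pref <- c(exon = 1L, utr5_proxy_exon = 2L, utr3_proxy_exon = 2L)
      for (i in unique(queryHits(hits))) {
        ks <- exCat[subjectHits(hits)[queryHits(hits) == i]]
        cat[i] <- ks[order(-pref[ks])[1]]
      }
    }
    # promoter wins over everything
    prom <- GRanges(seqnames(genes),
                    IRanges(pmax(1L, tss - as.integer(promoterWindow)),
                            tss + as.integer(promoterWindow)))
    cat[countOverlaps(tes, prom, ignore.strand = TRUE) > 0] <- "promoter"
  }
  data.frame(te_id = teid, category = cat, nearest_gene = nearest,
             tss_distance = dist, stringsAsFactors = FALSE)
}

#' Classify TEs as self-expressed vs gene-dependent
#'
#' A TE overlapping any gene body by >= 1 bp (strand-agnostic, transcript
#' span) is gene-dependent: its RNA-seq signal may derive from host-gene
#' transcription. TEs entirely intergenic are self-expressed, i.e.
#' presumed autonomously transcribed.
#'
#' @param tes TE \code{GRanges} with \code{te_id}.
#' @param genes gene \code{GRanges}.
#' @return data.frame: \code{te_id}, \code{class} in
#'   \{\code{self_expressed}, \code{gene_dependent}\}.
#' @export
classifyTEs <- function(tes, genes) {
  ov <- if (length(genes)) countOverlaps(tes, genes, ignore.strand = TRUE) > 0
        else rep(FALSE, length(tes))
  data.frame(te_id = mcols(tes)$te_id,
             class = ifelse(ov, "gene_dependent", "self_expressed"),
             stringsAsFactors = FALSE)
}

#' Nearest flanking genes of each TE
#'
#' For each TE, the closest gene ending before it (upstream in genome
#' coordinates) and the closest gene starting after it (downstream), by
#' genomic gap; a gene overlapping the TE is returned on both sides with
#' distance 0. Missing sides (chromosome ends, geneless chromosomes) are
#' \code{NA}.
#'
#' @param tes TE \code{GRanges} with \code{te_id}.
#' @param genes gene \code{GRanges} with \code{gene_id}.
#' @return data.frame: \code{te_id}, \code{upstream_gene},
#'   \code{upstream_dist}, \code{downstream_gene}, \code{downstream_dist}.
#' @export
nearestFlankingGenes <- function(tes, genes) {
  n <- length(tes)
  up <- dn <- rep(NA_character_, n)
  upD <- dnD <- rep(NA_real_, n)
  gchrom <- as.character(seqnames(genes))
  tchrom <- as.character(seqnames(tes))
  ov <- findOverlaps(tes, genes, ignore.strand = TRUE)
  for (chr in unique(tchrom)) {
    gi <- which(gchrom == chr)
    ti <- which(tchrom == chr)
    if (!length(gi)) next
    ge <- end(genes)[gi]; gs <- start(genes)[gi]
    ordE <- order(ge); ordS <- order(gs)
    for (i in ti) {
      k <- findInterval(start(tes)[i] - 1L, ge[ordE])
      if (k >= 1L) {
        j <- gi[ordE[k]]
        up[i] <- mcols(genes)$gene_id[j]
        upD[i] <- start(tes)[i] - end(genes)[j] - 1L
      }
      k2 <- length(gi) - findInterval(end(tes)[i], gs[ordS] - 0.5)
      if (k2 >= 1L) {
        j <- gi[ordS[length(gi) - k2 + 1L]]
        dn[i] <- mcols(genes)$gene_id[j]
        dnD[i] <- start(genes)[j] - end(tes)[i] - 1L
      }
    }
  }
  if (length(ov)) {
    for (i in unique(queryHits(ov))) {
      js <- subjectHits(ov)[queryHits(ov) == i]
      g <- sort(mcols(genes)$gene_id[js])[1]
      up[i] <- dn[i] <- g
      upD[i] <- dnD[i] <- 0
    }
  }
  data.frame(te_id = mcols(tes)$te_id, upstream_gene = up,
             upstream_dist = upD, downstream_gene = dn,
             downstream_dist = dnD, stringsAsFactors = FALSE)
}
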