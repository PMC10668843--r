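#' @importFrom GenomicRanges GRanges strand seqnames start end width
#'   findOverlaps countOverlaps reduce mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits split
#' @importFrom utils read.delim write.table
NULL

parseError <- function(path, lineno, what) {
  stop(sprintf("%s: line %d: %s", path, lineno, what), call. = FALSE)
}

#' Read a chromosome-sizes table
#'
#' Two tab-separated columns: chromosome name, length in bp.
#'
#' @param path file path.
#' @return Named integer vector of chromosome lengths.
#' @export
readChromSizes <- function(path) {
  d <- read.delim(path, header = FALSE, comment.char = "#",
                  stringsAsFactors = FALSE)
  sizes <- as.integer(d[[2]])
  if (any(is.na(sizes)) || any(sizes <= 0))
    stop("chromosome lengths must be positive integers", call. = FALSE)
  names(sizes) <- as.character(d[[1]])
  sizes
}

#' @rdname readChromSizes
#' @param sizes named integer vector of chromosome lengths.
#' @export
writeChromSizes <- function(sizes, path) {
  write.table(data.frame(names(sizes), unname(sizes)), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
}

#' Read a BED file of genomic intervals
#'
#' BED coordinates are 0-based half-open; they are converted to the 1-based
#' closed convention of \code{GRanges} on read (\code{start + 1}), so a BED
#' line \code{chr1 100 200} becomes the GRanges interval \code{chr1:101-200}
#' covering the same 100 bp. Optional columns 4-6 (name, score, strand) are
#' preserved as metadata columns. Malformed lines (non-integer coordinates,
#' empty intervals) raise an error naming the offending line.
#'
#' @param path BED file path.
#' @return A \code{GRanges}, in file order.
#' @export
readBed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  idx <- which(keep)
  if (!length(idx))
    return(GRanges())
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  n <- length(idx)
  chrom <- character(n); s0 <- integer(n); e0 <- integer(n)
  name <- rep(NA_character_, n); score <- rep(NA_real_, n)
  strand <- rep("*", n)
  for (i in seq_len(n)) {
    f <- fields[[i]]
    if (length(f) < 3L)
      parseError(path, idx[i], "expected >= 3 tab-separated columns")
    st <- suppressWarnings(as.integer(f[2]))
    en <- suppressWarnings(as.integer(f[3]))
    if (is.na(st) || is.na(en))
      parseError(path, idx[i], "non-integer coordinates")
    if (st < 0 || st >= en)
      parseError(path, idx[i], "requires 0 <= start < end")
    chrom[i] <- f[1]; s0[i] <- st; e0[i] <- en
    if (length(f) >= 4L) name[i] <- f[4]
    if (length(f) >= 5L) score[i] <- suppressWarnings(as.numeric(f[5]))
    if (length(f) >= 6L) {
      if (!f[6] %in% c("+", "-", "."))
        parseError(path, idx[i], sprintf("unknown strand symbol '%s'", f[6]))
      strand[i] <- if (f[6] == ".") "*" else f[6]
    }
  }
  gr <- GRanges(chrom, IRanges(s0 + 1L, e0), strand = strand)
  if (any(!is.na(name))) mcols(gr)$name <- name
  if (any(!is.na(score))) mcols(gr)$score <- score
  gr
}

#' @rdname readBed
#' @param gr a \code{GRanges} to serialise (1-based closed, converted back
#'   to BED's 0-based half-open on write).
#' @export
writeBed <- function(gr, path) {
  d <- data.frame(chrom = as.character(seqnames(gr)),
                  start = start(gr) - 1L, end = end(gr))
  mc <- mcols(gr)
  if ("name" %in% colnames(mc)) {
    d$name <- mc$name
    if ("score" %in% colnames(mc)) {
      d$score <- mc$score
      s <- as.character(strand(gr))
      d$strand <- ifelse(s == "*", ".", s)
    }
  }
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
}

#' Read gene models from a GTF file
#'
#' Parses \code{gene} and \code{exon} features (all other feature types are
#' ignored). GTF is 1-based closed, matching the internal \code{GRanges}
#' convention, so coordinates are taken verbatim. The transcription start
#' site is the gene start on the \code{+} strand and the gene end on the
#' \code{-} strand; genes without a determinate strand are rejected.
#'
#' @param path GTF file path.
#' @return A \code{GRanges} of gene bodies with metadata columns
#'   \code{gene_id}, \code{tss} (1-based position) and \code{exons}
#'   (a \code{GRangesList} of exons nested within each gene).
#' @export
readGtfGenes <- function(path) {
  g <- rtracklayer::import(path, format = "gtf")
  if (!"gene_id" %in% colnames(mcols(g)) ||
      anyNA(mcols(g)$gene_id[mcols(g)$type %in% c("gene", "exon")]))
    stop(sprintf("%s: gene/exon feature without a gene_id attribute", path),
         call. = FALSE)
  genes <- g[mcols(g)$type == "gene"]
  if (!length(genes)) stop(sprintf("%s: no gene features", path), call. = FALSE)
  str <- as.character(strand(genes))
  if (any(!str %in% c("+", "-")))
    stop(sprintf("%s: gene with unknown strand symbol", path), call. = FALSE)
  exons <- g[mcols(g)$type == "exon"]
  exList <- S4Vectors::split(GRanges(seqnames(exons),
                                     IRanges(start(exons), end(exons)),
                                     strand = strand(exons)),
                             factor(mcols(exons)$gene_id,
                                    levels = mcols(genes)$gene_id))
  out <- GRanges(seqnames(genes), IRanges(start(genes), end(genes)),
                 strand = strand(genes))
  mcols(out)$gene_id <- mcols(genes)$gene_id
  mcols(out)$tss <- ifelse(str == "+", start(genes), end(genes))
  mcols(out)$exons <- exList
  out
}

# class/family column -> closed TE-class vocabulary; non-TE repeat
# categories are dropped from the TE universe entirely.
.rmClassMap <- function(clsfam) {
  top <- sub("/.*$", "", clsfam)
  top <- sub("\\?$", "", top)
  drop <- top %in% c("Simple_repeat", "Low_complexity", "Satellite",
                     "rRNA", "tRNA", "snRNA", "srpRNA", "scRNA")
  cls <- ifelse(top %in% c("LINE", "SINE", "LTR", "DNA"), top, "Other")
  list(class = cls, drop = drop)
}

#' Read a RepeatMasker .out annotation
#'
#' Expects the standard layout: two header lines plus a blank line, then
#' whitespace-delimited rows whose query begin/end are 1-based closed
#' (taken verbatim into \code{GRanges}). The repeat class/family column is
#' mapped onto the closed vocabulary \{LINE, SINE, LTR, DNA, Other\};
#' simple repeats, low-complexity, satellite and structural-RNA rows are
#' dropped because they are not transposable elements.
#'
#' @param path RepeatMasker .out path.
#' @return A \code{GRanges} with metadata columns \code{te_id},
#'   \code{te_class} and \code{family}.
#' @export
readRepeatMaskerOut <- function(path) {
  lines <- readLines(path)
  body <- if (length(lines) > 3L) lines[-(1:3)] else character()
  body_idx <- which(nzchar(trimws(body))) + 3L
  if (!length(body_idx)) return(GRanges())
  chrom <- character(); s <- integer(); e <- integer(); strand <- character()
  fam <- character(); cls <- character(); lineno <- integer()
  for (i in body_idx) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 11L)
      parseError(path, i, "truncated RepeatMasker row (< 11 fields)")
    qb <- suppressWarnings(as.integer(f[6]))
    qe <- suppressWarnings(as.integer(f[7]))
    if (is.na(qb) || is.na(qe) || qb > qe)
      parseError(path, i, "invalid query coordinates")
    m <- .rmClassMap(f[11])
    if (m$drop) next
    chrom <- c(chrom, f[5]); s <- c(s, qb); e <- c(e, qe)
    strand <- c(strand, if (f[9] == "C") "-" else "+")
    fam <- c(fam, f[11]); cls <- c(cls, m$class); lineno <- c(lineno, i)
  }
  if (!length(s)) return(GRanges())
  gr <- GRanges(chrom, IRanges(s, e), strand = strand)
  mcols(gr)$te_id <- sprintf("TE_%s_%d", sub("/.*$", "", fam), lineno)
  mcols(gr)$te_class <- cls
  mcols(gr)$family <- fam
  gr
}

#' Read/write a staged expression matrix as TSV
#'
#' The TSV carries feature ids in the first column and one column per
#' sample named \code{<stage>_<replicate>} (e.g. \code{LE33_1}).
#'
#' @param path TSV path.
#' @param unit unit tag to attach (\code{"FPKM"}, \code{"TPM"},
#'   \code{"counts"}).
#' @return \code{readExpressionMatrix}: a \linkS4class{StageExpressionSet}.
#' @export
readExpressionMatrix <- function(path, unit = "FPKM") {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  cn <- colnames(m)
  stage <- sub("_[^_]+$", "", cn)
  repl <- sub("^.*_", "", cn)
  StageExpressionSet(m, stage, repl, unit)
}

#' @rdname readExpressionMatrix
#' @param se a \code{StageExpressionSet}.
#' @export
writeExpressionMatrix <- function(se, path) {
  m <- assay(se)
  d <- data.frame(feature = rownames(m), m, check.names = FALSE)
  colnames(d) <- c("feature", paste0(sampleStages(se), "_",
                                     sampleReplicates(se)))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read/write CpG methylation counts
#'
#' TSV columns: chromosome, 0-based CpG position, methylated read count,
#' total read count. Each CpG becomes a width-1 \code{GRanges} position
#' (1-based internally) with counts as metadata.
#'
#' @param path TSV path.
#' @return A \code{GRanges} with metadata columns \code{meth} and
#'   \code{total}.
#' @export
readMethylation <- function(path) {
  d <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  meth <- as.numeric(d[[3]]); total <- as.numeric(d[[4]])
  if (any(total < 1) || any(meth < 0) || any(meth > total))
    stop("methylation counts require 0 <= methylated <= total, total >= 1",
         call. = FALSE)
  gr <- GRanges(as.character(d[[1]]), IRanges(as.integer(d[[2]]) + 1L,
                                              width = 1L))
  mcols(gr)$meth <- meth
  mcols(gr)$total <- total
  gr
}

#' @rdname readMethylation
#' @param track methylation \code{GRanges} as returned by
#'   \code{readMethylation}.
#' @export
writeMethylation <- function(track, path) {
  d <- data.frame(chrom = as.character(seqnames(track)),
                  pos = start(track) - 1L,
                  meth = mcols(track)$meth, total = mcols(track)$total)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read/write a GWAS locus table
#'
#' TSV columns: trait category, chromosome, 1-based SNP position.
#'
#' @param path TSV path.
#' @return data.frame with columns \code{category}, \code{chrom},
#'   \code{pos}.
#' @export
readGwasTable <- function(path) {
  d <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  data.frame(category = as.character(d[[1]]), chrom = as.character(d[[2]]),
             pos = as.integer(d[[3]]), stringsAsFactors = FALSE)
}

#' @rdname readGwasTable
#' @param gwas data.frame as returned by \code{readGwasTable}.
#' @export
writeGwasTable <- function(gwas, path) {
  write.table(gwas, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a GMT gene-set collection
#'
#' @param path GMT path (term, description, member genes, tab-separated).
#' @return Named list of character vectors of member gene ids.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("GMT line needs term, description and >= 1 gene", call. = FALSE)
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  if (anyDuplicated(names(sets)))
    stop("duplicate GMT term ids", call. = FALSE)
  sets
}

#' Export a regulatory network as a deterministic edge-list TSV
#'
#' One row per edge: source, target, edge_type (\code{TE-TE} or
#' \code{TE-gene}) and weight (topological overlap for TE-TE edges, signed
#' Spearman rho for TE-gene edges), sorted by source then target so that
#' repeated exports are byte-identical.
#'
#' @param network a \linkS4class{RegulatoryNetwork}.
#' @param path output TSV path.
#' @export
writeEdgeList <- function(network, path) {
  tt <- as.data.frame(networkTeEdges(network))
  tg <- as.data.frame(networkTeGeneEdges(network))
  rows <- rbind(
    if (nrow(tt)) data.frame(source = tt$from, target = tt$to,
                             edge_type = "TE-TE", weight = tt$weight,
                             stringsAsFactors = FALSE),
    if (nrow(tg)) data.frame(source = tg$te, target = tg$gene,
                             edge_type = "TE-gene", weight = tg$rho,
                             stringsAsFactors = FALSE)
  )
  if (is.null(rows))
    rows <- data.frame(source = character(), target = character(),
                       edge_type = character(), weight = numeric())
  rows <- rows[order(rows$source, rows$target, method = "radix"), ,
               drop = FALSE]
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
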