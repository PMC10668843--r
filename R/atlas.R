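#' FPKM normalisation
#'
#' FPKM = count / ((length / 1e3) * (library size / 1e6)).
#'
#' @param counts non-negative count matrix (features x samples).
#' @param lengths feature lengths in bp (> 0), one per row.
#' @param libSizes library sizes (> 0), one per column. Externally computed
#'   size factors (e.g. TMM-adjusted effective library sizes) can be passed
#'   here directly.
#' @param stage,replicate per-column design labels.
#' @return A \linkS4class{StageExpressionSet} with unit \code{"FPKM"}.
#' @export
computeFpkm <- function(counts, lengths, libSizes, stage, replicate) {
  counts <- as.matrix(counts)
  if (any(lengths <= 0)) stop("feature lengths must be > 0", call. = FALSE)
  if (any(libSizes <= 0)) stop("library sizes must be > 0", call. = FALSE)
  fpkm <- sweep(counts / (lengths / 1e3), 2, libSizes / 1e6, "/")
  StageExpressionSet(fpkm, stage, replicate, "FPKM")
}

#' TPM normalisation
#'
#' Per column: rate_i = count_i / length_i; TPM_i = rate_i / sum(rates) *
#' 1e6, so every column with any signal sums to 1e6. All-zero columns stay
#' zero.
#'
#' @inheritParams computeFpkm
#' @return A \linkS4class{StageExpressionSet} with unit \code{"TPM"}.
#' @export
computeTpm <- function(counts, lengths, stage, replicate) {
  counts <- as.matrix(counts)
  if (any(lengths <= 0)) stop("feature lengths must be > 0", call. = FALSE)
  rate <- counts / lengths
  tot <- colSums(rate)
  tpm <- sweep(rate, 2, ifelse(tot > 0, tot, 1), "/") * 1e6
  StageExpressionSet(tpm, stage, replicate, "TPM")
}

#' Call expressed TEs per stage
#'
#' A TE is expressed at a stage when its mean FPKM over that stage's
#' replicates strictly exceeds the threshold (default 1); a stage mean of
#' exactly 1 is therefore not expressed. The union over stages is the set
#' of detectable TEs.
#'
#' @param se a \linkS4class{StageExpressionSet} (FPKM).
#' @param threshold strict lower bound on the stage-mean FPKM.
#' @return A list with \code{perStage} (named list of expressed TE id
#'   vectors), \code{union} (detectable TEs) and \code{counts} (named
#'   integer vector of per-stage set sizes).
#' @export
callExpressed <- function(se, threshold = 1.0) {
  sm <- stageMeans(se)
  perStage <- lapply(colnames(sm), function(s) {
    rownames(sm)[sm[, s] > threshold]
  })
  names(perStage) <- colnames(sm)
  union <- unique(unlist(perStage, use.names = FALSE))
  list(perStage = perStage, union = union,
       counts = vapply(perStage, length, integer(1)))
}

#' Stage-mean expression matrix
#'
#' Arithmetic mean over each stage's replicates; columns ordered by first
#' appearance of each stage (registry order when built from the standard
#' design).
#'
#' @param se a \linkS4class{StageExpressionSet}.
#' @return Matrix features x stages.
#' @export
stageMeans <- function(se) {
  st <- sampleStages(se)
  stages <- unique(st)
  if (any(table(st) == 0)) stop("stage with zero replicates", call. = FALSE)
  m <- assay(se)
  out <- vapply(stages, function(s) rowMeans(m[, st == s, drop = FALSE]),
                numeric(nrow(m)))
  if (nrow(m) == 1L) out <- matrix(out, 1, dimnames = list(rownames(m), stages))
  colnames(out) <- stages
  rownames(out) <- rownames(m)
  out
}

#' Sample-level PCA of an expression matrix
#'
#' Runs \code{prcomp} on log2(x + 1)-transformed values with samples as
#' observations, centred and unscaled; zero-variance features are dropped
#' first.
#'
#' @param se a \linkS4class{StageExpressionSet} with >= 2 samples.
#' @return List with \code{scores} (samples x PCs), \code{varianceExplained}
#'   (fractions, non-increasing) and \code{nFeatures} used.
#' @export
pcaSamples <- function(se) {
  m <- assay(se)
  if (ncol(m) < 2L) stop("PCA needs >= 2 samples", call. = FALSE)
  lm2 <- t(log2(m + 1))
  v <- apply(lm2, 2, stats::var)
  lm2 <- lm2[, v > 0, drop = FALSE]
  if (!ncol(lm2)) stop("no features with nonzero variance", call. = FALSE)
  pc <- stats::prcomp(lm2, center = TRUE, scale. = FALSE)
  list(scores = pc$x,
       varianceExplained = pc$sdev^2 / sum(pc$sdev^2),
       nFeatures = ncol(lm2))
}

#' Row-standardised stage-mean matrix for heatmap display
#'
#' Rows are the detectable (union) TEs, columns the 27 stages in registry
#' order; values are z-scores of log2(stage-mean FPKM + 1). Constant rows
#' map to all-zero rather than NaN.
#'
#' @param se a \linkS4class{StageExpressionSet} (FPKM).
#' @param calls result of [callExpressed()].
#' @param stageOrder column order; defaults to the registry stages present.
#' @return Matrix detectable TEs x stages.
#' @export
heatmapMatrix <- function(se, calls, stageOrder = NULL) {
  sm <- stageMeans(se)
  if (is.null(stageOrder))
    stageOrder <- intersect(stageRegistry()$stage, colnames(sm))
  sm <- log2(sm[calls$union, stageOrder, drop = FALSE] + 1)
  mu <- rowMeans(sm)
  sd <- apply(sm, 1, stats::sd)
  z <- (sm - mu) / ifelse(sd > 0, sd, 1)
  z[sd == 0, ] <- 0
  z
}
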