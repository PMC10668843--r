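suppressPackageStartupMessages({
  library(GenomicRanges)
  library(SummarizedExperiment)
})

# Shared fixtures, built lazily once per test run.
.cache <- new.env(parent = emptyenv())

defaultStudy <- function() {
  if (is.null(.cache$study))
    .cache$study <- simulateStudy(simConfig(seed = 1L))
  .cache$study
}

teIndex <- function(study) {
  stats::setNames(seq_along(study$tes), mcols(study$tes)$te_id)
}

# The analysis chain shared by the module-recovery, pair-recovery and
# network acceptance tests (all on the default seed-1 fixture, default
# thresholds).
defaultAnalysis <- function() {
  if (!is.null(.cache$analysis)) return(.cache$analysis)
  st <- defaultStudy()
  idx <- teIndex(st)
  calls <- callExpressed(st$teExpr, 1.0)
  classes <- classifyTEs(st$tes[idx[calls$union]], st$genes)
  selfIds <- classes$te_id[classes$class == "self_expressed"]
  expr <- assay(st$teExpr)[selfIds, , drop = FALSE]
  expr <- expr[apply(expr, 1, stats::var) > 0, , drop = FALSE]
  selfIds <- rownames(expr)
  sft <- pickSoftThreshold(expr)
  tom <- tomSimilarity(adjacencyMatrix(expr, sft$beta))
  labels <- detectModules(1 - tom, 30L)
  partition <- mergeModules(expr, labels, 0.25)
  flank <- nearestFlankingGenes(st$tes[idx[selfIds]], st$genes)
  pairs <- suppressWarnings(
    teGenePairs(stageMeans(st$teExpr)[selfIds, , drop = FALSE],
                stageMeans(st$geneExpr), flank, 0.05, 0.3))
  .cache$analysis <- list(
    study = st, idx = idx, calls = calls, classes = classes,
    selfIds = selfIds, expr = expr, sft = sft, tom = tom,
    labels = labels, partition = partition, flank = flank, pairs = pairs)
  .cache$analysis
}

# Adjusted Rand index from the pair-counting contingency formula
# (independent of any clustering package).
adjustedRand <- function(x, y) {
  tab <- table(x, y)
  sij <- sum(choose(tab, 2))
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  e <- a * b / n2
  (sij - e) / ((a + b) / 2 - e)
}

# Reference Benjamini-Hochberg step-up, written independently of
# stats::p.adjust.
bhReference <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(sorted)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# A tiny deterministic StageExpressionSet over the full 27-stage design.
smallSet <- function(values, nFeatures = 1L, unit = "FPKM") {
  reg <- stageRegistry()
  stage <- rep(reg$stage, each = 3)
  repl <- rep(1:3, nrow(reg))
  m <- matrix(values, nFeatures, length(stage), byrow = TRUE,
              dimnames = list(paste0("f", seq_len(nFeatures)),
                              paste0(stage, "_", repl)))
  StageExpressionSet(m, stage, repl, unit)
}
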