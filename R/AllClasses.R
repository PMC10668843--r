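#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

#' StageExpressionSet: expression across a staged developmental design
#'
#' A thin \linkS4class{SummarizedExperiment} subclass holding one expression
#' assay (features x samples) together with per-sample \code{stage} and
#' \code{replicate} metadata and a unit tag (\code{"FPKM"}, \code{"TPM"} or
#' \code{"counts"}). All values must be finite and non-negative.
#'
#' @slot unit character(1), one of \code{"FPKM"}, \code{"TPM"}, \code{"counts"}.
#' @seealso [StageExpressionSet()] for the constructor, [stageMeans()],
#'   [callExpressed()]
#' @export
setClass("StageExpressionSet",
  contains = "SummarizedExperiment",
  slots = c(unit = "character")
)

setValidity("StageExpressionSet", function(object) {
  msg <- character()
  if (length(object@unit) != 1L || !object@unit %in% c("FPKM", "TPM", "counts"))
    msg <- c(msg, "'unit' must be one of \"FPKM\", \"TPM\", \"counts\"")
  if (!all(c("stage", "replicate") %in% colnames(colData(object))))
    msg <- c(msg, "colData must contain 'stage' and 'replicate' columns")
  m <- assay(object)
  if (any(!is.finite(m)) || any(m < 0))
    msg <- c(msg, "expression values must be finite and >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a StageExpressionSet
#'
#' @param mat numeric matrix, features x samples, non-negative.
#' @param stage character vector of stage labels, one per column.
#' @param replicate integer/character replicate labels, one per column.
#' @param unit unit tag: \code{"FPKM"}, \code{"TPM"} or \code{"counts"}.
#' @return A \linkS4class{StageExpressionSet}.
#' @examples
#' m <- matrix(rexp(12), 2, 6,
#'   dimnames = list(c("a", "b"), paste0("s", 1:6)))
#' se <- StageExpressionSet(m, rep(c("LE33", "LD0"), each = 3),
#'   rep(1:3, 2), "FPKM")
#' exprUnit(se)
#' @export
StageExpressionSet <- function(mat, stage, replicate, unit = "counts") {
  mat <- as.matrix(mat)
  stopifnot(ncol(mat) == length(stage), ncol(mat) == length(replicate))
  se <- SummarizedExperiment(
    assays = list(expr = mat),
    colData = DataFrame(stage = as.character(stage),
                        replicate = as.character(replicate),
                        row.names = colnames(mat))
  )
  new("StageExpressionSet", se, unit = unit)
}

#' @describeIn StageExpressionSet unit tag of the stored values
#' @param x,object a \code{StageExpressionSet}
#' @export
exprUnit <- function(x) x@unit

#' @describeIn StageExpressionSet per-sample stage labels
#' @export
sampleStages <- function(x) as.character(colData(x)$stage)

#' @describeIn StageExpressionSet per-sample replicate labels
#' @export
sampleReplicates <- function(x) as.character(colData(x)$replicate)

setMethod("show", "StageExpressionSet", function(object) {
  cat(sprintf("StageExpressionSet (%s): %d features x %d samples, %d stages\n",
              object@unit, nrow(object), ncol(object),
              length(unique(sampleStages(object)))))
})

#' EnrichmentResult: outcome of a genome-shuffle permutation test
#'
#' @slot observed observed count of query intervals overlapping a feature.
#' @slot nPerm number of permutations.
#' @slot nullMean,nullSd summary of the permutation null.
#' @slot fold observed / null mean.
#' @slot pEmp add-one empirical p-value, in (0, 1].
#' @slot pAdj BH-adjusted p across a batch (NA until adjusted).
#' @slot label free-text label (assay or trait category).
#' @export
setClass("EnrichmentResult",
  slots = c(observed = "numeric", nPerm = "integer", nullMean = "numeric",
            nullSd = "numeric", fold = "numeric", pEmp = "numeric",
            pAdj = "numeric", label = "character")
)

setValidity("EnrichmentResult", function(object) {
  msg <- character()
  if (object@fold < 0) msg <- c(msg, "fold must be >= 0")
  if (object@pEmp <= 0 || object@pEmp > 1) msg <- c(msg, "pEmp must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

EnrichmentResult <- function(observed, nPerm, nullMean, nullSd, fold, pEmp,
                             pAdj = NA_real_, label = NA_character_) {
  new("EnrichmentResult", observed = as.numeric(observed),
      nPerm = as.integer(nPerm), nullMean = nullMean, nullSd = nullSd,
      fold = fold, pEmp = pEmp, pAdj = pAdj, label = label)
}

#' @describeIn EnrichmentResult fold enrichment (observed / null mean)
#' @param x,object an \code{EnrichmentResult}
#' @export
foldEnrichment <- function(x) x@fold

#' @describeIn EnrichmentResult add-one empirical p-value
#' @export
empiricalP <- function(x) x@pEmp

setMethod("show", "EnrichmentResult", function(object) {
  cat(sprintf(
    "EnrichmentResult%s: observed %g, null %.2f +/- %.2f (N = %d), fold %.3f, p = %.3g\n",
    if (is.na(object@label)) "" else paste0(" [", object@label, "]"),
    object@observed, object@nullMean, object@nullSd, object@nPerm,
    object@fold, object@pEmp))
})

#' ModulePartition: co-expression module assignment with eigengenes
#'
#' @slot labels named character vector, one module label per feature;
#'   \code{"grey"} marks unassigned features.
#' @slot eigengenes samples x modules matrix of unit-norm eigengenes
#'   (grey excluded).
#' @slot varianceExplained named numeric, per-module eigengene variance
#'   explained.
#' @slot stateCor,stateP modules x developmental-states matrices of Pearson
#'   correlations and two-sided p-values (empty until computed).
#' @export
setClass("ModulePartition",
  slots = c(labels = "character", eigengenes = "matrix",
            varianceExplained = "numeric", stateCor = "matrix",
            stateP = "matrix")
)

setValidity("ModulePartition", function(object) {
  msg <- character()
  if (is.null(names(object@labels))) msg <- c(msg, "labels must be named")
  mods <- setdiff(unique(object@labels), "grey")
  if (ncol(object@eigengenes) && !setequal(colnames(object@eigengenes), mods))
    msg <- c(msg, "eigengene columns must match non-grey module labels")
  if (length(msg)) msg else TRUE
})

ModulePartition <- function(labels, eigengenes = matrix(numeric(), 0, 0),
                            varianceExplained = numeric(),
                            stateCor = matrix(numeric(), 0, 0),
                            stateP = matrix(numeric(), 0, 0)) {
  new("ModulePartition", labels = labels, eigengenes = eigengenes,
      varianceExplained = varianceExplained, stateCor = stateCor,
      stateP = stateP)
}

#' @describeIn ModulePartition named per-feature module labels
#' @param x,object a \code{ModulePartition}
#' @export
moduleLabels <- function(x) x@labels

#' @describeIn ModulePartition samples x modules eigengene matrix
#' @export
moduleEigengenes <- function(x) x@eigengenes

#' @describeIn ModulePartition module x state correlation matrix
#' @export
stateCorrelation <- function(x) x@stateCor

#' @describeIn ModulePartition module x state correlation p-values
#' @export
statePValues <- function(x) x@stateP

setMethod("show", "ModulePartition", function(object) {
  tab <- sort(table(object@labels), decreasing = TRUE)
  cat(sprintf("ModulePartition: %d features, %d modules (+ grey)\n",
              length(object@labels),
              length(setdiff(names(tab), "grey"))))
  print(tab)
})

#' RegulatoryNetwork: typed TE-TE-gene network
#'
#' Nodes are TEs or genes; TE-TE edges carry topological-overlap weights,
#' TE-gene edges carry a signed Spearman correlation. Hub TEs are TEs
#' overlapping a Meat-and-Carcass GWAS window.
#'
#' @slot nodes DataFrame: id, type ("TE"/"gene"), hub (logical),
#'   score (within-network degree).
#' @slot teEdges DataFrame: from, to, weight.
#' @slot teGeneEdges DataFrame: te, gene, rho, sign.
#' @export
setClass("RegulatoryNetwork",
  slots = c(nodes = "DataFrame", teEdges = "DataFrame",
            teGeneEdges = "DataFrame")
)

setValidity("RegulatoryNetwork", function(object) {
  msg <- character()
  ids <- object@nodes$id
  if (anyDuplicated(ids)) msg <- c(msg, "node ids must be unique")
  ep <- c(object@teEdges$from, object@teEdges$to,
          object@teGeneEdges$te, object@teGeneEdges$gene)
  if (length(ep) && !all(ep %in% ids))
    msg <- c(msg, "every edge endpoint must be a node")
  if (length(msg)) msg else TRUE
})

RegulatoryNetwork <- function(nodes, teEdges, teGeneEdges) {
  new("RegulatoryNetwork", nodes = nodes, teEdges = teEdges,
      teGeneEdges = teGeneEdges)
}

#' @describeIn RegulatoryNetwork node table (id, type, hub, score)
#' @param x,object a \code{RegulatoryNetwork}
#' @export
networkNodes <- function(x) x@nodes

#' @describeIn RegulatoryNetwork TE-TE edge table
#' @export
networkTeEdges <- function(x) x@teEdges

#' @describeIn RegulatoryNetwork TE-gene edge table
#' @export
networkTeGeneEdges <- function(x) x@teGeneEdges

setMethod("show", "RegulatoryNetwork", function(object) {
  cat(sprintf(
    "RegulatoryNetwork: %d nodes (%d TEs, %d hubs, %d genes), %d TE-TE + %d TE-gene edges\n",
    nrow(object@nodes), sum(object@nodes$type == "TE"),
    sum(object@nodes$hub), sum(object@nodes$type == "gene"),
    nrow(object@teEdges), nrow(object@teGeneEdges)))
})
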