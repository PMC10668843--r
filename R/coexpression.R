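.moduleColors <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue"
)

#' Unsigned co-expression adjacency
#'
#' a_ij = |cor(x_i, x_j)|^beta (Pearson across samples), with a zero
#' diagonal so that row sums are node connectivities.
#'
#' @param expr features x samples matrix.
#' @param beta soft-threshold power.
#' @return Symmetric adjacency matrix with zero diagonal.
#' @export
adjacencyMatrix <- function(expr, beta) {
  a <- abs(stats::cor(t(expr)))^beta
  diag(a) <- 0
  a
}

# Scale-free topology fit: R^2 of log10 p(k) vs log10 k over equal-width
# connectivity bins (empty bins dropped), forced to 0 when the regression
# slope is positive.
.scaleFreeR2 <- function(k, nBins = 10L) {
  k <- k[k > 0]
  if (length(k) < 2L || diff(range(k)) == 0) return(0)
  br <- seq(min(k), max(k), length.out = nBins + 1L)
  bin <- cut(k, br, include.lowest = TRUE)
  pk <- tapply(k, bin, length) / length(k)
  km <- tapply(k, bin, mean)
  keep <- !is.na(pk) & pk > 0 & km > 0
  if (sum(keep) < 3L) return(0)
  fit <- stats::lm(log10(pk[keep]) ~ log10(km[keep]))
  if (stats::coef(fit)[2] > 0) return(0)
  summary(fit)$r.squared
}

#' Soft-threshold selection for scale-free topology
#'
#' For each candidate power, builds the unsigned adjacency, computes node
#' connectivities and the scale-free fit index R^2 (log-log degree
#' distribution regression over equal-width histogram bins, empty bins
#' dropped, sign-penalised to 0 for a positive slope). The chosen power is
#' the smallest candidate whose R^2 reaches the target. When none does the
#' fit index is uninformative (it rises towards the grid maximum as the
#' adjacency sparsifies, regardless of topology), so the fallback is the
#' conventional sample-size default for unsigned networks (9/8/7/6 for
#' < 20 / < 30 / < 40 / >= 40 samples), flagged via \code{reachedTarget}.
#'
#' @param expr features x samples matrix (>= 3 samples); constant rows are
#'   dropped with a warning before correlation.
#' @param powers ascending candidate powers (default 1:30).
#' @param r2Target target fit index (default 0.9).
#' @param nBins connectivity bins for the fit (default 10).
#' @return List: \code{table} (power, r2, meanK), \code{beta} (chosen),
#'   \code{reachedTarget} (logical).
#' @export
pickSoftThreshold <- function(expr, powers = 1:30, r2Target = 0.9,
                              nBins = 10L) {
  v <- apply(expr, 1, stats::var)
  if (any(v == 0)) {
    warning(sprintf("dropping %d constant-expression features", sum(v == 0)))
    expr <- expr[v > 0, , drop = FALSE]
  }
  if (ncol(expr) < 3L) stop("need >= 3 samples", call. = FALSE)
  ac <- abs(stats::cor(t(expr)))
  diag(ac) <- 0
  r2 <- meanK <- numeric(length(powers))
  for (i in seq_along(powers)) {
    k <- rowSums(ac^powers[i])
    meanK[i] <- mean(k)
    r2[i] <- .scaleFreeR2(k, nBins)
  }
  hit <- which(r2 >= r2Target)
  beta <- if (length(hit)) {
    powers[hit[1]]
  } else {
    n <- ncol(expr)
    fallback <- if (n < 20L) 9L else if (n < 30L) 8L else if (n < 40L) 7L
      else 6L
    powers[which.min(abs(powers - fallback))]
  }
  list(table = data.frame(power = powers, r2 = r2, meanK = meanK),
       beta = beta, reachedTarget = length(hit) > 0)
}

#' Topological overlap matrix
#'
#' TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij) for
#' i != j, TOM_ii = 1, where k are adjacency row sums. High topological
#' overlap means two nodes share neighbours as well as a direct link;
#' 1 - TOM is the clustering dissimilarity.
#'
#' @param a symmetric adjacency with zero diagonal and entries in [0, 1].
#' @return Symmetric TOM with unit diagonal and entries in [0, 1].
#' @export
tomSimilarity <- function(a) {
  if (!isSymmetric(unname(a), tol = 1e-12))
    stop("adjacency must be symmetric", call. = FALSE)
  if (any(diag(a) != 0)) stop("adjacency diagonal must be zero", call. = FALSE)
  if (any(a < 0) || any(a > 1))
    stop("adjacency entries must lie in [0, 1]", call. = FALSE)
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Detect candidate co-expression modules
#'
#' Average-linkage hierarchical clustering of the TOM dissimilarity,
#' cut at a fixed height (a configurable quantile of the dendrogram merge
#' heights); clusters smaller than \code{minModuleSize} are relabelled
#' \code{grey} (unassigned). Non-grey clusters are named by decreasing
#' size using the conventional module colour sequence.
#'
#' @param dissim square dissimilarity matrix (1 - TOM) with feature
#'   dimnames.
#' @param minModuleSize minimum cluster size to keep (default 30).
#' @param cutQuantile quantile of merge heights at which to cut (default
#'   0.75: in a block-structured TOM the lower merges consolidate modules
#'   and the topmost merges join modules and background, so the cut must
#'   sit between the two regimes rather than near the dendrogram top).
#' @return Named character vector of module labels.
#' @export
detectModules <- function(dissim, minModuleSize = 30L, cutQuantile = 0.75) {
  n <- nrow(dissim)
  ids <- rownames(dissim)
  if (is.null(ids)) ids <- paste0("f", seq_len(n))
  if (n < minModuleSize)
    return(stats::setNames(rep("grey", n), ids))
  hc <- stats::hclust(stats::as.dist(dissim), method = "average")
  h <- stats::quantile(hc$height, cutQuantile)
  cl <- stats::cutree(hc, h = h)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= minModuleSize]
  labels <- rep("grey", n)
  if (length(keep)) {
    ord <- keep[order(-sizes[keep])]
    cols <- c(.moduleColors,
              paste0("module", seq_len(max(0, length(ord) -
                                             length(.moduleColors)))))
    for (i in seq_along(ord))
      labels[cl == as.integer(ord[i])] <- cols[i]
  }
  stats::setNames(labels, ids)
}

#' Module eigengene
#'
#' First principal component of the module's row-standardised expression:
#' the first right-singular vector over samples, with its sign fixed so it
#' correlates positively with the module's mean standardised profile.
#'
#' @param exprSubset module features x samples matrix (>= 2 features).
#' @return List: \code{eigengene} (unit-norm sample vector),
#'   \code{varianceExplained}.
#' @export
moduleEigengene <- function(exprSubset) {
  if (nrow(exprSubset) < 2L) stop("module needs >= 2 features", call. = FALSE)
  sdv <- apply(exprSubset, 1, stats::sd)
  if (all(sdv == 0)) stop("all-constant module", call. = FALSE)
  std <- (exprSubset - rowMeans(exprSubset)) / ifelse(sdv > 0, sdv, 1)
  std[sdv == 0, ] <- 0
  sv <- svd(std)
  e <- sv$v[, 1]
  ref <- colMeans(std)
  if (sum(e * ref) < 0) e <- -e
  list(eigengene = e, varianceExplained = sv$d[1]^2 / sum(sv$d^2))
}

.eigengeneMatrix <- function(expr, labels) {
  mods <- setdiff(unique(labels), "grey")
  mods <- mods[order(mods)]
  eg <- vapply(mods, function(m) {
    moduleEigengene(expr[names(labels)[labels == m], , drop = FALSE])$eigengene
  }, numeric(ncol(expr)))
  ve <- vapply(mods, function(m) {
    moduleEigengene(expr[names(labels)[labels == m], , drop = FALSE])$varianceExplained
  }, numeric(1))
  if (length(mods) == 1L)
    eg <- matrix(eg, ncol = 1, dimnames = list(colnames(expr), mods))
  else colnames(eg) <- mods
  rownames(eg) <- colnames(expr)
  list(eigengenes = eg, varianceExplained = ve)
}

#' Merge similar modules by eigengene correlation
#'
#' Iteratively merges the closest pair of modules whose eigengene
#' dissimilarity (1 - Pearson correlation) falls below \code{cut},
#' recomputing eigengenes after every merge, until no pair qualifies.
#'
#' @param expr features x samples matrix covering all labelled features.
#' @param labels named module labels from [detectModules()].
#' @param cut merge threshold on eigengene dissimilarity (default 0.25).
#' @return A \linkS4class{ModulePartition} with merged labels, eigengenes
#'   and per-module variance explained.
#' @export
mergeModules <- function(expr, labels, cut = 0.25) {
  expr <- expr[names(labels), , drop = FALSE]
  repeat {
    mods <- setdiff(unique(labels), "grey")
    if (length(mods) < 2L) break
    em <- .eigengeneMatrix(expr, labels)
    d <- 1 - stats::cor(em$eigengenes)
    diag(d) <- Inf
    if (min(d) >= cut) break
    ij <- which(d == min(d), arr.ind = TRUE)[1, ]
    a <- colnames(d)[ij[1]]; b <- colnames(d)[ij[2]]
    # keep the larger module's name
    if (sum(labels == a) < sum(labels == b)) { tmp <- a; a <- b; b <- tmp }
    labels[labels == b] <- a
  }
  mods <- setdiff(unique(labels), "grey")
  if (length(mods)) {
    em <- .eigengeneMatrix(expr, labels)
    ModulePartition(labels, em$eigengenes, em$varianceExplained)
  } else {
    ModulePartition(labels)
  }
}

#' Module-state correlation
#'
#' Correlates each module eigengene with the binary indicator of each of
#' the four developmental states over samples (Pearson), with two-sided
#' p-values from the t-distribution.
#'
#' @param partition a \linkS4class{ModulePartition} with eigengenes.
#' @param sampleStageLabels stage label of each sample, in eigengene
#'   sample order.
#' @return The partition with \code{stateCor} and \code{stateP} filled
#'   (modules x states).
#' @export
moduleStateCorrelation <- function(partition, sampleStageLabels) {
  reg <- stageRegistry()
  stateOf <- stats::setNames(reg$state, reg$stage)
  states <- developmentalStates()
  eg <- moduleEigengenes(partition)
  if (!ncol(eg)) return(partition)
  sampleState <- stateOf[sampleStageLabels]
  cors <- ps <- matrix(NA_real_, ncol(eg), length(states),
                       dimnames = list(colnames(eg), states))
  for (m in colnames(eg)) for (s in states) {
    ind <- as.numeric(sampleState == s)
    ct <- stats::cor.test(eg[, m], ind)
    cors[m, s] <- unname(ct$estimate)
    ps[m, s] <- ct$p.value
  }
  partition@stateCor <- cors
  partition@stateP <- ps
  partition
}
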