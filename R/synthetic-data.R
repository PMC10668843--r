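#' Configuration for the synthetic miniature study
#'
#' Defaults describe a seconds-scale study that emulates the real design:
#' a 2 x 10 Mb genome, 300 genes, 1,000 TEs (40% intergenic), five planted
#' co-expression modules of 40 TEs at within-module correlation 0.8, 90
#' planted signed TE-gene pairs, 20 designated hub TEs, 200 peaks per
#' assay with 60% placed on expressed TEs, and 100 GWAS loci per trait
#' category with half of the Meat-and-Carcass loci placed within +/- 20 kb
#' of hub TEs.
#'
#' @param seed integer seed; every generator derives its randomness from
#'   it.
#' @param chromLengths named chromosome lengths (bp).
#' @param nGenes,nTEs feature counts.
#' @param intergenicFraction fraction of TEs placed outside gene bodies.
#' @param moduleSizes planted module sizes (all intergenic, expressed).
#' @param withinModuleCor target mean pairwise correlation inside a
#'   module; replicate noise is calibrated to reach it.
#' @param nHubTEs designated hub TEs (taken from the first module).
#' @param nPosPairs,nNegPairs planted positive/negative TE-gene pairs.
#' @param geneNoise lognormal sdlog of planted/background gene replicates.
#' @param replicateNoise lognormal sdlog for non-module TE replicates;
#'   0 switches all replicate noise off.
#' @param embryonicOnlyCount intergenic TEs expressed pre-birth only.
#' @param otherExpressedIntergenic constitutively expressed intergenic
#'   TEs without module structure.
#' @param genicExpressedFraction fraction of genic TEs expressed.
#' @param nPeaksPerAssay,peakTeFraction peak counts and the fraction
#'   placed on expressed TEs.
#' @param nGwasPerCategory,hubGwasExcess GWAS loci per trait category and
#'   the fraction of Meat-and-Carcass loci anchored near hub TEs.
#' @param nCpgPerTe,readDepth methylation coverage settings.
#' @return A validated config list.
#' @export
simConfig <- function(seed = 1L,
                      chromLengths = c(chr1 = 10e6, chr2 = 10e6),
                      nGenes = 400L, nTEs = 1000L,
                      intergenicFraction = 0.4,
                      moduleSizes = rep(40L, 5),
                      withinModuleCor = 0.8,
                      nHubTEs = 20L,
                      nPosPairs = 40L, nNegPairs = 20L,
                      geneNoise = 0.2,
                      replicateNoise = 0.15,
                      embryonicOnlyCount = 30L,
                      otherExpressedIntergenic = 40L,
                      genicExpressedFraction = 0.4,
                      nPeaksPerAssay = 200L, peakTeFraction = 0.6,
                      nGwasPerCategory = 100L, hubGwasExcess = 0.5,
                      nCpgPerTe = 5L, readDepth = 20L) {
  cfg <- as.list(environment())
  if (any(unlist(cfg[c("nGenes", "nTEs", "nPeaksPerAssay",
                       "nGwasPerCategory", "nCpgPerTe")]) <= 0))
    stop("all counts must be positive", call. = FALSE)
  nInter <- round(nTEs * intergenicFraction)
  if (sum(moduleSizes) + embryonicOnlyCount + otherExpressedIntergenic >
      nInter)
    stop("module sizes exceed the intergenic TE budget", call. = FALSE)
  if (nHubTEs > moduleSizes[1])
    stop("hub TEs must fit in the first module", call. = FALSE)
  cfg
}

gwasCategories <- function() {
  c("Meat and Carcass", "Health", "Production", "Reproduction", "Exterior")
}

#' Generate the miniature genome and annotations
#'
#' Genes are placed non-overlapping, approximately uniformly (one per
#' equal-width slot, random offset) with 2-5 exons each; TEs are placed
#' with the configured intergenic fraction (the rest inside gene bodies)
#' and assigned classes from \{LINE, SINE, LTR, DNA\}. Fully
#' deterministic given \code{config$seed}.
#'
#' @param config from [simConfig()].
#' @return List: \code{chromSizes}, \code{genes} (GRanges as from
#'   [readGtfGenes()]), \code{tes} (GRanges with te_id/te_class/family),
#'   \code{truth} (roles, planted modules, hub ids).
#' @export
generateGenomeAnnotations <- function(config) {
  set.seed(config$seed)
  L <- config$chromLengths
  nPer <- round(config$nGenes * L / sum(L))
  nPer[length(nPer)] <- config$nGenes - sum(nPer[-length(nPer)])
  maxGene <- 12000L
  gchrom <- character(); gs <- integer(); ge <- integer()
  for (ci in seq_along(L)) {
    slot <- floor(L[ci] / nPer[ci])
    if (slot < maxGene + 2L)
      stop("infeasible packing: too many genes for the genome",
           call. = FALSE)
    len <- sample(2000:maxGene, nPer[ci], replace = TRUE)
    offs <- floor(stats::runif(nPer[ci]) * (slot - len - 1)) + 1L
    gchrom <- c(gchrom, rep(names(L)[ci], nPer[ci]))
    gs <- c(gs, as.integer((seq_len(nPer[ci]) - 1L) * slot + offs))
    ge <- c(ge, as.integer((seq_len(nPer[ci]) - 1L) * slot + offs + len - 1L))
  }
  gstr <- sample(c("+", "-"), config$nGenes, replace = TRUE)
  genes <- GRanges(gchrom, IRanges(gs, ge), strand = gstr)
  mcols(genes)$gene_id <- sprintf("G%04d", seq_len(config$nGenes))
  mcols(genes)$tss <- ifelse(gstr == "+", gs, ge)
  nEx <- sample(2:5, config$nGenes, replace = TRUE)
  exList <- lapply(seq_len(config$nGenes), function(i) {
    k <- nEx[i]; w <- ge[i] - gs[i] + 1L
    es <- gs[i] + as.integer((seq_len(k) - 1L) * floor(w / k))
    ee <- pmin(ge[i], es + as.integer(floor(w / (2L * k))))
    GRanges(factor(gchrom[i], levels = names(L)), IRanges(es, ee),
            strand = gstr[i])
  })
  mcols(genes)$exons <- methods::as(exList, "GRangesList")

  nInter <- round(config$nTEs * config$intergenicFraction)
  nGenic <- config$nTEs - nInter
  teLen <- sample(300:3000, config$nTEs, replace = TRUE)
  tchrom <- character(config$nTEs); ts <- integer(config$nTEs)
  # intergenic: batch rejection-sample uniform placements off gene bodies
  placed <- 0L
  while (placed < nInter) {
    todo <- seq.int(placed + 1L, nInter)
    ci <- sample.int(length(L), length(todo), replace = TRUE, prob = L)
    s <- floor(stats::runif(length(todo)) * (L[ci] - teLen[todo])) + 1L
    cand <- GRanges(names(L)[ci], IRanges(as.integer(s),
                                          as.integer(s) + teLen[todo] - 1L))
    ok <- countOverlaps(cand, genes, ignore.strand = TRUE) == 0L
    keep <- todo[ok]
    tchrom[keep] <- names(L)[ci[ok]]
    ts[keep] <- as.integer(s[ok])
    # compact accepted placements to the front of the remaining block
    nAcc <- sum(ok)
    if (nAcc) {
      tchrom[seq.int(placed + 1L, placed + nAcc)] <- tchrom[keep]
      ts[seq.int(placed + 1L, placed + nAcc)] <- ts[keep]
      lenKeep <- teLen[keep]
      teLen[seq.int(placed + 1L, placed + nAcc)] <- lenKeep
      placed <- placed + nAcc
    }
  }
  # genic: uniform gene, uniform offset within the body
  host <- sample.int(config$nGenes, nGenic, replace = TRUE)
  for (j in seq_len(nGenic)) {
    i <- nInter + j
    g <- host[j]
    teLen[i] <- min(teLen[i], ge[g] - gs[g])
    ts[i] <- gs[g] + floor(stats::runif(1) * (ge[g] - gs[g] - teLen[i] + 1L))
    tchrom[i] <- gchrom[g]
  }
  cls <- sample(c("LINE", "SINE", "LTR", "DNA"), config$nTEs,
                replace = TRUE, prob = c(0.35, 0.35, 0.15, 0.15))
  tes <- GRanges(tchrom, IRanges(ts, ts + teLen - 1L),
                 strand = sample(c("+", "-"), config$nTEs, replace = TRUE))
  mcols(tes)$te_id <- sprintf("TE%04d", seq_len(config$nTEs))
  mcols(tes)$te_class <- cls
  mcols(tes)$family <- paste0(cls, "/fam",
                              sample(1:3, config$nTEs, replace = TRUE))

  # roles over intergenic TEs: planted modules, embryonic-only,
  # constitutive, silent; genic TEs: expressed or silent
  roles <- rep("silent", config$nTEs)
  interIdx <- sample(seq_len(nInter))  # shuffle so roles are spread
  nMod <- sum(config$moduleSizes)
  modAssign <- stats::setNames(rep(NA_character_, config$nTEs),
                               mcols(tes)$te_id)
  modIdx <- interIdx[seq_len(nMod)]
  roles[modIdx] <- "module"
  modAssign[modIdx] <- rep(paste0("M", seq_along(config$moduleSizes)),
                           config$moduleSizes)
  off <- nMod
  if (config$embryonicOnlyCount > 0) {
    idx <- interIdx[off + seq_len(config$embryonicOnlyCount)]
    roles[idx] <- "embryonic_only"
    off <- off + config$embryonicOnlyCount
  }
  if (config$otherExpressedIntergenic > 0) {
    idx <- interIdx[off + seq_len(config$otherExpressedIntergenic)]
    roles[idx] <- "constitutive"
  }
  genicIdx <- nInter + seq_len(nGenic)
  nGenicExpr <- round(nGenic * config$genicExpressedFraction)
  roles[sample(genicIdx, nGenicExpr)] <- "constitutive"
  hubs <- mcols(tes)$te_id[modIdx[seq_len(config$nHubTEs)]]

  truth <- list(
    roles = stats::setNames(roles, mcols(tes)$te_id),
    moduleAssignment = modAssign,
    hubTEs = hubs,
    expressed = stats::setNames(roles != "silent", mcols(tes)$te_id)
  )
  list(chromSizes = L, genes = genes, tes = tes, truth = truth)
}

# Smooth latent stage profiles, one per module, peaking in distinct
# developmental windows across the 27 stages.
.moduleLatents <- function(nModules, nStages = 27L) {
  centers <- seq(3, nStages - 3, length.out = nModules)
  t(vapply(centers, function(cc) exp(-(seq_len(nStages) - cc)^2 / 18),
           numeric(nStages)))
}

#' Generate the staged TE and gene expression matrices
#'
#' Module TEs follow a shared smooth latent stage profile through a
#' latent-times-loading model with multiplicative lognormal replicate
#' noise whose variance is calibrated so that within-module pairwise
#' correlation matches \code{withinModuleCor}. Planted positive pairs give
#' the flanking gene the TE's latent profile; negative pairs use its
#' reflection. Embryonic-only TEs are expressed pre-birth and silent
#' post-birth; silent TEs stay below stage-mean FPKM 0.5 by construction.
#'
#' @param ann output of [generateGenomeAnnotations()].
#' @param config from [simConfig()].
#' @return List: \code{teExpr} and \code{geneExpr}
#'   (\linkS4class{StageExpressionSet}, FPKM/TPM), \code{truth} (augmented
#'   with planted pairs).
#' @export
generateExpression <- function(ann, config) {
  set.seed(config$seed + 1L)
  reg <- stageRegistry()
  nStage <- nrow(reg)
  nRep <- 3L
  stages <- rep(reg$stage, each = nRep)
  reps <- rep(seq_len(nRep), nStage)
  teIds <- mcols(ann$tes)$te_id
  roles <- ann$truth$roles
  latents <- .moduleLatents(length(config$moduleSizes), nStage)
  zeroNoise <- config$replicateNoise == 0

  mu <- matrix(0.1, length(teIds), nStage,
               dimnames = list(teIds, reg$stage))
  loading <- stats::setNames(rep(NA_real_, length(teIds)), teIds)
  for (i in which(roles == "module")) {
    m <- as.integer(sub("M", "", ann$truth$moduleAssignment[i]))
    loading[i] <- stats::runif(1, 0.8, 1.2)
    mu[i, ] <- 3 * (1 + 4 * loading[i] * latents[m, ])
  }
  embMask <- reg$phase == "embryonic"
  for (i in which(roles == "embryonic_only"))
    mu[i, ] <- ifelse(embMask, 5 * exp(stats::rnorm(nStage, 0, 0.4)), 0.05)
  # constitutive TEs span a wide dynamic range of baseline abundance so
  # that stage-wise expression rank tracks overall abundance rank
  for (i in which(roles == "constitutive")) {
    base <- exp(stats::runif(1, log(2), log(40)))
    mu[i, ] <- base * exp(stats::rnorm(nStage, 0, 0.3))
  }

  # per-TE noise sdlog: calibrated for module TEs, fixed scale otherwise
  sig <- rep(config$replicateNoise, length(teIds))
  r <- config$withinModuleCor
  for (i in which(roles == "module")) {
    v <- stats::var(rep(mu[i, ], each = nRep)) * (81 - 1) / 81
    m2 <- mean(rep(mu[i, ], each = nRep)^2)
    sig[i] <- sqrt(log(1 + v * (1 - r) / (r * m2)))
  }
  if (zeroNoise) sig[] <- 0
  big <- mu[, rep(seq_len(nStage), each = nRep)]
  noise <- matrix(stats::rnorm(length(big)), nrow(big))
  te <- big * exp(sig * noise - sig^2 / 2)
  colnames(te) <- paste0(stages, "_", reps)
  teExpr <- StageExpressionSet(te, stages, reps, "FPKM")

  # planted TE-gene pairs among module TEs, via genuine flanking genes;
  # a gene is eligible only when exactly one expressed intergenic TE (the
  # module TE itself) has it as a flanking gene, so the planted signal
  # cannot leak into other candidate pairs
  selfExpr <- teIds[roles %in% c("module", "constitutive",
                                 "embryonic_only")]
  selfGr <- ann$tes[match(selfExpr, teIds)]
  fl <- nearestFlankingGenes(selfGr, ann$genes)
  flankCount <- table(c(fl$upstream_gene, fl$downstream_gene))
  candTe <- sample(teIds[roles == "module"])
  rowOf <- match(candTe, fl$te_id)
  pairs <- data.frame(te_id = character(), gene_id = character(),
                      sign = character(), stringsAsFactors = FALSE)
  usedGenes <- character()
  wanted <- sample(c(rep("positive", config$nPosPairs),
                     rep("negative", config$nNegPairs)))
  k <- 0L
  for (j in seq_along(candTe)) {
    if (k >= length(wanted)) break
    row <- fl[rowOf[j], ]
    cands <- stats::na.omit(c(row$upstream_gene, row$downstream_gene))
    cands <- cands[!cands %in% usedGenes &
                     !is.na(flankCount[cands]) & flankCount[cands] == 1]
    if (!length(cands)) next
    g <- cands[1]
    k <- k + 1L
    pairs <- rbind(pairs, data.frame(te_id = candTe[j], gene_id = g,
                                     sign = wanted[k],
                                     stringsAsFactors = FALSE))
    usedGenes <- c(usedGenes, g)
  }

  geneIds <- mcols(ann$genes)$gene_id
  gmu <- matrix(0, length(geneIds), nStage,
                dimnames = list(geneIds, reg$stage))
  for (g in seq_along(geneIds))
    gmu[g, ] <- 10 * exp(stats::rnorm(nStage, 0, 0.7))
  for (j in seq_len(nrow(pairs))) {
    m <- as.integer(sub("M", "", ann$truth$moduleAssignment[pairs$te_id[j]]))
    lat <- latents[m, ]
    prof <- if (pairs$sign[j] == "positive") lat else max(lat) - lat
    gmu[pairs$gene_id[j], ] <- 10 * (0.3 + 2 * prof)
  }
  gsig <- if (zeroNoise) 0 else config$geneNoise
  gbig <- gmu[, rep(seq_len(nStage), each = nRep)]
  gnoise <- matrix(stats::rnorm(length(gbig)), nrow(gbig))
  gene <- gbig * exp(gsig * gnoise - gsig^2 / 2)
  colnames(gene) <- paste0(stages, "_", reps)
  geneExpr <- StageExpressionSet(gene, stages, reps, "TPM")

  truth <- ann$truth
  truth$pairs <- pairs
  list(teExpr = teExpr, geneExpr = geneExpr, truth = truth)
}

#' Generate a CpG methylation track anticorrelated with TE expression
#'
#' Each TE is covered by \code{nCpgPerTe} CpG sites whose binomial success
#' probability decreases with the TE's overall expression rank, so highly
#' expressed TEs sit in lowly methylated regions and silent TEs in highly
#' methylated ones. Every CpG has at least one read.
#'
#' @param tes TE \code{GRanges}.
#' @param teExpr TE \linkS4class{StageExpressionSet}.
#' @param config from [simConfig()].
#' @return A methylation \code{GRanges} (see [readMethylation()]).
#' @export
generateMethylation <- function(tes, teExpr, config) {
  set.seed(config$seed + 2L)
  mFpkm <- rowMeans(assay(teExpr))[mcols(tes)$te_id]
  r <- (rank(mFpkm, ties.method = "first") - 1) / length(mFpkm)
  pTe <- pmin(0.95, pmax(0.05, 0.88 - 0.6 * r +
                           stats::rnorm(length(r), 0, 0.04)))
  k <- config$nCpgPerTe
  pos <- unlist(lapply(seq_along(tes), function(i) {
    w <- width(tes)[i]
    start(tes)[i] + unique(pmin(w - 1L,
      as.integer(round(seq(0.1, 0.9, length.out = k) * w))))
  }))
  nPer <- vapply(seq_along(tes), function(i) {
    w <- width(tes)[i]
    length(unique(pmin(w - 1L,
      as.integer(round(seq(0.1, 0.9, length.out = k) * w)))))
  }, integer(1))
  chrom <- rep(as.character(seqnames(tes)), nPer)
  p <- rep(pTe, nPer)
  total <- 1L + stats::rpois(length(pos), config$readDepth)
  meth <- stats::rbinom(length(pos), total, p)
  gr <- GRanges(chrom, IRanges(pos, width = 1L))
  mcols(gr)$meth <- meth
  mcols(gr)$total <- total
  gr
}

#' Generate epigenomic peak sets and a GWAS locus catalogue
#'
#' A configured fraction of each assay's peaks is centred on randomly
#' chosen expressed TEs (guaranteeing overlap); the rest are uniform.
#' Meat-and-Carcass loci are placed within +/- 20 kb of designated hub
#' TEs at the configured excess rate; all other trait categories are
#' uniform.
#'
#' @param tes TE \code{GRanges}.
#' @param truth truth list carrying \code{expressed} and \code{hubTEs}.
#' @param chromSizes named chromosome lengths.
#' @param config from [simConfig()].
#' @return List: \code{peaks} (named list of \code{GRanges} for ATAC,
#'   H3K27ac, H3K4me3), \code{gwas} (data.frame category/chrom/pos).
#' @export
generatePeaksGwas <- function(tes, truth, chromSizes, config) {
  set.seed(config$seed + 3L)
  L <- chromSizes
  exprTes <- tes[truth$expressed[mcols(tes)$te_id]]
  peakW <- 400L
  mkPeaks <- function(n) {
    nOn <- round(n * config$peakTeFraction)
    onIdx <- sample(seq_along(exprTes), nOn, replace = TRUE)
    cen <- start(exprTes)[onIdx] +
      floor(stats::runif(nOn) * width(exprTes)[onIdx])
    onChrom <- as.character(seqnames(exprTes))[onIdx]
    nOff <- n - nOn
    offChrom <- names(L)[sample.int(length(L), nOff, replace = TRUE,
                                    prob = L)]
    offCen <- floor(stats::runif(nOff) * (L[offChrom] - peakW)) + peakW / 2
    chrom <- c(onChrom, offChrom)
    cen <- c(cen, offCen)
    s <- pmax(1, as.integer(cen - peakW / 2))
    GRanges(chrom, IRanges(s, s + peakW - 1L))
  }
  peaks <- list(ATAC = mkPeaks(config$nPeaksPerAssay),
                H3K27ac = mkPeaks(config$nPeaksPerAssay),
                H3K4me3 = mkPeaks(config$nPeaksPerAssay))

  hubGr <- tes[mcols(tes)$te_id %in% truth$hubTEs]
  flank <- 20000L
  gwas <- do.call(rbind, lapply(gwasCategories(), function(cat) {
    n <- config$nGwasPerCategory
    nHub <- if (cat == "Meat and Carcass")
      round(n * config$hubGwasExcess) else 0L
    if (nHub > 0) {
      hi <- sample(seq_along(hubGr), nHub, replace = TRUE)
      lo <- pmax(1L, start(hubGr)[hi] - flank + 1L)
      hiP <- end(hubGr)[hi] + flank - 1L
      posH <- lo + floor(stats::runif(nHub) * (hiP - lo + 1))
      chromH <- as.character(seqnames(hubGr))[hi]
    } else { posH <- numeric(); chromH <- character() }
    nU <- n - nHub
    chromU <- names(L)[sample.int(length(L), nU, replace = TRUE, prob = L)]
    posU <- floor(stats::runif(nU) * (L[chromU] - 1)) + 1
    data.frame(category = cat, chrom = c(chromH, chromU),
               pos = as.integer(c(posH, posU)), stringsAsFactors = FALSE)
  }))
  rownames(gwas) <- NULL
  list(peaks = peaks, gwas = gwas)
}

#' Simulate the full miniature study in memory
#'
#' @param config from [simConfig()].
#' @return List: \code{chromSizes}, \code{genes}, \code{tes},
#'   \code{teExpr}, \code{geneExpr}, \code{methylation}, \code{peaks},
#'   \code{gwas}, \code{truth}.
#' @export
simulateStudy <- function(config = simConfig()) {
  ann <- generateGenomeAnnotations(config)
  ex <- generateExpression(ann, config)
  meth <- generateMethylation(ann$tes, ex$teExpr, config)
  pg <- generatePeaksGwas(ann$tes, ex$truth, ann$chromSizes, config)
  list(chromSizes = ann$chromSizes, genes = ann$genes, tes = ann$tes,
       teExpr = ex$teExpr, geneExpr = ex$geneExpr, methylation = meth,
       peaks = pg$peaks, gwas = pg$gwas, truth = ex$truth)
}

.writeGtf <- function(genes, path) {
  gl <- sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
                as.character(seqnames(genes)), start(genes), end(genes),
                as.character(strand(genes)), mcols(genes)$gene_id)
  exons <- mcols(genes)$exons
  el <- unlist(lapply(seq_along(genes), function(i) {
    e <- exons[[i]]
    sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
            as.character(seqnames(e)), start(e), end(e),
            as.character(strand(e)), mcols(genes)$gene_id[i])
  }))
  writeLines(c(gl, el), path)
}

#' Write a simulated study to disk in the pipeline's input formats
#'
#' Emits chrom.sizes, tes.bed (name = te_id) plus te_info.tsv
#' (te_id/class/family), genes.gtf, te_fpkm.tsv, gene_tpm.tsv,
#' methylation.tsv, one BED per peak assay, gwas.tsv and truth.json.
#'
#' @param study from [simulateStudy()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  writeChromSizes(study$chromSizes, p("chrom.sizes"))
  teBed <- study$tes
  mcols(teBed) <- S4Vectors::DataFrame(name = mcols(study$tes)$te_id,
                                       score = 0)
  writeBed(teBed, p("tes.bed"))
  write.table(data.frame(te_id = mcols(study$tes)$te_id,
                         te_class = mcols(study$tes)$te_class,
                         family = mcols(study$tes)$family),
              p("te_info.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  .writeGtf(study$genes, p("genes.gtf"))
  writeExpressionMatrix(study$teExpr, p("te_fpkm.tsv"))
  writeExpressionMatrix(study$geneExpr, p("gene_tpm.tsv"))
  writeMethylation(study$methylation, p("methylation.tsv"))
  for (a in names(study$peaks))
    writeBed(study$peaks[[a]], p(paste0("peaks_", a, ".bed")))
  writeGwasTable(study$gwas, p("gwas.tsv"))
  truth <- study$truth
  truth$moduleAssignment <- as.list(truth$moduleAssignment)
  truth$expressed <- as.list(truth$expressed)
  truth$roles <- as.list(truth$roles)
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                       null = "null", na = "null")
  files <- list.files(dir, full.names = TRUE)
  invisible(stats::setNames(files, basename(files)))
}
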