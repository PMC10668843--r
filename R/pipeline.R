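#' Pipeline configuration with published default thresholds
#'
#' Collects every tunable threshold of the pipeline with its default:
#' expressed-call FPKM > 1; expression-tier percentiles 0.3/0.6 (fixed in
#' [tierByExpression()]); 1000 permutations; +/- 20 kb GWAS windows;
#' minimum module size 30; module-merge cut height 0.25; TE-TE
#' topological-overlap threshold 0.2; adjusted-p cut 0.05 with |rho| 0.3
#' for TE-gene pairs; promoter window +/- 3 kb.
#'
#' @param seed global seed; each stage derives its own sub-seed from it.
#' @param inputDir directory of study files (as written by [writeStudy()]);
#'   \code{NULL} simulates a study with [simConfig()]\code{(seed)}.
#' @param outDir output directory.
#' @param fpkmThreshold,nPerm,gwasFlank,minModuleSize,mergeCutHeight,
#'   teTeThreshold,pAdjCut,rhoCut,promoterWindow thresholds as above.
#' @param gmt optional GMT path for the gene-set stage; when absent a
#'   deterministic synthetic collection over the gene universe is used.
#' @return Config list.
#' @export
pipelineConfig <- function(seed = 1L, inputDir = NULL, outDir = "teatlas_out",
                           fpkmThreshold = 1.0, nPerm = 1000L,
                           gwasFlank = 20000L, minModuleSize = 30L,
                           mergeCutHeight = 0.25, teTeThreshold = 0.2,
                           pAdjCut = 0.05, rhoCut = 0.3,
                           promoterWindow = 3000L, gmt = NULL) {
  as.list(environment())
}

.loadStudy <- function(dir) {
  need <- c("chrom.sizes", "tes.bed", "te_info.tsv", "genes.gtf",
            "te_fpkm.tsv", "gene_tpm.tsv", "methylation.tsv", "gwas.tsv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing))
    stop(sprintf("stage 'simulate' outputs missing from %s: %s", dir,
                 paste(missing, collapse = ", ")), call. = FALSE)
  tesBed <- readBed(file.path(dir, "tes.bed"))
  info <- read.delim(file.path(dir, "te_info.tsv"),
                     stringsAsFactors = FALSE)
  tes <- GRanges(seqnames(tesBed), IRanges(start(tesBed), end(tesBed)),
                 strand = strand(tesBed))
  mcols(tes)$te_id <- mcols(tesBed)$name
  mcols(tes)$te_class <- info$te_class[match(mcols(tesBed)$name,
                                             info$te_id)]
  mcols(tes)$family <- info$family[match(mcols(tesBed)$name, info$te_id)]
  peaks <- list()
  for (a in c("ATAC", "H3K27ac", "H3K4me3")) {
    f <- file.path(dir, paste0("peaks_", a, ".bed"))
    if (file.exists(f)) peaks[[a]] <- readBed(f)
  }
  list(chromSizes = readChromSizes(file.path(dir, "chrom.sizes")),
       tes = tes,
       genes = readGtfGenes(file.path(dir, "genes.gtf")),
       teExpr = readExpressionMatrix(file.path(dir, "te_fpkm.tsv"), "FPKM"),
       geneExpr = readExpressionMatrix(file.path(dir, "gene_tpm.tsv"),
                                       "TPM"),
       methylation = readMethylation(file.path(dir, "methylation.tsv")),
       peaks = peaks,
       gwas = readGwasTable(file.path(dir, "gwas.tsv")))
}

.tsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full TE-atlas pipeline
#'
#' Executes, in dependency order: simulate (or load inputs), atlas,
#' classify, enrich, modules, network and gene-set stages, writing one
#' TSV per result plus a manifest JSON with an md5 hash of every artifact.
#' The resolved configuration is written next to the outputs as
#' \code{config_resolved.yaml}. Reruns with the same config and seed
#' produce identical hashes.
#'
#' @param config from [pipelineConfig()].
#' @return Invisibly, the manifest list.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outDir, f)
  # resolved configuration is recorded next to the outputs; it carries
  # run-local paths, so it is not part of the content-hash manifest
  yaml::write_yaml(config, out("config_resolved.yaml"))
  written <- character()

  # -- simulate / load ------------------------------------------------
  if (is.null(config$inputDir)) {
    simDir <- out("sim")
    writeStudy(simulateStudy(simConfig(seed = config$seed)), simDir)
    written <- c(written, list.files(simDir, full.names = TRUE))
    # reload from disk so simulated and pre-supplied inputs follow the
    # identical parse path (and identical rounding)
    study <- .loadStudy(simDir)
  } else {
    study <- .loadStudy(config$inputDir)
  }
  teById <- stats::setNames(seq_along(study$tes),
                            mcols(study$tes)$te_id)

  # -- atlas ----------------------------------------------------------
  calls <- callExpressed(study$teExpr, config$fpkmThreshold)
  written <- c(written, .tsv(
    data.frame(stage = names(calls$counts), expressed = calls$counts),
    out("atlas_expressed_counts.tsv")))
  pca <- pcaSamples(study$teExpr)
  written <- c(written, .tsv(
    data.frame(sample = rownames(pca$scores),
               PC1 = pca$scores[, 1], PC2 = pca$scores[, 2]),
    out("atlas_pca.tsv")))
  hm <- heatmapMatrix(study$teExpr, calls)
  written <- c(written, .tsv(
    data.frame(te_id = rownames(hm), hm, check.names = FALSE),
    out("atlas_heatmap_matrix.tsv")))

  # -- classify -------------------------------------------------------
  exprTes <- study$tes[teById[calls$union]]
  context <- annotateContext(exprTes, study$genes, config$promoterWindow)
  classes <- classifyTEs(exprTes, study$genes)
  classify <- merge(context, classes, by = "te_id", sort = TRUE)
  written <- c(written, .tsv(classify, out("classify_context.tsv")))

  # -- enrich (peaks + methylation tiers) -----------------------------
  enrichRows <- list()
  for (i in seq_along(study$peaks)) {
    r <- permutationEnrichment(exprTes, study$peaks[[i]],
                               study$chromSizes, config$nPerm,
                               seed = config$seed + 100L + i,
                               label = names(study$peaks)[i])
    enrichRows[[i]] <- data.frame(assay = r@label, observed = r@observed,
                                  null_mean = r@nullMean, fold = r@fold,
                                  p_emp = r@pEmp)
  }
  if (length(enrichRows)) {
    et <- do.call(rbind, enrichRows)
    et$p_adj <- bhAdjust(et$p_emp)
    written <- c(written, .tsv(et, out("enrich_peaks.tsv")))
  }
  sm <- stageMeans(study$teExpr)
  tierRows <- lapply(colnames(sm), function(s) {
    ids <- calls$perStage[[s]]
    if (length(ids) < 3L) return(NULL)
    tiers <- tierByExpression(sm[ids, s])
    lev <- regionMethylation(study$methylation,
                             study$tes[teById[tiers$te_id]])
    ok <- !is.na(lev)
    data.frame(stage = s,
               tier = tiers$tier[ok], methylation = lev[ok])
  })
  tierTab <- do.call(rbind, tierRows)
  tierSummary <- stats::aggregate(methylation ~ stage + tier, tierTab, mean)
  written <- c(written, .tsv(tierSummary, out("enrich_methylation_tiers.tsv")))

  # -- modules (self-expressed TEs) -----------------------------------
  selfIds <- intersect(classes$te_id[classes$class == "self_expressed"],
                       calls$union)
  expr <- assay(study$teExpr)[selfIds, , drop = FALSE]
  expr <- expr[apply(expr, 1, stats::var) > 0, , drop = FALSE]
  selfIds <- rownames(expr)
  sft <- pickSoftThreshold(expr)
  adj <- adjacencyMatrix(expr, sft$beta)
  tom <- tomSimilarity(adj)
  labels <- detectModules(1 - tom, config$minModuleSize)
  partition <- mergeModules(expr, labels, config$mergeCutHeight)
  partition <- moduleStateCorrelation(partition,
                                      sampleStages(study$teExpr))
  written <- c(written, .tsv(
    data.frame(te_id = names(moduleLabels(partition)),
               module = moduleLabels(partition)),
    out("modules_labels.tsv")))
  written <- c(written, .tsv(sft$table, out("modules_soft_threshold.tsv")))
  sc <- stateCorrelation(partition)
  if (length(sc))
    written <- c(written, .tsv(
      data.frame(module = rownames(sc), sc, check.names = FALSE),
      out("modules_state_correlation.tsv")))

  # -- network --------------------------------------------------------
  flank <- nearestFlankingGenes(study$tes[teById[selfIds]], study$genes)
  pairs <- teGenePairs(stageMeans(study$teExpr)[selfIds, , drop = FALSE],
                       stageMeans(study$geneExpr), flank,
                       config$pAdjCut, config$rhoCut)
  edges <- teTeEdges(tom, moduleLabels(partition), config$teTeThreshold)
  mc <- study$gwas[study$gwas$category == "Meat and Carcass", ]
  win <- extendGwasLoci(mc$chrom, mc$pos, study$chromSizes,
                        config$gwasFlank)
  hubFlags <- flagHubTEs(study$tes[teById[selfIds]], win)
  network <- assembleHubNetwork(pairs, edges, hubFlags)
  written <- c(written, .tsv(pairs, out("network_te_gene_pairs.tsv")))
  writeEdgeList(network, out("network_edges.tsv"))
  written <- c(written, out("network_edges.tsv"), .tsv(
    as.data.frame(networkNodes(network)), out("network_nodes.tsv")))
  netTes <- networkNodes(network)
  netTes <- netTes$id[netTes$type == "TE"]
  if (length(netTes)) {
    gw <- networkGwasEnrichment(study$tes[teById[netTes]], study$gwas,
                                study$chromSizes, config$nPerm,
                                seed = config$seed + 200L,
                                flank = config$gwasFlank)
    written <- c(written, .tsv(
      data.frame(category = names(gw),
                 observed = vapply(gw, function(r) r@observed, 1),
                 fold = vapply(gw, foldEnrichment, 1),
                 p_emp = vapply(gw, empiricalP, 1),
                 p_adj = vapply(gw, function(r) r@pAdj, 1)),
      out("network_gwas_enrichment.tsv")))
  }

  # -- gene sets ------------------------------------------------------
  universe <- mcols(study$genes)$gene_id
  collection <- if (!is.null(config$gmt)) readGmt(config$gmt) else {
    blocks <- split(universe, ceiling(seq_along(universe) / 20))
    stats::setNames(blocks, paste0("SYNTH_TERM_", names(blocks)))
  }
  goTab <- hypergeomEnrich(teSetToGenes(selfIds, context), collection,
                           universe)
  written <- c(written, .tsv(goTab, out("go_enrichment.tsv")))

  manifest <- list(
    seed = config$seed,
    files = as.list(tools::md5sum(sort(unique(written))))
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE)
  invisible(manifest)
}
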