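test_that("classifyPairs preserves the published boundary asymmetry", {
  expect_equal(classifyPairs(0.3, 0.04), "positive")    # inclusive at 0.3
  expect_true(is.na(classifyPairs(-0.3, 0.04)))         # exclusive at -0.3
  expect_equal(classifyPairs(-0.300001, 0.04), "negative")
  expect_true(is.na(classifyPairs(0.29, 0.04)))         # below rho cut
  expect_true(is.na(classifyPairs(0.9, 0.05)))          # p_adj not < 0.05
  expect_equal(classifyPairs(c(0.5, -0.5, 0.1), c(0.01, 0.01, 0.01)),
               c("positive", "negative", NA))
})

test_that("teGenePairs detects monotone pairs over 27 stage means", {
  stages <- stageRegistry()$stage
  up <- seq(1, 10, length.out = 27)
  te <- rbind(TEa = up, TEb = rev(up), TEc = rep(2, 27))
  colnames(te) <- stages
  gene <- rbind(G1 = up^2, G2 = up)  # co-/anti-monotone with TEa/TEb
  colnames(gene) <- stages
  flanking <- data.frame(
    te_id = c("TEa", "TEb", "TEc"),
    upstream_gene = c("G1", "G2", "G1"),
    upstream_dist = 1, downstream_gene = NA_character_,
    downstream_dist = NA_real_, stringsAsFactors = FALSE)
  pairs <- suppressWarnings(teGenePairs(te, gene, flanking))
  expect_equal(pairs$sign[pairs$te_id == "TEa"], "positive")
  expect_equal(pairs$rho[pairs$te_id == "TEa"], 1)
  expect_equal(pairs$sign[pairs$te_id == "TEb"], "negative")
  expect_equal(pairs$rho[pairs$te_id == "TEb"], -1)
  expect_false("TEc" %in% pairs$te_id)  # constant profile skipped
  expect_warning(teGenePairs(te, gene, flanking), "constant")
})

test_that("lowering rho_cut never removes a reported pair", {
  an <- defaultAnalysis()
  st <- an$study
  tighter <- an$pairs
  looser <- suppressWarnings(
    teGenePairs(stageMeans(st$teExpr)[an$selfIds, , drop = FALSE],
                stageMeans(st$geneExpr), an$flank, 0.05, 0.2))
  key <- function(d) paste(d$te_id, d$gene_id, d$sign)
  expect_true(all(key(tighter) %in% key(looser)))
})

test_that("teTeEdges keeps same-module edges at TOM >= threshold", {
  ids <- c("TEa", "TEb", "TEc", "TEd")
  tom <- matrix(0, 4, 4, dimnames = list(ids, ids))
  tom["TEa", "TEb"] <- tom["TEb", "TEa"] <- 0.25
  tom["TEa", "TEc"] <- tom["TEc", "TEa"] <- 0.15
  tom["TEa", "TEd"] <- tom["TEd", "TEa"] <- 0.5
  tom["TEb", "TEc"] <- tom["TEc", "TEb"] <- 0.2  # exact boundary
  diag(tom) <- 1
  labels <- c(TEa = "blue", TEb = "blue", TEc = "blue", TEd = "brown")
  edges <- teTeEdges(tom, labels, threshold = 0.2)
  expect_equal(edges$from, c("TEa", "TEb"))
  expect_equal(edges$to, c("TEb", "TEc"))
  expect_equal(edges$weight, c(0.25, 0.2))  # 0.2 kept, 0.15 dropped
  # cross-module 0.5 dropped
  expect_false(any(edges$from == "TEd" | edges$to == "TEd"))
  # raising the threshold never adds an edge
  higher <- teTeEdges(tom, labels, threshold = 0.24)
  expect_true(all(paste(higher$from, higher$to) %in%
                    paste(edges$from, edges$to)))
  # grey never forms edges
  grey <- teTeEdges(tom, stats::setNames(rep("grey", 4), ids), 0.01)
  expect_equal(nrow(grey), 0L)
})

test_that("flagHubTEs follows the worked window-overlap arithmetic", {
  cs <- c(chr1 = 10e6)
  te <- GRanges("chr1", IRanges(100001, 100500))
  mcols(te)$te_id <- "TEx"
  # SNP 0-based 120400 -> window [100401, 140401]: overlaps the TE
  win1 <- extendGwasLoci("chr1", 120401L, cs)
  expect_true(flagHubTEs(te, win1)[["TEx"]])
  # SNP 0-based 140000 -> window [120001, 160001]: no overlap
  win2 <- extendGwasLoci("chr1", 140001L, cs)
  expect_false(flagHubTEs(te, win2)[["TEx"]])
  # no loci -> no hubs
  expect_false(any(flagHubTEs(te, GRanges())))
})

test_that("assembleHubNetwork applies the one-hop hub closure", {
  pairs <- data.frame(
    te_id = c("TEa", "TEb", "TEz"), gene_id = c("G1", "G2", "G3"),
    rho = c(0.9, -0.8, 0.7), p = 1e-6, p_adj = 1e-5,
    sign = c("positive", "negative", "positive"), stringsAsFactors = FALSE)
  edges <- data.frame(from = c("TEa", "TEb", "TEy"),
                      to = c("TEb", "TEc", "TEz"),
                      weight = c(0.4, 0.3, 0.5),
                      module = "blue", stringsAsFactors = FALSE)
  hubs <- c(TEa = TRUE, TEb = FALSE, TEc = FALSE, TEy = FALSE, TEz = FALSE)
  net <- assembleHubNetwork(pairs, edges, hubs)
  nodes <- as.data.frame(networkNodes(net))
  # only TE-TE edges with a hub endpoint survive: TEb-TEc and TEy-TEz
  # are dropped, so TEc, TEy, TEz (and TEz's pair) never enter
  expect_setequal(nodes$id[nodes$type == "TE"], c("TEa", "TEb"))
  expect_setequal(nodes$id[nodes$type == "gene"], c("G1", "G2"))
  expect_equal(nrow(networkTeEdges(net)), 1L)
  # TEb is one hop from hub TEa: its gene edge is retained
  expect_true("G2" %in% networkTeGeneEdges(net)$gene)
  # connectivity = degree: each TE touches the other TE plus its gene
  expect_equal(nodes$score[nodes$id == "TEb"], 2L)
  expect_equal(nodes$score[nodes$id == "TEa"], 2L)
  expect_true(nodes$hub[nodes$id == "TEa"])
  expect_output(show(net), "RegulatoryNetwork")

  # no hubs at all -> empty network
  none <- assembleHubNetwork(pairs, edges,
                             stats::setNames(rep(FALSE, 5), names(hubs)))
  expect_equal(nrow(networkNodes(none)), 0L)
})

test_that("planted hub TEs all enter the network; non-module TEs never do", {
  an <- defaultAnalysis()
  st <- an$study
  mc <- st$gwas[st$gwas$category == "Meat and Carcass", ]
  win <- extendGwasLoci(mc$chrom, mc$pos, st$chromSizes, 20000L)
  hubFlags <- flagHubTEs(st$tes[an$idx[an$selfIds]], win)
  edges <- teTeEdges(an$tom, moduleLabels(an$partition), 0.2)
  net <- assembleHubNetwork(an$pairs, edges, hubFlags)
  nodes <- as.data.frame(networkNodes(net))
  netTes <- nodes$id[nodes$type == "TE"]
  expect_true(all(st$truth$hubTEs %in% netTes))
  expect_true(all(st$truth$roles[netTes] == "module"))
})

test_that("networkGwasEnrichment is seeded and near 1 under uniform loci", {
  st <- defaultStudy()
  idx <- teIndex(st)
  set.seed(77)
  nLoci <- 100L
  cats <- unique(st$gwas$category)
  uniform <- do.call(rbind, lapply(cats, function(ct) {
    chrom <- sample(names(st$chromSizes), nLoci, replace = TRUE,
                    prob = st$chromSizes)
    data.frame(category = ct, chrom = chrom,
               pos = floor(runif(nLoci) * (st$chromSizes[chrom] - 1)) + 1L,
               stringsAsFactors = FALSE)
  }))
  tes <- st$tes[idx[names(st$truth$expressed)[st$truth$expressed]]]
  res <- networkGwasEnrichment(tes, uniform, st$chromSizes, nPerm = 300,
                               seed = 5)
  expect_setequal(names(res), cats)
  folds <- vapply(res, foldEnrichment, numeric(1))
  expect_true(all(folds > 0.8 & folds < 1.2))
  expect_true(all(vapply(res, function(r) r@pAdj, numeric(1)) >=
                    vapply(res, empiricalP, numeric(1))))
  res2 <- networkGwasEnrichment(tes, uniform, st$chromSizes, nPerm = 300,
                                seed = 5)
  expect_identical(vapply(res, foldEnrichment, numeric(1)),
                   vapply(res2, foldEnrichment, numeric(1)))
})
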