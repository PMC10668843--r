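test_that("readBed converts 0-based half-open to 1-based closed", {
  f <- withr::local_tempfile()
  writeLines(c("chr1\t100\t200", "chr1\t0\t50", "chr2\t5\t6"), f)
  gr <- readBed(f)
  expect_length(gr, 3L)
  expect_equal(as.character(seqnames(gr)), c("chr1", "chr1", "chr2"))
  expect_equal(start(gr), c(101L, 1L, 6L))
  expect_equal(end(gr), c(200L, 50L, 6L))
  expect_equal(width(gr)[1], 100L)
})

test_that("readBed preserves name/score/strand and file order", {
  f <- withr::local_tempfile()
  writeLines(c("# comment", "track name=x",
               "chr1\t10\t20\tA\t5\t+",
               "chr1\t0\t5\tB\t1\t-",
               "chr2\t7\t9\tC\t0\t."), f)
  gr <- readBed(f)
  expect_equal(mcols(gr)$name, c("A", "B", "C"))
  expect_equal(mcols(gr)$score, c(5, 1, 0))
  expect_equal(as.character(strand(gr)), c("+", "-", "*"))
})

test_that("readBed rejects malformed lines with line numbers", {
  f <- withr::local_tempfile()
  writeLines(c("chr1\t10\t20", "chr1\t100\t100"), f)
  expect_error(readBed(f), "line 2.*start < end")
  writeLines(c("chr1\tten\t20"), f)
  expect_error(readBed(f), "line 1.*non-integer")
  writeLines(c("chr1\t10"), f)
  expect_error(readBed(f), "line 1.*3 tab-separated")
  writeLines(c("chr1\t10\t20\tA\t0\tx"), f)
  expect_error(readBed(f), "strand")
})

test_that("BED round-trip reproduces coordinates exactly", {
  set.seed(42)
  s <- sort(sample.int(1e6, 50))
  gr <- GRanges("chr3", IRanges(s, s + sample.int(5000, 50)),
                strand = sample(c("+", "-", "*"), 50, TRUE))
  mcols(gr)$name <- sprintf("iv%02d", 1:50)
  mcols(gr)$score <- round(runif(50), 3)
  f <- withr::local_tempfile()
  writeBed(gr, f)
  back <- readBed(f)
  expect_equal(start(back), start(gr))
  expect_equal(end(back), end(gr))
  expect_equal(as.character(strand(back)), as.character(strand(gr)))
  expect_equal(mcols(back)$name, mcols(gr)$name)
  # write again: byte-identical
  f2 <- withr::local_tempfile()
  writeBed(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("readGtfGenes derives the TSS from strand and keeps exons", {
  f <- withr::local_tempfile()
  writeLines(c(
    'chr1\tsim\tgene\t101\t200\t.\t+\t.\tgene_id "GA";',
    'chr1\tsim\texon\t101\t130\t.\t+\t.\tgene_id "GA";',
    'chr1\tsim\texon\t160\t200\t.\t+\t.\tgene_id "GA";',
    'chr1\tsim\tgene\t501\t900\t.\t-\t.\tgene_id "GB";',
    'chr1\tsim\texon\t501\t600\t.\t-\t.\tgene_id "GB";',
    'chr1\tsim\tCDS\t101\t130\t.\t+\t.\tgene_id "GA";',
    'chr1\tsim\ttranscript\t101\t200\t.\t+\t.\tgene_id "GA";'
  ), f)
  g <- readGtfGenes(f)
  expect_length(g, 2L)
  expect_equal(mcols(g)$gene_id, c("GA", "GB"))
  # + strand: tss = start (GTF 1-based verbatim); - strand: tss = end
  expect_equal(mcols(g)$tss, c(101L, 900L))
  expect_equal(start(g), c(101L, 501L))
  expect_equal(lengths(mcols(g)$exons), c(GA = 2L, GB = 1L))
})

test_that("readGtfGenes rejects missing gene_id and unknown strand", {
  f <- withr::local_tempfile()
  writeLines('chr1\tsim\tgene\t101\t200\t.\t.\t.\tgene_id "GA";', f)
  expect_error(readGtfGenes(f), "strand")
  writeLines("chr1\tsim\tgene\t101\t200\t.\t+\t.\tfoo \"x\";", f)
  expect_error(readGtfGenes(f), "gene_id")
})

test_that("readRepeatMaskerOut maps classes and drops non-TE repeats", {
  f <- withr::local_tempfile()
  hdr <- c("   SW  perc perc perc  query      position in query",
           "score  div. del. ins.  sequence    begin     end",
           "")
  rows <- c(
    "  463 1.3 0.6 1.7 chr1 101 200 (0) + L1MA4 LINE/L1 1 100 (0) 1",
    "  463 1.3 0.6 1.7 chr1 301 400 (0) C MIR SINE/MIR 1 100 (0) 2",
    "  463 1.3 0.6 1.7 chr1 501 600 (0) + (TA)n Simple_repeat 1 100 (0) 3",
    "  463 1.3 0.6 1.7 chr1 701 800 (0) + weird Unknown 1 100 (0) 4",
    "  463 1.3 0.6 1.7 chr2 101 150 (0) + ltr7 LTR/ERVK 1 50 (0) 5"
  )
  writeLines(c(hdr, rows), f)
  te <- readRepeatMaskerOut(f)
  expect_length(te, 4L)  # Simple_repeat dropped
  expect_equal(mcols(te)$te_class, c("LINE", "SINE", "Other", "LTR"))
  expect_equal(start(te)[1], 101L)  # 1-based verbatim
  expect_equal(end(te)[1], 200L)
  expect_equal(as.character(strand(te))[2], "-")  # C means complement
  expect_false(anyDuplicated(mcols(te)$te_id) > 0)
})

test_that("readRepeatMaskerOut reports truncated rows by line number", {
  f <- withr::local_tempfile()
  writeLines(c("h1", "h2", "",
               "  463 1.3 0.6 1.7 chr1 101 200 (0) + L1 LINE/L1 1 100 (0) 1",
               "  463 1.3 0.6"), f)
  expect_error(readRepeatMaskerOut(f), "line 5.*truncated")
})

test_that("chrom sizes round-trip and validate", {
  f <- withr::local_tempfile()
  writeChromSizes(c(chr1 = 1000L, chr2 = 2000L), f)
  expect_equal(readChromSizes(f), c(chr1 = 1000L, chr2 = 2000L))
  writeLines("chr1\t-5", f)
  expect_error(readChromSizes(f), "positive")
})

test_that("expression matrices round-trip with stage metadata", {
  se <- smallSet(rexp(81 * 3), nFeatures = 3)
  f <- withr::local_tempfile()
  writeExpressionMatrix(se, f)
  back <- readExpressionMatrix(f, "FPKM")
  expect_s4_class(back, "StageExpressionSet")
  expect_equal(exprUnit(back), "FPKM")
  expect_equal(sampleStages(back), sampleStages(se))
  expect_equal(sampleReplicates(back), sampleReplicates(se))
  expect_equal(assay(back), assay(se), tolerance = 1e-12)
})

test_that("methylation tracks convert 0-based positions and validate", {
  f <- withr::local_tempfile()
  writeLines(c("chrom\tpos\tmeth\ttotal", "chr1\t99\t3\t10", "chr1\t200\t0\t1"),
             f)
  tr <- readMethylation(f)
  expect_equal(start(tr), c(100L, 201L))  # 0-based file -> 1-based GRanges
  expect_equal(mcols(tr)$meth, c(3, 0))
  f2 <- withr::local_tempfile()
  writeMethylation(tr, f2)
  expect_equal(readLines(f2)[-1], c("chr1\t99\t3\t10", "chr1\t200\t0\t1"))
  writeLines(c("chrom\tpos\tmeth\ttotal", "chr1\t99\t5\t4"), f)
  expect_error(readMethylation(f), "methylated <= total")
  writeLines(c("chrom\tpos\tmeth\ttotal", "chr1\t99\t0\t0"), f)
  expect_error(readMethylation(f), "total >= 1")
})

test_that("GWAS tables round-trip", {
  g <- data.frame(category = c("Health", "Meat and Carcass"),
                  chrom = c("chr1", "chr2"), pos = c(100L, 2000L),
                  stringsAsFactors = FALSE)
  f <- withr::local_tempfile()
  writeGwasTable(g, f)
  expect_equal(readGwasTable(f), g)
})

test_that("readGmt parses terms and rejects duplicates", {
  f <- withr::local_tempfile()
  writeLines(c("T1\tdesc\tG1\tG2", "T2\tdesc\tG3"), f)
  sets <- readGmt(f)
  expect_equal(sets, list(T1 = c("G1", "G2"), T2 = "G3"))
  writeLines(c("T1\tdesc\tG1", "T1\tdesc\tG2"), f)
  expect_error(readGmt(f), "duplicate")
  writeLines("T1\tdesc", f)
  expect_error(readGmt(f), ">= 1 gene")
})

test_that("writeEdgeList is deterministic and handles empty networks", {
  empty <- assembleHubNetwork(
    data.frame(te_id = character(), gene_id = character(), rho = numeric(),
               p = numeric(), p_adj = numeric(), sign = character()),
    data.frame(from = character(), to = character(), weight = numeric(),
               module = character()),
    c(TE1 = FALSE))
  f <- withr::local_tempfile()
  writeEdgeList(empty, f)
  expect_equal(readLines(f), "source\ttarget\tedge_type\tweight")

  pairs <- data.frame(te_id = "TEb", gene_id = "G1", rho = -0.9,
                      p = 1e-5, p_adj = 1e-4, sign = "negative",
                      stringsAsFactors = FALSE)
  edges <- data.frame(from = "TEa", to = "TEb", weight = 0.25,
                      module = "blue", stringsAsFactors = FALSE)
  net <- assembleHubNetwork(pairs, edges, c(TEa = TRUE, TEb = FALSE))
  writeEdgeList(net, f)
  lines <- readLines(f)
  expect_equal(lines[2], "TEa\tTEb\tTE-TE\t0.25")
  expect_equal(lines[3], "TEb\tG1\tTE-gene\t-0.9")
  f2 <- withr::local_tempfile()
  writeEdgeList(net, f2)
  expect_identical(readLines(f2), lines)
})
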