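# Brute-force TOM evaluation straight from the formula, used as an
# independent oracle.
tomBruteForce <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { out[i, j] <- 1; next }
    s <- 0
    for (u in seq_len(n)) s <- s + a[i, u] * a[u, j]
    out[i, j] <- (s + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  out
}

randomAdjacency <- function(n, seed) {
  set.seed(seed)
  a <- matrix(runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 0
  a
}

test_that("adjacencyMatrix at beta 1 equals |cor| with zero diagonal", {
  set.seed(5)
  x <- matrix(rnorm(10 * 30), 10, 30)
  a <- adjacencyMatrix(x, 1)
  ref <- abs(cor(t(x)))
  diag(ref) <- 0
  expect_equal(a, ref, tolerance = 1e-12)
  expect_true(isSymmetric(a))
})

test_that("pickSoftThreshold has decreasing mean connectivity in beta", {
  set.seed(6)
  x <- matrix(rnorm(30 * 20), 30, 20,
              dimnames = list(paste0("f", 1:30), NULL))
  sft <- pickSoftThreshold(x, powers = c(1, 2, 4, 6, 10))
  expect_true(all(diff(sft$table$meanK) < 0))
  # chosen beta obeys the smallest-reaching rule when the target is met
  if (sft$reachedTarget) {
    hit <- sft$table$power[sft$table$r2 >= 0.9]
    expect_equal(sft$beta, hit[1])
  }
  # constant rows are dropped with a warning
  x2 <- rbind(x, fconst = rep(2, 20))
  expect_warning(pickSoftThreshold(x2, powers = 1:3), "constant")
  expect_error(pickSoftThreshold(x[, 1:2, drop = FALSE], powers = 1),
               ">= 3 samples")
})

test_that("pickSoftThreshold falls back to the sample-size default", {
  an <- defaultAnalysis()
  expect_false(an$sft$reachedTarget)
  expect_equal(an$sft$beta, 6L)  # unsigned default for >= 40 samples
})

test_that("tomSimilarity matches hand-computed and degenerate cases", {
  # no edges: off-diagonal 0, diagonal 1
  z <- matrix(0, 4, 4)
  tz <- tomSimilarity(z)
  expect_equal(diag(tz), rep(1, 4))
  expect_equal(tz[upper.tri(tz)], rep(0, 6))

  # fully connected triangle with a = 1: TOM = (1+1)/(2+1-1) = 1
  f <- matrix(1, 3, 3); diag(f) <- 0
  expect_equal(tomSimilarity(f)[1, 2], 1)

  # validation
  bad <- matrix(runif(9), 3, 3)
  expect_error(tomSimilarity(bad), "symmetric")
  d <- matrix(0.5, 3, 3)
  expect_error(tomSimilarity(d), "diagonal")
  e <- matrix(2, 3, 3); e <- (e + t(e)) / 2; diag(e) <- 0
  expect_error(tomSimilarity(e), "\\[0, 1\\]")
})

test_that("tomSimilarity agrees with the brute-force oracle", {
  for (seed in c(1, 2, 3)) {
    a <- randomAdjacency(12, seed)
    expect_lt(max(abs(tomSimilarity(a) - tomBruteForce(a))), 1e-10)
  }
})

test_that("detectModules recovers two planted blocks and applies size rule", {
  set.seed(10)
  nS <- 60
  lat1 <- exp(-((1:nS) - 12)^2 / 18)
  lat2 <- exp(-((1:nS) - 48)^2 / 18)
  mk <- function(lat, n, nm) {
    m <- t(vapply(seq_len(n), function(i) {
      mu <- 3 * (1 + 4 * runif(1, 0.8, 1.2) * lat)
      mu * exp(rnorm(nS, 0, 0.25))
    }, numeric(nS)))
    rownames(m) <- paste0(nm, seq_len(n))
    m
  }
  noise <- matrix(rexp(80 * nS, 0.3), 80, nS,
                  dimnames = list(paste0("n", 1:80), NULL))
  expr <- rbind(mk(lat1, 40, "a"), mk(lat2, 40, "b"), noise)
  tom <- tomSimilarity(adjacencyMatrix(expr, 6))
  labels <- detectModules(1 - tom, minModuleSize = 30L)
  mods <- setdiff(unique(labels), "grey")
  expect_length(mods, 2L)
  # each planted block lands intact in its own module
  expect_equal(length(unique(labels[1:40])), 1L)
  expect_equal(length(unique(labels[41:80])), 1L)
  expect_false(labels[1] == labels[41])
  expect_true(all(labels[1:80] != "grey"))
  # noise features are predominantly unassigned
  expect_gt(mean(labels[81:160] == "grey"), 0.5)

  # fewer features than the minimum size: all grey
  small <- detectModules((1 - tom)[1:20, 1:20], minModuleSize = 30L)
  expect_true(all(small == "grey"))

  # permutation invariance up to label names
  perm <- sample(nrow(expr))
  shuffled <- detectModules((1 - tom)[perm, perm], minModuleSize = 30L)
  expect_equal(adjustedRand(labels, shuffled[names(labels)]), 1)
})

test_that("moduleEigengene is the oriented unit first PC", {
  prof <- sin(seq(0, 3, length.out = 20))
  x <- rbind(a = 2 * prof + 5, b = 0.5 * prof + 1, c = 3 * prof)
  eg <- moduleEigengene(x)
  expect_equal(sum(eg$eigengene^2), 1, tolerance = 1e-12)
  expect_equal(eg$varianceExplained, 1, tolerance = 1e-12)
  # positively oriented with the mean standardised profile
  expect_gt(cor(eg$eigengene, prof), 0.999)
  expect_error(moduleEigengene(x[1, , drop = FALSE]), ">= 2 features")
  expect_error(moduleEigengene(matrix(1, 3, 5)), "all-constant")
})

test_that("mergeModules merges by eigengene dissimilarity below the cut", {
  set.seed(12)
  prof1 <- sin(seq(0, 3, length.out = 30))
  prof2 <- prof1 + rnorm(30, 0, 0.25)      # high eigengene correlation
  prof3 <- cos(seq(0, 9, length.out = 30)) # unrelated
  mk <- function(p, n, nm) {
    m <- t(vapply(seq_len(n), function(i) p * runif(1, 0.5, 2) +
                    rnorm(30, 0, 0.05), numeric(30)))
    rownames(m) <- paste0(nm, seq_len(n))
    m
  }
  expr <- rbind(mk(prof1, 5, "a"), mk(prof2, 5, "b"), mk(prof3, 5, "c"))
  labels <- stats::setNames(rep(c("blue", "brown", "turquoise"), each = 5),
                            rownames(expr))
  p1 <- mergeModules(expr, labels, cut = 0.25)
  lab1 <- moduleLabels(p1)
  expect_equal(length(setdiff(unique(lab1), "grey")), 2L)
  expect_equal(length(unique(lab1[1:10])), 1L)   # a+b merged
  expect_false(lab1[1] == lab1[11])              # c kept apart

  # tight cut: nothing merges
  p2 <- mergeModules(expr, labels, cut = 1e-6)
  expect_equal(length(setdiff(unique(moduleLabels(p2)), "grey")), 3L)

  # monotonicity: raising the cut never increases the module count
  cuts <- c(0.05, 0.25, 0.6, 0.9)
  counts <- vapply(cuts, function(ct)
    length(setdiff(unique(moduleLabels(mergeModules(expr, labels, ct))),
                   "grey")), integer(1))
  expect_true(all(diff(counts) <= 0))

  # single module unchanged
  single <- stats::setNames(rep("blue", 5), rownames(expr)[1:5])
  p3 <- mergeModules(expr[1:5, ], single, cut = 0.25)
  expect_equal(unname(moduleLabels(p3)), rep("blue", 5))
})

test_that("moduleStateCorrelation correlates eigengenes with state indicators", {
  reg <- stageRegistry()
  sampleStage <- rep(reg$stage, each = 3)
  ind <- as.numeric(reg$state[match(sampleStage, reg$stage)] ==
                      "fiber_type_transition")
  eg <- matrix(ind / sqrt(sum(ind^2)), ncol = 1,
               dimnames = list(NULL, "blue"))
  part <- TEAtlas:::ModulePartition(
    stats::setNames(rep("blue", 2), c("t1", "t2")), eg,
    c(blue = 1))
  part <- moduleStateCorrelation(part, sampleStage)
  sc <- stateCorrelation(part)
  expect_equal(sc["blue", "fiber_type_transition"], 1, tolerance = 1e-12)
  expect_true(all(sc["blue", colnames(sc) != "fiber_type_transition"] < 0))
  expect_lt(statePValues(part)["blue", "fiber_type_transition"], 1e-10)
  # indicator bookkeeping: stages in state x 3 replicates
  expect_equal(sum(ind), sum(reg$state == "fiber_type_transition") * 3)
})

test_that("a planted module peaking in LD0-LD60 maps to fiber_type_transition", {
  an <- defaultAnalysis()
  st <- an$study
  part <- moduleStateCorrelation(an$partition, sampleStages(st$teExpr))
  # find the recovered module carrying planted module M4 (latent centred
  # around stage 19 = LD30)
  m4 <- names(st$truth$moduleAssignment)[
    !is.na(st$truth$moduleAssignment) & st$truth$moduleAssignment == "M4"]
  lab <- moduleLabels(part)
  recovered <- names(which.max(table(lab[intersect(m4, names(lab))])))
  sc <- stateCorrelation(part)
  expect_equal(colnames(sc)[which.max(sc[recovered, ])],
               "fiber_type_transition")
})
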