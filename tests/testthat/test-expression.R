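test_that("cpm follows its definition and is scale invariant", {
  m <- matrix(c(100L, 999900L, 50L, 499950L), 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_equal(cpm(m)["g1", "s1"], 100)
  expect_equal(cpm(2L * m), cpm(m))
  m0 <- m; m0[, 2] <- 0L
  expect_error(cpm(m0), "library size")
})

test_that("single-sample logFC and logCPM follow their closed forms", {
  # tumor CPM 40, two normals with mean CPM 10, library size 1e6
  counts <- matrix(c(40L, 8L, 12L), 1, dimnames = list("gA", c("T1", "N1", "N2")))
  filler <- matrix(c(1e6L - 40L, 1e6L - 8L, 1e6L - 12L), 1,
                   dimnames = list("filler", NULL))
  m <- rbind(counts, filler)
  colnames(m) <- c("T1", "N1", "N2")
  se <- makeCountsSE(m, c(T1 = "TUMOR", N1 = "NORMAL", N2 = "NORMAL"))
  deg <- singleSampleDEG(se, "T1", phi = 0.1, prior = 0.5, tau = 1)
  gA <- deg[deg$gene == "gA", ]
  expect_equal(gA$logFC, log2(40.5 / 10.5), tolerance = 1e-12)
  expect_equal(gA$logCPM, log2(mean(c(40, 8, 12)) + 0.5), tolerance = 1e-12)
  expect_true(gA$isDEG)
  # a zero count with prior 0.5 gives logCPM = log2(0.5) = -1
  z <- rbind(m, gZ = c(0L, 0L, 0L))
  se2 <- makeCountsSE(z, c(T1 = "TUMOR", N1 = "NORMAL", N2 = "NORMAL"))
  deg2 <- singleSampleDEG(se2, "T1", phi = 0.1)
  expect_equal(deg2$logCPM[deg2$gene == "gZ"], -1, tolerance = 1e-6)
  expect_equal(deg2$logFC[deg2$gene == "gZ"], 0)
  expect_error(singleSampleDEG(se, "N1", phi = 0.1), "not a TUMOR")
})

test_that("logFC is antisymmetric under swapping tumor and normal", {
  set.seed(5)
  m <- matrix(rpois(40, 500), 20,
              dimnames = list(sprintf("g%02d", 1:20), c("X", "Y")))
  seA <- makeCountsSE(m, c(X = "TUMOR", Y = "NORMAL"))
  seB <- makeCountsSE(m, c(X = "NORMAL", Y = "TUMOR"))
  a <- singleSampleDEG(seA, "X", phi = 0.1)
  b <- singleSampleDEG(seB, "Y", phi = 0.1)
  expect_equal(a$logFC, -b$logFC, tolerance = 1e-12)
})

test_that("the common dispersion estimator hits the boundary without signal", {
  m <- matrix(50L, 1, 4, dimnames = list("gA", c("T1", "T2", "N1", "N2")))
  m <- rbind(m, filler = c(1000L, 1000L, 1000L, 1000L))
  se <- makeCountsSE(m, c(T1 = "TUMOR", T2 = "TUMOR",
                          N1 = "NORMAL", N2 = "NORMAL"))
  expect_warning(est <- estimateCommonBCV(se), "boundary")
  expect_true(est$atBoundary)
  expect_lt(est$phi, 2e-6)
  expect_error(estimateCommonBCV(
    makeCountsSE(m[, 1:3], c(T1 = "TUMOR", T2 = "TUMOR", N1 = "NORMAL"))),
    "two samples per condition")
})

test_that("the dispersion estimate tracks edgeR's qCML estimate", {
  skip_if_not_installed("edgeR")
  se <- simulateNBCounts(600, 12, 12, bcv = 0.4, seed = 77)
  ours <- estimateCommonBCV(se)$bcv
  d <- edgeR::DGEList(counts = SummarizedExperiment::assay(se),
                      group = se$condition)
  d <- edgeR::estimateCommonDisp(d)
  expect_equal(ours, sqrt(d$common.dispersion), tolerance = 0.05)
})

test_that("the dispersion estimate is insensitive to library-size spread", {
  # same generative abundances and dispersion, very different library
  # sizes: the offsets absorb the depth differences
  seEven <- simulateNBCounts(500, 10, 10, bcv = 0.3,
                             libSizeRange = c(1e6, 1e6), seed = 303)
  seWild <- simulateNBCounts(500, 10, 10, bcv = 0.3,
                             libSizeRange = c(2e5, 5e6), seed = 303)
  a <- estimateCommonBCV(seEven)$bcv
  b <- estimateCommonBCV(seWild)$bcv
  expect_equal(a, b, tolerance = 0.05)
  expect_equal(a, 0.3, tolerance = 0.07)
})

test_that("neighborhood fold-change features follow their definitions", {
  logfc <- c(n1 = 2.5, n2 = -3.0, n3 = 0.5, far = 9)
  got <- neighFC(logfc, c("n1", "n2", "n3"), tau = 1)
  expect_equal(unname(got), c(-0.5, -0.25), tolerance = 1e-12)
  expect_equal(unname(neighFC(logfc, character(), tau = 1)), c(0, 0))
  expect_equal(unname(neighFC(logfc, "n3", tau = 1)), c(0, 0))

  cnvCol <- c(n1 = -2L, n2 = 0L, n3 = 1L)
  logfc2 <- c(n1 = 2.4, n2 = 3.0, n3 = 0.2)
  got2 <- neighCnvFC(logfc2, cnvCol, c("n1", "n2", "n3"), tau = 1)
  expect_equal(unname(got2), c(2.4, 2.4), tolerance = 1e-12)
  expect_equal(unname(neighCnvFC(logfc2, c(n1 = 0L, n2 = 0L, n3 = 0L),
                                 c("n1", "n2", "n3"), 1)), c(0, 0))
})

test_that("neighborhood features match brute-force oracles on random data", {
  set.seed(2211)
  for (rep in 1:10) {
    tg <- randomTestGraph(sample(5:12, 1), p = 0.3)
    logfc <- setNames(rnorm(length(tg$nodes), sd = 2), tg$nodes)
    cnvCol <- setNames(sample(-2:2, length(tg$nodes), replace = TRUE),
                       tg$nodes)
    nb <- neighborsWithinHops(tg$graph, 1)
    for (g in tg$nodes) {
      nbg <- if (g %in% names(nb)) nb[[g]] else character()
      expect_equal(unname(neighFC(logfc, nbg, 1)),
                   bruteNeighFC(logfc, nbg, 1), tolerance = 1e-9)
      expect_equal(unname(neighCnvFC(logfc, cnvCol, nbg, 1)),
                   bruteNeighCnvFC(logfc, cnvCol, nbg, 1), tolerance = 1e-9)
    }
  }
})

test_that("RNA feature rows honour the off-network convention", {
  co <- smallCohort()
  cfg <- smallConfig()
  ft <- suppressWarnings(featurizeCohort(co, cfg, "rna"))
  onNet <- igraph::V(cohortNetwork(co))$name
  expect_true(all(c("logFC", "logCPM", "degree", "closeness", "betweenness",
                    "logFC_x_degree", "logFC_x_closeness",
                    "logFC_x_betweenness", "neigh_FC", "neigh_normFC") %in%
                  colnames(ft)))
  expect_equal(ft$logFC_x_degree, ft$logFC * ft$degree, tolerance = 1e-12)
  expect_equal(ft$logFC_x_closeness, ft$logFC * ft$closeness,
               tolerance = 1e-12)
  off <- !ft$gene %in% onNet
  if (any(off)) {
    expect_true(all(ft$degree[off] == 0))
    expect_true(all(ft$neigh_FC[off] == 0))
  }
  # row universe: all altered pairs of samples with a DEG profile
  pairs <- alteredPairs(cohortMutations(co), cohortCNV(co))
  expect_equal(nrow(ft), nrow(pairs))
})

test_that("pairs of samples without a DEG profile are dropped loudly", {
  prof <- list(S1 = data.frame(gene = "G1", logFC = 2, logCPM = 5,
                               pValue = 0.1, isDEG = TRUE))
  pairs <- data.frame(sample = c("S1", "S9"), gene = "G1")
  g <- igraph::make_empty_graph(0, directed = FALSE)
  expect_warning(ft <- assembleRnaFeatures(prof, g, pairs, driverConfig()),
                 "S9")
  expect_equal(ft$sample, "S1")
})
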