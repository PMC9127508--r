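test_that("sample-level splitting is deterministic and well sized", {
  ids <- sprintf("P%02d", 1:10)
  sp <- splitSamples(ids, 0.7, seed = 3)
  expect_length(sp$train, 7L)
  expect_length(sp$test, 3L)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_identical(sp, splitSamples(ids, 0.7, seed = 3))
  expect_error(splitSamples("one", 0.7), "two samples")
})

test_that("balanced bootstraps equalize class counts exactly", {
  set.seed(21)
  y <- factor(rep(c("NEUTRAL", "TSG", "OG"), c(100, 10, 10)))
  for (i in 1:20) {
    idx <- balancedBootstrap(y)
    expect_equal(as.integer(table(y[idx])), rep(10L, 3))
  }
  # equal counts already: a plain per-class bootstrap of size m
  yEq <- factor(rep(c("A", "B"), each = 5))
  expect_equal(as.integer(table(yEq[balancedBootstrap(yEq)])), c(5L, 5L))
})

test_that("every bagging base estimator sees a balanced bootstrap", {
  ft <- smallFeatures()
  cfg <- smallConfig()
  cfg$grid <- data.frame(nEstimators = 25L, maxDepth = Inf, minBucket = 1L)
  model <- trainDriverModel(ft, cfg)
  labeled <- ft$label[ft$label != "UNLABELED"]
  y <- factor(labeled, levels = classLevels(model))
  indices <- model@fit$indices
  expect_length(indices, 25L)
  counts <- vapply(indices, function(idx) as.integer(table(y[idx])),
                   integer(nlevels(y)))
  expect_true(all(counts == counts[1, 1]))
})

test_that("training with a grid tunes by sample-level CV", {
  ft <- smallFeatures()
  cfg <- smallConfig()
  cfg$grid <- data.frame(nEstimators = c(10L, 20L),
                         maxDepth = c(3, Inf), minBucket = 1L)
  cfg$cvFolds <- 3L
  model <- trainDriverModel(ft, cfg)
  expect_s4_class(model, "DriverModel")
  expect_equal(nrow(cvResults(model)), 2L)
  expect_true(all(is.finite(cvResults(model)$meanMacroF1)))
  expect_true(model@best$nEstimators %in% c(10L, 20L))
})

test_that("refitting with the same seed reproduces predictions exactly", {
  ft <- smallFeatures()
  cfg <- smallConfig()
  m1 <- trainDriverModel(ft, cfg)
  m2 <- trainDriverModel(ft, cfg)
  expect_identical(predict(m1, ft), predict(m2, ft))
  p1 <- predictAndRank(m1, ft)
  p2 <- predictAndRank(m2, ft)
  expect_identical(p1, p2)
})

test_that("single-class training data are rejected", {
  ft <- smallFeatures()
  ft$label[ft$label != "UNLABELED"] <- "NEUTRAL"
  expect_error(trainDriverModel(ft, smallConfig()), "single class")
})

test_that("all three ensemble algorithms learn the planted signal", {
  ft <- smallFeatures()
  sp <- splitSamples(unique(ft$sample), 0.7, seed = 99)
  tr <- ft[ft$sample %in% sp$train, ]
  te <- ft[ft$sample %in% sp$test, ]
  for (alg in c("balanced_bagging", "balanced_random_forest",
                "easy_ensemble")) {
    cfg <- smallConfig(algorithm = alg)
    model <- suppressWarnings(trainDriverModel(tr, cfg))
    ev <- evaluateModel(model, te)
    expect_gt(ev$accuracy, 0.7, label = alg)
    expect_gt(ev$macroF1, 0.6, label = alg)
    probs <- predict(model, te)
    expect_equal(unname(rowSums(probs)), rep(1, nrow(probs)),
                 tolerance = 1e-9)
  }
})

test_that("evaluation metrics match an independent oracle", {
  ft <- smallFeatures()
  cfg <- smallConfig()
  model <- trainDriverModel(ft, cfg)
  ev <- evaluateModel(model, ft)
  probs <- predict(model, ft[ft$label != "UNLABELED", ])
  pred <- colnames(probs)[max.col(probs, ties.method = "first")]
  truth <- ft$label[ft$label != "UNLABELED"]
  want <- bruteMetrics(truth, pred, classLevels(model))
  expect_equal(ev$accuracy, want$accuracy, tolerance = 1e-9)
  expect_equal(ev$perClass$precision, unname(want$perClass[, "precision"]),
               tolerance = 1e-9)
  expect_equal(ev$perClass$recall, unname(want$perClass[, "recall"]),
               tolerance = 1e-9)
  expect_equal(ev$perClass$f1, unname(want$perClass[, "f1"]),
               tolerance = 1e-9)
  # F1 is the harmonic mean of the housed precision and recall
  pc <- ev$perClass
  ok <- !is.na(pc$f1) & (pc$precision + pc$recall) > 0
  expect_equal(pc$f1[ok],
               2 * pc$precision[ok] * pc$recall[ok] /
                 (pc$precision[ok] + pc$recall[ok]),
               tolerance = 1e-9)
  # confusion-matrix row sums equal class supports
  expect_equal(unname(rowSums(ev$confusion)), pc$support)
})

test_that("zero-support classes are undefined, not zero", {
  ft <- smallFeatures()
  cfg <- smallConfig()
  model <- trainDriverModel(ft, cfg)
  noTsg <- ft[ft$label %in% c("NEUTRAL", "OG"), ]
  ev <- evaluateModel(model, noTsg)
  expect_true(is.na(ev$perClass$f1[ev$perClass$class == "TSG"]))
  expect_true(is.na(ev$perClass$recall[ev$perClass$class == "TSG"]))
})

test_that("ROC and PR point sets are sane", {
  ft <- smallFeatures()
  model <- trainDriverModel(ft, smallConfig())
  ev <- evaluateModel(model, ft)
  for (cl in classLevels(model)) {
    roc <- ev$roc[[cl]]
    expect_true(all(diff(roc$fpr) >= 0))
    expect_true(all(diff(roc$tpr) >= 0))
    expect_equal(roc$tpr[nrow(roc)], 1)
    pr <- ev$pr[[cl]]
    expect_true(all(pr$precision >= 0 & pr$precision <= 1))
  }
})

test_that("prediction ranks by driver score with lexicographic ties", {
  ft <- smallFeatures()
  model <- trainDriverModel(ft, smallConfig())
  pr <- predictAndRank(model, ft)
  expect_equal(pr$driverScore, 1 - pr$prob_NEUTRAL, tolerance = 1e-12)
  one <- pr[pr$sample == pr$sample[1], ]
  one <- one[order(one$rank), ]
  expect_equal(one$rank, seq_len(nrow(one)))
  expect_true(all(diff(one$driverScore) <= 1e-12))
  ties <- split(one$gene, one$driverScore)
  for (tg in ties) expect_false(is.unsorted(tg))
  # argmax class
  pcol <- paste0("prob_", pr$predictedClass[1])
  expect_equal(pr[[pcol]][1], max(pr$prob_NEUTRAL[1], pr$prob_TSG[1],
                                  pr$prob_OG[1]))
})

test_that("precision at rank follows its definition", {
  rankings <- data.frame(
    sample = "S1", gene = c("A", "B", "C", "D", "E"),
    driverScore = c(0.9, 0.8, 0.7, 0.6, 0.5), rank = 1:5)
  got <- precisionAtRank(rankings, c("A", "C"), kMax = 3)
  expect_equal(got$precision, c(1, 1 / 2, 2 / 3))
  # empty reference: 0 everywhere
  expect_equal(precisionAtRank(rankings, character(), 3)$precision,
               rep(0, 3))
  # excluding a gene removes it from candidates and numerator:
  # ranking becomes B, C, D, E with reference hits at C only
  got2 <- precisionAtRank(rankings, c("A", "C"), kMax = 3, exclude = "A")
  expect_equal(got2$precision, c(0, 1 / 2, 1 / 3))
  # k beyond the list length: precision over the available genes
  got3 <- precisionAtRank(rankings, c("A", "C"), kMax = 8)
  expect_equal(got3$precision[8], 2 / 5)
  # mean over samples
  two <- rbind(rankings,
               data.frame(sample = "S2", gene = c("A", "Z"),
                          driverScore = c(0.9, 0.1), rank = 1:2))
  got4 <- precisionAtRank(two, c("A"), kMax = 1)
  expect_equal(got4$precision, 1)
})

test_that("feature importances are normalized and flag planted signal", {
  ft <- smallFeatures()
  model <- trainDriverModel(ft, smallConfig())
  imp <- importanceConsensus(model)
  expect_equal(sum(imp$consensus$contribution), 1, tolerance = 1e-9)
  expect_true(all(imp$consensus$contribution >= 0))
  expect_identical(imp$consensus, importanceConsensus(list(model))$consensus)
  expect_lte(nrow(imp$top), 20L)
  # a constant feature can contribute nothing
  ft0 <- ft
  ft0$dead_feature <- 0
  m0 <- trainDriverModel(ft0, smallConfig())
  i0 <- importanceConsensus(m0)$consensus
  expect_equal(i0$contribution[i0$feature == "dead_feature"], 0)
  # domain/miRNA sublists only ever contain positive contributions
  expect_true(all(imp$domains$contribution > 0))
  expect_true(all(startsWith(imp$domains$feature, "domain_")))
})

test_that("a feature manifest mismatch is fatal", {
  ft <- smallFeatures()
  model <- trainDriverModel(ft, smallConfig())
  broken <- ft[, -(which(colnames(ft) == "logFC"))]
  expect_error(predict(model, broken), "manifest")
})

test_that("label permutation collapses held-out driver F1", {
  ft <- smallFeatures()
  cfg <- smallConfig()
  sp <- splitSamples(unique(ft$sample), 0.7, seed = cfg$seed)
  tr <- ft[ft$sample %in% sp$train, ]
  te <- ft[ft$sample %in% sp$test, ]
  ctl <- suppressWarnings(permutedLabelControl(tr, te, cfg))
  f1 <- function(ev) mean(ev$perClass$f1[ev$perClass$class %in%
                                         c("TSG", "OG")], na.rm = TRUE)
  expect_gt(f1(ctl$original), f1(ctl$shuffled[[1]]))
  # a permutation preserves class counts and differs between seeds
  set.seed(1); permA <- sample(tr$label)
  set.seed(2); permB <- sample(tr$label)
  expect_equal(as.vector(table(permA)), as.vector(table(tr$label)))
  expect_false(identical(permA, permB))
})
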