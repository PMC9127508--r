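test_that("ordinal encoding maps the declared order and missingness", {
  expect_equal(ordinalEncode(c(NA, "N", "D"), c("N", "D")), c(0L, 1L, 2L))
  expect_error(ordinalEncode("X", c("N", "D")), "outside the declared")
  # 0 occurs exactly where the raw prediction is missing
  set.seed(1)
  v <- sample(c("B", "P", "D", NA), 50, replace = TRUE)
  enc <- ordinalEncode(v, c("B", "P", "D"))
  expect_identical(enc == 0L, is.na(v))
})

test_that("one-hot mutation types always sum to one", {
  m <- onehotMutationType(c("missense", "weird", "nonsense"))
  expect_equal(unname(rowSums(m)), c(1, 1, 1))
  expect_equal(unname(m[1, "type_missense"]), 1L)
  expect_equal(unname(m[2, "type_other"]), 1L)
})

test_that("pair aggregation keeps the most damaging evidence", {
  cfg <- toyConfig()
  mut <- readMutations(file.path(toyDir(), "mutations.tsv"), cfg)
  agg <- aggregateMutationPairs(mut, cfg)
  # single-mutation pair: identity aggregation with oriented SIFT score
  s1g1 <- agg[agg$sample == "S1" & agg$gene == "G1", ]
  expect_equal(s1g1$sift_score, 1 - 0.05)   # orientation flip
  expect_equal(s1g1$polyphen_score, 0.95)
  expect_equal(s1g1$sift_ordinal, 2L)       # "D" in (T, D)
  # two-mutation pair S3/G1: max oriented scores, ordinal max, union of
  # domains; the nonsense mutation has the higher mean oriented score
  s3g1 <- agg[agg$sample == "S3" & agg$gene == "G1", ]
  expect_equal(s3g1$sift_score, max(1 - 0.1, 1 - 0.02))
  expect_equal(s3g1$polyphen_score, 0.97)
  expect_equal(s3g1$type, "nonsense")
  expect_setequal(s3g1$domains[[1]], "PF00870")
  # all-missing tool stays missing, ordinal is 0
  s3g6 <- agg[agg$sample == "S3" & agg$gene == "G6", ]
  expect_true(is.na(s3g6$sift_score))
  expect_equal(s3g6$sift_ordinal, 0L)
})

test_that("tied mean scores break by the configured severity order", {
  cfg <- toyConfig()
  mut <- data.frame(
    sample = "S1", gene = "GX", chrom = "1", pos = c(10L, 20L),
    ref = "A", alt = "T", type = c("missense", "nonsense"),
    sift_score = c(0.2, 0.2), sift_pred = "D",
    polyphen_score = c(0.8, 0.8), polyphen_pred = "D",
    stringsAsFactors = FALSE)
  mut$domains <- list(character(), character())
  agg <- aggregateMutationPairs(mut, cfg)
  expect_equal(agg$type, "nonsense")   # nonsense outranks missense
})

test_that("domain bits are the union over a pair's mutations", {
  m <- domainFeatures(list(c("PF00870"), c("PF00870", "PF00028"),
                           c("PF99999"), character()),
                      c("PF00870", "PF00028"))
  expect_equal(unname(m[1, ]), c(1L, 0L))
  expect_equal(unname(m[2, ]), c(1L, 1L))
  expect_equal(unname(m[3, ]), c(0L, 0L))
  expect_equal(unname(m[4, ]), c(0L, 0L))
})

test_that("the small feature set keeps rows the all set must drop", {
  cfg <- toyConfig()
  mut <- readMutations(file.path(toyDir(), "mutations.tsv"), cfg)
  all <- assembleSnvFeatures(mut, cfg, "all")
  small <- assembleSnvFeatures(mut, cfg, "small")
  expect_equal(nrow(small), 9L)
  expect_equal(nrow(all), 7L)   # S2/G1 and S3/G6 have missing scores
  expect_gte(nrow(small), nrow(all))
  expect_false(any(grepl("_score$", colnames(small))))
  expect_true(all(c("sift_score", "polyphen_score") %in% colnames(all)))
  expect_false(any(is.na(as.matrix(all[, -(1:2)]))))
  # dropped pairs are exactly the ones with a missing score
  dropped <- setdiff(paste(small$sample, small$gene),
                     paste(all$sample, all$gene))
  expect_setequal(dropped, c("S2 G1", "S3 G6"))
  # onco-domain bit set for the P53-domain mutation
  expect_equal(small$domain_PF00870[small$sample == "S1" &
                                    small$gene == "G1"], 1L)
})

test_that("feature assembly is invariant to input row order", {
  cfg <- toyConfig()
  mut <- readMutations(file.path(toyDir(), "mutations.tsv"), cfg)
  set.seed(9)
  shuf <- mut[sample(nrow(mut)), ]
  norm <- function(df) {
    df <- df[order(df$sample, df$gene), ]
    rownames(df) <- NULL
    df
  }
  expect_identical(norm(assembleSnvFeatures(mut, cfg, "small")),
                   norm(assembleSnvFeatures(shuf, cfg, "small")))
  expect_identical(norm(assembleSnvFeatures(mut, cfg, "all")),
                   norm(assembleSnvFeatures(shuf, cfg, "all")))
})

test_that("no mutations give an empty feature table", {
  cfg <- toyConfig()
  mut <- readMutations(file.path(toyDir(), "mutations.tsv"), cfg)[0, ]
  ft <- assembleSnvFeatures(mut, cfg, "small")
  expect_equal(nrow(ft), 0L)
})
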