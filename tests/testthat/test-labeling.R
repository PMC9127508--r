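test_that("evidence filtering is strictly greater-than", {
  res <- list(mutationDrivers = data.frame(
    gene = c("A", "B", "C", "D"), pos = 1:4, ref = "A", alt = "T",
    label = "TSG", evidence_score = c(16, 15, 14.9, NA)))
  cfg <- driverConfig(evidenceThreshold = 15)
  kept <- filterMutationDrivers(res, cfg)
  expect_equal(kept$gene, "A")
  cfg2 <- driverConfig(evidenceThreshold = 15, keepMissingEvidence = TRUE)
  expect_setequal(filterMutationDrivers(res, cfg2)$gene, c("A", "D"))
  empty <- list(mutationDrivers = res$mutationDrivers[0, ])
  expect_equal(nrow(filterMutationDrivers(empty, cfg)), 0L)
})

test_that("all four strategies reproduce the hand-enumerated toy tables", {
  toy <- readToyInputs()
  cfg <- toyConfig()
  co <- methods::new("DriverCohort",
    mutations = toy$mutations,
    counts = makeCountsSE(matrix(1L, 1, 2, dimnames = list("G1", c("S1", "N1"))),
                          c(S1 = "TUMOR", N1 = "NORMAL")),
    cnv = toy$cnv, mirna = matrix(0, 0, 0), oncoMirnas = character(),
    network = toy$network, resources = toy$resources,
    groundTruth = NULL, cancerType = "TOY")
  for (strategy in c("mutation_exact_binary", "mutation_exact_tsg_og",
                     "gene_pan", "gene_cancer_specific")) {
    got <- suppressWarnings(suppressMessages(labelCohort(co, strategy, cfg)))
    full <- rbind(got$labels, got$unlabeled)
    full <- full[order(full$sample, full$gene), ]
    rownames(full) <- NULL
    expect_identical(full, expectedToyLabels(strategy), label = strategy)
  }
})

test_that("conflicting exact matches are left unlabeled with a warning", {
  toy <- readToyInputs()
  drv <- filterMutationDrivers(toy$resources, toyConfig())
  expect_warning(
    lab <- labelMutationExact(toy$mutations, drv,
                              toy$resources$neutralGenes, binary = FALSE),
    "G1@S3")
  expect_equal(lab$label[lab$sample == "S3" & lab$gene == "G1"], "UNLABELED")
  # the same pair is an unambiguous DRIVER in the binary problem
  lab2 <- labelMutationExact(toy$mutations, drv,
                             toy$resources$neutralGenes, binary = TRUE)
  expect_equal(lab2$label[lab2$sample == "S3" & lab2$gene == "G1"], "DRIVER")
})

test_that("mutation-exact strategies never label CNV-only pairs", {
  toy <- readToyInputs()
  drv <- filterMutationDrivers(toy$resources, toyConfig())
  lab <- suppressWarnings(labelMutationExact(
    toy$mutations, drv, toy$resources$neutralGenes, binary = TRUE))
  # (S1, G2) and (S3, G5) are CNV-only alterations in the toy cohort
  expect_false(any(lab$sample == "S1" & lab$gene == "G2"))
  expect_false(any(lab$sample == "S3" & lab$gene == "G5"))
  expect_true(all(lab$alteration_kind == "MUTATION"))
})

test_that("neutral labeling is identical across strategies", {
  neutralOf <- function(strategy) {
    df <- expectedToyLabels(strategy)
    df <- df[df$label == "NEUTRAL", c("sample", "gene")]
    rownames(df) <- NULL
    df
  }
  base <- neutralOf("gene_pan")
  for (s in c("mutation_exact_binary", "mutation_exact_tsg_og",
              "gene_cancer_specific")) {
    got <- neutralOf(s)
    # gene strategies add the CNV-only neutral pair; mutated neutral
    # pairs are labeled identically everywhere
    mutated <- got[got$sample != "S2" | got$gene != "G4", ]
    expect_true(all(paste(mutated$sample, mutated$gene) %in%
                    paste(base$sample, base$gene)))
  }
})

test_that("label tables merge duplicate keys and count classes", {
  pairs <- data.frame(
    sample = c("S1", "S1", "S1", "S2"),
    gene = c("GA", "GA", "GB", "GA"),
    alteration_kind = c("MUTATION", "CNV", "MUTATION", "CNV"),
    label = c("TSG", "TSG", "NEUTRAL", "UNLABELED"),
    strategy = "gene_pan", stringsAsFactors = FALSE)
  tab <- buildLabelTable(pairs)
  expect_equal(nrow(tab$labels), 2L)
  merged <- tab$labels[tab$labels$gene == "GA", ]
  expect_equal(merged$alteration_kind, "BOTH")
  expect_equal(unname(tab$counts[c("TSG", "NEUTRAL", "OG")]), c(1L, 1L, 0L))
  expect_equal(nrow(tab$unlabeled), 1L)

  conflict <- pairs
  conflict$label[2] <- "OG"
  expect_error(buildLabelTable(conflict), "conflicting")

  emptyTab <- buildLabelTable(pairs[0, ])
  expect_equal(nrow(emptyTab$labels), 0L)
  expect_equal(sum(emptyTab$counts), 0L)
})

test_that("gene-level labeling excludes dual-role genes and honours tags", {
  gd <- data.frame(gene = c("GA", "GB", "GB", "GC"),
                   tag = c("possible oncogene", "tsg", "oncogene", "junk"),
                   cancer_type = "PAN", stringsAsFactors = FALSE)
  mut <- data.frame(sample = "S1", gene = c("GA", "GB", "GC"),
                    stringsAsFactors = FALSE)
  expect_warning(expect_message(
    lab <- labelGeneLevel(mut, NULL, gd, character(), "PAN"), "GB"), "junk")
  expect_equal(lab$label[lab$gene == "GA"], "OG")
  expect_equal(lab$label[lab$gene == "GB"], "UNLABELED")
  expect_equal(lab$label[lab$gene == "GC"], "UNLABELED")
})
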