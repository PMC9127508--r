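# Shared fixtures.  The toy cohort files ship with the package; the
# reduced synthetic cohort keeps the model tests fast while exercising
# every pipeline stage.

toyDir <- function() {
  system.file("extdata", "toy", package = "perDriveR", mustWork = TRUE)
}

toyConfig <- function(...) {
  driverConfig(cancerDomains = c("PF00870", "PF00028"),
               cancerType = "TOY", ...)
}

readToyInputs <- function(config = toyConfig()) {
  d <- toyDir()
  list(
    mutations = readMutations(file.path(d, "mutations.tsv"), config),
    cnv = readCNV(file.path(d, "cnv.tsv")),
    network = readNetwork(file.path(d, "network.tsv"), config),
    resources = readDriverResources(file.path(d, "drivers_mutation.tsv"),
                                    file.path(d, "drivers_gene.tsv"),
                                    file.path(d, "neutral_genes.txt"))
  )
}

expectedToyLabels <- function(strategy) {
  readLabelTable(file.path(toyDir(),
                           paste0("expected_labels_", strategy, ".tsv")))
}

# small cohort for model-level unit tests (sizes documented in the
# methods vignette)
smallCohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulateCohort(synthConfig(
        nTumor = 30L, nNormal = 10L, nGenes = 120L,
        nTsg = 8L, nOg = 8L, nNeutral = 25L, seed = 515L))
    cache
  }
})

smallConfig <- function(...) {
  synthDriverConfig(
    grid = data.frame(nEstimators = 30L, maxDepth = Inf, minBucket = 1L),
    seed = 7L, ...)
}

# a labeled feature table from the small cohort, cached
smallFeatures <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- smallCohort()
      cfg <- smallConfig()
      lab <- suppressMessages(labelCohort(co, "gene_cancer_specific", cfg))
      ft <- suppressWarnings(featurizeCohort(co, cfg, "multiomic"))
      lt <- rbind(lab$labels, lab$unlabeled)
      m <- match(paste(ft$sample, ft$gene), paste(lt$sample, lt$gene))
      ft$label <- ifelse(is.na(m), "UNLABELED", lt$label[m])
      cache <<- ft
    }
    cache
  }
})
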