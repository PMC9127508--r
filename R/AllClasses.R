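#' @import methods
NULL

setOldClass("igraph")

#' Container for one multi-omic tumor cohort
#'
#' Bundles the six inputs of the pipeline: an annotated somatic mutation
#' table, a raw gene-level count matrix with tumor/normal conditions (as a
#' [SummarizedExperiment::SummarizedExperiment]), a GISTIC-style gene-level
#' copy-number score matrix, a miRNA expression matrix with its declared
#' oncogenic subset, a score-filtered protein-interaction network, and the
#' driver/neutral gene resources used for labeling.  Synthetic cohorts
#' additionally carry the planted ground truth.
#'
#' @slot mutations data.frame, one row per annotated somatic mutation
#'   (columns `sample`, `gene`, `chrom`, `pos`, `ref`, `alt`, `type`,
#'   per-tool `<tool>_score` / `<tool>_pred` columns and a `domains` column).
#' @slot counts SummarizedExperiment with assay `counts` and
#'   `colData()$condition` in `TUMOR`/`NORMAL`.
#' @slot cnv integer matrix, genes x tumor samples, GISTIC-style scores.
#' @slot mirna numeric matrix, miRNAs x samples.
#' @slot oncoMirnas character, subset of `rownames(mirna)` declared
#'   cancer-associated.
#' @slot network igraph, undirected, already filtered on interaction score.
#' @slot resources list with elements `mutationDrivers`, `geneDrivers`,
#'   `neutralGenes` (see [readDriverResources()]).
#' @slot groundTruth list or NULL; planted per-gene classes for synthetic
#'   cohorts.
#' @slot cancerType character scalar tag used by cancer-type-specific
#'   labeling.
#'
#' @seealso [simulateCohort()], [readCohort()]
#' @export
setClass("DriverCohort",
    representation(
        mutations = "data.frame",
        counts = "ANY",
        cnv = "matrix",
        mirna = "matrix",
        oncoMirnas = "character",
        network = "igraph",
        resources = "list",
        groundTruth = "ANY",
        cancerType = "character"
    )
)

setValidity("DriverCohort", function(object) {
    msg <- character()
    req <- c("sample", "gene", "chrom", "pos", "ref", "alt", "type")
    if (!all(req %in% colnames(object@mutations)))
        msg <- c(msg, paste0("mutations must contain columns: ",
                             paste(req, collapse = ", ")))
    if (!is(object@counts, "SummarizedExperiment"))
        msg <- c(msg, "counts must be a SummarizedExperiment")
    else if (!"condition" %in%
             colnames(SummarizedExperiment::colData(object@counts)))
        msg <- c(msg, "counts colData must contain 'condition'")
    if (length(object@oncoMirnas) &&
        !all(object@oncoMirnas %in% rownames(object@mirna)))
        msg <- c(msg, "oncoMirnas must be a subset of rownames(mirna)")
    if (!all(c("mutationDrivers", "geneDrivers", "neutralGenes") %in%
             names(object@resources)))
        msg <- c(msg, "resources must have mutationDrivers, geneDrivers, neutralGenes")
    if (length(msg)) msg else TRUE
})

#' Trained imbalance-aware ensemble classifier
#'
#' Holds the fitted ensemble together with its feature manifest, class
#' order, the selected hyper-parameters and the cross-validation trace, so
#' that predictions can verify they are applied to a compatible feature
#' table.
#'
#' @slot algorithm one of `"balanced_bagging"`, `"balanced_random_forest"`,
#'   `"easy_ensemble"`.
#' @slot fit fitted ensemble object (internal representation).
#' @slot featureNames character, ordered feature manifest used at fit time.
#' @slot classLevels character, class order of the probability columns.
#' @slot best list, hyper-parameters of the refit model.
#' @slot cvResults data.frame, one row per grid point with mean CV macro-F1.
#' @slot seed integer seed the model was trained under.
#'
#' @seealso [trainDriverModel()], [predictAndRank()]
#' @export
setClass("DriverModel",
    representation(
        algorithm = "character",
        fit = "ANY",
        featureNames = "character",
        classLevels = "character",
        best = "list",
        cvResults = "data.frame",
        seed = "integer"
    )
)

setValidity("DriverModel", function(object) {
    if (!object@algorithm %in% c("balanced_bagging", "balanced_random_forest",
                                 "easy_ensemble"))
        return("unknown algorithm")
    if (length(object@classLevels) < 2L)
        return("a trained model needs at least two classes")
    TRUE
})

#' @describeIn DriverCohort compact overview of the cohort contents
#' @param object a `DriverCohort`
#' @export
setMethod("show", "DriverCohort", function(object) {
    cond <- SummarizedExperiment::colData(object@counts)$condition
    cat("DriverCohort (", object@cancerType, ")\n", sep = "")
    cat("  mutations : ", nrow(object@mutations), " calls in ",
        length(unique(object@mutations$gene)), " genes / ",
        length(unique(object@mutations$sample)), " samples\n", sep = "")
    cat("  counts    : ", nrow(object@counts), " genes x ",
        ncol(object@counts), " samples (",
        sum(cond == "TUMOR"), " tumor, ", sum(cond == "NORMAL"),
        " normal)\n", sep = "")
    cat("  cnv       : ", nrow(object@cnv), " genes x ", ncol(object@cnv),
        " samples\n", sep = "")
    cat("  mirna     : ", nrow(object@mirna), " miRNAs (",
        length(object@oncoMirnas), " oncogenic)\n", sep = "")
    cat("  network   : ", igraph::vcount(object@network), " genes, ",
        igraph::ecount(object@network), " edges\n", sep = "")
    cat("  resources : ", nrow(object@resources$mutationDrivers),
        " driver mutations, ", nrow(object@resources$geneDrivers),
        " driver-gene rows, ", length(object@resources$neutralGenes),
        " neutral genes\n", sep = "")
    if (!is.null(object@groundTruth))
        cat("  groundTruth: planted classes available\n")
    invisible(NULL)
})

#' @describeIn DriverModel print algorithm, classes and tuning summary
#' @param object a `DriverModel`
#' @export
setMethod("show", "DriverModel", function(object) {
    cat("DriverModel <", object@algorithm, ">\n", sep = "")
    cat("  classes :", paste(object@classLevels, collapse = ", "), "\n")
    cat("  features:", length(object@featureNames), "\n")
    bp <- vapply(object@best, function(x) format(x), character(1))
    cat("  selected:", paste(names(bp), bp, sep = "=", collapse = ", "), "\n")
    if (nrow(object@cvResults) > 1L)
        cat("  CV grid :", nrow(object@cvResults), "points, best macro-F1 =",
            sprintf("%.3f", max(object@cvResults$meanMacroF1)), "\n")
    invisible(NULL)
})

#' Accessors for DriverCohort slots
#'
#' Plain accessor functions for the pieces of a [DriverCohort-class]
#' object; user code should use these rather than `@` slot access.
#'
#' @param x a `DriverCohort`
#' @return the corresponding component.
#' @name cohort-accessors
NULL

#' @rdname cohort-accessors
#' @export
cohortMutations <- function(x) x@mutations

#' @rdname cohort-accessors
#' @export
cohortCounts <- function(x) x@counts

#' @rdname cohort-accessors
#' @export
cohortCNV <- function(x) x@cnv

#' @rdname cohort-accessors
#' @export
cohortMirna <- function(x) x@mirna

#' @rdname cohort-accessors
#' @export
oncoMirnas <- function(x) x@oncoMirnas

#' @rdname cohort-accessors
#' @export
cohortNetwork <- function(x) x@network

#' @rdname cohort-accessors
#' @export
driverResources <- function(x) x@resources

#' @rdname cohort-accessors
#' @export
groundTruth <- function(x) x@groundTruth

#' @rdname cohort-accessors
#' @export
cancerType <- function(x) x@cancerType

#' Accessors for DriverModel slots
#'
#' @param x a `DriverModel`
#' @return the corresponding component.
#' @name model-accessors
NULL

#' @rdname model-accessors
#' @export
modelAlgorithm <- function(x) x@algorithm

#' @rdname model-accessors
#' @export
modelFeatures <- function(x) x@featureNames

#' @rdname model-accessors
#' @export
classLevels <- function(x) x@classLevels

#' @rdname model-accessors
#' @export
cvResults <- function(x) x@cvResults
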