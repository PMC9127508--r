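#' Default per-tool configuration for mutation impact scores
#'
#' Each annotation tool contributes a numeric score column
#' (`<tool>_score`) and a categorical prediction column (`<tool>_pred`).
#' The configuration declares, per tool, the ordered category list
#' (benign first, most damaging last) used for ordinal encoding, and the
#' orientation of the numeric score: `+1` when larger means more damaging,
#' `-1` when smaller means more damaging (the score is flipped to
#' `1 - s` before per-pair aggregation so that all tools share a common
#' "larger = more damaging" direction).
#'
#' The default declares the two tools emitted by the synthetic cohort
#' generator: a SIFT-like tool (low score damaging, categories
#' tolerated/damaging) and a PolyPhen-like tool (high score damaging,
#' categories benign/possibly/probably damaging).
#'
#' @return named list; one element per tool with fields `orientation`
#'   and `categories`.
#' @export
defaultToolConfig <- function() {
    list(
        sift = list(orientation = -1, categories = c("T", "D")),
        polyphen = list(orientation = 1, categories = c("B", "P", "D"))
    )
}

#' Mutation type vocabulary
#'
#' Fixed vocabulary of mutation types used for one-hot encoding.  Types
#' outside the vocabulary are mapped to `"other"` at read time.
#'
#' @return character vector of the nine recognised types.
#' @export
mutationTypeVocabulary <- function() {
    c("missense", "nonsense", "frameshift_ins", "frameshift_del",
      "inframe_ins", "inframe_del", "splice", "silent", "other")
}

#' Run configuration for the driver classification pipeline
#'
#' Collects the thresholds and options that the pipeline stages consume.
#' Field semantics (defaults in parentheses):
#'
#' * `stringScoreCutoff` (700): interaction edges are retained iff the
#'   maximum of the experimental and database channel scores is strictly
#'   above this value.
#' * `evidenceThreshold` (15): driver mutations are retained iff their
#'   evidence score is strictly above this value;
#'   `keepMissingEvidence` keeps rows with missing evidence (for
#'   pre-curated resources).
#' * `hops` (1): neighborhood radius for network features.
#' * `tau` (1.0): differential-expression threshold on |logFC| in log2
#'   units (fold change 2).
#' * `prior` (0.5): prior count on the CPM scale stabilising logFC and
#'   logCPM.
#' * `splitRatio` (0.70): fraction of samples assigned to training.
#' * `cvFolds` (5): folds of the sample-level grid-search CV.
#' * `algorithm`, `grid`: ensemble algorithm and hyper-parameter grid
#'   (columns `nEstimators`, `maxDepth`, `minBucket`).
#' * `featureSet`: `"all"` keeps numeric score features and drops pairs
#'   with missing scores; `"small"` drops score features and keeps all
#'   pairs (ordinals encode missing as 0).
#' * `tools`, `mutationTypes`, `severityOrder`, `domainDelim`,
#'   `cancerDomains`, `cancerType`: mutation encoding options.
#' * `phiOverride`: reuse a stored cohort dispersion instead of
#'   re-estimating (e.g. when featurizing new samples).
#' * `seed`: seed for every stochastic step downstream.
#'
#' @param ... named fields overriding the defaults listed above.
#' @return list of class `driverConfig`.
#' @examples
#' cfg <- driverConfig(tau = 1, cancerType = "SYNTH")
#' cfg$stringScoreCutoff
#' @export
driverConfig <- function(...) {
    cfg <- list(
        stringScoreCutoff = 700L,
        evidenceThreshold = 15,
        keepMissingEvidence = FALSE,
        hops = 1L,
        tau = 1.0,
        prior = 0.5,
        splitRatio = 0.70,
        cvFolds = 5L,
        seed = 1L,
        featureSet = "small",
        algorithm = "balanced_bagging",
        grid = expand.grid(
            nEstimators = c(50L, 100L, 200L),
            maxDepth = c(Inf, 10, 20),
            minBucket = 1L
        ),
        tools = defaultToolConfig(),
        mutationTypes = mutationTypeVocabulary(),
        severityOrder = c("nonsense", "frameshift_del", "frameshift_ins",
                          "splice", "inframe_del", "inframe_ins",
                          "missense", "silent", "other"),
        domainDelim = ";",
        cancerDomains = character(),
        cancerType = "PAN",
        phiOverride = NULL
    )
    override <- list(...)
    unknown <- setdiff(names(override), names(cfg))
    if (length(unknown))
        stop("unknown driverConfig field(s): ", paste(unknown, collapse = ", "))
    cfg[names(override)] <- override
    .validateConfig(cfg)
    class(cfg) <- "driverConfig"
    cfg
}

.validateConfig <- function(cfg) {
    stopifnot(
        cfg$splitRatio > 0, cfg$splitRatio < 1,
        cfg$hops >= 1L,
        cfg$tau > 0,
        cfg$prior > 0,
        cfg$cvFolds >= 2L,
        cfg$featureSet %in% c("all", "small"),
        cfg$algorithm %in% c("balanced_bagging", "balanced_random_forest",
                             "easy_ensemble"),
        nrow(cfg$grid) >= 1L,
        all(c("nEstimators", "maxDepth", "minBucket") %in% colnames(cfg$grid))
    )
    for (tl in cfg$tools)
        stopifnot(tl$orientation %in% c(-1, 1), length(tl$categories) >= 1L)
    invisible(TRUE)
}

#' @export
print.driverConfig <- function(x, ...) {
    cat("driverConfig:\n")
    cat("  cutoffs : string >", x$stringScoreCutoff,
        "| evidence >", x$evidenceThreshold,
        "| tau =", x$tau, "| hops =", x$hops, "\n")
    cat("  model   :", x$algorithm, "| grid", nrow(x$grid),
        "| folds", x$cvFolds, "| split", x$splitRatio,
        "| seed", x$seed, "\n")
    cat("  features:", x$featureSet, "| tools:",
        paste(names(x$tools), collapse = ", "), "| domains:",
        length(x$cancerDomains), "\n")
    invisible(x)
}
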