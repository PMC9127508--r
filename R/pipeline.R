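## End-to-end orchestration: label -> featurize -> split -> train ->
## evaluate -> predict/rank.

#' Run the full classification pipeline on a cohort
#'
#' Labels the cohort's altered (sample, gene) pairs under one strategy,
#' assembles the requested feature block, splits the samples 70:30 (or
#' `config$splitRatio`), trains the configured ensemble on the labeled
#' training pairs, evaluates on both sides of the split, and ranks all
#' pairs (labeled and unlabeled) per sample by driver score.
#'
#' All randomness (split, resampling, tree fitting) is seeded from
#' `config$seed`; two runs with equal inputs and configuration produce
#' identical outputs.
#'
#' @param cohort a [DriverCohort-class].
#' @param config a [driverConfig()].
#' @param strategy labeling strategy (see [labelCohort()]).
#' @param block feature block (see [featurizeCohort()]).
#' @param network optional replacement network (randomization control).
#' @return list of class `driverPipeline` with elements `labelTable`,
#'   `features` (with `label` column), `split`, `model`, `evalTrain`,
#'   `evalTest`, `predictions`.
#' @export
runPipeline <- function(cohort, config = driverConfig(),
                        strategy = "gene_cancer_specific",
                        block = "multiomic", network = NULL) {
    labelTable <- labelCohort(cohort, strategy, config)
    features <- featurizeCohort(cohort, config, block, network = network)
    lt <- rbind(labelTable$labels, labelTable$unlabeled)
    m <- match(paste(features$sample, features$gene, sep = "\r"),
               paste(lt$sample, lt$gene, sep = "\r"))
    features$label <- ifelse(is.na(m), "UNLABELED", lt$label[m])
    split <- splitSamples(unique(features$sample), config$splitRatio,
                          seed = config$seed)
    isTrain <- features$sample %in% split$train
    labeled <- features$label != "UNLABELED"
    missingInTrain <- setdiff(unique(features$label[labeled]),
                              unique(features$label[labeled & isTrain]))
    if (length(missingInTrain))
        warning("class(es) absent from the training split: ",
                paste(missingInTrain, collapse = ", "))
    model <- trainDriverModel(features[isTrain, , drop = FALSE], config)
    structure(list(
        labelTable = labelTable,
        features = features,
        split = split,
        model = model,
        evalTrain = evaluateModel(model, features[isTrain, , drop = FALSE]),
        evalTest = evaluateModel(model, features[!isTrain, , drop = FALSE]),
        predictions = predictAndRank(model, features)
    ), class = "driverPipeline")
}

#' @export
print.driverPipeline <- function(x, ...) {
    cat("driverPipeline:", nrow(x$features), "pairs (",
        sum(x$features$label != "UNLABELED"), "labeled ),",
        length(x$split$train), "train /", length(x$split$test),
        "test samples\n")
    cat("held-out "); print(x$evalTest)
    invisible(x)
}
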