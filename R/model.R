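## Imbalance-aware ensemble classifiers, sample-level splitting and
## cross-validation, evaluation, randomization controls, ranking and
## feature-importance reports.
##
## All fitting routines consume the current RNG state; the public entry
## points seed it from the run configuration so that full pipeline runs
## are bit-reproducible.

.FEATURE_KEYS <- c("sample", "gene", "label")

.featureMatrix <- function(features) {
    cols <- setdiff(colnames(features), .FEATURE_KEYS)
    x <- features[, cols, drop = FALSE]
    bad <- vapply(x, function(v) any(is.na(v)), logical(1))
    if (any(bad))
        stop("feature column(s) with missing values (apply the feature-set ",
             "policy first): ", paste(cols[bad], collapse = ", "))
    x
}

#' Sample-level train/test split
#'
#' Splits *samples* (not pairs) so that all pairs of a sample fall on
#' the same side of the split.  `floor(ratio * n)` samples (at least 1,
#' at most n - 1) go to training.  Deterministic under `seed`.
#'
#' @param samples character vector of sample ids (duplicates allowed;
#'   the unique set is split).
#' @param ratio training fraction in (0, 1).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return list with `train` and `test` character vectors.
#' @export
splitSamples <- function(samples, ratio = 0.7, seed = NULL) {
    us <- unique(samples)
    if (length(us) < 2L) stop("need at least two samples to split")
    if (!is.null(seed)) set.seed(seed)
    nTrain <- min(length(us) - 1L, max(1L, floor(ratio * length(us))))
    shuffled <- sample(us)
    list(train = sort(shuffled[seq_len(nTrain)]),
         test = sort(shuffled[-seq_len(nTrain)]))
}

#' Class-balanced bootstrap indices
#'
#' Random under-sampling of the majority classes to the minority-class
#' count, drawing with replacement within each class; every base
#' estimator of a bagging ensemble receives an independent balanced
#' bootstrap.
#'
#' @param labels factor (or character) of class labels.
#' @return integer index multiset with exactly equal class counts.
#' @export
balancedBootstrap <- function(labels) {
    labels <- as.factor(labels)
    idxByClass <- split(seq_along(labels), droplevels(labels))
    m <- min(lengths(idxByClass))
    unlist(lapply(idxByClass, function(idx)
        idx[sample.int(length(idx), m, replace = TRUE)]), use.names = FALSE)
}

.balancedUndersample <- function(labels) {
    idxByClass <- split(seq_along(labels), droplevels(as.factor(labels)))
    m <- min(lengths(idxByClass))
    unlist(lapply(idxByClass, function(idx)
        if (length(idx) == m) idx else idx[sample.int(length(idx), m)]),
        use.names = FALSE)
}

.rpartControl <- function(maxDepth, minBucket) {
    rpart::rpart.control(
        maxdepth = if (is.finite(maxDepth)) min(maxDepth, 30) else 30,
        minbucket = minBucket, minsplit = max(2L, 2L * minBucket),
        cp = 0, xval = 0, maxsurrogate = 0, maxcompete = 0)
}

.alignProb <- function(p, levels) {
    out <- matrix(0, nrow(p), length(levels),
                  dimnames = list(NULL, levels))
    out[, colnames(p)] <- p
    out
}

## ---- balanced bagging -------------------------------------------------

.fitBalancedBagging <- function(x, y, nEstimators, maxDepth, minBucket) {
    ctrl <- .rpartControl(maxDepth, minBucket)
    data <- data.frame(.class = y, x, check.names = FALSE)
    fits <- vector("list", nEstimators)
    indices <- vector("list", nEstimators)
    for (t in seq_len(nEstimators)) {
        idx <- balancedBootstrap(y)
        fits[[t]] <- rpart::rpart(.class ~ ., data = data[idx, , drop = FALSE],
                                  method = "class", control = ctrl)
        indices[[t]] <- idx
    }
    structure(list(fits = fits, indices = indices, levels = levels(y)),
              class = "balancedBagging")
}

.predictProb <- function(fit, x, ...) UseMethod(".predictProb")

.predictProb.balancedBagging <- function(fit, x, ...) {
    newdata <- data.frame(x, check.names = FALSE)
    acc <- matrix(0, nrow(newdata), length(fit$levels),
                  dimnames = list(NULL, fit$levels))
    for (f in fit$fits)
        acc <- acc + .alignProb(stats::predict(f, newdata, type = "prob"),
                                fit$levels)
    acc / length(fit$fits)
}

## ---- balanced random forest ------------------------------------------

.fitBalancedRF <- function(x, y, nEstimators, maxDepth, minBucket) {
    y <- droplevels(y)
    m <- min(table(y))
    sampsize <- rep(m, nlevels(y))
    maxnodes <- if (is.finite(maxDepth))
        max(2L, min(2L^maxDepth, sum(sampsize))) else NULL
    fit <- randomForest::randomForest(
        x = x, y = y, ntree = nEstimators, replace = TRUE,
        strata = y, sampsize = sampsize, nodesize = minBucket,
        maxnodes = maxnodes)
    structure(list(rf = fit, levels = levels(y)), class = "balancedRF")
}

.predictProb.balancedRF <- function(fit, x, ...) {
    p <- stats::predict(fit$rf, x, type = "prob")
    .alignProb(p, fit$levels)
}

## ---- easy ensemble ----------------------------------------------------

## SAMME multi-class AdaBoost on one balanced under-sample; shallow
## trees are the conventional weak learner.
.fitSAMME <- function(data, nRounds, maxDepth, minBucket) {
    K <- nlevels(data$.class)
    n <- nrow(data)
    w <- rep(1 / n, n)
    ctrl <- .rpartControl(min(maxDepth, 4), minBucket)
    learners <- list()
    alphas <- numeric()
    for (r in seq_len(nRounds)) {
        fit <- rpart::rpart(.class ~ ., data = data, weights = w,
                            method = "class", control = ctrl)
        pred <- stats::predict(fit, data, type = "class")
        miss <- pred != data$.class
        err <- sum(w[miss]) / sum(w)
        if (err >= 1 - 1 / K) break    # weak learner no better than chance
        err <- max(err, 1e-8)
        alpha <- log((1 - err) / err) + log(K - 1)
        w <- w * exp(alpha * miss)
        w <- w / sum(w)
        learners[[length(learners) + 1L]] <- fit
        alphas <- c(alphas, alpha)
        if (err <= 1e-8) break
    }
    list(learners = learners, alphas = alphas)
}

.fitEasyEnsemble <- function(x, y, nEstimators, maxDepth, minBucket,
                             nRounds = 10L) {
    data <- data.frame(.class = y, x, check.names = FALSE)
    subsets <- vector("list", nEstimators)
    indices <- vector("list", nEstimators)
    for (t in seq_len(nEstimators)) {
        idx <- .balancedUndersample(y)
        subsets[[t]] <- .fitSAMME(data[idx, , drop = FALSE], nRounds,
                                  maxDepth, minBucket)
        indices[[t]] <- idx
    }
    structure(list(subsets = subsets, indices = indices,
                   levels = levels(y)), class = "easyEnsemble")
}

.predictProb.easyEnsemble <- function(fit, x, ...) {
    newdata <- data.frame(x, check.names = FALSE)
    votes <- matrix(0, nrow(newdata), length(fit$levels),
                    dimnames = list(NULL, fit$levels))
    for (sub in fit$subsets) {
        for (r in seq_along(sub$learners)) {
            cls <- as.character(stats::predict(sub$learners[[r]], newdata,
                                               type = "class"))
            votes[cbind(seq_len(nrow(newdata)), match(cls, fit$levels))] <-
                votes[cbind(seq_len(nrow(newdata)), match(cls, fit$levels))] +
                sub$alphas[r]
        }
    }
    rs <- rowSums(votes)
    rs[rs == 0] <- 1
    votes / rs
}

## ---- training with grid-search CV ------------------------------------

.fitEnsemble <- function(algorithm, x, y, params) {
    switch(algorithm,
        balanced_bagging = .fitBalancedBagging(
            x, y, params$nEstimators, params$maxDepth, params$minBucket),
        balanced_random_forest = .fitBalancedRF(
            x, y, params$nEstimators, params$maxDepth, params$minBucket),
        easy_ensemble = .fitEasyEnsemble(
            x, y, max(2L, round(params$nEstimators / 10)),
            params$maxDepth, params$minBucket))
}

.macroF1 <- function(truth, pred, classes = NULL) {
    if (is.null(classes)) classes <- unique(as.character(truth))
    f1 <- vapply(classes, function(cl) {
        tp <- sum(truth == cl & pred == cl)
        fp <- sum(truth != cl & pred == cl)
        fn <- sum(truth == cl & pred != cl)
        if (tp + fn == 0) return(NA_real_)    # class absent: undefined
        prec <- if (tp + fp > 0) tp / (tp + fp) else 0
        rec <- tp / (tp + fn)
        if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    }, numeric(1))
    mean(f1, na.rm = TRUE)
}

#' Train an imbalance-aware ensemble classifier
#'
#' Grid search over `config$grid` with `config$cvFolds`-fold
#' cross-validation on the training pairs, selecting the point with the
#' best mean macro-F1, then refit on the full training data.  Folds are
#' assigned at the *sample* level, matching the sample-level outer
#' split, so pairs of one sample never straddle a fold boundary.  A
#' grid with a single row skips the search and fits directly.  Training
#' data with a single class is a fatal error; a class present in the
#' cohort but absent from training proceeds with a warning.
#'
#' The RNG is seeded with `config$seed`, making refits reproducible.
#'
#' @param features labeled feature table (columns `sample`, `gene`,
#'   `label`, features); `UNLABELED` rows are ignored.
#' @param config a [driverConfig()] (`algorithm`, `grid`, `cvFolds`,
#'   `seed`).
#' @return a [DriverModel-class].
#' @export
trainDriverModel <- function(features, config = driverConfig()) {
    set.seed(config$seed)
    keep <- !is.na(features$label) & features$label != "UNLABELED"
    features <- features[keep, , drop = FALSE]
    classOrder <- intersect(c("NEUTRAL", "DRIVER", "TSG", "OG"),
                            unique(features$label))
    if (length(classOrder) < 2L)
        stop("training data contain a single class; cannot fit a classifier")
    y <- factor(features$label, levels = classOrder)
    x <- .featureMatrix(features)
    grid <- config$grid
    cvResults <- data.frame(grid, meanMacroF1 = NA_real_)
    bestIdx <- 1L
    if (nrow(grid) > 1L) {
        us <- unique(features$sample)
        foldOf <- stats::setNames(
            sample(rep(seq_len(config$cvFolds), length.out = length(us))), us)
        folds <- foldOf[features$sample]
        for (g in seq_len(nrow(grid))) {
            scores <- numeric(0)
            for (f in seq_len(config$cvFolds)) {
                inFold <- folds == f
                if (!any(inFold) || length(unique(y[!inFold])) < 2L) next
                fit <- .fitEnsemble(config$algorithm,
                                    x[!inFold, , drop = FALSE],
                                    droplevels(y[!inFold]),
                                    as.list(grid[g, ]))
                p <- .predictProb(fit, x[inFold, , drop = FALSE])
                pred <- colnames(p)[max.col(p, ties.method = "first")]
                scores <- c(scores, .macroF1(y[inFold], pred))
            }
            cvResults$meanMacroF1[g] <- mean(scores)
        }
        bestIdx <- which.max(cvResults$meanMacroF1)
    }
    best <- as.list(grid[bestIdx, ])
    fit <- .fitEnsemble(config$algorithm, x, y, best)
    methods::new("DriverModel",
        algorithm = config$algorithm,
        fit = fit,
        featureNames = colnames(x),
        classLevels = classOrder,
        best = best,
        cvResults = cvResults,
        seed = as.integer(config$seed))
}

#' Class probabilities from a trained model
#'
#' @param object a [DriverModel-class].
#' @param newdata feature table with the same feature manifest the
#'   model was trained on (a mismatch is a fatal error).
#' @param ... unused.
#' @return numeric matrix of per-class probabilities, columns in
#'   `classLevels(object)` order.
#' @export
setMethod("predict", "DriverModel", function(object, newdata, ...) {
    x <- newdata[, setdiff(colnames(newdata), .FEATURE_KEYS), drop = FALSE]
    if (!identical(colnames(x), object@featureNames)) {
        if (setequal(colnames(x), object@featureNames)) {
            x <- x[, object@featureNames, drop = FALSE]
        } else {
            stop("feature manifest mismatch between model and data")
        }
    }
    p <- .predictProb(object@fit, x)
    .alignProb(p, object@classLevels)
})

## ---- evaluation -------------------------------------------------------

.curvePoints <- function(score, positive) {
    ord <- order(-score)
    lab <- positive[ord]
    tp <- cumsum(lab)
    fp <- cumsum(!lab)
    keep <- c(diff(score[ord]) != 0, TRUE)    # one point per threshold
    P <- sum(positive)
    N <- sum(!positive)
    roc <- data.frame(fpr = c(0, fp[keep] / max(N, 1)),
                      tpr = c(0, tp[keep] / max(P, 1)))
    pr <- data.frame(recall = tp[keep] / max(P, 1),
                     precision = tp[keep] / (tp[keep] + fp[keep]))
    list(roc = roc, pr = pr)
}

#' Evaluate a trained model on labeled pairs
#'
#' Predicts the held-out pairs and derives every metric from the
#' confusion matrix (rows = truth, columns = prediction): accuracy and
#' per-class precision, recall and F1 (the harmonic mean of the housed
#' precision and recall).  Classes with zero support are reported as
#' `NA` (undefined), not 0.  One-vs-rest ROC and PR point sets are
#' attached per class.
#'
#' @param model a [DriverModel-class].
#' @param features labeled feature table.
#' @return list of class `driverEvaluation`: `accuracy`, `perClass`
#'   data.frame, `confusion` table, `macroF1`, `roc`, `pr`.
#' @export
evaluateModel <- function(model, features) {
    keep <- !is.na(features$label) & features$label != "UNLABELED"
    features <- features[keep, , drop = FALSE]
    probs <- predict(model, features)
    pred <- colnames(probs)[max.col(probs, ties.method = "first")]
    lev <- model@classLevels
    truth <- factor(features$label, levels = lev)
    pred <- factor(pred, levels = lev)
    confusion <- table(truth = truth, prediction = pred)
    diagv <- diag(confusion)
    support <- rowSums(confusion)
    predicted <- colSums(confusion)
    precision <- ifelse(predicted > 0, diagv / predicted, NA_real_)
    recall <- ifelse(support > 0, diagv / support, NA_real_)
    f1 <- ifelse(!is.na(precision) & !is.na(recall) & (precision + recall) > 0,
                 2 * precision * recall / (precision + recall),
                 ifelse(support > 0, 0, NA_real_))
    precision[support == 0] <- NA_real_
    f1[support == 0] <- NA_real_
    perClass <- data.frame(class = lev, support = as.integer(support),
                           precision = as.numeric(precision),
                           recall = as.numeric(recall),
                           f1 = as.numeric(f1),
                           row.names = NULL)
    curves <- lapply(lev, function(cl)
        .curvePoints(probs[, cl], truth == cl))
    names(curves) <- lev
    structure(list(
        accuracy = sum(diagv) / sum(confusion),
        perClass = perClass,
        confusion = confusion,
        macroF1 = mean(perClass$f1[perClass$support > 0]),
        roc = lapply(curves, `[[`, "roc"),
        pr = lapply(curves, `[[`, "pr")
    ), class = "driverEvaluation")
}

#' @export
print.driverEvaluation <- function(x, ...) {
    cat("accuracy:", sprintf("%.4f", x$accuracy),
        " macro-F1:", sprintf("%.4f", x$macroF1), "\n")
    print(x$perClass, digits = 3)
    invisible(x)
}

## ---- controls ---------------------------------------------------------

#' Label-permutation overfitting control
#'
#' Permutes the training labels uniformly (class counts preserved, test
#' labels untouched), retrains under the same configuration, and
#' reports the held-out per-class metrics next to the unshuffled
#' model's.  A model that merely memorises spurious structure keeps its
#' score; a model exploiting real signal collapses.
#'
#' @param trainFeatures,testFeatures labeled feature tables.
#' @param config a [driverConfig()].
#' @param baseline optional pre-trained [DriverModel-class] on
#'   `trainFeatures` (retrained when omitted).
#' @param nShuffles number of independent permutations.
#' @return list with `original` evaluation and `shuffled`, a list of
#'   evaluations (one per permutation).
#' @export
permutedLabelControl <- function(trainFeatures, testFeatures,
                                 config = driverConfig(),
                                 baseline = NULL, nShuffles = 1L) {
    if (is.null(baseline))
        baseline <- trainDriverModel(trainFeatures, config)
    original <- evaluateModel(baseline, testFeatures)
    shuffled <- vector("list", nShuffles)
    for (i in seq_len(nShuffles)) {
        cfg <- config
        cfg$seed <- config$seed + i
        set.seed(cfg$seed)
        perm <- trainFeatures
        perm$label <- sample(perm$label)
        model <- trainDriverModel(perm, cfg)
        shuffled[[i]] <- evaluateModel(model, testFeatures)
    }
    list(original = original, shuffled = shuffled)
}

#' Network-randomization control
#'
#' Reruns the full pipeline with the interaction network replaced by a
#' node-label-permuted and by a degree-preserving-rewired copy, and
#' reports the held-out mean F1 over the driver classes (TSG/OG, or
#' DRIVER) for the true network and each randomization.  A network that
#' encodes real biology should beat both controls.  The RNA feature
#' block is the default: half its features derive from the network, so
#' the control isolates the network's contribution.
#'
#' @param cohort a [DriverCohort-class].
#' @param config a [driverConfig()]; `config$seed` (+1, +2) seeds the
#'   two randomizations.
#' @param strategy labeling strategy.
#' @param block feature block.
#' @return list with `f1` (named vector: `true`, `node_label`,
#'   `degree_preserving`) and the three pipeline results.
#' @export
networkRandomizationControl <- function(cohort, config = driverConfig(),
                                        strategy = "gene_cancer_specific",
                                        block = "rna") {
    driverF1 <- function(ev) {
        cls <- intersect(c("TSG", "OG", "DRIVER"), ev$perClass$class)
        mean(ev$perClass$f1[ev$perClass$class %in% cls])
    }
    base <- runPipeline(cohort, config, strategy, block)
    set.seed(config$seed + 1L)
    gNode <- randomizeNetwork(cohortNetwork(cohort), "node_label")
    node <- runPipeline(cohort, config, strategy, block, network = gNode)
    set.seed(config$seed + 2L)
    gDeg <- randomizeNetwork(cohortNetwork(cohort), "degree_preserving")
    degp <- runPipeline(cohort, config, strategy, block, network = gDeg)
    list(f1 = c(true = driverF1(base$evalTest),
                node_label = driverF1(node$evalTest),
                degree_preserving = driverF1(degp$evalTest)),
         true = base, node_label = node, degree_preserving = degp)
}

## ---- prediction and ranking ------------------------------------------

#' Predict classes and rank genes within each sample
#'
#' Predicted class is the probability argmax; the driver score is
#' `1 - P(NEUTRAL)` (TSG and OG treated symmetrically as "driver").
#' Within each sample, genes are ranked by descending driver score,
#' ties broken lexicographically by gene symbol.  The same gene may
#' receive different classes in different samples; no cross-sample
#' constraint is applied.
#'
#' @param model a [DriverModel-class].
#' @param features feature table (labeled or unlabeled pairs).
#' @return data.frame `sample`, `gene`, `predictedClass`,
#'   `prob_<class>` columns, `driverScore`, `rank`.
#' @export
predictAndRank <- function(model, features) {
    probs <- predict(model, features)
    pred <- colnames(probs)[max.col(probs, ties.method = "first")]
    driverScore <- if ("NEUTRAL" %in% colnames(probs))
        1 - probs[, "NEUTRAL"] else rowSums(probs)
    out <- data.frame(sample = features$sample, gene = features$gene,
                      predictedClass = pred, stringsAsFactors = FALSE)
    for (cl in colnames(probs)) out[[paste0("prob_", cl)]] <- probs[, cl]
    out$driverScore <- driverScore
    out$rank <- NA_integer_
    for (s in unique(out$sample)) {
        rows <- which(out$sample == s)
        ord <- order(-out$driverScore[rows], out$gene[rows])
        out$rank[rows[ord]] <- seq_along(rows)
    }
    out
}

#' Mean precision at increasing ranks
#'
#' For each sample, `precision@k = |top-k genes in the reference| / k`
#' for `k = 1..kMax`, computed on the sample's ranking after removing
#' any excluded genes (e.g. genes the model was trained on, which are
#' removed from both the candidate list and the numerator).  Samples
#' with fewer than `k` genes contribute their precision over the
#' available genes.  The mean over samples is reported per `k`.
#'
#' @param rankings data.frame from [predictAndRank()].
#' @param referenceGenes character vector of reference driver genes.
#' @param kMax largest rank evaluated.
#' @param exclude optional character vector of genes to drop from the
#'   rankings before scoring.
#' @return data.frame `k`, `precision`.
#' @export
precisionAtRank <- function(rankings, referenceGenes, kMax = 20L,
                            exclude = NULL) {
    perSample <- lapply(split(rankings, rankings$sample), function(df) {
        df <- df[order(df$rank), , drop = FALSE]
        if (!is.null(exclude))
            df <- df[!df$gene %in% exclude, , drop = FALSE]
        if (!nrow(df)) return(rep(NA_real_, kMax))
        hits <- cumsum(df$gene %in% referenceGenes) / seq_len(nrow(df))
        hits[pmin(seq_len(kMax), nrow(df))]
    })
    prec <- rowMeans(do.call(cbind, perSample), na.rm = TRUE)
    data.frame(k = seq_len(kMax), precision = prec)
}

## ---- feature importance ----------------------------------------------

.ensembleImportance <- function(fit, featureNames) {
    imp <- stats::setNames(numeric(length(featureNames)), featureNames)
    addNorm <- function(v, weight = 1) {
        if (is.null(v) || !length(v) || sum(v) == 0) return(NULL)
        v <- v / sum(v)
        imp[names(v)] <<- imp[names(v)] + weight * v
    }
    if (inherits(fit, "balancedBagging")) {
        for (f in fit$fits) addNorm(f$variable.importance)
    } else if (inherits(fit, "balancedRF")) {
        gini <- randomForest::importance(fit$rf, type = 2)[, 1]
        addNorm(gini)
    } else if (inherits(fit, "easyEnsemble")) {
        for (sub in fit$subsets)
            for (r in seq_along(sub$learners))
                addNorm(sub$learners[[r]]$variable.importance,
                        weight = sub$alphas[r])
    } else stop("feature importance requires a tree-ensemble model")
    if (sum(imp) > 0) imp <- imp / sum(imp)
    imp
}

#' Consensus feature contribution across models
#'
#' Per model, impurity-based importances are averaged over the base
#' estimators and normalized to sum to 1; the consensus contribution of
#' a feature is the mean over all supplied models (which must share a
#' feature manifest).  Also reports the top-`k` features and the
#' domain- and miRNA-feature sublists with consensus contribution
#' strictly above 0.
#'
#' @param models list of [DriverModel-class] objects (or a single one).
#' @param topK size of the top listing.
#' @return list with `consensus` (data.frame `feature`,
#'   `contribution`, sorted), `perModel` matrix, `top`, `domains`,
#'   `mirnas`.
#' @export
importanceConsensus <- function(models, topK = 20L) {
    if (is(models, "DriverModel")) models <- list(models)
    manifest <- models[[1]]@featureNames
    for (m in models)
        if (!identical(m@featureNames, manifest))
            stop("models do not share a feature manifest")
    perModel <- vapply(models, function(m)
        .ensembleImportance(m@fit, manifest), numeric(length(manifest)))
    perModel <- matrix(perModel, nrow = length(manifest),
                       dimnames = list(manifest,
                                       vapply(models, modelAlgorithm,
                                              character(1))))
    consensus <- rowMeans(perModel)
    df <- data.frame(feature = manifest, contribution = unname(consensus),
                     stringsAsFactors = FALSE)
    df <- df[order(-df$contribution, df$feature), , drop = FALSE]
    rownames(df) <- NULL
    pick <- function(prefix)
        df[startsWith(df$feature, prefix) & df$contribution > 0, ,
           drop = FALSE]
    list(consensus = df,
         perModel = perModel,
         top = utils::head(df, topK),
         domains = pick("domain_"),
         mirnas = pick("mirna_"))
}
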