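## Mutation-evidence encodings.  The classification unit is the
## (sample, gene) pair; per-mutation annotations are aggregated to the
## pair by maximum severity.

#' Ordinal encoding of a categorical tool prediction
#'
#' Missing predictions map to 0; the k-th category of the declared
#' benign-to-damaging order maps to k (1-indexed).
#'
#' @param values character vector of predictions (NA = missing).
#' @param categories declared ordered category list for the tool.
#' @return integer vector; 0 exactly where the prediction is missing.
#' @export
ordinalEncode <- function(values, categories) {
    out <- match(values, categories)
    bad <- !is.na(values) & is.na(out)
    if (any(bad))
        stop("prediction value(s) outside the declared category order: ",
             paste(unique(values[bad]), collapse = ", "))
    out[is.na(values)] <- 0L
    as.integer(out)
}

#' One-hot encoding of mutation types
#'
#' @param types character vector of mutation types.
#' @param vocabulary type vocabulary (unknown types map to `"other"`).
#' @return 0/1 integer matrix, one column per vocabulary entry
#'   (`type_<t>`); each row sums to 1.
#' @export
onehotMutationType <- function(types, vocabulary = mutationTypeVocabulary()) {
    types[!types %in% vocabulary] <- "other"
    m <- outer(types, vocabulary, "==") * 1L
    colnames(m) <- paste0("type_", vocabulary)
    m
}

## Oriented score: flips tools whose raw scale has smaller = more
## damaging, so that aggregation by max always keeps the most damaging
## mutation.
.orientScore <- function(score, orientation) {
    if (orientation < 0) 1 - score else score
}

#' Aggregate per-mutation evidence to (sample, gene) pairs
#'
#' Collapses all mutations of a pair into one evidence summary:
#' per-tool score = maximum oriented score over the pair's mutations
#' (NA when every mutation is missing the tool); per-tool ordinal =
#' maximum; the one-hot mutation type is the type of the mutation with
#' the highest mean oriented score, ties broken by the configured
#' severity order; domains are the union over mutations.
#'
#' @param mutations mutation data.frame from [readMutations()].
#' @param config a [driverConfig()].
#' @return data.frame with one row per pair: `sample`, `gene`, `type`,
#'   `<tool>_score` (oriented), `<tool>_ordinal`, and a `domains`
#'   list-column.
#' @export
aggregateMutationPairs <- function(mutations, config = driverConfig()) {
    tools <- names(config$tools)
    if (!nrow(mutations)) {
        out <- data.frame(sample = character(), gene = character(),
                          type = character())
        for (tool in tools) {
            out[[paste0(tool, "_score")]] <- numeric()
            out[[paste0(tool, "_ordinal")]] <- integer()
        }
        out$domains <- list()
        return(out)
    }
    oriented <- sapply(tools, function(tool)
        .orientScore(mutations[[paste0(tool, "_score")]],
                     config$tools[[tool]]$orientation))
    oriented <- matrix(oriented, nrow = nrow(mutations),
                       dimnames = list(NULL, tools))
    ordinals <- sapply(tools, function(tool)
        ordinalEncode(mutations[[paste0(tool, "_pred")]],
                      config$tools[[tool]]$categories))
    ordinals <- matrix(ordinals, nrow = nrow(mutations),
                       dimnames = list(NULL, tools))
    meanScore <- rowMeans(oriented, na.rm = TRUE)
    meanScore[is.nan(meanScore)] <- -Inf     # all-missing mutations rank last
    sevRank <- match(mutations$type, config$severityOrder)
    sevRank[is.na(sevRank)] <- length(config$severityOrder) + 1L
    key <- paste(mutations$sample, mutations$gene, sep = "\r")
    idxByPair <- split(seq_len(nrow(mutations)), key)
    first <- !duplicated(key)
    out <- data.frame(sample = mutations$sample[first],
                      gene = mutations$gene[first],
                      type = NA_character_, stringsAsFactors = FALSE)
    scoreM <- matrix(NA_real_, nrow(out), length(tools),
                     dimnames = list(NULL, tools))
    ordM <- matrix(0L, nrow(out), length(tools),
                   dimnames = list(NULL, tools))
    domains <- vector("list", nrow(out))
    pairKeys <- key[first]
    for (i in seq_len(nrow(out))) {
        idx <- idxByPair[[pairKeys[i]]]
        for (j in seq_along(tools)) {
            sc <- oriented[idx, j]
            if (any(!is.na(sc))) scoreM[i, j] <- max(sc, na.rm = TRUE)
            ordM[i, j] <- max(ordinals[idx, j])
        }
        ms <- meanScore[idx]
        best <- idx[ms == max(ms)]
        if (length(best) > 1L) best <- best[which.min(sevRank[best])]
        out$type[i] <- mutations$type[best]
        domains[[i]] <- sort(unique(unlist(mutations$domains[idx])))
    }
    for (tool in tools) {
        out[[paste0(tool, "_score")]] <- scoreM[, tool]
        out[[paste0(tool, "_ordinal")]] <- ordM[, tool]
    }
    out$domains <- domains
    out
}

#' Onco-domain indicator features
#'
#' One 0/1 column per cancer-type Pfam domain; bit d is 1 iff any
#' mutation of the pair is annotated with domain d.
#'
#' @param domainSets list of character vectors (one per pair).
#' @param cancerDomains ordered Pfam list for the cancer type.
#' @return 0/1 integer matrix with columns `domain_<pfam>`.
#' @export
domainFeatures <- function(domainSets, cancerDomains) {
    m <- matrix(0L, length(domainSets), length(cancerDomains),
                dimnames = list(NULL, paste0("domain_", cancerDomains)))
    for (i in seq_along(domainSets))
        m[i, cancerDomains %in% domainSets[[i]]] <- 1L
    m
}

#' Assemble the SNV feature block
#'
#' Builds one feature row per mutated (sample, gene) pair: the one-hot
#' mutation-type block, the per-tool ordinal block, the per-tool
#' (oriented) score block under the `"all"` policy, and the onco-domain
#' indicator block.  Under `"all"`, pairs with any missing score are
#' dropped (the tools could not score them); under `"small"`, the score
#' block is omitted and no pair is dropped -- the ordinals carry
#' missingness as 0.  Hence `"small"` never has fewer rows than
#' `"all"`.
#'
#' @param mutations mutation data.frame.
#' @param config a [driverConfig()].
#' @param featureSet `"all"` or `"small"` (defaults to
#'   `config$featureSet`).
#' @return feature table data.frame (`sample`, `gene` + feature
#'   columns), with attribute `featureSet`.
#' @export
assembleSnvFeatures <- function(mutations, config = driverConfig(),
                                featureSet = config$featureSet) {
    featureSet <- match.arg(featureSet, c("all", "small"))
    agg <- aggregateMutationPairs(mutations, config)
    tools <- names(config$tools)
    scoreCols <- paste0(tools, "_score")
    ordCols <- paste0(tools, "_ordinal")
    onehot <- onehotMutationType(agg$type, config$mutationTypes)
    dom <- domainFeatures(agg$domains, config$cancerDomains)
    out <- cbind(agg[, c("sample", "gene"), drop = FALSE],
                 as.data.frame(onehot),
                 agg[, ordCols, drop = FALSE])
    if (featureSet == "all") {
        out <- cbind(out, agg[, scoreCols, drop = FALSE])
        if (length(dom)) out <- cbind(out, as.data.frame(dom))
        complete <- !apply(is.na(agg[, scoreCols, drop = FALSE]), 1, any)
        out <- out[complete, , drop = FALSE]
    } else if (length(dom)) {
        out <- cbind(out, as.data.frame(dom))
    }
    rownames(out) <- NULL
    attr(out, "featureSet") <- featureSet
    out
}
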