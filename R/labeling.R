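## Labeling strategies.  The classification unit is the (sample, gene)
## pair: a gene altered in one sample is labeled for that sample only.

.LABEL_STRATEGIES <- c("mutation_exact_binary", "mutation_exact_tsg_og",
                       "gene_pan", "gene_cancer_specific")

#' Filter the mutation-level driver list on evidence score
#'
#' Retains driver mutations whose evidence score is *strictly* greater
#' than `config$evidenceThreshold`.  Rows with missing evidence are
#' retained only when `config$keepMissingEvidence` is `TRUE` (for
#' resources declared pre-curated).
#'
#' @param resources list from [readDriverResources()].
#' @param config a [driverConfig()].
#' @return data.frame of retained driver mutations.
#' @export
filterMutationDrivers <- function(resources, config = driverConfig()) {
    md <- resources$mutationDrivers
    keep <- !is.na(md$evidence_score) &
        md$evidence_score > config$evidenceThreshold
    if (config$keepMissingEvidence) keep <- keep | is.na(md$evidence_score)
    md[keep, , drop = FALSE]
}

#' Label mutated pairs by exact driver-mutation match
#'
#' A (sample, gene) pair is labeled by searching each of its mutations
#' in the driver set keyed on (gene, pos, ref, alt).  Any mutation of a
#' neutral-list gene makes the pair `NEUTRAL` regardless of position.
#' Otherwise one or more exact matches yield `DRIVER` (when
#' `binary = TRUE`) or the matched row's `TSG`/`OG` label; a pair
#' matching both a TSG- and an OG-labeled driver mutation is set
#' `UNLABELED` with a warning; pairs with no match stay `UNLABELED`.
#' A pair with one matching and one non-matching mutation is labeled
#' driver: the gene, not the mutation, is the classification unit.
#'
#' @param mutations mutation data.frame from [readMutations()].
#' @param driverSet filtered mutation driver data.frame
#'   (see [filterMutationDrivers()]).
#' @param neutralGenes character vector of neutral gene symbols.
#' @param binary logical; collapse TSG/OG to a single `DRIVER` class.
#' @return data.frame with columns `sample`, `gene`, `alteration_kind`
#'   (always `MUTATION`), `label`, `strategy`.
#' @export
labelMutationExact <- function(mutations, driverSet, neutralGenes,
                               binary = FALSE) {
    strategy <- if (binary) "mutation_exact_binary" else "mutation_exact_tsg_og"
    dkey <- paste(driverSet$gene, driverSet$pos,
                  toupper(driverSet$ref), toupper(driverSet$alt))
    dlab <- driverSet$label
    if (binary) dlab <- rep("DRIVER", length(dlab))
    mkey <- paste(mutations$gene, mutations$pos,
                  toupper(mutations$ref), toupper(mutations$alt))
    hit <- dlab[match(mkey, dkey)]
    pairKey <- paste(mutations$sample, mutations$gene, sep = "\r")
    pairs <- !duplicated(pairKey)
    out <- data.frame(sample = mutations$sample[pairs],
                      gene = mutations$gene[pairs],
                      alteration_kind = "MUTATION",
                      label = "UNLABELED",
                      strategy = strategy,
                      stringsAsFactors = FALSE)
    hitByPair <- split(hit, pairKey)
    conflicts <- character()
    for (i in seq_len(nrow(out))) {
        if (out$gene[i] %in% neutralGenes) {
            out$label[i] <- "NEUTRAL"
            next
        }
        h <- unique(stats::na.omit(
            hitByPair[[paste(out$sample[i], out$gene[i], sep = "\r")]]))
        if (length(h) == 1L) {
            out$label[i] <- h
        } else if (length(h) > 1L) {
            conflicts <- c(conflicts, paste0(out$gene[i], "@", out$sample[i]))
        }
    }
    if (length(conflicts))
        warning("pair(s) matching both TSG- and OG-labeled driver ",
                "mutations left UNLABELED: ",
                paste(conflicts, collapse = ", "))
    out
}

.geneRoleMap <- function(geneDrivers) {
    tag <- tolower(trimws(geneDrivers$tag))
    role <- rep(NA_character_, length(tag))
    role[tag %in% c("tsg", "possible tsg")] <- "TSG"
    role[tag %in% c("oncogene", "possible oncogene")] <- "OG"
    unknown <- is.na(role)
    if (any(unknown))
        warning("ignoring driver-gene row(s) with unknown tag: ",
                paste(unique(geneDrivers$tag[unknown]), collapse = ", "))
    df <- data.frame(gene = geneDrivers$gene[!unknown],
                     role = role[!unknown], stringsAsFactors = FALSE)
    roles <- split(df$role, df$gene)
    dual <- names(roles)[vapply(roles, function(r)
        all(c("TSG", "OG") %in% r), logical(1))]
    if (length(dual))
        message("excluding gene(s) with both TSG and OG roles: ",
                paste(dual, collapse = ", "))
    df <- df[!df$gene %in% dual, , drop = FALSE]
    df <- df[!duplicated(df$gene), , drop = FALSE]
    stats::setNames(df$role, df$gene)
}

#' Collect altered (sample, gene) pairs from mutations and CNV
#'
#' The alteration universe is the union of mutated pairs and pairs with
#' a nonzero copy-number score; pairs present in both carry kind `BOTH`.
#'
#' @param mutations mutation data.frame (may be NULL).
#' @param cnv integer matrix genes x samples (may be NULL).
#' @return data.frame `sample`, `gene`, `alteration_kind`.
#' @export
alteredPairs <- function(mutations = NULL, cnv = NULL) {
    mut <- if (!is.null(mutations) && nrow(mutations)) {
        unique(mutations[, c("sample", "gene")])
    } else data.frame(sample = character(), gene = character())
    cp <- if (!is.null(cnv) && length(cnv)) {
        idx <- which(cnv != 0L, arr.ind = TRUE)
        data.frame(sample = colnames(cnv)[idx[, 2]],
                   gene = rownames(cnv)[idx[, 1]],
                   stringsAsFactors = FALSE)
    } else data.frame(sample = character(), gene = character())
    mutKey <- paste(mut$sample, mut$gene, sep = "\r")
    cnvKey <- paste(cp$sample, cp$gene, sep = "\r")
    all <- rbind(mut, cp[!cnvKey %in% mutKey, , drop = FALSE])
    allKey <- paste(all$sample, all$gene, sep = "\r")
    kind <- ifelse(allKey %in% mutKey & allKey %in% cnvKey, "BOTH",
                   ifelse(allKey %in% mutKey, "MUTATION", "CNV"))
    data.frame(sample = all$sample, gene = all$gene,
               alteration_kind = kind, stringsAsFactors = FALSE)
}

#' Label altered pairs from a gene-level driver list
#'
#' Every altered pair (mutation or nonzero CNV) of a gene tagged
#' `"tsg"`/`"possible tsg"` is labeled `TSG`, of a gene tagged
#' `"oncogene"`/`"possible oncogene"` is labeled `OG`.  Genes appearing
#' with both role families are excluded from the driver set before
#' labeling.  Neutral-list genes are `NEUTRAL`; everything else is
#' `UNLABELED`.  With `cancerType = "PAN"` only the pan-cancer rows of
#' the driver list are used; otherwise only rows whose `cancer_type`
#' matches.
#'
#' @param mutations mutation data.frame (tumor samples).
#' @param cnv integer CNV matrix genes x samples.
#' @param geneDrivers gene-level driver data.frame
#'   (`gene`, `tag`, `cancer_type`).
#' @param neutralGenes character vector.
#' @param cancerType `"PAN"` or a cancer-type code.
#' @return data.frame `sample`, `gene`, `alteration_kind`, `label`,
#'   `strategy`.
#' @export
labelGeneLevel <- function(mutations, cnv, geneDrivers, neutralGenes,
                           cancerType = "PAN") {
    strategy <- if (identical(cancerType, "PAN")) "gene_pan"
                else "gene_cancer_specific"
    gd <- geneDrivers[geneDrivers$cancer_type == cancerType, , drop = FALSE]
    roles <- .geneRoleMap(gd)
    out <- alteredPairs(mutations, cnv)
    out$label <- "UNLABELED"
    out$label[out$gene %in% names(roles)] <-
        roles[out$gene[out$gene %in% names(roles)]]
    out$label[out$gene %in% neutralGenes] <- "NEUTRAL"
    out$strategy <- strategy
    out
}

#' Deduplicate a label table and count classes
#'
#' Collapses duplicate (sample, gene) keys (identical labels merge,
#' `MUTATION` + `CNV` kinds merge to `BOTH`; conflicting labels are a
#' fatal error), splits off the `UNLABELED` rows reserved for
#' prediction, and reports per-class counts.
#'
#' @param pairs label data.frame from one strategy.
#' @return list with `labels` (labeled rows), `unlabeled`, and `counts`
#'   (named integer vector over NEUTRAL/DRIVER/TSG/OG).
#' @export
buildLabelTable <- function(pairs) {
    classes <- c("NEUTRAL", "DRIVER", "TSG", "OG")
    if (!nrow(pairs)) {
        empty <- pairs
        return(list(labels = empty, unlabeled = empty,
                    counts = stats::setNames(integer(4), classes)))
    }
    key <- paste(pairs$sample, pairs$gene, sep = "\r")
    if (anyDuplicated(key)) {
        lab <- split(pairs$label, key)
        bad <- names(lab)[vapply(lab, function(x)
            length(unique(x)) > 1L, logical(1))]
        if (length(bad))
            stop("conflicting labels for duplicated pair(s): ",
                 paste(gsub("\r", "@", bad), collapse = ", "))
        kinds <- split(pairs$alteration_kind, key)
        first <- !duplicated(key)
        merged <- pairs[first, , drop = FALSE]
        mkey <- key[first]
        multi <- vapply(kinds[mkey], function(k)
            if (length(unique(k)) > 1L) "BOTH" else unique(k), character(1))
        merged$alteration_kind <- unname(multi)
        pairs <- merged
    }
    pairs <- pairs[order(pairs$sample, pairs$gene), , drop = FALSE]
    rownames(pairs) <- NULL
    labeled <- pairs[pairs$label != "UNLABELED", , drop = FALSE]
    counts <- stats::setNames(integer(length(classes)), classes)
    tab <- table(labeled$label)
    counts[names(tab)] <- as.integer(tab)
    list(labels = labeled,
         unlabeled = pairs[pairs$label == "UNLABELED", , drop = FALSE],
         counts = counts)
}

#' Label a cohort under one strategy
#'
#' Dispatcher applying one of the four labeling strategies to a cohort:
#' `"mutation_exact_binary"` and `"mutation_exact_tsg_og"` match
#' individual mutations against the evidence-filtered driver-mutation
#' list (CNV-only pairs are never labeled by these strategies);
#' `"gene_pan"` and `"gene_cancer_specific"` label every altered pair
#' from the gene-level driver list.  Neutral labeling is identical
#' across strategies.
#'
#' @param cohort a [DriverCohort-class].
#' @param strategy one of the four strategy names.
#' @param config a [driverConfig()].
#' @return list as returned by [buildLabelTable()].
#' @export
labelCohort <- function(cohort, strategy = "gene_cancer_specific",
                        config = driverConfig()) {
    strategy <- match.arg(strategy, .LABEL_STRATEGIES)
    res <- driverResources(cohort)
    pairs <- switch(strategy,
        mutation_exact_binary = labelMutationExact(
            cohortMutations(cohort), filterMutationDrivers(res, config),
            res$neutralGenes, binary = TRUE),
        mutation_exact_tsg_og = labelMutationExact(
            cohortMutations(cohort), filterMutationDrivers(res, config),
            res$neutralGenes, binary = FALSE),
        gene_pan = labelGeneLevel(
            cohortMutations(cohort), cohortCNV(cohort), res$geneDrivers,
            res$neutralGenes, cancerType = "PAN"),
        gene_cancer_specific = labelGeneLevel(
            cohortMutations(cohort), cohortCNV(cohort), res$geneDrivers,
            res$neutralGenes, cancerType = cancerType(cohort))
    )
    buildLabelTable(pairs)
}
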