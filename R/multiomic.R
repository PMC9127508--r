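## The multi-omic feature block: SNV + RNA + CNV + CNV-conditioned
## neighborhood + onco-miRNA expression, joined on (sample, gene).

#' Onco-miRNA expression block for one sample
#'
#' Sample-level expression of the declared oncogenic miRNAs, in a fixed
#' (sorted) manifest order; the block is identical for every gene of a
#' sample.  Missing miRNAs or samples give 0 with a warning.
#'
#' @param mirna miRNA expression matrix (miRNAs x samples).
#' @param oncoMirnas declared cancer-associated subset.
#' @param sample sample identifier.
#' @return named numeric vector (`mirna_<name>`).
#' @export
mirnaBlock <- function(mirna, oncoMirnas, sample) {
    manifest <- sort(oncoMirnas)
    out <- stats::setNames(numeric(length(manifest)),
                           paste0("mirna_", manifest))
    if (!sample %in% colnames(mirna)) {
        warning("sample '", sample, "' absent from the miRNA matrix; ",
                "using an all-zero block")
        return(out)
    }
    present <- manifest %in% rownames(mirna)
    if (any(!present))
        warning("onco-miRNA(s) absent from the matrix set to 0: ",
                paste(manifest[!present], collapse = ", "))
    out[present] <- mirna[manifest[present], sample]
    out
}

#' Assemble the multi-omic feature block
#'
#' Left-joins the SNV, RNA, CNV and miRNA blocks on the altered-pair
#' universe (mutated pairs union pairs with nonzero CNV).  CNV-only
#' pairs carry `has_mutation = 0` with an all-zero SNV block (zeros are
#' a sentinel for "no mutation", distinguishable from benign evidence
#' through the flag); mutation-only pairs carry `cnv_score = 0`.  The
#' `"all"` vs `"small"` score policy applies to the SNV score block of
#' mutated rows only.  Adds the CNV-conditioned neighborhood features
#' `neigh_CNV_FC` / `neigh_CNV_normFC` and the sample-level onco-miRNA
#' block.
#'
#' @param snvTable SNV feature table from [assembleSnvFeatures()].
#' @param rnaTable RNA feature table from [assembleRnaFeatures()]
#'   covering the full pair universe.
#' @param cnv integer CNV matrix genes x samples.
#' @param mirna miRNA expression matrix.
#' @param oncoMirnas declared oncogenic subset.
#' @param profiles DEG profiles (for the CNV neighborhood features).
#' @param graph interaction network.
#' @param config a [driverConfig()].
#' @return multi-omic feature table with attribute `featureSet`.
#' @export
assembleMultiomicFeatures <- function(snvTable, rnaTable, cnv, mirna,
                                      oncoMirnas, profiles, graph,
                                      config = driverConfig()) {
    key <- function(df) paste(df$sample, df$gene, sep = "\r")
    out <- rnaTable
    snvCols <- setdiff(colnames(snvTable), c("sample", "gene"))
    m <- match(key(out), key(snvTable))
    out$has_mutation <- as.integer(!is.na(m))
    for (col in snvCols) {
        v <- snvTable[[col]][m]
        v[is.na(v)] <- 0
        out[[col]] <- v
    }
    out$cnv_score <- 0L
    inCnv <- out$gene %in% rownames(cnv) & out$sample %in% colnames(cnv)
    out$cnv_score[inCnv] <- cnv[cbind(out$gene[inCnv], out$sample[inCnv])]
    nb <- neighborsWithinHops(graph, config$hops)
    out$neigh_CNV_FC <- 0
    out$neigh_CNV_normFC <- 0
    for (s in unique(out$sample)) {
        prof <- profiles[[s]]
        logfc <- stats::setNames(prof$logFC, prof$gene)
        cnvCol <- if (s %in% colnames(cnv)) cnv[, s]
                  else stats::setNames(integer(nrow(cnv)), rownames(cnv))
        rows <- which(out$sample == s)
        vals <- t(vapply(out$gene[rows], function(g)
            neighCnvFC(logfc, cnvCol, nb[[g]], tau = config$tau),
            numeric(2)))
        out$neigh_CNV_FC[rows] <- vals[, 1]
        out$neigh_CNV_normFC[rows] <- vals[, 2]
        mb <- mirnaBlock(mirna, oncoMirnas, s)
        for (j in seq_along(mb)) out[rows, names(mb)[j]] <- mb[[j]]
    }
    attr(out, "featureSet") <- attr(snvTable, "featureSet")
    rownames(out) <- NULL
    out
}

#' Featurize a cohort into one of the three feature blocks
#'
#' End-to-end feature assembly for a cohort: determines the altered
#' (sample, gene) universe, computes per-sample DEG profiles (common
#' BCV estimated once), and builds the requested block:
#'
#' * `"snv"`: mutation-evidence features on mutated pairs;
#' * `"rna"`: expression + network features on all altered pairs;
#' * `"multiomic"`: both, plus CNV, CNV-neighborhood and onco-miRNA
#'   features.
#'
#' Under the `"all"` feature set, mutated pairs with missing scores are
#' dropped (for `"multiomic"`, CNV-only pairs are always kept).
#'
#' @param cohort a [DriverCohort-class].
#' @param config a [driverConfig()].
#' @param block `"multiomic"`, `"rna"` or `"snv"`.
#' @param network optional replacement interaction network (used by the
#'   network-randomization control); defaults to the cohort's.
#' @return feature table data.frame.
#' @export
featurizeCohort <- function(cohort, config = driverConfig(),
                            block = c("multiomic", "rna", "snv"),
                            network = NULL) {
    block <- match.arg(block)
    if (is.null(network)) network <- cohortNetwork(cohort)
    mutations <- cohortMutations(cohort)
    if (block == "snv")
        return(assembleSnvFeatures(mutations, config))
    se <- cohortCounts(cohort)
    profiles <- degProfiles(se, config)
    cnv <- cohortCNV(cohort)
    pairs <- alteredPairs(mutations, cnv)
    rna <- assembleRnaFeatures(profiles, network, pairs, config)
    if (block == "rna") return(rna)
    snv <- assembleSnvFeatures(mutations, config)
    mo <- assembleMultiomicFeatures(snv, rna, cnv, cohortMirna(cohort),
                                    oncoMirnas(cohort), profiles, network,
                                    config)
    if (config$featureSet == "all") {
        ## drop mutated pairs that "all" could not score; CNV-only stay
        kept <- paste(snv$sample, snv$gene)
        mutated <- paste(mutations$sample, mutations$gene)
        moKey <- paste(mo$sample, mo$gene)
        mo <- mo[!(moKey %in% setdiff(mutated, kept)), , drop = FALSE]
    }
    rownames(mo) <- NULL
    mo
}
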