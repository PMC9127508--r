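## Readers and writers for all external tabular dialects.  All inputs are
## TSV with a header; MISSING numeric/categorical cells are "." or empty
## and become NA (a typed sentinel, never coerced to 0).

.readTSV <- function(path, ...) {
    utils::read.delim(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, check.names = FALSE,
                      na.strings = c(".", "", "NA"), ...)
}

.fmtNum <- function(x) {
    ## 6 significant digits, locale-independent, stable across runs
    ifelse(is.na(x), "NA", formatC(x, digits = 6, format = "g"))
}

.writeTSV <- function(df, path) {
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], .fmtNum)
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(paste(colnames(df), collapse = "\t"), con, sep = "\n")
    if (nrow(df)) {
        rows <- do.call(paste, c(lapply(df, as.character), sep = "\t"))
        writeLines(rows, con, sep = "\n")
    }
    invisible(path)
}

#' Read an annotated somatic mutation table
#'
#' Parses a MAF-style annotated mutation TSV: one row per mutation with
#' the required columns `sample`, `gene`, `chrom`, `pos`, `ref`, `alt`,
#' `type`, plus `<tool>_score` / `<tool>_pred` columns for every tool
#' declared in `config$tools` and an optional `domains` column holding
#' Pfam accessions joined by `config$domainDelim`.
#'
#' Score and prediction cells that are blank or `"."` become `NA`
#' (missing).  Mutation types outside [mutationTypeVocabulary()] are
#' mapped to `"other"` with a warning.  Coordinates are 1-based; alleles
#' are uppercased; gene and sample identifiers are trimmed, never
#' alias-resolved.
#'
#' @param path TSV file path.
#' @param config a [driverConfig()].
#' @return data.frame of mutations with a `domains` list-column of
#'   parsed Pfam accessions.
#' @export
readMutations <- function(path, config = driverConfig()) {
    df <- .readTSV(path, colClasses = "character")
    req <- c("sample", "gene", "chrom", "pos", "ref", "alt", "type")
    miss <- setdiff(req, colnames(df))
    if (length(miss))
        stop("mutation table is missing required column(s): ",
             paste(miss, collapse = ", "))
    out <- data.frame(
        sample = trimws(df$sample),
        gene = trimws(df$gene),
        chrom = as.character(df$chrom),
        pos = as.integer(df$pos),
        ref = toupper(trimws(df$ref)),
        alt = toupper(trimws(df$alt)),
        type = df$type,
        stringsAsFactors = FALSE
    )
    if (any(is.na(out$pos)) || any(out$pos < 1L))
        stop("mutation positions must be integers >= 1")
    bad <- !out$type %in% config$mutationTypes
    if (any(bad)) {
        warning(sum(bad), " mutation(s) with unknown type mapped to 'other'")
        out$type[bad] <- "other"
    }
    for (tool in names(config$tools)) {
        sc <- paste0(tool, "_score")
        pc <- paste0(tool, "_pred")
        if (sc %in% colnames(df)) {
            out[[sc]] <- suppressWarnings(as.numeric(df[[sc]]))
        } else {
            warning("column '", sc, "' absent; treating all values as missing")
            out[[sc]] <- NA_real_
        }
        if (pc %in% colnames(df)) {
            out[[pc]] <- as.character(df[[pc]])
        } else {
            warning("column '", pc, "' absent; treating all values as missing")
            out[[pc]] <- NA_character_
        }
        known <- config$tools[[tool]]$categories
        stray <- setdiff(unique(out[[pc]][!is.na(out[[pc]])]), known)
        if (length(stray))
            stop("tool '", tool, "' has prediction value(s) outside the ",
                 "declared category order: ", paste(stray, collapse = ", "))
    }
    if ("domains" %in% colnames(df)) {
        out$domains <- lapply(df$domains, function(x) {
            if (is.na(x)) return(character())
            d <- trimws(strsplit(x, config$domainDelim, fixed = TRUE)[[1]])
            d[nzchar(d) & d != "."]
        })
    } else {
        out$domains <- replicate(nrow(out), character(), simplify = FALSE)
    }
    out
}

#' Read and filter a scored interaction network
#'
#' Reads a STRING-dialect edge list (columns `gene_a`, `gene_b`,
#' `experimental_score`, `database_score`, integer scores 0--1000) and
#' retains an edge iff the *maximum* of the two per-channel scores is
#' strictly greater than `config$stringScoreCutoff` (the boundary value
#' itself is excluded).  Self-loops are dropped and symmetric duplicates
#' collapsed; the result is an undirected, unweighted graph (scores gate
#' edge existence only).
#'
#' @inheritParams readMutations
#' @return an [igraph::igraph] object.
#' @export
readNetwork <- function(path, config = driverConfig()) {
    df <- utils::read.table(path, header = TRUE, sep = "",
                            stringsAsFactors = FALSE, check.names = FALSE)
    req <- c("gene_a", "gene_b", "experimental_score", "database_score")
    miss <- setdiff(req, colnames(df))
    if (length(miss))
        stop("network file is missing required column(s): ",
             paste(miss, collapse = ", "))
    for (col in c("experimental_score", "database_score")) {
        v <- suppressWarnings(as.numeric(df[[col]]))
        bad <- which(is.na(v) | v != floor(v))
        if (length(bad))
            stop("non-integer ", col, " at row ", bad[1])
        df[[col]] <- as.integer(v)
    }
    df$gene_a <- trimws(df$gene_a)
    df$gene_b <- trimws(df$gene_b)
    keep <- pmax(df$experimental_score, df$database_score) >
        config$stringScoreCutoff
    df <- df[keep & df$gene_a != df$gene_b, , drop = FALSE]
    if (!nrow(df))
        return(igraph::make_empty_graph(0, directed = FALSE))
    key <- paste(pmin(df$gene_a, df$gene_b), pmax(df$gene_a, df$gene_b))
    df <- df[!duplicated(key), , drop = FALSE]
    ## score columns are kept as edge attributes for provenance; they are
    ## never used as weights downstream
    igraph::graph_from_data_frame(df[, req], directed = FALSE)
}

#' Build a counts container from a matrix and a condition map
#'
#' @param counts non-negative integer matrix, genes x samples.
#' @param condition named character vector (or factor) mapping every
#'   sample to `"TUMOR"` or `"NORMAL"`.
#' @return SummarizedExperiment with assay `counts`.
#' @export
makeCountsSE <- function(counts, condition) {
    counts <- as.matrix(counts)
    if (any(counts < 0)) stop("counts must be non-negative")
    if (anyDuplicated(rownames(counts)))
        stop("duplicate gene symbols in counts")
    miss <- setdiff(colnames(counts), names(condition))
    if (length(miss))
        stop("sample(s) absent from condition map: ",
             paste(miss, collapse = ", "))
    cond <- as.character(condition[colnames(counts)])
    if (!all(cond %in% c("TUMOR", "NORMAL")))
        stop("condition values must be TUMOR or NORMAL")
    SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        colData = S4Vectors::DataFrame(condition = cond,
                                       row.names = colnames(counts))
    )
}

#' Read a raw count matrix and its tumor/normal condition map
#'
#' @param countsPath TSV, first column `gene`, one column per sample.
#' @param conditionPath two-column TSV `sample`, `condition`.
#' @return SummarizedExperiment (see [makeCountsSE()]).
#' @export
readCounts <- function(countsPath, conditionPath) {
    df <- .readTSV(countsPath)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    storage.mode(m) <- "integer"
    cond <- .readTSV(conditionPath)
    makeCountsSE(m, stats::setNames(cond$condition, cond$sample))
}

#' Read a GISTIC-style gene-level copy-number score matrix
#'
#' @param path TSV, first column `gene`, one integer column per sample.
#' @return integer matrix genes x samples; 0 means no alteration.
#' @export
readCNV <- function(path) {
    df <- .readTSV(path)
    m <- as.matrix(df[, -1, drop = FALSE])
    if (any(is.na(m)) || any(m != floor(m)))
        stop("CNV scores must be integer-valued")
    storage.mode(m) <- "integer"
    rownames(m) <- df[[1]]
    m
}

#' Read a miRNA expression matrix and its oncogenic subset
#'
#' @param exprPath TSV, first column `mirna`, one column per sample.
#' @param oncoPath plain-text file, one cancer-associated miRNA per line.
#' @return list with `expression` (matrix) and `oncoMirnas` (character).
#' @export
readMirna <- function(exprPath, oncoPath) {
    df <- .readTSV(exprPath)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    if (any(m < 0)) stop("miRNA expression must be non-negative")
    onco <- trimws(readLines(oncoPath))
    onco <- onco[nzchar(onco)]
    absent <- setdiff(onco, rownames(m))
    if (length(absent)) {
        warning("oncogenic miRNA(s) absent from the expression matrix: ",
                paste(absent, collapse = ", "))
        onco <- setdiff(onco, absent)
    }
    list(expression = m, oncoMirnas = onco)
}

#' Read driver and neutral gene resources
#'
#' Reads the three labeling resources: a mutation-level driver list
#' (columns `gene`, `pos`, `ref`, `alt`, `label` in DRIVER/TSG/OG,
#' `evidence_score` possibly missing), a gene-level driver list (columns
#' `gene`, `tag`, `cancer_type`, where `cancer_type` is `PAN` or a
#' cancer-type code), and a neutral gene list (one symbol per line).
#' Neutral genes that also appear in the gene-level driver list are
#' reported and dropped from the neutral list so the two sets are
#' disjoint within a labeling run.
#'
#' @param mutationPath,genePath,neutralPath file paths.
#' @return list with `mutationDrivers`, `geneDrivers`, `neutralGenes`.
#' @export
readDriverResources <- function(mutationPath, genePath, neutralPath) {
    md <- .readTSV(mutationPath)
    req <- c("gene", "pos", "ref", "alt", "label", "evidence_score")
    miss <- setdiff(req, colnames(md))
    if (length(miss))
        stop("mutation driver list missing column(s): ",
             paste(miss, collapse = ", "))
    md$gene <- trimws(md$gene)
    md$pos <- as.integer(md$pos)
    md$ref <- toupper(trimws(md$ref))
    md$alt <- toupper(trimws(md$alt))
    md$evidence_score <- as.numeric(md$evidence_score)
    if (!all(md$label %in% c("DRIVER", "TSG", "OG")))
        stop("mutation driver labels must be DRIVER, TSG or OG")
    gd <- .readTSV(genePath)
    req <- c("gene", "tag", "cancer_type")
    miss <- setdiff(req, colnames(gd))
    if (length(miss))
        stop("gene driver list missing column(s): ",
             paste(miss, collapse = ", "))
    gd$gene <- trimws(gd$gene)
    neutral <- trimws(readLines(neutralPath))
    neutral <- neutral[nzchar(neutral)]
    overlap <- intersect(neutral, gd$gene)
    if (length(overlap)) {
        warning("gene(s) in both the neutral and driver lists dropped ",
                "from the neutral list: ", paste(overlap, collapse = ", "))
        neutral <- setdiff(neutral, overlap)
    }
    list(mutationDrivers = md, geneDrivers = gd, neutralGenes = neutral)
}

#' Write / read a feature table
#'
#' Stable TSV dialect: key columns `sample`, `gene` (and `label` when
#' present) first, followed by the feature columns in sorted name order;
#' floating point values at 6 significant digits.  Two writes of the
#' same table are byte-identical.
#'
#' @param ft feature table data.frame.
#' @param path output path.
#' @return `path`, invisibly (`readFeatureTable` returns the table).
#' @export
writeFeatureTable <- function(ft, path) {
    keys <- intersect(c("sample", "gene", "label"), colnames(ft))
    feats <- sort(setdiff(colnames(ft), keys))
    df <- ft[, c(keys, feats), drop = FALSE]
    if (nrow(df)) df <- df[order(df$sample, df$gene), , drop = FALSE]
    .writeTSV(df, path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
    .readTSV(path)
}

#' Write per-pair predictions
#'
#' TSV with columns `sample`, `gene`, `predictedClass`, one
#' `prob_<class>` column per class, `driverScore` and the within-sample
#' `rank`.  Deterministic given equal inputs.
#'
#' @param preds prediction data.frame from [predictAndRank()].
#' @param path output path.
#' @export
writePredictions <- function(preds, path) {
    .writeTSV(preds[order(preds$sample, preds$rank), , drop = FALSE], path)
}

#' Write / read a label table
#'
#' @param labels label table (columns `sample`, `gene`,
#'   `alteration_kind`, `label`, `strategy`).
#' @param path file path.
#' @export
writeLabelTable <- function(labels, path) {
    .writeTSV(labels[order(labels$sample, labels$gene), , drop = FALSE], path)
}

#' @rdname writeLabelTable
#' @export
readLabelTable <- function(path) {
    .readTSV(path)
}

#' Write an evaluation report as JSON
#'
#' @param report list as returned by [evaluateModel()].
#' @param path output path.
#' @export
writeMetricsJSON <- function(report, path) {
    out <- list(
        accuracy = report$accuracy,
        perClass = report$perClass,
        confusion = as.data.frame.matrix(report$confusion)
    )
    json <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = 10,
                             dataframe = "columns", na = "null")
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(json, con, sep = "\n")
    invisible(path)
}

#' Write a cohort to a directory of plain-text files
#'
#' Emits the six pipeline inputs (plus ground truth, when present) in
#' the dialects the `read*` functions consume: `mutations.tsv`,
#' `counts.tsv` + `conditions.tsv`, `cnv.tsv`, `mirna.tsv` +
#' `onco_mirnas.txt`, `network.tsv`, `drivers_mutation.tsv`,
#' `drivers_gene.tsv`, `neutral_genes.txt`.  The network file includes
#' any sub-threshold decoy edges carried in the resources so that the
#' read-side score filter is exercised.
#'
#' @param cohort a [DriverCohort-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    p <- function(f) file.path(dir, f)
    mut <- cohortMutations(cohort)
    mut$domains <- vapply(mut$domains, function(d)
        if (length(d)) paste(d, collapse = ";") else ".", character(1))
    .writeTSV(mut, p("mutations.tsv"))
    se <- cohortCounts(cohort)
    cm <- SummarizedExperiment::assay(se, "counts")
    .writeTSV(cbind(data.frame(gene = rownames(cm)), as.data.frame(cm)),
              p("counts.tsv"))
    .writeTSV(data.frame(sample = colnames(se),
                         condition = se$condition),
              p("conditions.tsv"))
    cnv <- cohortCNV(cohort)
    .writeTSV(cbind(data.frame(gene = rownames(cnv)), as.data.frame(cnv)),
              p("cnv.tsv"))
    mir <- cohortMirna(cohort)
    .writeTSV(cbind(data.frame(mirna = rownames(mir)), as.data.frame(mir)),
              p("mirna.tsv"))
    writeLines(oncoMirnas(cohort), p("onco_mirnas.txt"))
    net <- cohortNetwork(cohort)
    el <- igraph::as_edgelist(net)
    edges <- data.frame(gene_a = el[, 1], gene_b = el[, 2],
                        experimental_score = igraph::E(net)$experimental_score,
                        database_score = igraph::E(net)$database_score)
    res <- driverResources(cohort)
    if (!is.null(res$decoyEdges)) edges <- rbind(edges, res$decoyEdges)
    .writeTSV(edges, p("network.tsv"))
    md <- res$mutationDrivers
    .writeTSV(md, p("drivers_mutation.tsv"))
    .writeTSV(res$geneDrivers, p("drivers_gene.tsv"))
    writeLines(res$neutralGenes, p("neutral_genes.txt"))
    gt <- groundTruth(cohort)
    if (!is.null(gt)) .writeTSV(gt$genes, p("ground_truth_genes.tsv"))
    invisible(dir)
}

#' Read a cohort directory written by [writeCohort()]
#'
#' @param dir cohort directory.
#' @param config a [driverConfig()]; its cutoffs apply while reading.
#' @param cancerType cancer-type tag for the cohort.
#' @return a [DriverCohort-class].
#' @export
readCohort <- function(dir, config = driverConfig(),
                       cancerType = config$cancerType) {
    p <- function(f) file.path(dir, f)
    mir <- readMirna(p("mirna.tsv"), p("onco_mirnas.txt"))
    gt <- NULL
    if (file.exists(p("ground_truth_genes.tsv")))
        gt <- list(genes = .readTSV(p("ground_truth_genes.tsv")))
    net <- readNetwork(p("network.tsv"), config)
    methods::new("DriverCohort",
        mutations = readMutations(p("mutations.tsv"), config),
        counts = readCounts(p("counts.tsv"), p("conditions.tsv")),
        cnv = readCNV(p("cnv.tsv")),
        mirna = mir$expression,
        oncoMirnas = mir$oncoMirnas,
        network = net,
        resources = readDriverResources(p("drivers_mutation.tsv"),
                                        p("drivers_gene.tsv"),
                                        p("neutral_genes.txt")),
        groundTruth = gt,
        cancerType = cancerType)
}
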