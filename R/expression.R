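## Single-sample differential expression against pooled normals under a
## common negative-binomial dispersion, and the RNA feature block.

#' Counts per million
#'
#' `cpm_g = count_g / library_size * 1e6`, with the library size taken
#' as the column sum.  Scale-invariant: doubling all counts of a sample
#' leaves its CPM unchanged.
#'
#' @param counts non-negative matrix, genes x samples.
#' @return CPM matrix of the same shape.
#' @export
cpm <- function(counts) {
    lib <- colSums(counts)
    if (any(lib == 0)) stop("zero library size in sample(s): ",
                            paste(colnames(counts)[lib == 0], collapse = ", "))
    t(t(counts) / lib) * 1e6
}

## Per-gene MLE of the concentration q (counts ~ NB(mu = q * L_j, phi))
## for one condition group, by Fisher scoring on log q, vectorized over
## genes.  Genes with an all-zero group have MLE q = 0.
.mleGroupConcentration <- function(y, lib, k) {
    rs <- rowSums(y)
    zero <- rs == 0
    eta <- log(pmax(rs / sum(lib), 1e-12))
    for (it in 1:12) {
        mu <- exp(eta) %o% lib
        score <- rowSums(y - (y + k) * mu / (mu + k))
        info <- rowSums(mu * k / (mu + k))
        step <- pmin(pmax(score / pmax(info, 1e-10), -2), 2)
        eta <- eta + step
        if (all(abs(step[!zero]) < 1e-10)) break
    }
    q <- exp(eta)
    q[zero] <- 0
    q
}

.commonPhiNegLogLik <- function(logPhi, y, lib, groupIdx) {
    k <- 1 / exp(logPhi)
    total <- 0
    for (idx in groupIdx) {
        q <- .mleGroupConcentration(y[, idx, drop = FALSE], lib[idx], k)
        mu <- q %o% lib[idx]
        total <- total + sum(stats::dnbinom(y[, idx, drop = FALSE],
                                            size = k,
                                            mu = pmax(mu, 1e-12),
                                            log = TRUE))
    }
    -total
}

#' Estimate the common biological coefficient of variation
#'
#' Fits a single negative-binomial dispersion `phi` shared by all genes
#' under a two-group (tumor vs normal) means model with library-size
#' offsets: for a candidate `phi`, each gene's per-group mean is set to
#' its maximum-likelihood value, and `phi` maximizes the summed profile
#' log-likelihood across genes.  The search is one-dimensional on
#' `log(phi)` over \[1e-6, 4\] to tolerance 1e-4.  Genes with all-zero
#' counts are excluded.  The estimate is invariant under per-sample
#' library rescaling (the offsets absorb it), and deterministic given
#' the counts.
#'
#' `bcv = sqrt(phi)` is the coefficient of variation with which true
#' gene abundance varies between biological replicates; it is the
#' quantity later fixed when testing a single tumor sample against the
#' pooled normals.
#'
#' @param se SummarizedExperiment from [makeCountsSE()]; needs at least
#'   two samples in each condition.
#' @return list of class `bcvEstimate` with `phi`, `bcv`,
#'   `nGenesUsed`, and `atBoundary`.
#' @export
estimateCommonBCV <- function(se) {
    counts <- SummarizedExperiment::assay(se, "counts")
    cond <- se$condition
    if (any(table(factor(cond, c("TUMOR", "NORMAL"))) < 2L))
        stop("need at least two samples per condition to estimate the BCV")
    keep <- rowSums(counts) > 0
    y <- counts[keep, , drop = FALSE]
    lib <- colSums(counts)
    groupIdx <- split(seq_along(cond), cond)
    bounds <- log(c(1e-6, 4))
    opt <- stats::optimize(.commonPhiNegLogLik, interval = bounds,
                           tol = 1e-4, y = y, lib = lib,
                           groupIdx = groupIdx)
    phi <- exp(opt$minimum)
    atBoundary <- opt$minimum < bounds[1] + 1e-3 ||
        opt$minimum > bounds[2] - 1e-3
    if (atBoundary) {
        ## snap to the boundary value and say so
        phi <- exp(bounds[which.min(abs(opt$minimum - bounds))])
        warning("common dispersion estimate at the search boundary (phi = ",
                signif(phi, 3), ")")
    }
    structure(list(phi = phi, bcv = sqrt(phi), nGenesUsed = sum(keep),
                   atBoundary = atBoundary),
              class = "bcvEstimate")
}

#' @export
print.bcvEstimate <- function(x, ...) {
    cat("Common NB dispersion: phi =", signif(x$phi, 4),
        "(BCV =", paste0(signif(x$bcv, 4), ")"),
        "from", x$nGenesUsed, "genes\n")
    invisible(x)
}

#' Single-sample differential expression against pooled normals
#'
#' Compares one tumor sample with the pooled normal samples:
#'
#' * `logFC_g = log2((cpm_tumor + prior) / (mean normal cpm + prior))`;
#' * `logCPM_g = log2(mean cpm over the tumor sample and all normals + prior)`;
#' * `pValue`: two-sided NB tail probability of the tumor count given
#'   the pooled-normal concentration, the tumor library size, and the
#'   cohort dispersion `phi` (exported for reference, not used as a
#'   feature);
#' * `isDEG = |logFC| > tau`.
#'
#' @param se SummarizedExperiment of counts.
#' @param tumorSample tumor sample name (must have condition `TUMOR`).
#' @param phi common NB dispersion, typically from
#'   [estimateCommonBCV()] (`$phi`) or a stored cohort value.
#' @param prior prior count on the CPM scale.
#' @param tau DEG threshold on |logFC| in log2 units.
#' @return data.frame with columns `gene`, `logFC`, `logCPM`, `pValue`,
#'   `isDEG`.
#' @export
singleSampleDEG <- function(se, tumorSample, phi, prior = 0.5, tau = 1) {
    counts <- SummarizedExperiment::assay(se, "counts")
    cond <- se$condition
    normals <- colnames(counts)[cond == "NORMAL"]
    if (!length(normals)) stop("no NORMAL samples available")
    if (!tumorSample %in% colnames(counts)[cond == "TUMOR"])
        stop("'", tumorSample, "' is not a TUMOR sample of the cohort")
    cpmM <- cpm(counts)
    ct <- cpmM[, tumorSample]
    cn <- rowMeans(cpmM[, normals, drop = FALSE])
    logFC <- log2((ct + prior) / (cn + prior))
    logCPM <- log2(rowMeans(cpmM[, c(tumorSample, normals), drop = FALSE]) +
                   prior)
    lib <- colSums(counts)
    qn <- rowSums(counts[, normals, drop = FALSE]) / sum(lib[normals])
    mu <- qn * lib[tumorSample]
    k <- 1 / max(phi, 1e-8)
    yv <- counts[, tumorSample]
    lower <- stats::pnbinom(yv, size = k, mu = pmax(mu, 1e-12))
    upper <- 1 - stats::pnbinom(yv - 1, size = k, mu = pmax(mu, 1e-12))
    p <- pmin(1, 2 * pmin(lower, upper))
    p[mu == 0] <- 1
    data.frame(gene = rownames(counts), logFC = logFC, logCPM = logCPM,
               pValue = p, isDEG = abs(logFC) > tau,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-sample DEG profiles for all tumor samples
#'
#' Runs [singleSampleDEG()] for every tumor sample against the pooled
#' normals, estimating the common BCV once (unless
#' `config$phiOverride` supplies a stored value).
#'
#' @param se SummarizedExperiment of counts.
#' @param config a [driverConfig()].
#' @return named list of DEG data.frames, one per tumor sample; the
#'   dispersion used is attached as attribute `phi`.
#' @export
degProfiles <- function(se, config = driverConfig()) {
    phi <- config$phiOverride
    if (is.null(phi)) phi <- estimateCommonBCV(se)$phi
    tumors <- colnames(se)[se$condition == "TUMOR"]
    out <- lapply(tumors, function(s)
        singleSampleDEG(se, s, phi, prior = config$prior, tau = config$tau))
    names(out) <- tumors
    attr(out, "phi") <- phi
    out
}

#' Neighborhood fold-change features
#'
#' Over the differentially expressed members of a gene's neighborhood
#' `S = {v in neighbors : |logFC_v| > tau}`:
#' `neigh_FC = sum(logFC_v)` and `neigh_normFC = neigh_FC / |S|`
#' (0 when `S` is empty).
#'
#' @param logfc named numeric vector of per-gene logFC for one sample.
#' @param neighbors character vector of neighbor genes.
#' @param tau DEG threshold on |logFC|.
#' @return named numeric vector `c(neigh_FC, neigh_normFC)`.
#' @export
neighFC <- function(logfc, neighbors, tau = 1) {
    v <- logfc[intersect(neighbors, names(logfc))]
    s <- v[!is.na(v) & abs(v) > tau]
    total <- sum(s)
    c(neigh_FC = total,
      neigh_normFC = if (length(s)) total / length(s) else 0)
}

#' CNV-conditioned neighborhood fold-change features
#'
#' As [neighFC()], but the neighborhood is restricted to neighbors that
#' additionally carry a nonzero copy-number score in the sample:
#' `S = {v : cnv_v != 0 and |logFC_v| > tau}`.
#'
#' @param logfc named per-gene logFC vector for one sample.
#' @param cnvColumn named integer vector of CNV scores for the sample.
#' @param neighbors character vector of neighbor genes.
#' @param tau DEG threshold on |logFC|.
#' @return named numeric vector `c(neigh_CNV_FC, neigh_CNV_normFC)`.
#' @export
neighCnvFC <- function(logfc, cnvColumn, neighbors, tau = 1) {
    v <- logfc[intersect(neighbors, names(logfc))]
    cn <- cnvColumn[names(v)]
    cn[is.na(cn)] <- 0L
    s <- v[!is.na(v) & abs(v) > tau & cn != 0]
    total <- sum(s)
    c(neigh_CNV_FC = total,
      neigh_CNV_normFC = if (length(s)) total / length(s) else 0)
}

#' Assemble the RNA feature block
#'
#' One row per altered (sample, gene) pair with the expression and
#' network features: `logFC`, `logCPM`, `degree`, `closeness`,
#' `betweenness`, the three `logFC_x_*` products, and the neighborhood
#' features `neigh_FC`, `neigh_normFC`.  Genes absent from the network
#' get zero network and neighborhood features; genes absent from the
#' expression matrix get a zeroed RNA block (with a warning); pairs of
#' samples without a DEG profile are dropped with a warning.
#'
#' @param profiles named list of DEG profiles from [degProfiles()].
#' @param graph interaction network.
#' @param pairs data.frame with columns `sample`, `gene` (e.g. from
#'   [alteredPairs()]).
#' @param config a [driverConfig()] (`hops`, `tau`).
#' @return feature table data.frame (`sample`, `gene` + 10 features).
#' @export
assembleRnaFeatures <- function(profiles, graph, pairs,
                                config = driverConfig()) {
    noProfile <- !pairs$sample %in% names(profiles)
    if (any(noProfile)) {
        warning("dropping ", sum(noProfile),
                " pair(s) of sample(s) without a DEG profile: ",
                paste(unique(pairs$sample[noProfile]), collapse = ", "))
        pairs <- pairs[!noProfile, , drop = FALSE]
    }
    stats <- nodeCentralities(graph)
    nb <- neighborsWithinHops(graph, config$hops)
    rows <- vector("list", length(unique(pairs$sample)))
    i <- 0L
    missingExpr <- 0L
    for (s in unique(pairs$sample)) {
        prof <- profiles[[s]]
        logfc <- stats::setNames(prof$logFC, prof$gene)
        logcpm <- stats::setNames(prof$logCPM, prof$gene)
        genes <- pairs$gene[pairs$sample == s]
        fc <- unname(logfc[genes])
        cpmv <- unname(logcpm[genes])
        offExpr <- is.na(fc)
        missingExpr <- missingExpr + sum(offExpr)
        fc[offExpr] <- 0
        cpmv[is.na(cpmv)] <- 0
        m <- match(genes, stats$gene)
        deg <- ifelse(is.na(m), 0L, stats$degree[m])
        clo <- ifelse(is.na(m), 0, stats$closeness[m])
        btw <- ifelse(is.na(m), 0, stats$betweenness[m])
        nf <- t(vapply(genes, function(g)
            neighFC(logfc, nb[[g]], tau = config$tau), numeric(2)))
        i <- i + 1L
        rows[[i]] <- data.frame(
            sample = s, gene = genes,
            logFC = fc, logCPM = cpmv,
            degree = deg, closeness = clo, betweenness = btw,
            logFC_x_degree = fc * deg,
            logFC_x_closeness = fc * clo,
            logFC_x_betweenness = fc * btw,
            neigh_FC = nf[, 1], neigh_normFC = nf[, 2],
            row.names = NULL, stringsAsFactors = FALSE)
    }
    if (missingExpr > 0L)
        warning(missingExpr, " pair(s) without expression data kept with a ",
                "zeroed RNA block")
    out <- do.call(rbind, rows[seq_len(i)])
    if (is.null(out))
        out <- data.frame(sample = character(), gene = character())
    out
}
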