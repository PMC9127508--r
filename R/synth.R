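## Synthetic multi-omic cohorts with planted TSG/OG signal.  The
## generator emulates the statistical structure the classifier exploits
## (damaging mutation scores, planted expression fold changes, driver
## hubness with co-dysregulated neighborhoods, signed CNV, onco-miRNA
## expression) without mimicking any real cohort's marginals or gene
## symbols.

#' Configuration of the synthetic cohort generator
#'
#' Defaults define the reference simulation used throughout the test
#' suite: 100 samples (80 tumor / 20 normal), 300 genes with 15 planted
#' TSGs, 15 OGs and 60 neutral genes, a true biological coefficient of
#' variation of 0.4, planted driver |logFC| of 2 (TSGs down, OGs up),
#' damaging-score profiles Uniform(0.7, 1) for drivers vs
#' Uniform(0, 0.5) for non-drivers (on the oriented scale), and a 15%
#' missing-score rate so both feature-set policies are exercised.
#' Drivers are biased toward network hubs with moderate strength, and
#' the genes adjacent to drivers are co-dysregulated (|logFC|
#' `neighborLogFC`) so that neighborhood features carry real signal.
#'
#' @param ... named overrides of the defaults (see source for the full
#'   field list).
#' @return list of class `synthConfig`.
#' @export
synthConfig <- function(...) {
    cfg <- list(
        nTumor = 80L, nNormal = 20L, nGenes = 300L,
        nTsg = 15L, nOg = 15L, nNeutral = 60L,
        trueBcv = 0.4,
        plantedLogFC = 2.0,
        neighborLogFC = 1.5,
        neighborRate = 0.8,
        driverScoreRange = c(0.7, 1.0),
        neutralScoreRange = c(0.0, 0.5),
        mutRateDriver = 0.35, mutRateNeutral = 0.15, mutRateBackground = 0.05,
        cnvRateDriver = 0.35, cnvRateNeutral = 0.12, cnvRateBackground = 0.08,
        missingScoreRate = 0.15,
        hubBias = 1,
        paEdgesPerNode = 3L,
        domainRate = 0.6,
        hotspotRate = 0.7,
        nHotspotsPerDriver = 3L,
        nMirna = 20L, nOncoMirna = 8L,
        meanLog = log(150), sdLog = 1,
        libSizeRange = c(5e5, 2e6),
        cancerType = "SYNTH",
        seed = 2024L
    )
    override <- list(...)
    unknown <- setdiff(names(override), names(cfg))
    if (length(unknown))
        stop("unknown synthConfig field(s): ", paste(unknown, collapse = ", "))
    cfg[names(override)] <- override
    if (cfg$nTsg + cfg$nOg + cfg$nNeutral > cfg$nGenes)
        stop("planted classes exceed the number of genes")
    class(cfg) <- "synthConfig"
    cfg
}

#' Driver configuration matching the synthetic cohorts
#'
#' The [driverConfig()] whose tool declarations, domain list and cancer
#' type match the files emitted by [simulateCohort()].
#'
#' @param ... overrides forwarded to [driverConfig()].
#' @return a `driverConfig`.
#' @export
synthDriverConfig <- function(...) {
    driverConfig(cancerDomains = c("PF00870", "PF00028"),
                 cancerType = "SYNTH", ...)
}

#' Simulate a negative-binomial count experiment
#'
#' Gene baseline abundances are log-normal, library sizes uniform on
#' `libSizeRange`, and counts are negative-binomial with dispersion
#' `bcv^2` (`bcv = 0` gives Poisson).  `log2FoldChange` plants a
#' per-gene multiplicative change in the tumor group.
#'
#' @param nGenes,nTumor,nNormal experiment dimensions.
#' @param bcv true biological coefficient of variation.
#' @param log2FoldChange numeric scalar or per-gene vector of planted
#'   tumor-vs-normal log2 fold changes.
#' @param meanLog,sdLog log-normal baseline abundance parameters.
#' @param libSizeRange library-size range.
#' @param seed optional seed.
#' @return SummarizedExperiment of counts with tumor/normal conditions.
#' @export
simulateNBCounts <- function(nGenes, nTumor, nNormal, bcv = 0.4,
                             log2FoldChange = 0,
                             meanLog = log(150), sdLog = 1,
                             libSizeRange = c(5e5, 2e6), seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    genes <- sprintf("G%04d", seq_len(nGenes))
    samples <- c(sprintf("T%03d", seq_len(nTumor)),
                 sprintf("N%03d", seq_len(nNormal)))
    condition <- stats::setNames(rep(c("TUMOR", "NORMAL"),
                                     c(nTumor, nNormal)), samples)
    base <- stats::rlnorm(nGenes, meanLog, sdLog)
    cpmExp <- base / sum(base) * 1e6
    lib <- stats::runif(nTumor + nNormal, libSizeRange[1], libSizeRange[2])
    fc <- rep_len(log2FoldChange, nGenes)
    mu <- (cpmExp / 1e6) %o% lib
    mu[, condition == "TUMOR"] <- mu[, condition == "TUMOR"] *
        2^fc
    counts <- if (bcv > 0) {
        matrix(stats::rnbinom(length(mu), size = 1 / bcv^2, mu = mu),
               nGenes, dimnames = list(genes, samples))
    } else {
        matrix(stats::rpois(length(mu), lambda = mu),
               nGenes, dimnames = list(genes, samples))
    }
    storage.mode(counts) <- "integer"
    makeCountsSE(counts, condition)
}

.randomAllele <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

.randomAlt <- function(ref) {
    unname(vapply(ref, function(r)
        sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1)))
}

## one block of mutation rows for a set of (gene, sample) events
.simMutationRows <- function(gene, sample, isDriver, class, hotspots, cfg) {
    n <- length(gene)
    pos <- integer(n)
    ref <- character(n)
    alt <- character(n)
    type <- character(n)
    for (i in seq_len(n)) {
        hs <- hotspots[hotspots$gene == gene[i], , drop = FALSE]
        if (isDriver[i] && nrow(hs) && stats::runif(1) < cfg$hotspotRate) {
            j <- sample.int(nrow(hs), 1)
            pos[i] <- hs$pos[j]; ref[i] <- hs$ref[j]; alt[i] <- hs$alt[j]
        } else {
            pos[i] <- sample(setdiff(10:5000, hs$pos), 1)
            ref[i] <- .randomAllele(1)
            alt[i] <- .randomAlt(ref[i])
        }
    }
    tsgTypes <- c("nonsense", "frameshift_del", "missense", "splice")
    ogTypes <- c("missense", "inframe_del", "nonsense", "splice")
    passTypes <- c("silent", "missense", "other")
    for (i in seq_len(n)) {
        type[i] <- if (!isDriver[i]) {
            sample(passTypes, 1, prob = c(0.4, 0.5, 0.1))
        } else if (class[i] == "TSG") {
            sample(tsgTypes, 1, prob = c(0.4, 0.25, 0.25, 0.1))
        } else {
            sample(ogTypes, 1, prob = c(0.75, 0.1, 0.08, 0.07))
        }
    }
    u <- ifelse(isDriver,
                stats::runif(n, cfg$driverScoreRange[1], cfg$driverScoreRange[2]),
                stats::runif(n, cfg$neutralScoreRange[1], cfg$neutralScoreRange[2]))
    siftScore <- 1 - u                       # raw SIFT scale: low = damaging
    siftPred <- ifelse(u > 0.5, "D", "T")
    polyScore <- u
    polyPred <- cut(u, c(-Inf, 0.45, 0.85, Inf), labels = c("B", "P", "D"))
    missSift <- stats::runif(n) < cfg$missingScoreRate
    missPoly <- stats::runif(n) < cfg$missingScoreRate
    siftScore[missSift] <- NA; siftPred[missSift] <- NA
    polyScore[missPoly] <- NA; polyPred <- as.character(polyPred)
    polyPred[missPoly] <- NA
    domains <- vector("list", n)
    for (i in seq_len(n)) {
        d <- character()
        if (isDriver[i] && stats::runif(1) < cfg$domainRate)
            d <- if (class[i] == "TSG") "PF00870" else "PF00028"
        if (stats::runif(1) < 0.1) d <- c(d, "PF00001")
        domains[[i]] <- d
    }
    df <- data.frame(sample = sample, gene = gene, chrom = "1", pos = pos,
                     ref = ref, alt = alt, type = type,
                     sift_score = siftScore, sift_pred = siftPred,
                     polyphen_score = polyScore, polyphen_pred = polyPred,
                     stringsAsFactors = FALSE)
    df$domains <- domains
    df
}

#' Simulate a complete synthetic cohort
#'
#' Generates the six pipeline inputs plus ground truth, deterministic
#' under `config$seed`:
#'
#' 1. a preferential-attachment interaction network whose hubs
#'    preferentially host the planted drivers;
#' 2. per-gene planted expression effects: TSGs at `-plantedLogFC`, OGs
#'    at `+plantedLogFC` in all tumor samples, and genes adjacent to
#'    drivers co-dysregulated at `+-neighborLogFC` (sign following the
#'    majority of their driver neighbors);
#' 3. negative-binomial counts with dispersion `trueBcv^2` and random
#'    library sizes;
#' 4. somatic mutations at class-specific rates, with driver mutations
#'    concentrated in recurrent hotspot positions, damaging-score
#'    profiles, and a planted Pfam domain per driver class;
#' 5. signed GISTIC-style CNV calls (losses in TSGs, gains in OGs);
#' 6. a miRNA matrix with a declared oncogenic subset, and the
#'    driver/neutral labeling resources (hotspot driver mutations with
#'    evidence scores, tagged gene lists in pan-cancer and
#'    cancer-type-specific variants including two dual-role decoys, and
#'    the neutral list).
#'
#' @param config a [synthConfig()].
#' @return a [DriverCohort-class] with `groundTruth`.
#' @export
simulateCohort <- function(config = synthConfig()) {
    cfg <- config
    set.seed(cfg$seed)
    genes <- sprintf("G%03d", seq_len(cfg$nGenes))
    tumors <- sprintf("T%02d", seq_len(cfg$nTumor))
    normals <- sprintf("N%02d", seq_len(cfg$nNormal))

    ## network with driver-hub bias
    g <- igraph::sample_pa(cfg$nGenes, power = 1, m = cfg$paEdgesPerNode,
                           directed = FALSE)
    igraph::V(g)$name <- genes
    deg <- igraph::degree(g)
    nDriver <- cfg$nTsg + cfg$nOg
    driverGenes <- sample(genes, nDriver, prob = (deg + 1)^cfg$hubBias)
    tsg <- driverGenes[seq_len(cfg$nTsg)]
    og <- driverGenes[-seq_len(cfg$nTsg)]
    neutral <- sample(setdiff(genes, driverGenes), cfg$nNeutral)
    classOf <- stats::setNames(rep("BACKGROUND", cfg$nGenes), genes)
    classOf[tsg] <- "TSG"; classOf[og] <- "OG"; classOf[neutral] <- "NEUTRAL"
    igraph::E(g)$experimental_score <-
        sample(701:1000, igraph::ecount(g), replace = TRUE)
    igraph::E(g)$database_score <-
        sample(0:1000, igraph::ecount(g), replace = TRUE)

    ## planted expression effects
    planted <- stats::setNames(numeric(cfg$nGenes), genes)
    planted[tsg] <- -cfg$plantedLogFC
    planted[og] <- cfg$plantedLogFC
    nbr <- igraph::ego(g, order = 1, mindist = 1)
    names(nbr) <- genes
    for (gn in setdiff(genes, driverGenes)) {
        adjDrivers <- intersect(nbr[[gn]]$name, driverGenes)
        if (!length(adjDrivers) || stats::runif(1) >= cfg$neighborRate) next
        s <- sum(sign(planted[adjDrivers]))
        if (s == 0) s <- sample(c(-1, 1), 1)
        planted[gn] <- sign(s) * cfg$neighborLogFC
    }

    ## counts
    condition <- stats::setNames(rep(c("TUMOR", "NORMAL"),
                                     c(cfg$nTumor, cfg$nNormal)),
                                 c(tumors, normals))
    base <- stats::rlnorm(cfg$nGenes, cfg$meanLog, cfg$sdLog)
    cpmExp <- base / sum(base) * 1e6
    lib <- stats::runif(cfg$nTumor + cfg$nNormal,
                        cfg$libSizeRange[1], cfg$libSizeRange[2])
    mu <- (cpmExp / 1e6) %o% lib
    mu[, seq_len(cfg$nTumor)] <- mu[, seq_len(cfg$nTumor)] * 2^planted
    counts <- matrix(
        stats::rnbinom(length(mu), size = 1 / cfg$trueBcv^2, mu = mu),
        cfg$nGenes, dimnames = list(genes, c(tumors, normals)))
    storage.mode(counts) <- "integer"
    se <- makeCountsSE(counts, condition)

    ## alteration indicators
    mutRate <- stats::setNames(rep(cfg$mutRateBackground, cfg$nGenes), genes)
    mutRate[c(tsg, og)] <- cfg$mutRateDriver
    mutRate[neutral] <- cfg$mutRateNeutral
    cnvRate <- stats::setNames(rep(cfg$cnvRateBackground, cfg$nGenes), genes)
    cnvRate[c(tsg, og)] <- cfg$cnvRateDriver
    cnvRate[neutral] <- cfg$cnvRateNeutral
    mutMat <- matrix(stats::runif(cfg$nGenes * cfg$nTumor) <
                     rep(mutRate, cfg$nTumor),
                     cfg$nGenes, dimnames = list(genes, tumors))
    cnvHit <- matrix(stats::runif(cfg$nGenes * cfg$nTumor) <
                     rep(cnvRate, cfg$nTumor),
                     cfg$nGenes, dimnames = list(genes, tumors))
    cnv <- matrix(0L, cfg$nGenes, cfg$nTumor,
                  dimnames = list(genes, tumors))
    hit <- which(cnvHit, arr.ind = TRUE)
    if (nrow(hit)) {
        mag <- sample(c(1L, 2L), nrow(hit), replace = TRUE,
                      prob = c(0.6, 0.4))
        cls <- classOf[rownames(cnvHit)[hit[, 1]]]
        sgn <- ifelse(cls == "TSG", -1L,
                      ifelse(cls == "OG", 1L,
                             sample(c(-1L, 1L), nrow(hit), replace = TRUE)))
        cnv[hit] <- sgn * mag
    }

    ## hotspot driver mutations (the mutation-level labeling resource)
    hotspots <- do.call(rbind, lapply(driverGenes, function(gn) {
        pos <- sample(seq(100L, 4900L, by = 100L), cfg$nHotspotsPerDriver)
        ref <- .randomAllele(cfg$nHotspotsPerDriver)
        data.frame(gene = gn, pos = pos, ref = ref, alt = .randomAlt(ref),
                   label = unname(classOf[gn]),
                   evidence_score = round(stats::runif(
                       cfg$nHotspotsPerDriver, 5, 40), 1),
                   stringsAsFactors = FALSE)
    }))

    ## mutation table
    ev <- which(mutMat, arr.ind = TRUE)
    evGene <- rownames(mutMat)[ev[, 1]]
    evSample <- colnames(mutMat)[ev[, 2]]
    isDriver <- classOf[evGene] %in% c("TSG", "OG")
    ## some driver pairs carry a second mutation
    second <- isDriver & stats::runif(length(evGene)) < 0.25
    mutations <- .simMutationRows(
        c(evGene, evGene[second]), c(evSample, evSample[second]),
        c(isDriver, isDriver[second]),
        classOf[c(evGene, evGene[second])], hotspots, cfg)
    ord <- order(mutations$sample, mutations$gene, mutations$pos)
    mutations <- mutations[ord, , drop = FALSE]
    rownames(mutations) <- NULL

    ## miRNA
    mirNames <- sprintf("hsa-mir-%03d", seq_len(cfg$nMirna))
    mir <- matrix(stats::rlnorm(cfg$nMirna * (cfg$nTumor + cfg$nNormal),
                                log(500), 0.8),
                  cfg$nMirna, dimnames = list(mirNames, c(tumors, normals)))
    onco <- mirNames[seq_len(cfg$nOncoMirna)]
    mir[onco, tumors] <- mir[onco, tumors] * 2

    ## gene-level driver resource (pan-cancer and cancer-type-specific
    ## rows) with two dual-role decoy genes
    tagOf <- function(gs, tags) sample(tags, length(gs), replace = TRUE,
                                       prob = c(0.7, 0.3))
    gdOne <- data.frame(
        gene = c(tsg, og),
        tag = c(tagOf(tsg, c("tsg", "possible tsg")),
                tagOf(og, c("oncogene", "possible oncogene"))),
        stringsAsFactors = FALSE)
    dual <- sample(setdiff(genes, c(driverGenes, neutral)), 2)
    gdOne <- rbind(gdOne,
                   data.frame(gene = rep(dual, each = 2),
                              tag = rep(c("tsg", "oncogene"), 2)))
    geneDrivers <- rbind(
        data.frame(gdOne, cancer_type = "PAN"),
        data.frame(gdOne, cancer_type = cfg$cancerType))

    ## sub-threshold decoy edges exercised by the read-side filter
    nDecoy <- max(2L, round(0.05 * igraph::ecount(g)))
    decoyA <- sample(genes, nDecoy, replace = TRUE)
    decoyB <- sample(genes, nDecoy, replace = TRUE)
    decoy <- data.frame(gene_a = c(decoyA, genes[1]),
                        gene_b = c(decoyB, genes[1]),
                        experimental_score = c(sample(0:700, nDecoy,
                                                      replace = TRUE), 999L),
                        database_score = c(sample(0:700, nDecoy,
                                                  replace = TRUE), 999L))

    gt <- list(genes = data.frame(
        gene = genes,
        class = unname(classOf),
        plantedLogFC = unname(planted),
        degree = unname(deg),
        stringsAsFactors = FALSE))

    methods::new("DriverCohort",
        mutations = mutations,
        counts = se,
        cnv = cnv,
        mirna = mir,
        oncoMirnas = onco,
        network = g,
        resources = list(mutationDrivers = hotspots,
                         geneDrivers = geneDrivers,
                         neutralGenes = sort(neutral),
                         decoyEdges = decoy),
        groundTruth = gt,
        cancerType = cfg$cancerType)
}

#' Path to the hand-checkable toy fixture
#'
#' A 6-gene, 3-sample micro-cohort shipped as plain-text files together
#' with hand-enumerated expected label tables for all four labeling
#' strategies; used to pin the labeling semantics exactly.
#'
#' @return directory path within the installed package.
#' @export
toyExampleDir <- function() {
    system.file("extdata", "toy", package = "perDriveR", mustWork = TRUE)
}
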