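# Synthetic paired miRNA/mRNA data with planted ground truth, emulating a
# 4 time-point x 4 replicate postnatal time course: NB counts with
# per-sample size factors, planted fold-change trajectories, repressive
# miRNA->gene edges whose targets move oppositely, decoy predicted edges,
# and gene sets enriched among true targets. Everything is deterministic
# given the seed.

.trajectoryTemplates <- c("early_down", "mid_down", "late_up", "transient")

#' Configuration for the synthetic-data generator
#'
#' Defaults emulate the study design the package targets: four postnatal
#' time points (P01, P04, P09, P23) with four replicates each, a few
#' hundred miRNAs passing the expression floor, ~15% of them planted as
#' differentially expressed along one of four trajectory templates
#' (\code{early_down}: down from the P04-P01 window onward;
#' \code{mid_down}: from P09-P04; \code{late_up}: from P23-P09;
#' \code{transient}: down in P09-P04 only, half-recovered by P23), each
#' with at least \code{minTrueTargets} repressive edges to
#' oppositely-regulated genes plus uniform decoy predictions.
#'
#' @param nMirna number of miRNA features (default 240).
#' @param nGene number of genes in the transcriptome (default 3000).
#' @param timePoints ordered time-point labels.
#' @param replicates samples per time point (default 4).
#' @param fractionDE fraction of miRNAs planted DE (default 0.15).
#' @param lfcRange range of planted |log2FC| (default c(1.5, 2.5)).
#' @param templateWeights sampling weights for the four trajectory
#'   templates, in the order early_down, mid_down, late_up, transient
#'   (default roughly the composition reported for neonatal heart:
#'   c(0.20, 0.28, 0.47, 0.05)).
#' @param meanLog,sdLog log-normal parameters of baseline mean counts
#'   (defaults log(1500), 0.6).
#' @param minPlantedMean floor on planted-DE baseline means (default 500,
#'   keeping planted features above the low-count filter).
#' @param phiMeanLog,phiSdLog log-normal parameters of the NB dispersion
#'   (defaults log(0.05), 0.4).
#' @param fractionGeneDE fraction of genes DE per direction in the mRNA
#'   table (default 0.12 up + 0.12 down).
#' @param minTrueTargets true repressive edges per planted miRNA
#'   (default 60).
#' @param decoyRate decoy predicted edges per true edge (default 1.0).
#' @param nBackgroundSets random background gene sets (default 60).
#' @param plantedSetSize size of each planted enriched set (default 50).
#' @param plantedSetPurity fraction of a planted set drawn from its
#'   miRNA's true targets (default 0.7).
#' @param backgroundSetSize size range of background sets (default
#'   c(25, 80)).
#' @param seed integer RNG seed.
#' @return a list of class \code{"generatorConfig"}.
#' @export
generatorConfig <- function(nMirna = 240, nGene = 3000,
                            timePoints = c("P01", "P04", "P09", "P23"),
                            replicates = 4, fractionDE = 0.15,
                            lfcRange = c(1.5, 2.5),
                            templateWeights = c(0.20, 0.28, 0.47, 0.05),
                            meanLog = log(1500), sdLog = 0.6,
                            minPlantedMean = 500,
                            phiMeanLog = log(0.05), phiSdLog = 0.4,
                            fractionGeneDE = 0.12,
                            minTrueTargets = 60, decoyRate = 1.0,
                            nBackgroundSets = 60, plantedSetSize = 50,
                            plantedSetPurity = 0.7,
                            backgroundSetSize = c(25, 80), seed = 1) {
    cfg <- as.list(environment())
    stopifnot(nMirna > 0, nGene > 0, replicates >= 2,
              fractionDE >= 0, fractionDE <= 1,
              fractionGeneDE > 0, fractionGeneDE <= 0.5,
              minTrueTargets >= 1, decoyRate >= 0,
              plantedSetPurity >= 0, plantedSetPurity <= 1)
    structure(cfg, class = "generatorConfig")
}

.templateMultipliers <- function(template, lfc) {
    r <- 2^(-lfc)
    switch(template,
           early_down = c(1, r, r, r),
           mid_down   = c(1, 1, r, r),
           late_up    = c(1, 1, 1, 2^lfc),
           transient  = c(1, 1, r, 2^(-lfc / 2)),
           stop(sprintf("unknown template '%s'", template)))
}

# comparisons (as later-earlier labels) in which a template is truly DE,
# given the default 4-point plan; direction is the template's direction
.templateTruth <- function(template, tpo) {
    adj <- comparisonLabel(tpo[-1L], tpo[-4L])
    lr <- comparisonLabel(tpo[c(3, 4)], tpo[c(1, 1)])
    switch(template,
           early_down = list(first = adj[1L], direction = "down",
                             de = c(adj[1L], lr)),
           mid_down   = list(first = adj[2L], direction = "down",
                             de = c(adj[2L], lr)),
           late_up    = list(first = adj[3L], direction = "up",
                             de = c(adj[3L], lr[2L])),
           transient  = list(first = adj[2L], direction = "down",
                             de = c(adj[2L], lr[1L])))
}

#' Generate a synthetic paired miRNA/mRNA experiment
#'
#' Draws NB miRNA counts along planted trajectories, a differential mRNA
#' gene table whose planted-target genes move opposite to their miRNAs, a
#' predicted-target table (true repressive edges + decoys), a gene-set
#' collection with one planted set per planted miRNA, and the full ground
#' truth. The same config and seed reproduce the output exactly.
#'
#' @param config a \code{\link{generatorConfig}}.
#' @return list with elements \code{mirna}
#'   (\linkS4class{MirCountExperiment}), \code{mrna} (differential gene
#'   table data.frame), \code{predicted} (\code{PredictedTargets}),
#'   \code{geneSets} (\linkS4class{GeneSetCollection}), \code{universe}
#'   (all gene ids) and \code{truth} (see below). \code{truth} holds
#'   \code{mirna} (per-feature template/direction/lfc/mean/phi and true DE
#'   comparisons), \code{trueEdges}, \code{decoyEdges},
#'   \code{plantedSets}, \code{meanMatrix} and the config.
#' @examples
#' sim <- simulateExperiment(generatorConfig(nMirna = 60, nGene = 500,
#'                                           minTrueTargets = 20, seed = 7))
#' table(sim$truth$mirna$template)
#' @export
simulateExperiment <- function(config = generatorConfig()) {
    stopifnot(inherits(config, "generatorConfig"))
    set.seed(config$seed)
    tpo <- config$timePoints
    nT <- length(tpo)
    if (nT != 4L)
        stop("the trajectory templates assume 4 time points")
    mirIds <- sprintf("syn-miR-%03d", seq_len(config$nMirna))
    geneIds <- sprintf("GENE%04d", seq_len(config$nGene))

    ## planted miRNAs and trajectories
    nDE <- round(config$fractionDE * config$nMirna)
    deIdx <- if (nDE > 0) sort(sample.int(config$nMirna, nDE)) else integer(0)
    template <- rep(NA_character_, config$nMirna)
    if (nDE > 0)
        template[deIdx] <- sample(.trajectoryTemplates, nDE, replace = TRUE,
                                  prob = config$templateWeights)
    lfc <- rep(0, config$nMirna)
    lfc[deIdx] <- stats::runif(nDE, config$lfcRange[1L], config$lfcRange[2L])
    # a transient dip can only stay "ns" in both P23 comparisons when the
    # half-recovered level sits inside the (1/1.8, 1.8*2^-lfc) band, which
    # requires |log2FC| < 2*log2(1.8); cap transient effects there
    lfc[deIdx][template[deIdx] == "transient"] <-
        pmin(lfc[deIdx][template[deIdx] == "transient"], 1.55)
    mu0 <- stats::rlnorm(config$nMirna, config$meanLog, config$sdLog)
    mu0[deIdx] <- pmax(mu0[deIdx], config$minPlantedMean)
    phi <- stats::rlnorm(config$nMirna, config$phiMeanLog, config$phiSdLog)
    meanMatrix <- matrix(mu0, config$nMirna, nT,
                         dimnames = list(mirIds, tpo))
    for (i in deIdx)
        meanMatrix[i, ] <- mu0[i] * .templateMultipliers(template[i], lfc[i])

    ## NB counts with per-sample size factors
    sampleTp <- rep(tpo, each = config$replicates)
    sampleIds <- paste0(sampleTp, "_", rep(seq_len(config$replicates), nT))
    sf <- stats::rlnorm(length(sampleIds), 0, 0.1)
    counts <- matrix(0, config$nMirna, length(sampleIds),
                     dimnames = list(mirIds, sampleIds))
    for (j in seq_along(sampleIds))
        counts[, j] <- stats::rnbinom(config$nMirna,
                                      mu = sf[j] * meanMatrix[, sampleTp[j]],
                                      size = 1 / phi)
    mirna <- MirCountExperiment(counts, sampleTp, tpo)

    ## mRNA pools: disjoint up / down gene sets, DE in every comparison
    nPool <- round(config$fractionGeneDE * config$nGene)
    if (config$minTrueTargets > nPool)
        stop(sprintf(
            "config demands %d true edges per miRNA but only %d genes per direction pool",
            config$minTrueTargets, nPool))
    shuffled <- sample(geneIds)
    upPool <- sort(shuffled[seq_len(nPool)])
    downPool <- sort(shuffled[nPool + seq_len(nPool)])
    plan <- defaultComparisonPlan(tpo)
    allCmp <- c(plan$adjacent$comparison, plan$longRange$comparison)
    mrna <- do.call(rbind, lapply(allCmp, function(cmp) {
        pool <- c(upPool, downPool)
        data.frame(gene = pool, comparison = cmp,
                   direction = rep(c("up", "down"), c(length(upPool),
                                                      length(downPool))),
                   foldChange = 2^stats::runif(length(pool), 0.85, 3),
                   fdr = 10^stats::runif(length(pool), -6, -2.2),
                   stringsAsFactors = FALSE)
    }))

    ## true repressive edges: planted-down miRNA -> up genes, and vice versa
    trueEdges <- decoyEdges <- list()
    for (i in deIdx) {
        info <- .templateTruth(template[i], tpo)
        oppPool <- if (info$direction == "down") upPool else downPool
        tg <- sort(sample(oppPool, config$minTrueTargets))
        trueEdges[[mirIds[i]]] <- tg
        nDecoy <- round(config$decoyRate * length(tg))
        if (nDecoy > 0)
            decoyEdges[[mirIds[i]]] <-
                sort(sample(setdiff(geneIds, tg), nDecoy))
    }
    predicted <- lapply(mirIds[deIdx], function(m)
        sort(unique(c(trueEdges[[m]], decoyEdges[[m]]))))
    names(predicted) <- mirIds[deIdx]
    predicted <- structure(predicted[order(names(predicted))],
                           class = "PredictedTargets")

    ## gene sets: one planted set per planted miRNA + random background
    ccNames <- c("mitochondrion", "mitochondrial inner membrane",
                 "mitochondrial matrix", "nucleus", "cytosol",
                 "plasma membrane", "endoplasmic reticulum", "ribosome")
    setId <- setName <- category <- character(0)
    genes <- list()
    plantedSets <- data.frame(miRNA = character(0), setId = character(0),
                              stringsAsFactors = FALSE)
    for (i in deIdx) {
        sid <- sprintf("SETP_%s", mirIds[i])
        nFromTargets <- round(config$plantedSetPurity * config$plantedSetSize)
        members <- unique(c(
            sample(trueEdges[[mirIds[i]]],
                   min(nFromTargets, length(trueEdges[[mirIds[i]]]))),
            sample(geneIds, config$plantedSetSize - nFromTargets)))
        setId <- c(setId, sid)
        setName <- c(setName, sprintf("planted pathway %s", mirIds[i]))
        category <- c(category, "GO_BP")
        genes <- c(genes, list(sort(members)))
        plantedSets <- rbind(plantedSets,
                             data.frame(miRNA = mirIds[i], setId = sid,
                                        stringsAsFactors = FALSE))
    }
    for (b in seq_len(config$nBackgroundSets)) {
        sz <- sample(seq(config$backgroundSetSize[1L],
                         config$backgroundSetSize[2L]), 1L)
        setId <- c(setId, sprintf("SETB_%03d", b))
        cat_b <- c("GO_BP", "GO_CC", "KEGG")[1L + (b %% 3L)]
        setName <- c(setName, if (cat_b == "GO_CC")
            ccNames[1L + (b %% length(ccNames))] else
            sprintf("background pathway %03d", b))
        category <- c(category, cat_b)
        genes <- c(genes, list(sort(sample(geneIds, sz))))
    }
    geneSets <- GeneSetCollection(setId, setName, category, genes)

    truthMir <- data.frame(
        miRNA = mirIds, planted = seq_len(config$nMirna) %in% deIdx,
        template = template, lfc = lfc, baselineMean = mu0, phi = phi,
        direction = NA_character_, firstComparison = NA_character_,
        deComparisons = NA_character_, stringsAsFactors = FALSE)
    for (i in deIdx) {
        info <- .templateTruth(template[i], tpo)
        truthMir$direction[i] <- info$direction
        truthMir$firstComparison[i] <- info$first
        truthMir$deComparisons[i] <- paste(info$de, collapse = ",")
    }
    truth <- list(
        mirna = truthMir,
        trueEdges = data.frame(
            miRNA = rep(names(trueEdges), lengths(trueEdges)),
            gene = unlist(trueEdges, use.names = FALSE),
            stringsAsFactors = FALSE),
        decoyEdges = data.frame(
            miRNA = rep(names(decoyEdges), lengths(decoyEdges)),
            gene = unlist(decoyEdges, use.names = FALSE),
            stringsAsFactors = FALSE),
        plantedSets = plantedSets,
        upPool = upPool, downPool = downPool,
        meanMatrix = meanMatrix, sizeFactors = sf, seed = config$seed,
        config = unclass(config))
    list(mirna = mirna, mrna = mrna, predicted = predicted,
         geneSets = geneSets, universe = geneIds, truth = truth)
}

#' Generate a synthetic qPCR plate from planted truth
#'
#' Builds a plate for selected planted miRNAs with \code{Cq = cqBase -
#' log2(relative abundance) + N(0, noiseSd)}, two flat reference assays
#' and two flat spike-ins. With zero noise, a planted 4-fold increase
#' yields a ddCt of exactly -2.
#'
#' @param truth the \code{truth} element of
#'   \code{\link{simulateExperiment}} output.
#' @param targets miRNA ids to assay (default: up to 8 planted miRNAs).
#' @param noiseSd Gaussian Cq noise SD in cycles (default 0.15; must be
#'   >= 0).
#' @param replicates samples per group (default from the truth's config).
#' @param cqBase baseline Cq of targets at the first time point
#'   (default 24).
#' @param seed RNG seed (default: the truth's seed + 1).
#' @return a qPCR plate data.frame (see \code{\link{readQpcrPlate}}).
#' @export
simulateQpcrPlate <- function(truth, targets = NULL, noiseSd = 0.15,
                              replicates = NULL, cqBase = 24,
                              seed = NULL) {
    if (noiseSd < 0) stop("noiseSd must be >= 0")
    planted <- truth$mirna$miRNA[truth$mirna$planted]
    if (is.null(targets)) targets <- utils::head(planted, 8L)
    miss <- setdiff(targets, rownames(truth$meanMatrix))
    if (length(miss))
        stop(sprintf("no truth available for target '%s'", miss[1L]))
    if (is.null(replicates)) replicates <- truth$config$replicates
    if (is.null(seed)) seed <- truth$seed + 1L
    set.seed(seed)
    tpo <- colnames(truth$meanMatrix)
    rows <- list()
    for (tp in tpo) for (r in seq_len(replicates)) {
        s <- paste0(tp, "_", r)
        for (m in targets) {
            rel <- truth$meanMatrix[m, tp] / truth$meanMatrix[m, tpo[1L]]
            rows[[length(rows) + 1L]] <- data.frame(
                sample = s, assay = m,
                cq = cqBase - log2(rel) + stats::rnorm(1, 0, noiseSd),
                designation = "target", group = tp,
                stringsAsFactors = FALSE)
        }
        for (ref in c("ref-miR-A", "ref-miR-B"))
            rows[[length(rows) + 1L]] <- data.frame(
                sample = s, assay = ref,
                cq = (if (ref == "ref-miR-A") 18 else 20) +
                    stats::rnorm(1, 0, noiseSd),
                designation = "reference", group = tp,
                stringsAsFactors = FALSE)
        for (sp in c("UniSp3", "UniSp6"))
            rows[[length(rows) + 1L]] <- data.frame(
                sample = s, assay = sp,
                cq = (if (sp == "UniSp3") 15 else 16) +
                    stats::rnorm(1, 0, noiseSd),
                designation = "spike_in", group = tp,
                stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
}

#' Write the ground truth as JSON
#'
#' @param truth the truth list from \code{\link{simulateExperiment}}.
#' @param path output JSON path.
#' @export
writeTruth <- function(truth, path) {
    out <- truth
    out$meanMatrix <- NULL  # bulky; reproducible from config + seed
    jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    invisible(path)
}
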