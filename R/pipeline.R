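# End-to-end orchestration: low-count filter -> per-comparison DE ->
# temporal classification -> target verification -> eligibility gate ->
# enrichment -> network export, with a manifest (config hash, input
# checksums, output checksums) that makes a rerun reproducible
# byte-for-byte.

#' Assemble a pipeline configuration
#'
#' Thresholds default to the values the analysis is built around: linear
#' fold change >= 1.8, FDR <= 0.01, low-count floor 300, >= 40 verified
#' targets for enrichment eligibility, enrichment alpha 0.05.
#'
#' @param outDir output directory (created if needed).
#' @param countsPath,metadataPath,mrnaPath,predictedPath,gmtPaths input
#'   file paths (\code{gmtPaths}: named character vector, names =
#'   category). Omit all of them and set \code{synthetic = TRUE} to run
#'   on generated data.
#' @param synthetic logical; generate inputs with
#'   \code{\link{simulateExperiment}}.
#' @param generator a \code{\link{generatorConfig}} for synthetic mode.
#' @param timePointsOrder ordered time-point labels.
#' @param adjacent,longRange comparison plans (default
#'   \code{\link{defaultComparisonPlan}} of \code{timePointsOrder}).
#' @param fcThreshold,fdrAlpha,minMean,minTargets,alpha,epsilon thresholds
#'   (see module functions).
#' @param enrichMode \code{"fisher"} or \code{"ease"}.
#' @param universePolicy \code{"measured"} (mRNA-table genes intersected
#'   with annotated genes) or \code{"annotated"} (all collection genes).
#' @param mitoPattern term-name pattern for the mitochondria-associated
#'   GO:CC subnetwork export (default \code{"mitochondri"}).
#' @return list of class \code{"pipelineConfig"}.
#' @export
pipelineConfig <- function(outDir,
                           countsPath = NULL, metadataPath = NULL,
                           mrnaPath = NULL, predictedPath = NULL,
                           gmtPaths = NULL,
                           synthetic = is.null(countsPath),
                           generator = generatorConfig(),
                           timePointsOrder = c("P01", "P04", "P09", "P23"),
                           adjacent = NULL, longRange = NULL,
                           fcThreshold = 1.8, fdrAlpha = 0.01,
                           minMean = 300, minTargets = 40, alpha = 0.05,
                           epsilon = 0.5,
                           enrichMode = c("fisher", "ease"),
                           universePolicy = c("measured", "annotated"),
                           mitoPattern = "mitochondri") {
    plan <- defaultComparisonPlan(timePointsOrder)
    cfg <- list(outDir = outDir, countsPath = countsPath,
                metadataPath = metadataPath, mrnaPath = mrnaPath,
                predictedPath = predictedPath, gmtPaths = gmtPaths,
                synthetic = synthetic, generator = generator,
                timePointsOrder = timePointsOrder,
                adjacent = if (is.null(adjacent)) plan$adjacent else adjacent,
                longRange = if (is.null(longRange)) plan$longRange else
                    longRange,
                fcThreshold = fcThreshold, fdrAlpha = fdrAlpha,
                minMean = minMean, minTargets = minTargets, alpha = alpha,
                epsilon = epsilon, enrichMode = match.arg(enrichMode),
                universePolicy = match.arg(universePolicy),
                mitoPattern = mitoPattern)
    stopifnot(fcThreshold >= 1, fdrAlpha > 0, fdrAlpha <= 1, minMean >= 0,
              minTargets >= 1, alpha > 0, alpha <= 1)
    structure(cfg, class = "pipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of \code{\link{pipelineConfig}}; the
#' \code{generator} key holds \code{\link{generatorConfig}} arguments.
#'
#' @param path YAML file path.
#' @return a \code{"pipelineConfig"}.
#' @export
readPipelineConfig <- function(path) {
    y <- yaml::read_yaml(path)
    gen <- do.call(generatorConfig, if (is.null(y$generator)) list() else
        y$generator)
    y$generator <- gen
    do.call(pipelineConfig, y)
}

.md5String <- function(x) {
    tf <- tempfile()
    on.exit(unlink(tf))
    writeLines(x, tf)
    unname(tools::md5sum(tf))
}

.logStage <- function(stage, quiet) {
    if (!quiet) message(sprintf("[mirTarNet] stage: %s", stage))
}

#' Run the full pipeline
#'
#' Stages run in order: input loading (or synthetic generation), per-
#' comparison differential expression, temporal pattern classification,
#' per-comparison target verification, eligibility gating, enrichment of
#' eligible miRNAs, network assembly and chord/Sankey export (full network
#' plus the mitochondria-pattern GO:CC subnetwork), and a JSON manifest.
#' A stage failure aborts with the stage name. Rerunning with the same
#' config and inputs reproduces every output byte.
#'
#' @param config a \code{"pipelineConfig"} or path to its YAML form.
#' @param quiet suppress stage messages.
#' @return invisibly, a list with all in-memory stage results and
#'   \code{manifest}.
#' @export
runPipeline <- function(config, quiet = FALSE) {
    if (is.character(config)) config <- readPipelineConfig(config)
    stopifnot(inherits(config, "pipelineConfig"))
    out <- config$outDir
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    stage <- "inputs"
    res <- tryCatch({
        inputChecksums <- character(0)
        if (config$synthetic) {
            sim <- simulateExperiment(config$generator)
            mirna <- sim$mirna; mrna <- sim$mrna
            predicted <- sim$predicted; geneSets <- sim$geneSets
            universeAll <- sim$universe
            dir.create(file.path(out, "inputs"), showWarnings = FALSE)
            writeCountMatrix(mirna, file.path(out, "inputs", "mirna_counts.tsv"))
            writeSampleMetadata(
                data.frame(sample = colnames(mirna),
                           timePoint = as.character(timePoints(mirna))),
                file.path(out, "inputs", "sample_metadata.tsv"))
            writeDifferentialGeneTable(mrna,
                file.path(out, "inputs", "mrna_differential.tsv"))
            writePredictedTargets(predicted,
                file.path(out, "inputs", "predicted_targets.tsv"))
            writeGmt(geneSets, file.path(out, "inputs", "gene_sets.gmt"))
            writeTruth(sim$truth, file.path(out, "inputs", "truth.json"))
        } else {
            for (p in c(config$countsPath, config$metadataPath,
                        config$mrnaPath, config$predictedPath,
                        config$gmtPaths))
                if (!file.exists(p)) stop(sprintf("input not found: %s", p))
            mirna <- readMirCountExperiment(config$countsPath,
                                            config$metadataPath,
                                            config$timePointsOrder)
            if (is.null(config$mrnaPath))
                stop("target_integration prerequisite: mRNA table path missing")
            mrna <- readDifferentialGeneTable(config$mrnaPath)
            predicted <- readPredictedTargets(config$predictedPath)
            gs <- lapply(seq_along(config$gmtPaths), function(i)
                readGmt(config$gmtPaths[i],
                        category = names(config$gmtPaths)[i]))
            geneSets <- Reduce(function(a, b) GeneSetCollection(
                c(a@setId, b@setId), c(a@setName, b@setName),
                c(a@category, b@category), c(a@genes, b@genes)), gs)
            universeAll <- NULL
            sim <- NULL
            paths <- c(config$countsPath, config$metadataPath,
                       config$mrnaPath, config$predictedPath,
                       config$gmtPaths)
            inputChecksums <- stats::setNames(tools::md5sum(paths), paths)
        }

        stage <- "diffexpr"
        .logStage(stage, quiet)
        plan <- rbind(config$adjacent, config$longRange)
        sf <- sizeFactors(mirna)
        disp <- estimateDispersions(mirna, sf = sf)
        deDir <- file.path(out, "differential")
        dir.create(deDir, showWarnings = FALSE)
        results <- list()
        for (i in seq_len(nrow(plan))) {
            r <- callDifferential(mirna, plan$later[i], plan$earlier[i],
                                  fcThreshold = config$fcThreshold,
                                  fdrAlpha = config$fdrAlpha,
                                  minMean = config$minMean,
                                  epsilon = config$epsilon,
                                  dispersions = disp, sf = sf)
            results[[plan$comparison[i]]] <- r
            writeDifferentialResult(r, file.path(
                deDir, paste0(plan$comparison[i], ".tsv")))
        }

        stage <- "temporal_patterns"
        .logStage(stage, quiet)
        patterns <- classifyPatterns(results, config$adjacent,
                                     config$longRange,
                                     config$timePointsOrder)
        writePatterns(patterns, file.path(out, "temporal_patterns.tsv"))
        summary <- patternSummary(patterns, plan$comparison)
        .writeTsv(summary, file.path(out, "pattern_summary.tsv"))

        stage <- "target_integration"
        .logStage(stage, quiet)
        if (is.null(mrna))
            stop("target_integration prerequisite: mRNA table missing")
        verified <- list()
        for (cmp in plan$comparison) {
            calls <- as.data.frame(results[[cmp]])
            calls <- calls[calls$direction %in% c("up", "down"), ,
                           drop = FALSE]
            if (!nrow(calls)) next
            v <- verifyTargets(predicted, mrna, calls, cmp)
            verified[[cmp]] <- filterMinTargets(v, config$minTargets)
        }
        vAll <- if (length(verified)) do.call(rbind, unname(verified)) else
            filterMinTargets(verifyTargets(
                structure(list(), class = "PredictedTargets"), mrna,
                data.frame(feature = character(0),
                           direction = character(0)), "none"),
                config$minTargets)
        writeVerifiedTargets(vAll, file.path(out, "verified_targets.tsv"),
                             file.path(out, "verified_targets_summary.tsv"))

        stage <- "enrichment"
        .logStage(stage, quiet)
        universe <- if (config$universePolicy == "measured")
            defaultUniverse(mrna, geneSets) else
            sort(unique(unlist(geneSets@genes, use.names = FALSE)))
        records <- enrichAll(vAll, geneSets, universe,
                             alpha = config$alpha, mode = config$enrichMode)
        writeEnrichment(records, file.path(out, "enrichment.tsv"))

        stage <- "network_export"
        .logStage(stage, quiet)
        network <- suppressWarnings(buildNetwork(records))
        exportChord(network, file.path(out, "network_chord.tsv"))
        exportSankey(network, file.path(out, "network_sankey.json"))
        mito <- subnetworkByTermPattern(network, config$mitoPattern)
        mito$termNodes <- mito$termNodes[
            mito$termNodes$category == "GO_CC", , drop = FALSE]
        mito$edges <- mito$edges[mito$edges$setId %in%
                                 mito$termNodes$setId, , drop = FALSE]
        mito$mirnaNodes <- mito$mirnaNodes[
            mito$mirnaNodes$miRNA %in% mito$edges$miRNA, , drop = FALSE]
        exportSankey(mito, file.path(out, "network_mito_cc_sankey.json"))
        if (nrow(network$edges) == 0L && !quiet)
            message("[mirTarNet] empty network (no significant enrichment)")

        stage <- "manifest"
        .logStage(stage, quiet)
        cfgYaml <- yaml::as.yaml(.configForHash(config))
        outputs <- sort(setdiff(
            list.files(out, recursive = TRUE, full.names = FALSE),
            "manifest.json"))
        manifest <- list(
            tool = "mirTarNet",
            version = as.character(utils::packageVersion("mirTarNet")),
            configHash = .md5String(cfgYaml),
            inputChecksums = as.list(inputChecksums),
            outputs = stats::setNames(
                as.list(unname(tools::md5sum(file.path(out, outputs)))),
                outputs))
        jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                             auto_unbox = TRUE, pretty = TRUE)
        list(config = config, mirna = mirna, results = results,
             patterns = patterns, summary = summary, verified = vAll,
             enrichment = records, network = network, mito = mito,
             truth = if (config$synthetic) sim$truth else NULL,
             manifest = manifest)
    }, error = function(e)
        stop(sprintf("pipeline stage '%s' failed: %s", stage,
                     conditionMessage(e)), call. = FALSE))
    invisible(res)
}

# config serialized for hashing: keep the values that determine the
# output bytes; outDir only says where they land, so it is excluded
.configForHash <- function(config) {
    cfg <- unclass(config)
    cfg$generator <- unclass(cfg$generator)
    cfg$outDir <- NULL
    cfg
}
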