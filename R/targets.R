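# Anti-correlation target verification: a predicted target of an
# upregulated miRNA counts as "verified" iff the gene is downregulated in
# the matching mRNA comparison, and vice versa. miRNAs with fewer than
# minTargets verified genes are flagged ineligible for enrichment (they
# are kept, not deleted).

#' Verify predicted miRNA targets against differential mRNA calls
#'
#' For every differentially expressed miRNA, intersects its predicted
#' target genes with the mRNA genes moving in the opposite direction in
#' the same comparison. miRNAs for which the prediction database offers no
#' entry get an empty set flagged \code{noPrediction}.
#'
#' @param predicted \code{PredictedTargets} named list (see
#'   \code{\link{readPredictedTargets}}).
#' @param mrna differential mRNA gene table (see
#'   \code{\link{readDifferentialGeneTable}}); only rows of
#'   \code{comparison} are used unless \code{pool = TRUE}.
#' @param mirnaCalls a \linkS4class{DifferentialResult} (or data.frame
#'   with \code{feature}, \code{direction}) for the miRNA side of the same
#'   comparison; only \code{up}/\code{down} rows may be passed.
#' @param comparison comparison label (e.g. \code{"P09-P04"}).
#' @param pool logical; if TRUE the mRNA calls are pooled across all
#'   comparisons in \code{mrna} instead of matched per comparison.
#' @return \code{DataFrame} with one row per DE miRNA: \code{miRNA},
#'   \code{direction}, \code{comparison}, \code{verified}
#'   (\code{CharacterList}), \code{nVerified}, \code{noPrediction}.
#' @examples
#' pred <- structure(list(m1 = c("GA", "GB", "GC")),
#'                   class = "PredictedTargets")
#' mrna <- data.frame(gene = c("GB", "GC", "GD"), comparison = "P04-P01",
#'                    direction = "down", foldChange = 2, fdr = 0.001)
#' calls <- data.frame(feature = "m1", direction = "up")
#' verifyTargets(pred, mrna, calls, "P04-P01")
#' @export
verifyTargets <- function(predicted, mrna, mirnaCalls, comparison,
                          pool = FALSE) {
    calls <- as.data.frame(mirnaCalls)[, c("feature", "direction")]
    if (any(!calls$direction %in% c("up", "down")))
        stop(paste("only differentially expressed miRNAs (direction up/down)",
                   "can be integrated; filter out 'ns' rows first"))
    if (!pool) {
        mrna <- mrna[mrna$comparison == comparison, , drop = FALSE]
    }
    mrnaUp <- unique(normalizeGeneId(mrna$gene[mrna$direction == "up"]))
    mrnaDown <- unique(normalizeGeneId(mrna$gene[mrna$direction == "down"]))
    verified <- vector("list", nrow(calls))
    noPred <- logical(nrow(calls))
    for (i in seq_len(nrow(calls))) {
        pred <- predictedFor(predicted, calls$feature[i])
        if (is.null(pred)) {
            verified[[i]] <- character(0)
            noPred[i] <- TRUE
        } else {
            opp <- if (calls$direction[i] == "up") mrnaDown else mrnaUp
            verified[[i]] <- sort(intersect(normalizeGeneId(pred), opp))
        }
    }
    DataFrame(miRNA = calls$feature, direction = calls$direction,
              comparison = rep(comparison, nrow(calls)),
              verified = IRanges::CharacterList(verified),
              nVerified = lengths(verified), noPrediction = noPred)
}

#' Flag verified target sets eligible for enrichment
#'
#' Adds an \code{eligible} column: TRUE iff \code{nVerified >=
#' minTargets}. Nothing is removed.
#'
#' @param sets \code{DataFrame} from \code{\link{verifyTargets}}.
#' @param minTargets minimum number of verified targets (default 40).
#' @return the input with an \code{eligible} logical column.
#' @export
filterMinTargets <- function(sets, minTargets = 40) {
    if (minTargets < 1) stop("minTargets must be >= 1")
    sets$eligible <- sets$nVerified >= minTargets
    sets
}

#' Write verified target sets to TSV
#'
#' Emits the long-format (miRNA, comparison, gene) table and, optionally,
#' the per-miRNA summary with counts and eligibility.
#'
#' @param sets \code{DataFrame} from \code{\link{verifyTargets}} /
#'   \code{\link{filterMinTargets}}.
#' @param path long-format output path.
#' @param summaryPath optional summary output path.
#' @export
writeVerifiedTargets <- function(sets, path, summaryPath = NULL) {
    long <- data.frame(
        miRNA = rep(sets$miRNA, sets$nVerified),
        comparison = rep(sets$comparison, sets$nVerified),
        gene = unlist(as.list(sets$verified), use.names = FALSE),
        stringsAsFactors = FALSE)
    .writeTsv(long, path)
    if (!is.null(summaryPath)) {
        summ <- as.data.frame(sets[, setdiff(colnames(sets), "verified")])
        .writeTsv(summ, summaryPath)
    }
    invisible(path)
}
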