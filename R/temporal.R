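# Bookkeeping of differential-expression trajectories across the ordered
# adjacent comparisons (plus long-range comparisons): each miRNA is listed
# at the first comparison in which it is differentially expressed, then
# classified as persistent, transient, non-monotone or mixed from the
# comparisons that look beyond that first window.

#' Build a comparison plan
#'
#' @param later,earlier time-point labels (vectors of equal length).
#' @return data.frame with columns \code{comparison}, \code{later},
#'   \code{earlier}.
#' @export
comparisonPlan <- function(later, earlier) {
    data.frame(comparison = comparisonLabel(later, earlier),
               later = later, earlier = earlier, stringsAsFactors = FALSE)
}

#' Default comparison plan for a four-point time course
#'
#' Adjacent windows plus the two long-range comparisons against the first
#' time point.
#'
#' @param tpo ordered time-point labels (default P01, P04, P09, P23).
#' @return list with elements \code{adjacent} and \code{longRange}, each a
#'   \code{comparisonPlan} data.frame.
#' @export
defaultComparisonPlan <- function(tpo = c("P01", "P04", "P09", "P23")) {
    list(adjacent = comparisonPlan(tpo[-1L], tpo[-length(tpo)]),
         longRange = comparisonPlan(tpo[c(3L, 4L)], tpo[c(1L, 1L)]))
}

.directionMatrix <- function(results, comparisons) {
    miss <- setdiff(comparisons, names(results))
    if (length(miss))
        stop(sprintf("missing comparison table: %s", miss[1L]))
    feats <- sort(unique(unlist(lapply(results[comparisons],
                                       function(r) r$feature))))
    dir <- matrix("ns", length(feats), length(comparisons),
                  dimnames = list(feats, comparisons))
    for (cmp in comparisons) {
        r <- results[[cmp]]
        dir[match(r$feature, feats), cmp] <- r$direction
    }
    dir
}

#' Classify temporal differential-expression patterns
#'
#' For each miRNA, finds the first comparison (scanning \code{adjacent} in
#' order, then \code{longRange} if \code{firstFromLongRange}) with a
#' non-\code{ns} direction; that comparison and its direction define the
#' miRNA's pattern. Comparisons whose later time point lies beyond the
#' first hit's later point ("beyond" comparisons) then decide:
#' \itemize{
#'   \item \strong{non_monotone}: the opposite direction appears in any
#'     comparison;
#'   \item \strong{transient}: every beyond comparison is \code{ns} (the
#'     miRNA was differentially expressed only around its first window);
#'   \item \strong{persistent}: every available \emph{cumulative}
#'     comparison -- a beyond comparison whose baseline (earlier point) is
#'     at or before the first hit's baseline -- shows the same direction;
#'   \item \strong{mixed} otherwise.
#' }
#'
#' @param results named list of \linkS4class{DifferentialResult} (or
#'   data.frames with \code{feature} and \code{direction}), keyed by
#'   comparison label.
#' @param adjacent,longRange \code{comparisonPlan} data.frames; adjacent
#'   rows must be in time order.
#' @param timePointsOrder ordered time-point labels.
#' @param firstFromLongRange logical; whether long-range comparisons may
#'   define the first hit (default FALSE: they only inform
#'   persistence).
#' @return data.frame with one row per miRNA: \code{miRNA},
#'   \code{firstComparison} (NA if never DE), \code{direction},
#'   \code{persistent}, \code{transient}, \code{category} and
#'   \code{supportingComparisons} (comma-joined comparisons sharing the
#'   direction).
#' @export
classifyPatterns <- function(results, adjacent, longRange = NULL,
                             timePointsOrder, firstFromLongRange = FALSE) {
    allPlan <- rbind(adjacent, if (!is.null(longRange)) longRange)
    dir <- .directionMatrix(results, allPlan$comparison)
    idx <- function(tp) match(tp, timePointsOrder)
    firstOrder <- if (firstFromLongRange) allPlan else adjacent
    out <- lapply(rownames(dir), function(mir) {
        d <- dir[mir, ]
        firstHit <- which(d[firstOrder$comparison] != "ns")
        if (!length(firstHit))
            return(data.frame(miRNA = mir, firstComparison = NA_character_,
                              direction = NA_character_, persistent = FALSE,
                              transient = FALSE, category = "none",
                              supportingComparisons = "",
                              stringsAsFactors = FALSE))
        fc <- firstOrder[firstHit[1L], ]
        direction <- d[[fc$comparison]]
        beyond <- allPlan$comparison[idx(allPlan$later) > idx(fc$later)]
        cumulative <- allPlan$comparison[idx(allPlan$later) > idx(fc$later) &
                                         idx(allPlan$earlier) <= idx(fc$earlier)]
        opposite <- setdiff(c("up", "down"), direction)
        nonMono <- any(d == opposite)
        transient <- !nonMono && length(beyond) > 0 &&
            all(d[beyond] == "ns")
        persistent <- !nonMono && !transient &&
            all(d[cumulative] == direction)
        category <- if (nonMono) "non_monotone" else if (transient)
            "transient" else if (persistent) "persistent" else "mixed"
        data.frame(miRNA = mir, firstComparison = fc$comparison,
                   direction = direction, persistent = persistent,
                   transient = transient, category = category,
                   supportingComparisons = paste(
                       allPlan$comparison[d[allPlan$comparison] == direction],
                       collapse = ","),
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

#' Per-comparison summary of classified patterns
#'
#' @param patterns data.frame from \code{\link{classifyPatterns}}.
#' @param comparisons character vector of comparison labels to summarize.
#' @return data.frame with one row per comparison: \code{comparison},
#'   \code{nUp}, \code{nDown} (miRNAs differentially expressed in that
#'   comparison, by direction) and \code{nNew} (miRNAs whose first hit is
#'   that comparison).
#' @export
patternSummary <- function(patterns, comparisons) {
    supp <- strsplit(patterns$supportingComparisons, ",", fixed = TRUE)
    out <- lapply(comparisons, function(cmp) {
        inCmp <- vapply(supp, function(s) cmp %in% s, TRUE)
        data.frame(comparison = cmp,
                   nUp = sum(inCmp & patterns$direction == "up", na.rm = TRUE),
                   nDown = sum(inCmp & patterns$direction == "down",
                               na.rm = TRUE),
                   nNew = sum(patterns$firstComparison == cmp, na.rm = TRUE),
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

#' @rdname classifyPatterns
#' @param path output TSV path.
#' @export
writePatterns <- function(patterns, path) .writeTsv(patterns, path)
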