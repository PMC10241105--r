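#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom stats median pnorm pchisq sd var rnbinom rnorm rlnorm runif
#' @importFrom utils read.delim write.table packageVersion head
NULL

#' Container for a miRNA count matrix with ordered time-point metadata
#'
#' \code{MirCountExperiment} extends
#' \linkS4class{SummarizedExperiment} with a single \code{"counts"} assay of
#' non-negative integers and a \code{timePoint} column in \code{colData}.
#' The ordered vector of time-point labels (e.g. \code{c("P01","P04","P09",
#' "P23")} for postnatal days 1, 4, 9 and 23) lives in
#' \code{metadata(x)$timePointsOrder} and defines which comparisons are
#' "later vs earlier".
#'
#' @slot .. inherits all slots from \code{SummarizedExperiment}.
#' @seealso \code{\link{MirCountExperiment}} (constructor),
#'   \code{\link{timePoints}}, \code{\link{timePointsOrder}}
#' @exportClass MirCountExperiment
setClass("MirCountExperiment", contains = "SummarizedExperiment")

setValidity("MirCountExperiment", function(object) {
    msg <- character(0)
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        return("assay 'counts' is missing")
    counts <- SummarizedExperiment::assay(object, "counts")
    if (ncol(counts) < 1L)
        msg <- c(msg, "no samples: at least one sample is required")
    if (is.null(rownames(counts)) || is.null(colnames(counts)))
        msg <- c(msg, "counts must carry feature (row) and sample (column) names")
    if (!is.null(rownames(counts)) && anyDuplicated(rownames(counts)))
        msg <- c(msg, sprintf("duplicate feature id: %s",
                              rownames(counts)[duplicated(rownames(counts))][1L]))
    if (!is.null(colnames(counts)) && anyDuplicated(colnames(counts)))
        msg <- c(msg, sprintf("duplicate sample id: %s",
                              colnames(counts)[duplicated(colnames(counts))][1L]))
    if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
        msg <- c(msg, "counts must be finite non-negative integers")
    tpo <- S4Vectors::metadata(object)$timePointsOrder
    if (!is.null(object$timePoint)) {
        if (is.null(tpo))
            msg <- c(msg, "metadata(x)$timePointsOrder is missing")
        else if (!all(object$timePoint %in% tpo))
            msg <- c(msg, sprintf("time point '%s' not in timePointsOrder",
                                  setdiff(object$timePoint, tpo)[1L]))
    }
    if (length(msg)) msg else TRUE
})

#' Construct a MirCountExperiment
#'
#' @param counts integer matrix, features x samples, with row and column
#'   names.
#' @param timePoint character vector, one time-point label per sample
#'   (column of \code{counts}).
#' @param timePointsOrder character vector giving the labels in experimental
#'   order (earliest first).
#' @return a validated \linkS4class{MirCountExperiment}.
#' @examples
#' m <- matrix(rpois(8, 100), 2, 4,
#'             dimnames = list(c("miR-1","miR-2"), paste0("S", 1:4)))
#' mce <- MirCountExperiment(m, rep(c("P01","P04"), each = 2),
#'                           c("P01","P04"))
#' timePoints(mce)
#' @export
MirCountExperiment <- function(counts, timePoint, timePointsOrder) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "double"
    if (length(timePoint) != ncol(counts))
        stop("timePoint must have one entry per sample")
    se <- SummarizedExperiment(
        assays = SimpleList(counts = counts),
        colData = DataFrame(timePoint = as.character(timePoint),
                            row.names = colnames(counts)))
    S4Vectors::metadata(se)$timePointsOrder <- as.character(timePointsOrder)
    new("MirCountExperiment", se)
}

#' Per-feature differential expression results for one comparison
#'
#' A \code{DifferentialResult} extends \code{DFrame} (one row per feature)
#' with columns \code{feature}, per-time-point normalized base means,
#' \code{foldChange} (linear, later/earlier), \code{log2FoldChange},
#' \code{pvalue}, \code{fdr}, \code{direction} (\code{"up"}, \code{"down"}
#' or \code{"ns"}), \code{passedLowCountFilter} and \code{degenerate}.
#' The comparison and thresholds used are stored in \code{metadata()}.
#'
#' @exportClass DifferentialResult
setClass("DifferentialResult", contains = "DFrame")

setValidity("DifferentialResult", function(object) {
    need <- c("feature", "foldChange", "log2FoldChange", "pvalue", "fdr",
              "direction", "passedLowCountFilter")
    miss <- setdiff(need, colnames(object))
    if (length(miss))
        return(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
    if (!all(object$direction %in% c("up", "down", "ns")))
        return("direction must be one of up/down/ns")
    if (any(object$foldChange < 0, na.rm = TRUE))
        return("foldChange must be non-negative")
    TRUE
})

#' A collection of gene sets (GO/KEGG style)
#'
#' Lightweight container for named gene sets as exchanged in GMT format.
#' Each set has an identifier, a human-readable name, a category
#' (\code{GO_BP}, \code{GO_CC} or \code{KEGG}) and a character vector of
#' member gene ids.
#'
#' @slot setId character, unique set identifiers.
#' @slot setName character, display names (GMT description field).
#' @slot category character, one of \code{GO_BP}, \code{GO_CC}, \code{KEGG}.
#' @slot genes list of character vectors, parallel to \code{setId}.
#' @seealso \code{\link{readGmt}}, \code{\link{geneSets}}
#' @exportClass GeneSetCollection
setClass("GeneSetCollection",
         representation(setId = "character", setName = "character",
                        category = "character", genes = "list"))

setValidity("GeneSetCollection", function(object) {
    n <- length(object@setId)
    if (length(object@setName) != n || length(object@category) != n ||
        length(object@genes) != n)
        return("slots must be parallel (same length)")
    if (anyDuplicated(object@setId))
        return(sprintf("duplicate set id: %s",
                       object@setId[duplicated(object@setId)][1L]))
    if (n > 0 && any(lengths(object@genes) == 0L))
        return(sprintf("empty gene set: %s",
                       object@setId[lengths(object@genes) == 0L][1L]))
    if (!all(object@category %in% c("GO_BP", "GO_CC", "KEGG")))
        return("category must be GO_BP, GO_CC or KEGG")
    TRUE
})

#' Construct a GeneSetCollection
#'
#' @param setId,setName,category,genes parallel vectors/list describing the
#'   sets; see \linkS4class{GeneSetCollection}. \code{genes} entries are
#'   deduplicated.
#' @return a validated \linkS4class{GeneSetCollection}.
#' @export
GeneSetCollection <- function(setId, setName = setId,
                              category = rep("GO_BP", length(setId)),
                              genes) {
    genes <- lapply(genes, function(g) unique(as.character(g)))
    names(genes) <- setId
    new("GeneSetCollection", setId = as.character(setId),
        setName = as.character(setName), category = as.character(category),
        genes = genes)
}
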