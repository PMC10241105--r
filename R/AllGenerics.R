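#' Time-point label of each sample
#'
#' @param x a \linkS4class{MirCountExperiment}.
#' @return for \code{timePoints}, a factor with levels in experimental
#'   order; for \code{timePointsOrder}, the ordered character vector of
#'   labels.
#' @export
setGeneric("timePoints", function(x) standardGeneric("timePoints"))

#' @rdname timePoints
#' @export
setGeneric("timePointsOrder", function(x) standardGeneric("timePointsOrder"))

#' @rdname timePoints
#' @export
setMethod("timePoints", "MirCountExperiment", function(x) {
    factor(x$timePoint, levels = S4Vectors::metadata(x)$timePointsOrder)
})

#' @rdname timePoints
#' @export
setMethod("timePointsOrder", "MirCountExperiment", function(x) {
    S4Vectors::metadata(x)$timePointsOrder
})

#' Accessors for GeneSetCollection
#'
#' @param x a \linkS4class{GeneSetCollection}.
#' @return \code{geneSets} returns the named list of member-gene vectors;
#'   \code{setIds} the set identifiers; \code{setCategories} the categories.
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname geneSets
#' @export
setGeneric("setIds", function(x) standardGeneric("setIds"))

#' @rdname geneSets
#' @export
setGeneric("setCategories", function(x) standardGeneric("setCategories"))

#' @rdname geneSets
#' @export
setMethod("geneSets", "GeneSetCollection", function(x) x@genes)

#' @rdname geneSets
#' @export
setMethod("setIds", "GeneSetCollection", function(x) x@setId)

#' @rdname geneSets
#' @export
setMethod("setCategories", "GeneSetCollection",
          function(x) stats::setNames(x@category, x@setId))

#' @rdname geneSets
#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@setId))

#' @param object a \linkS4class{GeneSetCollection} or
#'   \linkS4class{MirCountExperiment}.
#' @rdname geneSets
#' @export
setMethod("show", "GeneSetCollection", function(object) {
    cat("GeneSetCollection with", length(object), "sets\n")
    if (length(object)) {
        tab <- table(object@category)
        cat(paste(sprintf("  %s: %d", names(tab), as.integer(tab)),
                  collapse = "\n"), "\n")
        cat("  set sizes:", min(lengths(object@genes)), "-",
            max(lengths(object@genes)), "genes\n")
    }
})

#' @rdname timePoints
#' @param object a \linkS4class{MirCountExperiment}.
#' @export
setMethod("show", "MirCountExperiment", function(object) {
    callNextMethod()
    cat("timePointsOrder:",
        paste(timePointsOrder(object), collapse = " < "), "\n")
})
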