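# Delta-delta-Ct relative quantification. Cq values (quantification
# cycles) are normalized per sample to the mean of the reference assays
# (dCt), group dCt means are compared to a control group (ddCt), and fold
# change is base^(-ddCt) with base 2 (no efficiency correction). Spike-in
# assays are quality controls only and never enter normalization.

#' Per-sample dCt normalization
#'
#' \eqn{\Delta Ct = Cq_{target} - mean(Cq_{references})} within each
#' sample. Every reference must have a finite Cq in every sample used;
#' targets with undetermined Cq yield an NA dCt flagged \code{missing}.
#'
#' @param plate qPCR plate data.frame (see \code{\link{readQpcrPlate}}).
#' @param referenceIds character vector of reference assay ids (e.g. the
#'   two housekeeping miRNAs used for normalization).
#' @return data.frame with \code{sample}, \code{assay}, \code{group},
#'   \code{deltaCt}, \code{missing} for every target assay.
#' @export
deltaCt <- function(plate, referenceIds) {
    if (!length(referenceIds)) stop("at least one reference assay required")
    refs <- plate[plate$assay %in% referenceIds, , drop = FALSE]
    targets <- plate[plate$designation == "target", , drop = FALSE]
    miss <- setdiff(referenceIds, refs$assay)
    if (length(miss))
        stop(sprintf("reference assay '%s' not on the plate", miss[1L]))
    for (s in unique(targets$sample)) {
        r <- refs[refs$sample == s, , drop = FALSE]
        bad <- setdiff(referenceIds, r$assay[is.finite(r$cq)])
        if (length(bad))
            stop(sprintf(
                "undetermined reference Cq: assay '%s' in sample '%s'",
                bad[1L], s))
    }
    refMean <- tapply(refs$cq[refs$assay %in% referenceIds],
                      refs$sample[refs$assay %in% referenceIds], mean)
    out <- data.frame(sample = targets$sample, assay = targets$assay,
                      group = targets$group,
                      deltaCt = targets$cq -
                          as.numeric(refMean[targets$sample]),
                      stringsAsFactors = FALSE)
    out$missing <- !is.finite(out$deltaCt)
    rownames(out) <- NULL
    out
}

#' Spike-in quality control
#'
#' Checks that every spike-in assay is present and that its Cq standard
#' deviation across samples stays below \code{maxSd}; spike-ins are never
#' used for normalization.
#'
#' @param plate qPCR plate data.frame.
#' @param maxSd flag threshold on the across-sample Cq SD (default 0.5
#'   cycles).
#' @return data.frame with \code{assay}, \code{sdCq}, \code{flagged}.
#' @export
spikeInQc <- function(plate, maxSd = 0.5) {
    sp <- plate[plate$designation == "spike_in", , drop = FALSE]
    if (!nrow(sp))
        return(data.frame(assay = character(0), sdCq = numeric(0),
                          flagged = logical(0)))
    sdv <- tapply(sp$cq, sp$assay, stats::sd)
    data.frame(assay = names(sdv), sdCq = as.numeric(sdv),
               flagged = as.numeric(sdv) > maxSd,
               stringsAsFactors = FALSE, row.names = NULL)
}

#' ddCt relative expression per group
#'
#' For each target assay and group, \eqn{\Delta\Delta Ct =
#' \overline{\Delta Ct}(group) - \overline{\Delta Ct}(control)} and fold
#' change \eqn{base^{-\Delta\Delta Ct}} (base 2 by default, i.e. perfect
#' amplification efficiency). The control group's own fold change is
#' exactly 1. The SD of per-replicate fold changes
#' \eqn{base^{-(\Delta Ct_i - \overline{\Delta Ct}(control))}} is
#' reported alongside.
#'
#' @param dct data.frame from \code{\link{deltaCt}}.
#' @param controlGroup label of the reference group (e.g. \code{"P01"}).
#' @param base amplification base (default 2).
#' @return data.frame with \code{assay}, \code{group}, \code{n},
#'   \code{meanDeltaCt}, \code{sdDeltaCt}, \code{deltaDeltaCt},
#'   \code{foldChange}, \code{sdFoldChange}.
#' @export
relativeExpression <- function(dct, controlGroup, base = 2) {
    dct <- dct[!dct$missing, , drop = FALSE]
    if (!controlGroup %in% dct$group)
        stop(sprintf("control group '%s' has no data", controlGroup))
    out <- list()
    for (a in unique(dct$assay)) {
        d <- dct[dct$assay == a, , drop = FALSE]
        ctrl <- d$deltaCt[d$group == controlGroup]
        if (!length(ctrl))
            stop(sprintf("control group '%s' empty for assay '%s'",
                         controlGroup, a))
        ctrlMean <- mean(ctrl)
        for (g in unique(d$group)) {
            v <- d$deltaCt[d$group == g]
            if (!length(v)) stop(sprintf("empty group '%s'", g))
            ddct <- mean(v) - ctrlMean
            if (g == controlGroup) ddct <- 0  # exact by definition
            perRep <- base^(-(v - ctrlMean))
            out[[length(out) + 1L]] <- data.frame(
                assay = a, group = g, n = length(v),
                meanDeltaCt = mean(v), sdDeltaCt = stats::sd(v),
                deltaDeltaCt = ddct, foldChange = base^(-ddct),
                sdFoldChange = stats::sd(perRep),
                stringsAsFactors = FALSE)
        }
    }
    do.call(rbind, out)
}

#' Two-sided t-test on dCt values
#'
#' Classical two-sample Student's t-test (equal variances by default;
#' Welch with \code{varEqual = FALSE}) comparing the dCt values of two
#' groups, as used for qPCR significance calls.
#'
#' @param a,b numeric vectors of dCt values (>= 2 finite values each).
#' @param varEqual logical, pooled-variance Student's test if TRUE
#'   (default).
#' @return list with \code{statistic}, \code{df}, \code{pvalue}.
#' @export
ttestDeltaCt <- function(a, b, varEqual = TRUE) {
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) < 2L || length(b) < 2L)
        stop("each group needs at least 2 finite dCt values")
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
        # degenerate noise-free groups: identical means are a null result,
        # different means are detected with certainty
        if (mean(a) == mean(b))
            return(list(statistic = 0, df = length(a) + length(b) - 2,
                        pvalue = 1))
        return(list(statistic = sign(mean(a) - mean(b)) * Inf,
                    df = length(a) + length(b) - 2, pvalue = 0))
    }
    tt <- stats::t.test(a, b, var.equal = varEqual)
    list(statistic = unname(tt$statistic), df = unname(tt$parameter),
         pvalue = tt$p.value)
}

#' Full qPCR analysis of a plate
#'
#' dCt normalization, per-group ddCt fold changes against the control
#' group, and a two-sided t-test of every non-control group against the
#' control, per target assay.
#'
#' @param plate qPCR plate data.frame.
#' @param referenceIds reference assay ids.
#' @param controlGroup control group label.
#' @param varEqual passed to \code{\link{ttestDeltaCt}}.
#' @param base amplification base.
#' @return data.frame of \code{\link{relativeExpression}} plus a
#'   \code{pvalue} column (NA for the control group).
#' @export
analyzeQpcr <- function(plate, referenceIds, controlGroup,
                        varEqual = TRUE, base = 2) {
    dct <- deltaCt(plate, referenceIds)
    rel <- relativeExpression(dct, controlGroup, base = base)
    rel$pvalue <- NA_real_
    for (i in seq_len(nrow(rel))) {
        if (rel$group[i] == controlGroup) next
        a <- dct$deltaCt[dct$assay == rel$assay[i] &
                         dct$group == rel$group[i] & !dct$missing]
        ctrl <- dct$deltaCt[dct$assay == rel$assay[i] &
                            dct$group == controlGroup & !dct$missing]
        if (length(a) >= 2L && length(ctrl) >= 2L)
            rel$pvalue[i] <- ttestDeltaCt(a, ctrl, varEqual)$pvalue
    }
    rel
}
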