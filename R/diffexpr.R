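# Negative-binomial differential expression for two-group time-point
# comparisons: median-of-ratios normalization, method-of-moments dispersion
# with shrinkage toward the mean, and a Wald test on the log ratio of
# group means. Variance model: Var(K) = mu + phi * mu^2.

#' Median-of-ratios size factors
#'
#' Computes one positive scale factor per sample as the median across
#' features of the ratio between the sample's count and the geometric-mean
#' pseudo-reference, using only features with strictly positive counts in
#' every sample.
#'
#' @param counts count matrix (features x samples) or
#'   \linkS4class{MirCountExperiment}.
#' @return named numeric vector of size factors, one per sample.
#' @examples
#' m <- matrix(c(10, 20, 30, 20, 40, 60), 3,
#'             dimnames = list(c("a","b","c"), c("s1","s2")))
#' sizeFactors(m)  # (1/sqrt(2), sqrt(2))
#' @export
sizeFactors <- function(counts) {
    if (is(counts, "MirCountExperiment"))
        counts <- SummarizedExperiment::assay(counts, "counts")
    counts <- as.matrix(counts)
    if (ncol(counts) == 1L)
        return(stats::setNames(1, colnames(counts)))
    allPos <- rowSums(counts > 0) == ncol(counts)
    if (!any(allPos))
        stop(paste("no feature has positive counts in every sample;",
                   "median-of-ratios is undefined --",
                   "consider total-count (pseudo-reference) normalization"))
    logRef <- rowMeans(log(counts[allPos, , drop = FALSE]))
    sf <- apply(counts[allPos, , drop = FALSE], 2L,
                function(col) exp(stats::median(log(col) - logRef)))
    if (any(!is.finite(sf)) || any(sf <= 0))
        stop("non-finite or non-positive size factor")
    sf
}

#' Method-of-moments NB dispersion estimates
#'
#' For each feature, within-group variance of normalized counts is pooled
#' across groups and converted to a dispersion via \eqn{\phi = (v - \mu) /
#' \mu^2}; estimates are shrunk toward the across-feature mean dispersion
#' with weight \code{shrink} and floored at \code{floor}. Features whose
#' pooled variance does not exceed the mean get the floor.
#'
#' @param counts count matrix or \linkS4class{MirCountExperiment}.
#' @param group character/factor of group (time-point) labels per sample;
#'   taken from the object for a \code{MirCountExperiment}.
#' @param sf size factors (default computed from \code{counts}).
#' @param floor minimum dispersion (default 1e-8).
#' @param shrink weight in [0,1] pulling each raw estimate toward the mean
#'   of the raw estimates (default 0.25).
#' @return named numeric vector of dispersions, one per feature.
#' @export
estimateDispersions <- function(counts, group = NULL, sf = NULL,
                                floor = 1e-8, shrink = 0.25) {
    if (is(counts, "MirCountExperiment")) {
        if (is.null(group)) group <- as.character(timePoints(counts))
        counts <- SummarizedExperiment::assay(counts, "counts")
    }
    counts <- as.matrix(counts)
    group <- as.character(group)
    if (length(group) != ncol(counts))
        stop("group must have one label per sample")
    n <- table(group)
    if (any(n < 2L))
        stop(sprintf("group '%s' has fewer than 2 samples",
                     names(n)[n < 2L][1L]))
    if (is.null(sf)) sf <- sizeFactors(counts)
    norm <- sweep(counts, 2L, sf, "/")
    groups <- unique(group)
    mu <- matrix(0, nrow(counts), length(groups))
    ssq <- matrix(0, nrow(counts), length(groups))
    df <- integer(length(groups))
    for (g in seq_along(groups)) {
        sub <- norm[, group == groups[g], drop = FALSE]
        mu[, g] <- rowMeans(sub)
        ssq[, g] <- rowSums((sub - mu[, g])^2)
        df[g] <- ncol(sub) - 1L
    }
    v <- rowSums(ssq) / sum(df)           # pooled within-group variance
    m <- rowMeans(mu)                     # mean of group means
    raw <- ifelse(m > 0 & v > m, (v - m) / m^2, floor)
    trendMean <- mean(raw)
    phi <- pmax((1 - shrink) * raw + shrink * trendMean, floor)
    stats::setNames(phi, rownames(counts))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH: order the m p-values, compute \eqn{m p_{(i)} / i}, enforce
#' monotonicity by a running minimum from the largest rank down, cap at 1,
#' and return in the input order.
#'
#' @param p numeric vector of p-values in [0,1].
#' @return adjusted values in [0,1], same order as input.
#' @export
benjaminiHochberg <- function(p) {
    if (!length(p)) stop("empty p-value vector")
    if (any(!is.finite(p)) || any(p < 0 | p > 1))
        stop("p-values must be finite and in [0, 1]")
    m <- length(p)
    o <- order(p, decreasing = TRUE)
    adj <- numeric(m)
    running <- Inf
    for (i in seq_len(m)) {            # from largest p (rank m) downward
        rank <- m - i + 1L
        running <- min(running, m * p[o[i]] / rank)
        adj[o[i]] <- min(running, 1)
    }
    adj
}

#' Low-expression filter on raw counts
#'
#' A feature is retained iff its mean raw count is at least \code{minMean}
#' at one or more time points; features below the threshold at every time
#' point are excluded from testing and multiplicity correction.
#'
#' @param counts count matrix or \linkS4class{MirCountExperiment}.
#' @param group per-sample time-point labels (taken from the object if a
#'   \code{MirCountExperiment}).
#' @param minMean threshold on the per-time-point mean raw count
#'   (default 300).
#' @return character vector of retained feature ids.
#' @export
lowCountFilter <- function(counts, group = NULL, minMean = 300) {
    if (is(counts, "MirCountExperiment")) {
        if (is.null(group)) group <- as.character(timePoints(counts))
        counts <- SummarizedExperiment::assay(counts, "counts")
    }
    counts <- as.matrix(counts)
    groups <- unique(as.character(group))
    means <- vapply(groups, function(g)
        rowMeans(counts[, group == g, drop = FALSE]), numeric(nrow(counts)))
    if (nrow(counts) == 1L) means <- matrix(means, nrow = 1L)
    keep <- apply(means >= minMean, 1L, any)
    rownames(counts)[keep]
}

#' Two-group NB Wald test
#'
#' Tests, per feature, whether the later-group mean of normalized counts
#' differs from the earlier-group mean, using the delta-method variance of
#' the log mean under \eqn{Var(K) = \mu + \phi \mu^2}:
#' \deqn{Var(\log\hat\mu_g) = n_g^{-2} \sum_{i \in g} (1/(s_i \mu_g) + \phi).}
#' The two-sided p-value comes from the normal reference. The reported fold
#' change is \code{(muLater + epsilon) / (muEarlier + epsilon)} (linear,
#' later/earlier); the pseudo-count enters the fold change only, except
#' that a group mean of exactly zero is floored at \code{epsilon} inside
#' the statistic to keep it finite. Features with zero total count in both
#' groups are degenerate: FC = 1, p = 1.
#'
#' @param counts count matrix or \linkS4class{MirCountExperiment}.
#' @param group per-sample time-point labels.
#' @param later,earlier the two time-point labels to compare
#'   (later vs earlier).
#' @param dispersions named per-feature dispersion vector (default
#'   estimated from \code{counts}).
#' @param sf size factors (default computed).
#' @param epsilon pseudo-count on group means for the fold change
#'   (default 0.5).
#' @return data.frame with one row per feature: \code{feature},
#'   \code{baseMeanEarlier}, \code{baseMeanLater}, \code{foldChange},
#'   \code{log2FoldChange}, \code{stat}, \code{pvalue}, \code{degenerate}.
#' @export
nbWaldTest <- function(counts, group = NULL, later, earlier,
                       dispersions = NULL, sf = NULL, epsilon = 0.5) {
    if (is(counts, "MirCountExperiment")) {
        if (is.null(group)) group <- as.character(timePoints(counts))
        counts <- SummarizedExperiment::assay(counts, "counts")
    }
    counts <- as.matrix(counts)
    group <- as.character(group)
    if (!later %in% group || !earlier %in% group)
        stop(sprintf("comparison groups '%s'/'%s' not present in metadata",
                     later, earlier))
    if (is.null(sf)) sf <- sizeFactors(counts)
    if (is.null(dispersions))
        dispersions <- estimateDispersions(counts, group, sf = sf)
    phi <- dispersions[rownames(counts)]
    norm <- sweep(counts, 2L, sf, "/")
    iL <- which(group == later); iE <- which(group == earlier)
    muL <- rowMeans(norm[, iL, drop = FALSE])
    muE <- rowMeans(norm[, iE, drop = FALSE])
    degenerate <- muL == 0 & muE == 0
    fc <- (muL + epsilon) / (muE + epsilon)
    # statistic on log means; zero means floored at epsilon to stay finite
    mLs <- pmax(muL, epsilon); mEs <- pmax(muE, epsilon)
    varL <- vapply(seq_len(nrow(counts)), function(f)
        sum(1 / (sf[iL] * mLs[f]) + phi[f]) / length(iL)^2, 0)
    varE <- vapply(seq_len(nrow(counts)), function(f)
        sum(1 / (sf[iE] * mEs[f]) + phi[f]) / length(iE)^2, 0)
    stat <- (log(mLs) - log(mEs)) / sqrt(varL + varE)
    p <- 2 * stats::pnorm(-abs(stat))
    fc[degenerate] <- 1; stat[degenerate] <- 0; p[degenerate] <- 1
    data.frame(feature = rownames(counts),
               baseMeanEarlier = muE, baseMeanLater = muL,
               foldChange = fc, log2FoldChange = log2(fc),
               stat = stat, pvalue = p, degenerate = degenerate,
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Call differential features for one time-point comparison
#'
#' Runs the full per-comparison chain: low-count filter on raw counts,
#' size-factor normalization, dispersion estimation, NB Wald test, BH
#' adjustment over retained features only, and direction assignment. A
#' feature is \code{"up"} iff \code{foldChange >= fcThreshold} and
#' \code{fdr <= fdrAlpha}; \code{"down"} iff \code{1/foldChange >=
#' fcThreshold} and \code{fdr <= fdrAlpha}; otherwise \code{"ns"}.
#' Features failing the low-count filter keep their statistics but get
#' \code{fdr = NA} and direction \code{"ns"}.
#'
#' @param x a \linkS4class{MirCountExperiment} (or count matrix with
#'   \code{group} supplied).
#' @param later,earlier time-point labels of the comparison; \code{later}
#'   must come after \code{earlier} in the time-point order when the order
#'   is known.
#' @param group per-sample labels (only for a bare matrix).
#' @param fcThreshold linear fold-change threshold (default 1.8).
#' @param fdrAlpha FDR significance level (default 0.01).
#' @param minMean low-count filter threshold (default 300).
#' @param epsilon fold-change pseudo-count (default 0.5).
#' @param dispersions,sf optional precomputed values.
#' @return a \linkS4class{DifferentialResult}, sorted by FDR then
#'   |log2FoldChange| descending, ties by feature id.
#' @examples
#' sim <- simulateExperiment(generatorConfig(nMirna = 50, seed = 1))
#' res <- callDifferential(sim$mirna, "P04", "P01")
#' head(as.data.frame(res))
#' @export
callDifferential <- function(x, later, earlier, group = NULL,
                             fcThreshold = 1.8, fdrAlpha = 0.01,
                             minMean = 300, epsilon = 0.5,
                             dispersions = NULL, sf = NULL) {
    if (is(x, "MirCountExperiment")) {
        tpo <- timePointsOrder(x)
        if (all(c(later, earlier) %in% tpo) &&
            match(later, tpo) <= match(earlier, tpo))
            stop(sprintf("'%s' does not come after '%s' in the time-point order",
                         later, earlier))
        if (is.null(group)) group <- as.character(timePoints(x))
        counts <- SummarizedExperiment::assay(x, "counts")
    } else counts <- as.matrix(x)
    retained <- lowCountFilter(counts, group, minMean = minMean)
    if (is.null(sf)) sf <- sizeFactors(counts)
    if (is.null(dispersions))
        dispersions <- estimateDispersions(counts, group, sf = sf)
    res <- nbWaldTest(counts, group, later, earlier,
                      dispersions = dispersions, sf = sf, epsilon = epsilon)
    res$passedLowCountFilter <- res$feature %in% retained
    res$fdr <- NA_real_
    if (any(res$passedLowCountFilter))
        res$fdr[res$passedLowCountFilter] <-
            benjaminiHochberg(res$pvalue[res$passedLowCountFilter])
    res$direction <- "ns"
    ok <- res$passedLowCountFilter & !is.na(res$fdr) & res$fdr <= fdrAlpha &
        !res$degenerate
    res$direction[ok & res$foldChange >= fcThreshold] <- "up"
    res$direction[ok & res$foldChange > 0 &
                  1 / res$foldChange >= fcThreshold] <- "down"
    ord <- order(res$fdr, -abs(res$log2FoldChange), res$feature,
                 na.last = TRUE)
    res <- res[ord, , drop = FALSE]
    out <- new("DifferentialResult", DataFrame(res, row.names = NULL))
    S4Vectors::metadata(out) <- list(
        comparison = comparisonLabel(later, earlier), later = later,
        earlier = earlier, fcThreshold = fcThreshold, fdrAlpha = fdrAlpha,
        minMean = minMean, epsilon = epsilon)
    out
}

#' Label of a time-point comparison
#'
#' @param later,earlier time-point labels.
#' @return the string \code{"<later>-<earlier>"} (e.g. \code{"P04-P01"}).
#' @export
comparisonLabel <- function(later, earlier) paste0(later, "-", earlier)
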