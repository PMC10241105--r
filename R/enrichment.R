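# Over-representation analysis of verified target sets against GO/KEGG
# style collections: one-sided hypergeometric upper-tail test, computed as
# an exact log-space sum, plus the conservative EASE variant (overlap
# decremented by one before the tail).

#' One-sided hypergeometric over-representation p-value
#'
#' \eqn{P(X \ge k)} for \eqn{X \sim} Hypergeometric(\eqn{N, K, n}): the
#' probability of drawing at least \code{k} annotated genes when \code{n}
#' query genes are drawn without replacement from a universe of \code{N}
#' genes of which \code{K} are annotated. The tail is summed exactly in
#' log space (log-binomial terms combined by log-sum-exp), stable for
#' universes up to at least 1e5 genes.
#'
#' @param k overlap (query genes in the set).
#' @param K annotated genes in the universe.
#' @param n query size.
#' @param N universe size.
#' @return the upper-tail probability in [0, 1].
#' @examples
#' hypergeometricP(5, 5, 5, 20)  # 1 / choose(20, 5)
#' @export
hypergeometricP <- function(k, K, n, N) {
    if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(K, n))
        stop(sprintf(
            "inconsistent margins: k=%d K=%d n=%d N=%d (need 0 <= k <= min(K, n); K, n <= N)",
            k, K, n, N))
    if (k == 0) return(1)
    x <- k:min(K, n)
    logTerms <- lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n)
    mx <- max(logTerms)
    min(exp(mx + log(sum(exp(logTerms - mx)))), 1)
}

#' EASE-style conservative enrichment p-value
#'
#' The EASE score removes one gene from the overlap before computing the
#' hypergeometric upper tail, penalizing small overlaps:
#' \code{hypergeometricP(max(k - 1, 0), K, n, N)}. For k of 0 or 1 the
#' score is 1.
#'
#' @inheritParams hypergeometricP
#' @return p-value in [0, 1], always \code{>= hypergeometricP(k, ...)}.
#' @export
easeP <- function(k, K, n, N) {
    if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(K, n))
        stop(sprintf(
            "inconsistent margins: k=%d K=%d n=%d N=%d (need 0 <= k <= min(K, n); K, n <= N)",
            k, K, n, N))
    hypergeometricP(max(k - 1, 0), K, n, N)
}

#' Gene-set over-representation for one verified target set
#'
#' Tests the verified target genes of one eligible miRNA against every
#' gene set in a collection, with all margins restricted to a gene
#' universe (by default the measured genes of the differential mRNA input
#' intersected with collection-annotated genes, assembled by the caller).
#' Query genes outside the universe are dropped (their number is
#' reported); sets with no annotated gene in the universe are skipped.
#' No correction across sets is applied to the significance flag -- the
#' raw p is compared to \code{alpha} -- but a BH-adjusted column is
#' emitted for transparency.
#'
#' @param set one row of the \code{DataFrame} from
#'   \code{\link{filterMinTargets}} (must be eligible), or a list with
#'   \code{miRNA}, \code{verified}, \code{eligible}.
#' @param collection a \linkS4class{GeneSetCollection}.
#' @param universe character vector of background gene ids.
#' @param alpha significance level on the raw p-value (default 0.05).
#' @param mode \code{"fisher"} (plain hypergeometric upper tail, default)
#'   or \code{"ease"}.
#' @return data.frame with one row per tested set: \code{miRNA},
#'   \code{setId}, \code{setName}, \code{category}, \code{overlap}
#'   (comma-joined genes), \code{k}, \code{K}, \code{n}, \code{N},
#'   \code{pvalue}, \code{fdrAcrossSets}, \code{significant}; sorted by
#'   p ascending, ties by set id. The number of query genes dropped as
#'   outside the universe is in \code{attr(, "droppedFromUniverse")}.
#' @export
enrichMirna <- function(set, collection, universe, alpha = 0.05,
                        mode = c("fisher", "ease")) {
    mode <- match.arg(mode)
    if (!length(universe)) stop("universe must be non-empty")
    if (is(set, "DataFrame")) {
        if (nrow(set) != 1L) stop("pass one verified target set at a time")
        set <- list(miRNA = set$miRNA[[1L]],
                    verified = unlist(as.list(set$verified[[1L]])),
                    eligible = set$eligible[[1L]])
    }
    if (is.null(set$eligible) || !isTRUE(set$eligible))
        stop(paste("target set is not eligible for enrichment;",
                   "apply filterMinTargets() and keep only eligible miRNAs"))
    universe <- unique(normalizeGeneId(universe))
    queryAll <- unique(normalizeGeneId(set$verified))
    query <- intersect(queryAll, universe)
    dropped <- length(queryAll) - length(query)
    N <- length(universe); n <- length(query)
    pfun <- if (mode == "ease") easeP else hypergeometricP
    rows <- lapply(seq_along(collection@setId), function(i) {
        members <- intersect(collection@genes[[i]], universe)
        K <- length(members)
        if (K == 0L) return(NULL)
        ov <- sort(intersect(query, members))
        k <- length(ov)
        data.frame(miRNA = set$miRNA, setId = collection@setId[i],
                   setName = collection@setName[i],
                   category = collection@category[i],
                   overlap = paste(ov, collapse = ","),
                   k = k, K = K, n = n, N = N,
                   pvalue = pfun(k, K, n, N),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(miRNA = character(0), setId = character(0),
                          setName = character(0), category = character(0),
                          overlap = character(0), k = integer(0),
                          K = integer(0), n = integer(0), N = integer(0),
                          pvalue = numeric(0))
    out$fdrAcrossSets <- if (nrow(out)) benjaminiHochberg(out$pvalue) else
        numeric(0)
    out$significant <- out$pvalue <= alpha
    out <- out[order(out$pvalue, out$setId), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "droppedFromUniverse") <- dropped
    out
}

#' Enrich every eligible miRNA in a verified target table
#'
#' @param sets \code{DataFrame} from \code{\link{filterMinTargets}}.
#' @param collection a \linkS4class{GeneSetCollection}.
#' @inheritParams enrichMirna
#' @return row-bound data.frame of \code{\link{enrichMirna}} results over
#'   eligible miRNAs (ineligible ones are skipped, not an error here).
#' @export
enrichAll <- function(sets, collection, universe, alpha = 0.05,
                      mode = c("fisher", "ease")) {
    mode <- match.arg(mode)
    keep <- which(sets$eligible)
    rows <- lapply(keep, function(i)
        enrichMirna(sets[i, ], collection, universe, alpha, mode))
    out <- if (length(rows)) do.call(rbind, rows) else
        enrichMirna(list(miRNA = "none", verified = character(0),
                         eligible = TRUE),
                    collection, universe, alpha, mode)[0, ]
    rownames(out) <- NULL
    out
}

#' Default enrichment universe
#'
#' Measured genes (those appearing in the differential mRNA table)
#' intersected with the genes annotated anywhere in the collection.
#'
#' @param mrna differential mRNA gene table.
#' @param collection a \linkS4class{GeneSetCollection}.
#' @return character vector of gene ids.
#' @export
defaultUniverse <- function(mrna, collection) {
    sort(intersect(unique(normalizeGeneId(mrna$gene)),
                   unique(unlist(collection@genes, use.names = FALSE))))
}

#' @rdname enrichMirna
#' @param records enrichment data.frame.
#' @param path output TSV path.
#' @export
writeEnrichment <- function(records, path) .writeTsv(records, path)
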