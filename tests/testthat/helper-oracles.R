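# Independent brute-force oracles used to validate the package's own
# implementations. These deliberately avoid the code paths they check.

# BH adjusted value by definition: the smallest level at which the
# step-up procedure rejects that p-value. Candidate levels are m*p_j/r_j
# over all j with p_j >= p_i, where r_j counts p-values <= p_j.
bhOracle <- function(p) {
    m <- length(p)
    rank <- vapply(p, function(pj) sum(p <= pj), 0L)
    vapply(p, function(pi) {
        cand <- m * p[p >= pi] / rank[p >= pi]
        min(min(cand), 1)
    }, 0)
}

# plain-arithmetic hypergeometric upper tail (no logs)
hyperTailOracle <- function(k, K, n, N) {
    if (k == 0) return(1)
    x <- k:min(K, n)
    sum(choose(K, x) * choose(N - K, n - x)) / choose(N, n)
}

# triple-loop target verification: for every (miRNA, predicted gene),
# scan the mRNA table rows for an opposite-direction hit in the
# comparison
verifyOracle <- function(predicted, mrna, calls, comparison) {
    out <- list()
    for (i in seq_len(nrow(calls))) {
        m <- calls$feature[i]
        pred <- predicted[[m]]
        hits <- character(0)
        if (!is.null(pred)) {
            opp <- if (calls$direction[i] == "up") "down" else "up"
            for (g in toupper(pred)) {
                for (j in seq_len(nrow(mrna))) {
                    if (toupper(mrna$gene[j]) == g &&
                        mrna$comparison[j] == comparison &&
                        mrna$direction[j] == opp) {
                        hits <- c(hits, g)
                        break
                    }
                }
            }
        }
        out[[m]] <- sort(unique(hits))
    }
    out
}

# NB likelihood-ratio test with fixed dispersion phi and unit size
# factors, as an independent check on the Wald p-value
nbLrtOracle <- function(countsA, countsB, phi) {
    ll <- function(x, mu) sum(stats::dnbinom(x, mu = mu, size = 1 / phi,
                                             log = TRUE))
    muA <- mean(countsA); muB <- mean(countsB)
    mu0 <- mean(c(countsA, countsB))
    lr <- 2 * (ll(countsA, muA) + ll(countsB, muB) -
               ll(countsA, mu0) - ll(countsB, mu0))
    stats::pchisq(max(lr, 0), df = 1, lower.tail = FALSE)
}
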