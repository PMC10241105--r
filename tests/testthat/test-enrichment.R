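test_that("hypergeometric tail matches closed forms and stats::phyper", {
    expect_equal(hypergeometricP(0, 5, 5, 20), 1)
    expect_equal(hypergeometricP(5, 5, 5, 20), 1 / choose(20, 5),
                 tolerance = 1e-12)
    expect_error(hypergeometricP(6, 5, 5, 20), "inconsistent margins")
    expect_error(hypergeometricP(2, 25, 5, 20), "inconsistent margins")
    # cross-check against R's hypergeometric distribution on random margins
    set.seed(3)
    for (i in 1:50) {
        N <- sample(5:2000, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
        k <- sample(0:min(K, n), 1)
        expect_equal(hypergeometricP(k, K, n, N),
                     phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                     tolerance = 1e-10)
    }
    # large-universe stability
    expect_gt(hypergeometricP(40, 200, 300, 1e5), 0)
})

test_that("p-value is non-increasing in the overlap", {
    p <- vapply(0:10, hypergeometricP, 0, K = 10, n = 10, N = 100)
    expect_true(all(diff(p) <= 1e-15))
})

test_that("EASE variant decrements the overlap", {
    expect_equal(easeP(0, 10, 10, 100), 1)
    expect_equal(easeP(1, 10, 10, 100), 1)
    expect_equal(easeP(6, 10, 10, 100),
                 hypergeometricP(5, 10, 10, 100))
    for (k in 1:8)
        expect_gte(easeP(k, 10, 10, 100),
                   hypergeometricP(k, 10, 10, 100))
})

test_that("a planted set outranks random sets for its own query", {
    set.seed(13)
    universe <- sprintf("G%03d", 1:400)
    query <- sample(universe, 45)
    planted <- unique(c(sample(query, 30), sample(universe, 10)))
    ids <- c("PLANTED", sprintf("RND%02d", 1:50))
    gsets <- c(list(planted),
               replicate(50, sample(universe, sample(20:60, 1)),
                         simplify = FALSE))
    coll <- GeneSetCollection(ids, ids, rep("GO_BP", 51), gsets)
    set <- list(miRNA = "m1", verified = query, eligible = TRUE)
    rec <- enrichMirna(set, coll, universe)
    expect_equal(rec$setId[1], "PLANTED")
    expect_true(rec$significant[1])
    # records sorted by p then set id
    expect_true(!is.unsorted(rec$pvalue))
})

test_that("disjoint queries yield p = 1 and ineligible sets error", {
    universe <- c(sprintf("A%d", 1:50), sprintf("B%d", 1:50))
    coll <- GeneSetCollection("S1", "S1", "GO_BP",
                              list(sprintf("A%d", 1:20)))
    set <- list(miRNA = "m", verified = sprintf("B%d", 1:30),
                eligible = TRUE)
    rec <- enrichMirna(set, coll, universe)
    expect_equal(rec$pvalue, 1)
    expect_false(rec$significant)

    bad <- list(miRNA = "m", verified = sprintf("B%d", 1:10),
                eligible = FALSE)
    expect_error(enrichMirna(bad, coll, universe), "filterMinTargets")
    expect_error(enrichMirna(set, coll, character(0)), "universe")
})

test_that("query genes outside the universe are dropped and counted", {
    universe <- sprintf("A%d", 1:50)
    coll <- GeneSetCollection("S1", "S1", "GO_BP",
                              list(sprintf("A%d", 1:20)))
    set <- list(miRNA = "m",
                verified = c(sprintf("A%d", 1:10), "ZZ1", "ZZ2"),
                eligible = TRUE)
    rec <- enrichMirna(set, coll, universe)
    expect_equal(attr(rec, "droppedFromUniverse"), 2L)
    expect_equal(rec$n, 10L)
})

test_that("null queries give p-values no smaller than uniform", {
    set.seed(29)
    universe <- sprintf("G%03d", 1:500)
    coll <- GeneSetCollection("S", "S", "GO_BP",
                              list(sample(universe, 50)))
    pvals <- replicate(300, {
        q <- sample(universe, 40)
        enrichMirna(list(miRNA = "m", verified = q, eligible = TRUE),
                    coll, universe)$pvalue
    })
    # discrete conservative test: P(p <= a) <= a for a grid of levels
    for (a in c(0.01, 0.05, 0.1, 0.25))
        expect_lte(mean(pvals <= a), a + 3 * sqrt(a * (1 - a) / 300))
    expect_gte(mean(pvals), 0.45)
})
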