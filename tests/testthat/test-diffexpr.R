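test_that("median-of-ratios size factors match hand-derived cases", {
    m <- matrix(rpois(40, 200), 10, 4,
                dimnames = list(sprintf("f%d", 1:10), sprintf("s%d", 1:4)))
    # identical samples -> all 1
    same <- m[, c(1, 1, 1)]
    colnames(same) <- c("a", "b", "c")
    expect_equal(unname(sizeFactors(same)), rep(1, 3))
    # sample2 = 2 x sample1 -> (1/sqrt(2), sqrt(2))
    dbl <- cbind(s1 = m[, 1] + 1, s2 = 2 * (m[, 1] + 1))
    expect_equal(unname(sizeFactors(dbl)), c(1 / sqrt(2), sqrt(2)))
    # single sample -> 1
    expect_equal(unname(sizeFactors(m[, 1, drop = FALSE])), 1)
    # no all-positive feature -> informative error
    z <- m; z[cbind(1:10, rep(1:4, length.out = 10))] <- 0
    expect_error(sizeFactors(z), "positive")
})

test_that("size factors agree with the DESeq2 reference implementation", {
    skip_if_not_installed("DESeq2")
    set.seed(101)
    m <- matrix(rnbinom(200 * 6, mu = 500, size = 5), 200, 6,
                dimnames = list(sprintf("f%d", 1:200), sprintf("s%d", 1:6)))
    expect_equal(unname(sizeFactors(m)),
                 unname(DESeq2::estimateSizeFactorsForMatrix(m)),
                 tolerance = 1e-12)
})

test_that("moment dispersion estimates recover simulated truth", {
    # zero within-group variance -> floor
    flat <- matrix(5, 1, 4, dimnames = list("f", sprintf("s%d", 1:4)))
    expect_equal(unname(estimateDispersions(flat, rep("g", 4),
                                            sf = rep(1, 4))), 1e-8)
    # Poisson feature: phi near 0
    set.seed(42)
    x <- matrix(rpois(1000, 100), 1,
                dimnames = list("f", sprintf("s%d", 1:1000)))
    phi <- estimateDispersions(x, rep("g", 1000), sf = rep(1, 1000))
    expect_gte(unname(phi), 0)
    expect_lte(unname(phi), 0.05)
    # NB feature with phi = 0.5
    set.seed(43)
    x2 <- matrix(rnbinom(1000, mu = 100, size = 2), 1,
                 dimnames = list("f", sprintf("s%d", 1:1000)))
    phi2 <- estimateDispersions(x2, rep("g", 1000), sf = rep(1, 1000))
    expect_gte(unname(phi2), 0.4)
    expect_lte(unname(phi2), 0.6)
    # a group with a single replicate is rejected
    expect_error(estimateDispersions(flat, c("g", "g", "g", "h")),
                 "fewer than 2")
})

test_that("NB Wald test: null, strong-effect and degenerate features", {
    # identical group means -> log2FC 0, p 1
    m <- matrix(rep(c(100, 200, 400), each = 8), 3, 8, byrow = TRUE,
                dimnames = list(c("f1", "f2", "f3"), sprintf("s%d", 1:8)))
    g <- rep(c("P01", "P04"), each = 4)
    r <- nbWaldTest(m, g, "P04", "P01", sf = rep(1, 8),
                    dispersions = setNames(rep(0.05, 3), rownames(m)))
    expect_equal(r$log2FoldChange, rep(0, 3))
    expect_equal(r$pvalue, rep(1, 3))

    # planted 4x effect at mean 1000, phi 0.05, 4 vs 4 -> p < 0.01,
    # and in the same ballpark as an NB likelihood-ratio oracle
    set.seed(7)
    a <- rnbinom(4, mu = 1000, size = 20)
    b <- rnbinom(4, mu = 4000, size = 20)
    m2 <- matrix(c(a, b), 1, dimnames = list("f", sprintf("s%d", 1:8)))
    r2 <- nbWaldTest(m2, g, "P04", "P01", sf = rep(1, 8),
                     dispersions = c(f = 0.05))
    expect_lt(r2$pvalue, 0.01)
    pLrt <- nbLrtOracle(a, b, 0.05)
    expect_lt(pLrt, 0.01)
    expect_lt(abs(log10(r2$pvalue) - log10(pLrt)),
              0.5 * max(1, abs(log10(pLrt))))

    # all-zero feature is degenerate
    z <- matrix(0, 1, 8, dimnames = list("f0", sprintf("s%d", 1:8)))
    rz <- nbWaldTest(z, g, "P04", "P01", sf = rep(1, 8),
                     dispersions = c(f0 = 0.05))
    expect_true(rz$degenerate)
    expect_equal(rz$foldChange, 1)
    expect_equal(rz$pvalue, 1)
})

test_that("BH step-up matches hand-derived cases and p.adjust", {
    expect_equal(benjaminiHochberg(0.03), 0.03)
    expect_equal(benjaminiHochberg(c(0.01, 0.02, 0.03)),
                 c(0.03, 0.03, 0.03))
    expect_equal(benjaminiHochberg(rep(0.2, 5)), rep(0.2, 5))
    expect_error(benjaminiHochberg(c(0.5, 1.2)), "\\[0, 1\\]")
    expect_error(benjaminiHochberg(numeric(0)), "empty")
    set.seed(9)
    for (i in 1:20) {
        p <- runif(sample(1:30, 1))
        expect_equal(benjaminiHochberg(p), p.adjust(p, "BH"))
    }
})

test_that("low-count filter excludes only features below threshold at all time points", {
    g <- rep(c("P01", "P04", "P09", "P23"), each = 2)
    m <- rbind(allLow = rep(250, 8),
               oneHigh = c(250, 250, 250, 250, 400, 400, 250, 250),
               boundary = rep(300, 8))
    colnames(m) <- sprintf("s%d", 1:8)
    kept <- lowCountFilter(m, g, minMean = 300)
    expect_false("allLow" %in% kept)
    expect_true("oneHigh" %in% kept)
    expect_true("boundary" %in% kept)
})

test_that("direction calls respect the fold-change and FDR thresholds", {
    # two strong features (up and down) and one just under the threshold
    set.seed(21)
    g <- rep(c("P01", "P04"), each = 4)
    mk <- function(muA, muB) rnbinom(8, mu = rep(c(muA, muB), each = 4),
                                     size = 100)
    m <- rbind(up = mk(1000, 4000), down = mk(4000, 1000),
               flat = mk(1000, 1000))
    colnames(m) <- sprintf("s%d", 1:8)
    r <- as.data.frame(callDifferential(m, "P04", "P01", group = g,
                                        minMean = 0))
    expect_equal(r$direction[match(c("up", "down", "flat"), r$feature)],
                 c("up", "down", "ns"))
})

test_that("swapping comparison direction inverts FC and preserves p", {
    sim <- smallSim(seed = 31)
    m <- SummarizedExperiment::assay(sim$mirna)
    g <- as.character(timePoints(sim$mirna))
    fwd <- nbWaldTest(m, g, "P04", "P01")
    rev <- nbWaldTest(m, g, "P01", "P04")
    expect_equal(fwd$pvalue, rev$pvalue, tolerance = 1e-12)
    # FC maps to 1/FC only where the pseudo-count is negligible; test on
    # the statistic, which is exactly anti-symmetric
    expect_equal(fwd$stat, -rev$stat, tolerance = 1e-12)
})

test_that("average Wald statistic grows with the true effect size", {
    set.seed(55)
    g <- rep(c("P01", "P04"), each = 4)
    avgStat <- vapply(c(0, 0.5, 1, 1.5, 2), function(lfc) {
        stats <- replicate(40, {
            m <- matrix(rnbinom(8, mu = rep(c(1000, 1000 * 2^lfc),
                                            each = 4), size = 20),
                        1, dimnames = list("f", sprintf("s%d", 1:8)))
            abs(nbWaldTest(m, g, "P04", "P01", sf = rep(1, 8),
                           dispersions = c(f = 0.05))$stat)
        })
        mean(stats)
    }, 0)
    expect_true(all(diff(avgStat) > 0))
})
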