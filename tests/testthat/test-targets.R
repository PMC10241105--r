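mkPred <- function(...) structure(list(...), class = "PredictedTargets")

mkMrna <- function(genes, directions, comparison = "P09-P04") {
    data.frame(gene = toupper(genes), comparison = comparison,
               direction = directions, foldChange = 2, fdr = 0.001,
               stringsAsFactors = FALSE)
}

test_that("verification intersects predictions with opposite-direction genes", {
    pred <- mkPred(m1 = c("gA", "gB", "gC"), m2 = "gA", m3 = c("gE", "gB"))
    mrna <- mkMrna(c("gB", "gC", "gD", "gE"),
                   c("down", "down", "down", "up"))
    calls <- dirTable(c("m1", "m2", "m3"), c("up", "down", "up"))
    v <- verifyTargets(pred, mrna, calls, "P09-P04")
    vlist <- setNames(as.list(v$verified), v$miRNA)
    expect_equal(vlist$m1, c("GB", "GC"))
    expect_equal(vlist$m2, character(0))       # no up gene predicted
    expect_equal(vlist$m3, "GB")               # gE is up like m3: rejected
    expect_false(any(v$noPrediction))
})

test_that("no-prediction miRNAs are flagged, ns miRNAs are rejected", {
    pred <- mkPred(m1 = "gA")
    mrna <- mkMrna("gA", "down")
    v <- verifyTargets(pred, mrna, dirTable(c("m1", "mX"), c("up", "up")),
                       "P09-P04")
    expect_false(v$noPrediction[v$miRNA == "m1"])
    expect_true(v$noPrediction[v$miRNA == "mX"])
    expect_equal(v$nVerified[v$miRNA == "mX"], 0L)
    expect_error(verifyTargets(pred, mrna, dirTable("m1", "ns"),
                               "P09-P04"), "ns")
})

test_that("verification equals the brute-force triple-loop oracle", {
    set.seed(77)
    genes <- sprintf("G%02d", 1:30)
    for (rep in 1:100) {
        mirs <- sprintf("m%d", 1:sample(1:4, 1))
        pred <- structure(
            lapply(mirs, function(m)
                sample(genes, sample(0:10, 1))),
            names = mirs, class = "PredictedTargets")
        # randomly drop a miRNA's prediction entirely
        if (runif(1) < 0.3) pred[[sample(length(pred), 1)]] <- NULL
        nDE <- sample(5:20, 1)
        mrna <- mkMrna(sample(genes, nDE),
                       sample(c("up", "down"), nDE, replace = TRUE))
        calls <- dirTable(mirs, sample(c("up", "down"), length(mirs),
                                       replace = TRUE))
        v <- verifyTargets(pred, mrna, calls, "P09-P04")
        oracle <- verifyOracle(pred, mrna, calls, "P09-P04")
        for (m in mirs)
            expect_identical(unname(unlist(as.list(
                v$verified[v$miRNA == m]))) %||% character(0),
                oracle[[m]])
    }
})

test_that("adding a down gene never shrinks an up-miRNA's verified set", {
    set.seed(78)
    genes <- sprintf("G%02d", 1:30)
    pred <- mkPred(m1 = sample(genes, 15))
    mrna <- mkMrna(sample(genes, 10),
                   sample(c("up", "down"), 10, replace = TRUE))
    calls <- dirTable("m1", "up")
    base <- unlist(as.list(verifyTargets(pred, mrna, calls,
                                         "P09-P04")$verified))
    extra <- setdiff(toupper(genes), mrna$gene)[1]
    mrna2 <- rbind(mrna, mkMrna(extra, "down"))
    grown <- unlist(as.list(verifyTargets(pred, mrna2, calls,
                                          "P09-P04")$verified))
    expect_true(all(base %in% grown))
})

test_that("eligibility gate is >= minTargets and deletes nothing", {
    v <- S4Vectors::DataFrame(
        miRNA = c("a", "b", "c"), direction = "up", comparison = "c1",
        verified = IRanges::CharacterList(list(character(0),
                                               sprintf("G%d", 1:39),
                                               sprintf("G%d", 1:40))),
        nVerified = c(0L, 39L, 40L), noPrediction = FALSE)
    out <- filterMinTargets(v, 40)
    expect_equal(out$eligible, c(FALSE, FALSE, TRUE))
    expect_equal(nrow(out), 3L)
    expect_error(filterMinTargets(v, 0), "minTargets")
})

test_that("verified sets on synthetic data beat the decoy base rate", {
    sim <- smallSim(seed = 41)
    cmp <- "P23-P09"
    res <- callDifferential(sim$mirna, "P23", "P09")
    calls <- as.data.frame(res)
    calls <- calls[calls$direction %in% c("up", "down"), ]
    skip_if(nrow(calls) == 0, "no DE miRNAs in this draw")
    v <- verifyTargets(sim$predicted, sim$mrna, calls, cmp)
    te <- sim$truth$trueEdges
    prec <- vapply(seq_len(nrow(v)), function(i) {
        ver <- unlist(as.list(v$verified[i]))
        if (!length(ver)) return(NA_real_)
        mean(ver %in% te$gene[te$miRNA == v$miRNA[i]])
    }, 0)
    # decoy base rate: fraction of decoy edges that could verify by chance
    baseRate <- nrow(sim$truth$decoyEdges) /
        (nrow(sim$truth$decoyEdges) + nrow(te))
    expect_gt(mean(prec, na.rm = TRUE), baseRate)
    expect_gt(mean(prec, na.rm = TRUE), 0.75)
})
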