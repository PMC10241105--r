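mkPlate <- function(df) {
    df$designation <- ifelse(grepl("^ref", df$assay), "reference",
                             ifelse(grepl("^UniSp", df$assay), "spike_in",
                                    "target"))
    df
}

test_that("dCt arithmetic and reference checks", {
    plate <- mkPlate(expand.grid(
        sample = c("s1", "s2"), assay = c("t1", "refA", "refB"),
        stringsAsFactors = FALSE))
    plate$group <- "P01"
    plate$cq <- c(25, 26, 20, 21, 22, 23)   # t1, refA, refB per sample
    d <- deltaCt(plate, c("refA", "refB"))
    expect_equal(d$deltaCt[d$sample == "s1"], 25 - 21)
    expect_equal(d$deltaCt[d$sample == "s2"], 26 - 22)
    # single reference
    d1 <- deltaCt(plate, "refA")
    expect_equal(d1$deltaCt[d1$sample == "s1"], 5)
    # per-sample constant offsets cancel
    shifted <- plate
    shifted$cq <- plate$cq + ifelse(plate$sample == "s1", 3, -1)
    expect_equal(deltaCt(shifted, c("refA", "refB"))$deltaCt, d$deltaCt)
    # undetermined reference errors with sample and assay named
    bad <- plate; bad$cq[bad$assay == "refA" & bad$sample == "s2"] <- NA
    expect_error(deltaCt(bad, c("refA", "refB")), "refA.*s2")
})

test_that("ddCt closed forms hold", {
    dct <- data.frame(sample = sprintf("s%d", 1:8),
                      assay = "t1", group = rep(c("P01", "P23"), each = 4),
                      deltaCt = c(4, 4, 4, 4, 2, 2, 2, 2),
                      missing = FALSE, stringsAsFactors = FALSE)
    rel <- relativeExpression(dct, "P01")
    expect_equal(rel$foldChange[rel$group == "P01"], 1)     # exact
    expect_equal(rel$deltaDeltaCt[rel$group == "P23"], -2)
    expect_equal(rel$foldChange[rel$group == "P23"], 4)
    # ddCt of +1 halves expression
    dct$deltaCt[dct$group == "P23"] <- 5
    expect_equal(relativeExpression(dct, "P01")$foldChange[2], 0.5)
    expect_error(relativeExpression(dct, "P99"), "control group")
})

test_that("t-test on dCt values matches hand computation and is symmetric", {
    expect_equal(ttestDeltaCt(c(1, 2, 3), c(1, 2, 3))$pvalue, 1)
    a <- c(1, 2, 3); b <- c(11, 12, 13)
    tt <- ttestDeltaCt(a, b)
    # hand-computed pooled t: diff 10, s_p = 1, se = sqrt(2/3)
    expect_equal(tt$statistic, -10 / sqrt(2 / 3), tolerance = 1e-12)
    expect_equal(tt$df, 4)
    expect_lt(tt$pvalue, 0.05)
    expect_equal(ttestDeltaCt(b, a)$pvalue, tt$pvalue)
    expect_error(ttestDeltaCt(a, 5), "at least 2")
})

test_that("zero-noise synthetic plates give exact ddCt values", {
    sim <- smallSim(seed = 19)
    truth <- sim$truth
    # force a known 4-fold late increase: pick a late_up miRNA and pin lfc
    lateUp <- truth$mirna$miRNA[truth$mirna$planted &
                                truth$mirna$template == "late_up"]
    skip_if(length(lateUp) == 0, "no late_up miRNA in this draw")
    m <- lateUp[1]
    truth$meanMatrix[m, ] <- truth$meanMatrix[m, "P01"] * c(1, 1, 1, 4)
    plate <- simulateQpcrPlate(truth, targets = m, noiseSd = 0)
    res <- analyzeQpcr(plate, c("ref-miR-A", "ref-miR-B"), "P01")
    expect_equal(res$deltaDeltaCt[res$group == "P23"], -2)
    expect_equal(res$foldChange[res$group == "P23"], 4)
    expect_equal(res$foldChange[res$group == "P01"], 1)
    # references flat across groups by construction at zero noise
    refs <- plate[plate$designation == "reference", ]
    expect_equal(length(unique(refs$cq[refs$assay == "ref-miR-A"])), 1L)
    expect_error(simulateQpcrPlate(truth, targets = m, noiseSd = -1),
                 "noiseSd")
    # seeded run reproducible
    p1 <- simulateQpcrPlate(truth, noiseSd = 0.2, seed = 5)
    p2 <- simulateQpcrPlate(truth, noiseSd = 0.2, seed = 5)
    expect_identical(p1, p2)
})

test_that("spike-ins are monitored but never normalized against", {
    sim <- smallSim(seed = 23)
    plate <- simulateQpcrPlate(sim$truth, noiseSd = 0)
    qc <- spikeInQc(plate)
    expect_equal(sort(qc$assay), c("UniSp3", "UniSp6"))
    expect_false(any(qc$flagged))
    noisy <- plate
    noisy$cq[noisy$assay == "UniSp3"] <-
        noisy$cq[noisy$assay == "UniSp3"] +
        seq(0, 4, length.out = sum(noisy$assay == "UniSp3"))
    expect_true(spikeInQc(noisy)$flagged[
        spikeInQc(noisy)$assay == "UniSp3"])
})
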