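mkRecords <- function(...) {
    rows <- list(...)
    do.call(rbind, lapply(rows, function(r)
        data.frame(miRNA = r[[1]], setId = r[[2]], setName = r[[3]],
                   category = r[[4]], overlap = paste(
                       sprintf("G%d", seq_len(r[[5]])), collapse = ","),
                   k = r[[5]], K = 50, n = 40, N = 400,
                   pvalue = r[[6]], significant = r[[6]] <= 0.05,
                   stringsAsFactors = FALSE)))
}

test_that("edge weights and term totals are additive", {
    rec <- mkRecords(list("m1", "T1", "term one", "GO_BP", 4, 0.01),
                     list("m2", "T1", "term one", "GO_BP", 6, 0.02),
                     list("m1", "T2", "term two", "KEGG", 12, 0.001),
                     list("m2", "T3", "ns term", "GO_BP", 9, 0.5))
    net <- buildNetwork(rec)
    expect_equal(nrow(net$edges), 3)           # ns record dropped
    expect_equal(net$termNodes$totalWeight[net$termNodes$setId == "T1"], 10)
    expect_equal(sort(net$edges$weight[net$edges$setId == "T1"]), c(4, 6))
    expect_equal(net$edges$weight[net$edges$setId == "T2"], 12)
    # deterministic ordering: terms by total weight desc then id
    expect_equal(net$termNodes$setId, c("T2", "T1"))
})

test_that("no significant records yields an empty network with a warning", {
    rec <- mkRecords(list("m1", "T1", "t", "GO_BP", 4, 0.9))
    expect_warning(net <- buildNetwork(rec), "empty")
    expect_equal(nrow(net$edges), 0)
    # exports still produce valid files
    tf <- tempfile(fileext = ".json")
    exportSankey(net, tf)
    js <- jsonlite::read_json(tf)
    expect_length(js$links, 0)
})

test_that("term-pattern subnetworks keep weights and drop dangling miRNAs", {
    rec <- mkRecords(
        list("m1", "T1", "mitochondrion", "GO_CC", 4, 0.01),
        list("m1", "T2", "mitochondrial inner membrane", "GO_CC", 6, 0.01),
        list("m2", "T3", "nucleus", "GO_CC", 5, 0.01))
    net <- buildNetwork(rec)
    sub <- subnetworkByTermPattern(net, "mitochondri")
    expect_equal(sort(sub$termNodes$setId), c("T1", "T2"))
    expect_equal(sub$mirnaNodes$miRNA, "m1")   # m2 only hit "nucleus"
    expect_equal(sum(sub$edges$weight), 10)
    # weights carried over, not recomputed
    expect_true(all(sub$edges$weight %in% net$edges$weight))
    empty <- subnetworkByTermPattern(net, "golgi")
    expect_equal(nrow(empty$edges), 0)
    expect_error(subnetworkByTermPattern(net, "(["), "invalid pattern")
})

test_that("exports conserve total weight and are byte-deterministic", {
    rec <- mkRecords(list("m1", "T1", "term one", "GO_BP", 5, 0.01),
                     list("m2", "T2", "term two", "KEGG", 7, 0.02))
    net <- buildNetwork(rec)
    d <- tempfile(); dir.create(d)
    exportChord(net, file.path(d, "c.tsv"))
    exportSankey(net, file.path(d, "s.json"))
    flow <- read.delim(file.path(d, "c.tsv"), comment.char = "#",
                       row.names = 1, check.names = FALSE)
    expect_equal(sum(flow), sum(net$edges$weight))
    sank <- jsonlite::read_json(file.path(d, "s.json"))
    expect_equal(sum(vapply(sank$links, function(l) l$value, 0)),
                 sum(net$edges$weight))
    expect_equal(sank$links[[1]]$value, 5)
    # identical bytes on re-export
    exportChord(net, file.path(d, "c2.tsv"))
    exportSankey(net, file.path(d, "s2.json"))
    expect_identical(readLines(file.path(d, "c.tsv")),
                     readLines(file.path(d, "c2.tsv")))
    expect_identical(readLines(file.path(d, "s.json")),
                     readLines(file.path(d, "s2.json")))
})
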