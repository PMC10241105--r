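# Programmatic fixtures shared across test files.

`%||%` <- function(a, b) if (is.null(a)) b else a

tinyCounts <- function() {
    matrix(c(10, 20, 0, 5, 300, 299), 3, 2, byrow = TRUE,
           dimnames = list(c("miR-a", "miR-b", "miR-c"), c("S1", "S2")))
}

# a direction table in the minimal shape classifyPatterns consumes
dirTable <- function(features, directions) {
    data.frame(feature = features, direction = directions,
               stringsAsFactors = FALSE)
}

# Encoded truth table mimicking the four-group postnatal time-course
# bookkeeping: 6 miRNAs first-DE in P04-P01 (1 up, 5 down), 13 down in
# P09-P04 of which 10 new, one of those transient, and 19 new up in
# P23-P09. Returns the per-comparison direction tables plus the expected
# classification.
figStyleTruth <- function() {
    up1 <- "miR-150-5p"
    early <- c("miR-484", "miR-1983", "miR-298-5p", "miR-210-3p",
               "miR-351-5p")
    earlyAlsoMid <- early[1:3]      # 13 down at P09-P04 = 3 early + 10 new
    mid <- sprintf("mid-miR-%02d", 1:9)
    transient <- "miR-6236"
    late <- sprintf("late-miR-%02d", 1:19)
    all <- c(up1, early, mid, transient, late)
    dirFor <- function(upSet, downSet)
        dirTable(all, ifelse(all %in% upSet, "up",
                             ifelse(all %in% downSet, "down", "ns")))
    results <- list(
        "P04-P01" = dirFor(up1, early),
        "P09-P04" = dirFor(character(0), c(earlyAlsoMid, mid, transient)),
        "P23-P09" = dirFor(late, character(0)),
        "P09-P01" = dirFor(up1, c(early, mid, transient)),
        "P23-P01" = dirFor(c(up1, late), c(early, mid)))
    expected <- data.frame(
        miRNA = all,
        firstComparison = c("P04-P01", rep("P04-P01", 5),
                            rep("P09-P04", 10), rep("P23-P09", 19)),
        direction = c("up", rep("down", 15), rep("up", 19)),
        transient = all %in% transient,
        stringsAsFactors = FALSE)
    expected$persistent <- !expected$transient
    list(results = results, expected = expected,
         counts = list(firstP04 = 6, downP09P04 = 13, newP09P04 = 10,
                       newUpP23P09 = 19))
}

smallSim <- function(seed = 11, ...) {
    simulateExperiment(generatorConfig(
        nMirna = 80, nGene = 800, minTrueTargets = 25,
        nBackgroundSets = 30, plantedSetSize = 25, seed = seed, ...))
}

writeTemp <- function(lines, ext = ".tsv") {
    tf <- tempfile(fileext = ext)
    writeLines(lines, tf)
    tf
}
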