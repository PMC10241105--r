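# All tables use a strict TSV dialect: tab separator, UTF-8, "." decimal,
# no quoting. Writers prepend one "# mirTarNet vX.Y.Z" comment line;
# readers skip "#" comment lines.

.versionHeader <- function() {
    sprintf("# mirTarNet v%s", as.character(utils::packageVersion("mirTarNet")))
}

.readTsv <- function(path, header = TRUE, colClasses = NA) {
    utils::read.delim(path, header = header, sep = "\t", quote = "",
                      comment.char = "#", stringsAsFactors = FALSE,
                      colClasses = colClasses, check.names = FALSE)
}

.writeTsv <- function(df, path) {
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(.versionHeader(), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' Normalize gene symbols for cross-table matching
#'
#' Gene identifiers coming from target-prediction tables, differential mRNA
#' tables and gene-set collections are matched after trimming whitespace and
#' uppercasing; miRNA identifiers are only trimmed (case preserved), since
#' miRNA nomenclature is case sensitive (e.g. miR vs let).
#'
#' @param x character vector of gene symbols.
#' @return normalized character vector.
#' @export
normalizeGeneId <- function(x) toupper(trimws(as.character(x)))

#' @rdname normalizeGeneId
#' @export
normalizeMirnaId <- function(x) trimws(as.character(x))

#' Read / write a feature x sample count matrix
#'
#' The TSV has a header row of sample ids and feature ids in the first
#' column. Counts must be non-negative integers; duplicate feature or
#' sample ids and non-integral or negative cells are rejected with an error
#' naming the offender.
#'
#' @param path file path of a tab-separated count table.
#' @return \code{readCountMatrix}: a numeric matrix (integral values) with
#'   feature row names and sample column names.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeCountMatrix(matrix(1:4, 2, dimnames = list(c("a","b"), c("s1","s2"))), tf)
#' readCountMatrix(tf)
#' @export
readCountMatrix <- function(path) {
    df <- tryCatch(.readTsv(path, header = TRUE),
                   error = function(e) stop("no samples: file is empty"))
    if (ncol(df) == 0L) stop("no samples: file is empty")
    if (ncol(df) < 2L) stop("no samples: count table needs >= 1 sample column")
    features <- trimws(as.character(df[[1L]]))
    samples <- trimws(colnames(df)[-1L])
    if (anyDuplicated(samples))
        stop(sprintf("duplicate sample id: %s",
                     samples[duplicated(samples)][1L]))
    if (anyDuplicated(features))
        stop(sprintf("duplicate feature id: %s",
                     features[duplicated(features)][1L]))
    m <- as.matrix(df[, -1L, drop = FALSE])
    suppressWarnings(storage.mode(m) <- "double")
    bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
    if (nrow(bad))
        stop(sprintf(
            "invalid count (negative, missing or non-integer) at feature '%s', sample '%s'",
            features[bad[1L, 1L]], samples[bad[1L, 2L]]))
    dimnames(m) <- list(features, samples)
    m
}

#' @param counts matrix of counts with dimnames, or a
#'   \linkS4class{MirCountExperiment}.
#' @rdname readCountMatrix
#' @export
writeCountMatrix <- function(counts, path) {
    if (is(counts, "MirCountExperiment"))
        counts <- SummarizedExperiment::assay(counts, "counts")
    df <- data.frame(feature = rownames(counts), counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
    .writeTsv(df, path)
}

#' Read / write sample metadata
#'
#' Two-column TSV (\code{sample}, \code{timePoint}). The ordered vector of
#' time-point labels is either given explicitly or taken as the order of
#' first appearance in the file.
#'
#' @param path TSV file path.
#' @param timePointsOrder optional character vector of labels, earliest
#'   first.
#' @return a data.frame with columns \code{sample} and \code{timePoint} and
#'   attribute \code{"timePointsOrder"}.
#' @export
readSampleMetadata <- function(path, timePointsOrder = NULL) {
    df <- .readTsv(path)
    if (!all(c("sample", "timePoint") %in% colnames(df)))
        stop("sample metadata needs columns 'sample' and 'timePoint'")
    df$sample <- trimws(df$sample)
    df$timePoint <- trimws(df$timePoint)
    if (anyDuplicated(df$sample))
        stop(sprintf("duplicate sample id: %s",
                     df$sample[duplicated(df$sample)][1L]))
    if (is.null(timePointsOrder)) timePointsOrder <- unique(df$timePoint)
    if (!all(df$timePoint %in% timePointsOrder))
        stop(sprintf("time point '%s' not in timePointsOrder",
                     setdiff(df$timePoint, timePointsOrder)[1L]))
    attr(df, "timePointsOrder") <- timePointsOrder
    df
}

#' @param metadata data.frame as returned by \code{readSampleMetadata}.
#' @rdname readSampleMetadata
#' @export
writeSampleMetadata <- function(metadata, path) {
    .writeTsv(metadata[, c("sample", "timePoint")], path)
}

#' Read a count matrix and sample metadata into a MirCountExperiment
#'
#' @param countsPath,metadataPath TSV file paths.
#' @param timePointsOrder optional explicit time-point order.
#' @return a \linkS4class{MirCountExperiment}; samples are those present in
#'   both files, in count-matrix order.
#' @export
readMirCountExperiment <- function(countsPath, metadataPath,
                                   timePointsOrder = NULL) {
    m <- readCountMatrix(countsPath)
    md <- readSampleMetadata(metadataPath, timePointsOrder)
    miss <- setdiff(colnames(m), md$sample)
    if (length(miss))
        stop(sprintf("sample '%s' has no metadata", miss[1L]))
    tp <- md$timePoint[match(colnames(m), md$sample)]
    MirCountExperiment(m, tp, attr(md, "timePointsOrder"))
}

#' Read / write gene-set collections in GMT format
#'
#' Standard GMT: one set per line, \code{set_id TAB description TAB gene1
#' TAB gene2 ...}. Duplicate genes within a line are deduplicated; blank
#' lines are skipped. A line with fewer than three fields (i.e. no genes),
#' or a duplicated set id, is an error.
#'
#' @param path GMT file path.
#' @param category category assigned to all sets in the file
#'   (\code{"GO_BP"}, \code{"GO_CC"} or \code{"KEGG"}), or a function of
#'   the set id returning the category.
#' @return a \linkS4class{GeneSetCollection}.
#' @export
readGmt <- function(path, category = "GO_BP") {
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
    if (!length(lines))
        return(GeneSetCollection(character(0), character(0), character(0),
                                 list()))
    parts <- strsplit(lines, "\t", fixed = TRUE)
    for (i in seq_along(parts)) {
        fields <- trimws(parts[[i]])
        fields <- fields[nzchar(fields) | seq_along(fields) <= 2L]
        if (length(fields) < 3L)
            stop(sprintf("GMT line %d has fewer than 3 fields (no genes)", i))
        parts[[i]] <- fields
    }
    ids <- vapply(parts, `[`, "", 1L)
    if (anyDuplicated(ids))
        stop(sprintf("duplicate set id in GMT: %s",
                     ids[duplicated(ids)][1L]))
    genes <- lapply(parts, function(f) unique(normalizeGeneId(f[-(1:2)])))
    cat_ <- if (is.function(category)) vapply(ids, category, "") else
        rep(category, length(ids))
    GeneSetCollection(ids, vapply(parts, `[`, "", 2L), cat_, genes)
}

#' @param collection a \linkS4class{GeneSetCollection}.
#' @rdname readGmt
#' @export
writeGmt <- function(collection, path) {
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(.versionHeader(), con)
    for (i in seq_along(collection@setId))
        writeLines(paste(c(collection@setId[i], collection@setName[i],
                           collection@genes[[i]]), collapse = "\t"), con)
    invisible(path)
}

#' Read / write a predicted miRNA-target table
#'
#' Two-column TSV (miRNA, gene), as exported from target-prediction
#' databases such as miRWalk. Returns a named list mapping each miRNA id to
#' its deduplicated character vector of predicted target genes. A miRNA
#' absent from the table has no entry in the list (\code{predictedFor}
#' returns \code{NULL}, "no prediction available"), which is distinct from
#' a miRNA present with an empty set.
#'
#' @param path TSV file path.
#' @param header logical; whether the file has a header line.
#' @return named list of character vectors (class
#'   \code{"PredictedTargets"}).
#' @export
readPredictedTargets <- function(path, header = TRUE) {
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[!startsWith(lines, "#")]
    if (header && length(lines)) lines <- lines[-1L]
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) return(structure(list(), class = "PredictedTargets"))
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf != 2L))
        stop(sprintf("malformed predicted-target row at line %d (expected 2 fields, got %d)",
                     which(nf != 2L)[1L] + as.integer(header), nf[nf != 2L][1L]))
    mir <- normalizeMirnaId(vapply(parts, `[`, "", 1L))
    gene <- normalizeGeneId(vapply(parts, `[`, "", 2L))
    if (any(!nzchar(gene)))
        stop(sprintf("empty gene id at line %d",
                     which(!nzchar(gene))[1L] + as.integer(header)))
    out <- lapply(split(gene, mir), unique)
    structure(out[order(names(out))], class = "PredictedTargets")
}

#' @param mirna a single miRNA id.
#' @param targets a \code{PredictedTargets} list.
#' @return \code{predictedFor}: the character vector of predicted genes, or
#'   \code{NULL} when the database offers no prediction for that miRNA.
#' @rdname readPredictedTargets
#' @export
predictedFor <- function(targets, mirna) {
    targets[[normalizeMirnaId(mirna)]]
}

#' @rdname readPredictedTargets
#' @export
writePredictedTargets <- function(targets, path) {
    df <- data.frame(
        miRNA = rep(names(targets), lengths(targets)),
        gene = unlist(targets, use.names = FALSE),
        stringsAsFactors = FALSE)
    .writeTsv(df, path)
}

#' Read / write a differential mRNA gene table
#'
#' Long-format TSV with columns \code{gene}, \code{comparison},
#' \code{direction} (\code{up}/\code{down}), \code{foldChange} (linear,
#' >= 0) and \code{fdr} (in [0,1]); one row per (gene, comparison). This is
#' the companion-transcriptome input against which predicted miRNA targets
#' are verified.
#'
#' @param path TSV file path.
#' @return a data.frame with normalized gene symbols.
#' @export
readDifferentialGeneTable <- function(path) {
    df <- .readTsv(path)
    need <- c("gene", "comparison", "direction", "foldChange", "fdr")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop(sprintf("differential gene table missing column(s): %s",
                     paste(miss, collapse = ", ")))
    df$gene <- normalizeGeneId(df$gene)
    df$comparison <- trimws(df$comparison)
    df$foldChange <- as.numeric(df$foldChange)
    df$fdr <- as.numeric(df$fdr)
    key <- paste(df$gene, df$comparison, sep = "\r")
    if (anyDuplicated(key)) {
        d <- df[duplicated(key), , drop = FALSE][1L, ]
        stop(sprintf("duplicate (gene, comparison) row: (%s, %s)",
                     d$gene, d$comparison))
    }
    if (!all(df$direction %in% c("up", "down")))
        stop("direction must be 'up' or 'down'")
    if (any(!is.finite(df$foldChange)) || any(df$foldChange < 0))
        stop("foldChange must be finite and >= 0")
    if (any(!is.finite(df$fdr)) || any(df$fdr < 0 | df$fdr > 1))
        stop("fdr must be in [0, 1]")
    df[, need]
}

#' @param table data.frame as returned by \code{readDifferentialGeneTable}.
#' @rdname readDifferentialGeneTable
#' @export
writeDifferentialGeneTable <- function(table, path) {
    .writeTsv(table[, c("gene", "comparison", "direction", "foldChange",
                        "fdr")], path)
}

#' Write a DifferentialResult table to TSV
#'
#' @param result a \linkS4class{DifferentialResult}.
#' @param path output TSV path.
#' @export
writeDifferentialResult <- function(result, path) {
    .writeTsv(as.data.frame(result), path)
}

#' Read / write a qPCR plate table
#'
#' Long-format TSV with columns \code{sample}, \code{assay}, \code{cq},
#' \code{designation} (\code{target}/\code{reference}/\code{spike_in}) and
#' \code{group}. Undetermined Cq values are encoded as \code{NA}.
#'
#' @param path TSV file path.
#' @return data.frame with those five columns.
#' @export
readQpcrPlate <- function(path) {
    df <- .readTsv(path)
    need <- c("sample", "assay", "cq", "designation", "group")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop(sprintf("qPCR plate missing column(s): %s",
                     paste(miss, collapse = ", ")))
    if (!all(df$designation %in% c("target", "reference", "spike_in")))
        stop("designation must be target, reference or spike_in")
    df$cq <- suppressWarnings(as.numeric(df$cq))
    if (any(df$cq < 0, na.rm = TRUE)) stop("Cq values must be >= 0")
    df[, need]
}

#' @param plate data.frame as returned by \code{readQpcrPlate}.
#' @rdname readQpcrPlate
#' @export
writeQpcrPlate <- function(plate, path) {
    .writeTsv(plate[, c("sample", "assay", "cq", "designation", "group")],
              path)
}
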