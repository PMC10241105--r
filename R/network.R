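# Bipartite miRNA -> gene-set network assembled from significant
# enrichment records. Edge weight = number of overlap genes, matching the
# chord-diagram convention where each section's size is proportional to
# the number of target genes associated with the term.

#' Build the bipartite miRNA-term network
#'
#' One edge per significant (miRNA, set) enrichment record, weighted by
#' the overlap size. Node tables are ordered deterministically: miRNAs by
#' id, terms by total incident weight descending then id.
#'
#' @param records enrichment data.frame (see \code{\link{enrichMirna}}).
#' @return list of class \code{"mirnaTermNetwork"} with \code{edges}
#'   (miRNA, setId, setName, category, weight, overlap),
#'   \code{mirnaNodes} (miRNA, totalWeight) and \code{termNodes} (setId,
#'   setName, category, totalWeight).
#' @export
buildNetwork <- function(records) {
    edges <- records[isTRUE0(records$significant), , drop = FALSE]
    edges <- edges[edges$k >= 1L, , drop = FALSE]
    if (!nrow(edges))
        warning("no significant enrichment records; network is empty")
    edges <- data.frame(miRNA = edges$miRNA, setId = edges$setId,
                        setName = edges$setName, category = edges$category,
                        weight = edges$k, overlap = edges$overlap,
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$miRNA, edges$setId), , drop = FALSE]
    rownames(edges) <- NULL
    mirnaW <- tapply(edges$weight, edges$miRNA, sum)
    mirnaNodes <- data.frame(miRNA = sort(names(mirnaW)),
                             totalWeight = as.integer(
                                 mirnaW[sort(names(mirnaW))]),
                             stringsAsFactors = FALSE, row.names = NULL)
    termW <- tapply(edges$weight, edges$setId, sum)
    terms <- unique(edges[, c("setId", "setName", "category")])
    terms$totalWeight <- as.integer(termW[terms$setId])
    terms <- terms[order(-terms$totalWeight, terms$setId), , drop = FALSE]
    rownames(terms) <- NULL
    structure(list(edges = edges, mirnaNodes = mirnaNodes,
                   termNodes = terms), class = "mirnaTermNetwork")
}

isTRUE0 <- function(x) if (is.null(x)) logical(0) else x %in% TRUE

#' Filter a network to terms matching a name pattern
#'
#' Retains terms whose name matches the (case-insensitive) pattern --
#' e.g. \code{"mitochondri"} selects the mitochondria-associated GO:CC
#' terms -- and drops miRNA nodes left without edges. Weights are carried
#' over from the full network, never recomputed.
#'
#' @param network a \code{"mirnaTermNetwork"}.
#' @param pattern regular expression / substring matched against
#'   \code{setName}, case-insensitively.
#' @return a filtered \code{"mirnaTermNetwork"}.
#' @export
subnetworkByTermPattern <- function(network, pattern) {
    ok <- tryCatch(suppressWarnings(grepl(pattern, network$termNodes$setName,
                                          ignore.case = TRUE)),
                   error = function(e)
                       stop(sprintf("invalid pattern '%s': %s", pattern,
                                    conditionMessage(e))))
    keepTerms <- network$termNodes$setId[ok]
    edges <- network$edges[network$edges$setId %in% keepTerms, ,
                           drop = FALSE]
    rownames(edges) <- NULL
    structure(list(
        edges = edges,
        mirnaNodes = network$mirnaNodes[
            network$mirnaNodes$miRNA %in% edges$miRNA, , drop = FALSE],
        termNodes = network$termNodes[ok, , drop = FALSE]),
        class = "mirnaTermNetwork")
}

#' @export
print.mirnaTermNetwork <- function(x, ...) {
    cat(sprintf("mirnaTermNetwork: %d miRNAs, %d terms, %d edges (total weight %d)\n",
                nrow(x$mirnaNodes), nrow(x$termNodes), nrow(x$edges),
                sum(x$edges$weight)))
    invisible(x)
}

#' Export a network for chord-diagram rendering
#'
#' Writes a square flow matrix over miRNA + term nodes as TSV (flows only
#' from miRNAs to terms; the matrix is zero elsewhere) and a JSON file of
#' node metadata. Output is byte-deterministic for a given network.
#'
#' @param network a \code{"mirnaTermNetwork"}.
#' @param path TSV path for the flow matrix; node metadata goes to
#'   \code{sub("\\\\.tsv$", "", path)} + \code{".nodes.json"}.
#' @return invisibly, the paths written.
#' @export
exportChord <- function(network, path) {
    mir <- network$mirnaNodes$miRNA
    term <- network$termNodes$setId
    nodes <- c(mir, term)
    flow <- matrix(0L, length(nodes), length(nodes),
                   dimnames = list(nodes, nodes))
    e <- network$edges
    for (i in seq_len(nrow(e)))
        flow[e$miRNA[i], e$setId[i]] <- flow[e$miRNA[i], e$setId[i]] +
            e$weight[i]
    df <- data.frame(node = rownames(flow), flow, check.names = FALSE,
                     stringsAsFactors = FALSE)
    .writeTsv(df, path)
    nodesPath <- paste0(sub("\\.tsv$", "", path), ".nodes.json")
    meta <- list(
        miRNAs = lapply(seq_len(nrow(network$mirnaNodes)), function(i)
            list(id = network$mirnaNodes$miRNA[i],
                 totalWeight = network$mirnaNodes$totalWeight[i])),
        terms = lapply(seq_len(nrow(network$termNodes)), function(i)
            list(id = network$termNodes$setId[i],
                 name = network$termNodes$setName[i],
                 category = network$termNodes$category[i],
                 totalWeight = network$termNodes$totalWeight[i])))
    jsonlite::write_json(meta, nodesPath, auto_unbox = TRUE, pretty = TRUE)
    invisible(c(path, nodesPath))
}

#' Export a network as Sankey links
#'
#' JSON with \code{nodes} (id, type) and \code{links}
#' (\code{source}, \code{target}, \code{value}); byte-deterministic.
#'
#' @param network a \code{"mirnaTermNetwork"}.
#' @param path output JSON path.
#' @return invisibly, \code{path}.
#' @export
exportSankey <- function(network, path) {
    e <- network$edges
    out <- list(
        nodes = c(lapply(network$mirnaNodes$miRNA, function(m)
                      list(id = m, type = "miRNA")),
                  lapply(network$termNodes$setId, function(t)
                      list(id = t, type = "term"))),
        links = lapply(seq_len(nrow(e)), function(i)
            list(source = e$miRNA[i], target = e$setId[i],
                 value = e$weight[i])))
    jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
    invisible(path)
}
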