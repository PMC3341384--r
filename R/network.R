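#' Construct a regulatory network from an edge table
#'
#' @param edges data.frame with columns `regulator`, `target` and optional
#'   `weight` (default 1).  One weight per ordered pair; duplicates are
#'   merged keeping the maximum, with a warning.
#' @param vertexOrder optional explicit vertex ordering; defaults to first
#'   appearance (regulator before target, line by line).
#' @return a [RegulatoryNetwork-class].
#' @export
RegulatoryNetwork <- function(edges, vertexOrder = NULL) {
    stopifnot(all(c("regulator", "target") %in% names(edges)))
    if (is.null(edges$weight)) edges$weight <- 1
    if (any(!is.finite(edges$weight) | edges$weight <= 0))
        stop("edge weights must be positive")
    key <- paste(edges$regulator, edges$target, sep = "\r")
    if (anyDuplicated(key)) {
        warning(sprintf("merged %d duplicate edge(s), keeping max weight",
                        sum(duplicated(key))))
        w <- tapply(edges$weight, key, max)
        first <- !duplicated(key)
        edges <- edges[first, , drop = FALSE]
        edges$weight <- as.numeric(w[key[first]])
    }
    if (is.null(vertexOrder)) {
        vertexOrder <- unique(as.vector(rbind(edges$regulator, edges$target)))
    }
    g <- igraph::graph_from_data_frame(
        data.frame(from = edges$regulator, to = edges$target,
                   weight = edges$weight, stringsAsFactors = FALSE),
        directed = TRUE,
        vertices = data.frame(name = vertexOrder, stringsAsFactors = FALSE))
    new("RegulatoryNetwork", graph = g, vertexOrder = vertexOrder)
}

#' Read a regulatory network from an edge-list TSV
#'
#' Lines are `regulator<TAB>target[<TAB>weight]`; missing weights default
#' to 1 (unweighted use).  Lines starting with `#` are comments.  Logs
#' vertex, edge and regulator counts.
#'
#' @param path file path.
#' @return a [RegulatoryNetwork-class].
#' @export
readEdgeList <- function(path) {
    lines <- readLines(path, encoding = "UTF-8")
    keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
    lineNo <- which(keep)
    parts <- strsplit(lines[keep], "\t", fixed = TRUE)
    if (length(parts) == 0L) stop("no edges in ", path)
    nf <- lengths(parts)
    if (any(nf < 2L | nf > 3L))
        stop(sprintf("malformed line %d: expected 2 or 3 fields, found %d",
             lineNo[nf < 2L | nf > 3L][1L], nf[nf < 2L | nf > 3L][1L]))
    w <- vapply(parts, function(p)
        if (length(p) == 3L) suppressWarnings(as.numeric(p[[3L]])) else 1,
        numeric(1L))
    if (anyNA(w))
        stop(sprintf("malformed weight at line %d", lineNo[is.na(w)][1L]))
    if (any(w <= 0))
        stop(sprintf("non-positive weight at line %d", lineNo[w <= 0][1L]))
    net <- RegulatoryNetwork(data.frame(
        regulator = vapply(parts, `[[`, character(1L), 1L),
        target = vapply(parts, `[[`, character(1L), 2L),
        weight = w, stringsAsFactors = FALSE))
    message(sprintf("readEdgeList: |V| = %d, |E| = %d, |R| = %d",
        length(networkVertices(net)), igraph::ecount(net@graph),
        length(regulators(net))))
    net
}

#' Write a network as an edge-list TSV
#'
#' @param net a [RegulatoryNetwork-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeEdgeListTSV <- function(net, path) {
    e <- networkEdges(net)
    writeLines(paste(e$regulator, e$target,
                     formatC(e$weight, digits = 10L, format = "g"),
                     sep = "\t"), path, useBytes = TRUE)
    invisible(path)
}

#' Transpose a network
#'
#' Reverses every edge (keeping its weight); vertices and their ordering
#' are unchanged, the regulator set is recomputed on the reversed graph.
#' Diffusion runs on the transpose so mass placed on target genes flows
#' backwards to their regulators.
#'
#' @param net a [RegulatoryNetwork-class].
#' @return the transposed [RegulatoryNetwork-class].
#' @export
transposeNetwork <- function(net) {
    new("RegulatoryNetwork", graph = igraph::reverse_edges(net@graph),
        vertexOrder = net@vertexOrder)
}

#' Row-stochastic transition matrix of a network
#'
#' `W[u, v] = w(u, v) / sum_v w(u, v)` over the network's stated vertex
#' ordering; vertices without outgoing edges (dangling) get all-zero rows,
#' so diffused mass on them simply decays.
#'
#' @param net a [RegulatoryNetwork-class].
#' @return a sparse `dgCMatrix` with rows summing to 1 or 0.
#' @export
transitionMatrix <- function(net) {
    vo <- net@vertexOrder
    e <- networkEdges(net)
    i <- match(e$regulator, vo)
    j <- match(e$target, vo)
    outw <- vapply(split(e$weight, i), sum, numeric(1L))
    W <- Matrix::sparseMatrix(i = i, j = j,
        x = e$weight / outw[as.character(i)],
        dims = c(length(vo), length(vo)), dimnames = list(vo, vo))
    W
}
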