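#' @name accessors
#' @title Accessors for tempomod classes
#' @description Small accessor generics so slots are never reached into
#'   directly.
#' @param x an object.
#' @return the corresponding component.
NULL

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setGeneric("timeLabels", function(x) standardGeneric("timeLabels"))
#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))
#' @rdname accessors
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))
#' @rdname accessors
#' @export
setGeneric("symbolMatrix", function(x) standardGeneric("symbolMatrix"))
#' @rdname accessors
#' @export
setGeneric("tauThreshold", function(x) standardGeneric("tauThreshold"))
#' @rdname accessors
#' @export
setGeneric("biclusterGenes", function(x) standardGeneric("biclusterGenes"))
#' @rdname accessors
#' @export
setGeneric("biclusterColumns", function(x) standardGeneric("biclusterColumns"))
#' @rdname accessors
#' @export
setGeneric("biclusterPattern", function(x) standardGeneric("biclusterPattern"))
#' @rdname accessors
#' @export
setGeneric("timeSpan", function(x) standardGeneric("timeSpan"))
#' @rdname accessors
#' @export
setGeneric("regulators", function(x) standardGeneric("regulators"))
#' @rdname accessors
#' @export
setGeneric("networkVertices", function(x) standardGeneric("networkVertices"))
#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname accessors
#' @export
setMethod("geneIds", "ExpressionTS", function(x) rownames(x@values))
#' @rdname accessors
#' @export
setMethod("geneIds", "DiscretizedTS", function(x) rownames(x@symbols))
#' @rdname accessors
#' @export
setMethod("timeLabels", "ExpressionTS", function(x) colnames(x@values))
#' @rdname accessors
#' @export
setMethod("exprValues", "ExpressionTS", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("missingMask", "ExpressionTS", function(x) x@missing)
#' @rdname accessors
#' @export
setMethod("symbolMatrix", "DiscretizedTS", function(x) x@symbols)
#' @rdname accessors
#' @export
setMethod("tauThreshold", "DiscretizedTS", function(x) x@tau)

#' @rdname accessors
#' @export
setMethod("biclusterGenes", "CCCBicluster", function(x) x@genes)
#' @rdname accessors
#' @export
setMethod("biclusterColumns", "CCCBicluster",
    function(x) seq.int(x@cStart, x@cEnd))
#' @rdname accessors
#' @export
setMethod("biclusterPattern", "CCCBicluster", function(x) x@pattern)
#' @rdname accessors
#' @export
setMethod("timeSpan", "CCCBicluster",
    function(x) c(x@cStart, x@cEnd + 1L))

#' @rdname accessors
#' @export
setMethod("regulators", "RegulatoryNetwork", function(x) {
    deg <- igraph::degree(x@graph, mode = "out")
    sort(names(deg)[deg > 0])
})
#' @rdname accessors
#' @export
setMethod("networkVertices", "RegulatoryNetwork", function(x) x@vertexOrder)
#' @rdname accessors
#' @export
setMethod("networkEdges", "RegulatoryNetwork", function(x) {
    e <- igraph::as_data_frame(x@graph, what = "edges")
    names(e) <- c("regulator", "target", "weight")[seq_along(names(e))]
    e
})

setMethod("show", "ExpressionTS", function(object) {
    cat(sprintf("ExpressionTS: %d genes x %d time points (%d missing cells)\n",
        nrow(object@values), ncol(object@values), sum(object@missing)))
})

setMethod("show", "DiscretizedTS", function(object) {
    cat(sprintf(
        "DiscretizedTS: %d genes x %d transition columns (tau = %g)\n",
        nrow(object@symbols), ncol(object@symbols), object@tau))
})

setMethod("show", "SuffixTree", function(object) {
    nd <- object@nodes
    cat(sprintf(
        "SuffixTree: %d rows, %d tokens, %d nodes (%d leaves)\n",
        length(object@rowIds), length(object@tokens), nd$nNodes,
        sum(nd$isLeaf)))
})

setMethod("show", "CCCBicluster", function(object) {
    cat(sprintf(
        "CCCBicluster %s: %d genes, columns [%d,%d] (time points %d..%d), pattern %s%s\n",
        object@id, length(object@genes), object@cStart, object@cEnd,
        object@cStart, object@cEnd + 1L, paste(object@pattern, collapse = ""),
        if (is.na(object@pValue)) "" else sprintf(", p = %.3g", object@pValue)))
})

setMethod("show", "RegulatoryNetwork", function(object) {
    cat(sprintf("RegulatoryNetwork: %d vertices, %d edges, %d regulators\n",
        length(object@vertexOrder), igraph::ecount(object@graph),
        length(regulators(object))))
})

setMethod("show", "TimeSeriesRanking", function(object) {
    cat(sprintf(
        "TimeSeriesRanking for module %s: %d time points%s\n",
        object@moduleId, length(object@timePoints),
        if (length(object@skipped))
            sprintf(" (%d skipped)", length(object@skipped)) else ""))
})

setMethod("show", "Snapshot", function(object) {
    cat(sprintf(
        "Snapshot of module %s at %s: %d regulators, %d targets, %d arcs\n",
        object@moduleId, object@timeLabel, nrow(object@tfs),
        length(object@targets), nrow(object@arcs)))
})
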