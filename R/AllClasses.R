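#' @import methods
#' @importFrom S4Vectors SimpleList
NULL

setOldClass("igraph")

#' Expression time series matrix
#'
#' Container for a genes x ordered-time-points matrix of real expression
#' values.  Row names are gene identifiers, column names the time labels in
#' chronological order; a parallel logical mask records missing cells.
#'
#' @slot values numeric matrix, genes in rows, time points in columns.
#' @slot missing logical matrix of the same shape; `TRUE` marks a missing
#'   measurement.
#' @export
setClass("ExpressionTS",
    representation(values = "matrix", missing = "matrix"))

setValidity("ExpressionTS", function(object) {
    v <- object@values; m <- object@missing
    if (is.null(rownames(v))) return("gene ids (row names) are required")
    if (anyDuplicated(rownames(v)))
        return(sprintf("duplicate gene id: %s",
                       rownames(v)[duplicated(rownames(v))][1L]))
    if (is.null(colnames(v))) return("time labels (column names) are required")
    if (ncol(v) < 2L) return("at least 2 time points are required")
    if (!identical(dim(v), dim(m))) return("values/missing shape mismatch")
    if (!is.logical(m)) return("missing mask must be logical")
    TRUE
})

#' Discretized transition matrix
#'
#' Symbolic encoding of the transitions between consecutive time points of
#' an expression matrix: one column per consecutive pair of time points,
#' every cell one of `D` (down-trend), `N` (no-trend), `U` (up-trend).
#' Transition column `c` (1-based) encodes the change between time points
#' `c` and `c + 1`.
#'
#' @slot symbols character matrix over `c("D","N","U")`; row names are gene
#'   ids, `ncol` equals the number of time points minus one.
#' @slot tau the non-negative threshold used: differences `>= tau` are `U`,
#'   `<= -tau` are `D`, anything else `N`.
#' @export
setClass("DiscretizedTS",
    representation(symbols = "matrix", tau = "numeric"))

setValidity("DiscretizedTS", function(object) {
    s <- object@symbols
    if (!all(s %in% c("D", "N", "U"))) return("symbols must be D, N or U")
    if (is.null(rownames(s))) return("gene ids (row names) are required")
    if (length(object@tau) != 1L || object@tau < 0)
        return("tau must be a single non-negative number")
    TRUE
})

#' Column-stamped row strings
#'
#' The alphabet-transformed view of a [DiscretizedTS-class]: every symbol gets its
#' transition-column index appended, so cell `(g, c)` holding `U` becomes the
#' stamped token `(U, c)`, and each row string ends with a terminator unique
#' to that row.  Tokens are atomic (symbol, column) pairs, printed as e.g.
#' `"U.3"`; column indices of any width are unambiguous.
#'
#' @slot tokens list of character vectors, one per gene, each token `"<sym>.<col>"`.
#' @slot terminators character vector of per-row terminator labels, unique.
#' @slot nColumns number of transition columns.
#' @export
setClass("StampedRows",
    representation(tokens = "list", terminators = "character",
                   nColumns = "integer"))

setValidity("StampedRows", function(object) {
    if (length(object@tokens) != length(object@terminators))
        return("one terminator per row is required")
    if (anyDuplicated(object@terminators))
        return("terminators must be unique across rows")
    TRUE
})

#' Generalized suffix tree of stamped rows
#'
#' Compressed trie of all suffixes of the stamped row strings, built online
#' (Ukkonen) in amortized linear time in the total token count.  Nodes carry
#' suffix links and subtree leaf counts; leaves are ordered by a depth-first
#' traversal so any node's leaf set is a contiguous range.
#'
#' @slot nodes list of integer node-table vectors as produced by the
#'   C-level builder (`start`, `end`, `slink`, `isLeaf`, `tokenDepth`,
#'   `firstPos`, `leafLo`, `leafHi`, `leafSuffix`, `edgeParent`, `edgeChild`).
#' @slot tokens integer vector, the concatenated token stream (terminators
#'   included).
#' @slot posRow,posCol per stream position: originating row index and
#'   transition column (`NA` for terminators).
#' @slot tokenLabels character labels parallel to `tokens`.
#' @slot rowIds gene ids of the rows the tree was built from.
#' @slot nCols number of transition columns.
#' @export
setClass("SuffixTree",
    representation(nodes = "list", tokens = "integer", posRow = "integer",
                   posCol = "integer", tokenLabels = "character",
                   rowIds = "character", nCols = "integer"))

#' A maximal contiguous-column coherent bicluster
#'
#' A set of genes sharing an identical discretized transition pattern over a
#' contiguous interval of transition columns.  Maximality means no further
#' gene matches the pattern on the interval (row-maximal) and extending the
#' interval by one column on either side strictly shrinks the gene set
#' (left-/right-maximal).
#'
#' @slot id character identifier (assigned after ordering).
#' @slot genes gene ids in the bicluster (at least 2).
#' @slot cStart,cEnd 1-based contiguous transition-column interval.
#' @slot pattern character vector of symbols, one per column of the interval.
#' @slot pValue,correctedP pattern p-value and its Bonferroni correction
#'   (`NA` until scored).
#' @export
setClass("CCCBicluster",
    representation(id = "character", genes = "character",
                   cStart = "integer", cEnd = "integer",
                   pattern = "character", pValue = "numeric",
                   correctedP = "numeric"),
    prototype(pValue = NA_real_, correctedP = NA_real_))

setValidity("CCCBicluster", function(object) {
    if (length(object@genes) < 1L) return("empty gene set")
    if (object@cEnd < object@cStart) return("empty column interval")
    if (length(object@pattern) != object@cEnd - object@cStart + 1L)
        return("pattern length must match the column interval")
    TRUE
})

#' List of CCC biclusters
#'
#' A [S4Vectors::SimpleList] of [CCCBicluster] objects, ordered by
#' descending area (genes x columns), then ascending start column, then
#' pattern.
#' @export
setClass("CCCBiclusterList", contains = "SimpleList",
    prototype = prototype(elementType = "CCCBicluster"))

#' Directed weighted regulatory network
#'
#' Wraps a directed `igraph` with a fixed vertex ordering (first appearance
#' in the edge list).  Regulators are the vertices with positive out-degree;
#' one weight per ordered vertex pair (duplicates are merged by maximum
#' at read time).
#'
#' @slot graph directed weighted igraph.
#' @slot vertexOrder character, the stated vertex ordering used by every
#'   matrix and vector built from the network.
#' @export
setClass("RegulatoryNetwork",
    representation(graph = "igraph", vertexOrder = "character"))

setValidity("RegulatoryNetwork", function(object) {
    if (!igraph::is_directed(object@graph)) return("graph must be directed")
    if (!setequal(object@vertexOrder, igraph::V(object@graph)$name))
        return("vertexOrder must list exactly the graph vertices")
    if (anyDuplicated(object@vertexOrder)) return("duplicate vertex in order")
    TRUE
})

#' Heat-kernel diffusion parameters
#'
#' @slot t non-negative heat diffusion coefficient; small values favour
#'   regulators close to the seed genes, larger values diffuse farther.
#' @slot Z positive number of discrete iterations approximating the kernel.
#'   Defaults `t = 0.25`, `Z = 100`.
#' @export
setClass("DiffusionParams",
    representation(t = "numeric", Z = "integer"),
    prototype(t = 0.25, Z = 100L))

setValidity("DiffusionParams", function(object) {
    if (length(object@t) != 1L || object@t < 0) return("t must be >= 0")
    if (length(object@Z) != 1L || object@Z < 1L) return("Z must be >= 1")
    TRUE
})

#' Per-time-point preference (seed) vector
#'
#' Initial mass over the network vertex ordering: the (absolute) expression
#' of the module genes present in the network at one time point, zero
#' elsewhere.
#'
#' @slot values named non-negative numeric over the vertex ordering.
#' @slot seeds module genes that received mass.
#' @slot excluded module genes absent from the network.
#' @slot timeLabel the time point the expression was taken from.
#' @export
setClass("PreferenceVector",
    representation(values = "numeric", seeds = "character",
                   excluded = "character", timeLabel = "character"))

setValidity("PreferenceVector", function(object) {
    if (any(object@values < 0)) return("preference mass must be non-negative")
    if (all(object@values == 0)) return("preference vector is all zero")
    TRUE
})

#' Regulator ranking at one time point
#'
#' @slot values named diffusion scores over all vertices.
#' @slot ranking data.frame with columns `regulator`, `score`, `rank`
#'   (descending score, ties broken lexicographically by id).
#' @slot timeLabel time point label.
#' @export
setClass("RankingVector",
    representation(values = "numeric", ranking = "data.frame",
                   timeLabel = "character"))

#' Rankings of a module across its time span
#'
#' @slot moduleId the bicluster id.
#' @slot timePoints labels of the (non-skipped) time points, in order.
#' @slot rankings list of [RankingVector-class], one per time point.
#' @slot skipped labels of time points skipped for lack of usable seed mass.
#' @export
setClass("TimeSeriesRanking",
    representation(moduleId = "character", timePoints = "character",
                   rankings = "list", skipped = "character"))

#' Regulatory snapshot of a module at one time point
#'
#' The displayed content of one frame: score-ordered top regulators, the
#' module's target genes, and the regulation arcs among displayed nodes.
#'
#' @slot moduleId,timeLabel identifiers of the frame.
#' @slot tfs data.frame `regulator`, `score`, `rank` in non-increasing score
#'   order (left to right on the top semicircle).
#' @slot targets displayed target genes (bottom semicircle).
#' @slot arcs data.frame `source`, `sink`, `relation` with relation one of
#'   `"regulates"`, `"regulated_by"`, `"neutral"`.
#' @slot topK the rank cutoff applied (or `NA` in threshold mode).
#' @slot scoreThreshold score cutoff applied (or `NA` in top-k mode).
#' @slot highlight nodes whose regulations are emphasized.
#' @export
setClass("Snapshot",
    representation(moduleId = "character", timeLabel = "character",
                   tfs = "data.frame", targets = "character",
                   arcs = "data.frame", topK = "integer",
                   scoreThreshold = "numeric", highlight = "character"))

setValidity("Snapshot", function(object) {
    sc <- object@tfs$score
    if (length(sc) > 1L && any(diff(sc) > 1e-12))
        return("regulators must be in non-increasing score order")
    nodes <- c(object@tfs$regulator, object@targets)
    if (nrow(object@arcs) &&
        !all(c(object@arcs$source, object@arcs$sink) %in% nodes))
        return("arc endpoints must be displayed nodes")
    TRUE
})
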