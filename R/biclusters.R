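#' Construct a bicluster
#'
#' @param genes gene ids.
#' @param cStart,cEnd contiguous 1-based transition-column interval.
#' @param pattern character symbols over the interval.
#' @param id identifier.
#' @return a [CCCBicluster-class].
#' @export
CCCBicluster <- function(genes, cStart, cEnd, pattern, id = NA_character_) {
    new("CCCBicluster", id = as.character(id), genes = genes,
        cStart = as.integer(cStart), cEnd = as.integer(cEnd),
        pattern = pattern)
}

# Deterministic ordering: descending area |I|*|J|, then ascending cStart,
# then lexicographic pattern, then first gene id.
.orderBiclusters <- function(bcs) {
    if (length(bcs) == 0L) return(bcs)
    area <- vapply(bcs, function(b)
        length(b@genes) * (b@cEnd - b@cStart + 1L), numeric(1L))
    cs <- vapply(bcs, function(b) b@cStart, integer(1L))
    pat <- vapply(bcs, function(b) paste(b@pattern, collapse = ""), character(1L))
    g1 <- vapply(bcs, function(b) b@genes[1L], character(1L))
    bcs <- bcs[order(-area, cs, pat, g1)]
    for (i in seq_along(bcs)) bcs[[i]]@id <- as.character(i)
    bcs
}

.asBiclusterList <- function(bcs) {
    lst <- S4Vectors::SimpleList(bcs)
    names(lst) <- vapply(bcs, function(b) b@id, character(1L))
    new("CCCBiclusterList", lst)
}

#' Enumerate all maximal CCC biclusters
#'
#' Every internal node of the generalized suffix tree whose path starts at a
#' stamped column and covers at least two rows is a right- and row-maximal
#' bicluster candidate; left-maximality holds unless an incoming suffix link
#' arrives from a node with an equal subtree leaf count (in that case every
#' occurrence of the pattern extends one column to the left with the same
#' row set, so the candidate is redundant).  Single-gene patterns are
#' discarded.  Runs in time linear in the matrix size.
#'
#' @param tree a [SuffixTree-class] built from the stamped rows of `d`
#'   (built on the fly when `NULL`).
#' @param d the [DiscretizedTS-class] the tree was built from.
#' @return a [CCCBiclusterList-class], ordered by descending area.
#' @export
enumerateBiclusters <- function(d, tree = NULL) {
    stopifnot(is(d, "DiscretizedTS"))
    if (is.null(tree)) tree <- buildSuffixTree(transformAlphabet(d))
    if (!identical(tree@rowIds, rownames(symbolMatrix(d))) ||
        tree@nCols != ncol(symbolMatrix(d)))
        stop("suffix tree does not match the discretized matrix")
    nd <- tree@nodes
    lc <- leafCounts(tree)
    nNodes <- nd$nNodes
    root <- nd$root

    internal <- !nd$isLeaf & seq_len(nNodes) != root
    cStart <- rep(NA_integer_, nNodes)
    fp <- nd$firstPos
    cStart[internal] <- tree@posCol[fp[internal]]

    cand <- which(internal & !is.na(cStart) & lc >= 2L)

    # left-maximality: an incoming suffix link from a node with an equal
    # leaf count disqualifies the target
    u <- which(internal & nd$slink > 0L & nd$slink != root)
    bad <- unique(nd$slink[u][lc[u] == lc[nd$slink[u]]])
    cand <- setdiff(cand, bad)

    s <- symbolMatrix(d)
    if (any(cStart[cand] + nd$tokenDepth[cand] - 1L > ncol(s)))
        stop("suffix tree path exceeds matrix columns (tree/matrix mismatch)")
    # gather row sets, then order with vectorized keys before building the
    # S4 objects (their invariants hold by construction, so the validated
    # prototype is reused without per-object validity checks)
    leafRows <- tree@posRow[nd$leafSuffix]
    rowsList <- lapply(cand, function(v)
        sort.int(unique(leafRows[seq.int(nd$leafLo[v], nd$leafHi[v])]),
                 method = "radix"))
    cs <- cStart[cand]
    ce <- cs + nd$tokenDepth[cand] - 1L
    ng <- lengths(rowsList)
    rowStr <- do.call(paste0, lapply(seq_len(ncol(s)), function(c) s[, c]))
    firstRow <- vapply(rowsList, `[`, integer(1L), 1L)
    pat <- substr(rowStr[firstRow], cs, ce)
    ord <- order(-(ng * (ce - cs + 1L)), cs, pat, tree@rowIds[firstRow])
    proto <- new("CCCBicluster", genes = c("a", "b"), cStart = 1L,
                 cEnd = 1L, pattern = "U")
    ids <- as.character(seq_along(ord))
    patSplit <- strsplit(pat, "", fixed = TRUE)
    bcs <- lapply(seq_along(ord), function(k) {
        i <- ord[k]
        b <- proto
        slot(b, "id", check = FALSE) <- ids[[k]]
        slot(b, "genes", check = FALSE) <- tree@rowIds[rowsList[[i]]]
        slot(b, "cStart", check = FALSE) <- cs[i]
        slot(b, "cEnd", check = FALSE) <- ce[i]
        slot(b, "pattern", check = FALSE) <- patSplit[[i]]
        b
    })
    .asBiclusterList(bcs)
}

#' Brute-force bicluster enumeration (test oracle)
#'
#' Exhaustively scans every contiguous column interval, groups rows by their
#' pattern on it, keeps groups of at least two rows, and rejects candidates
#' whose row set survives a one-column extension on either side.  Quadratic
#' in the number of columns; guarded to small inputs.
#'
#' @param d a [DiscretizedTS-class] with `nrow * ncol <= 10^4`.
#' @return a [CCCBiclusterList-class] in the same order as
#'   [enumerateBiclusters()].
#' @export
bruteForceBiclusters <- function(d) {
    s <- symbolMatrix(d)
    if (nrow(s) * ncol(s) > 1e4)
        stop("matrix too large for the brute-force oracle")
    nc <- ncol(s)
    bcs <- list()
    for (c1 in seq_len(nc)) for (c2 in c1:nc) {
        pat <- apply(s[, c1:c2, drop = FALSE], 1L, paste, collapse = "")
        for (p in unique(pat)) {
            rows <- which(pat == p)
            if (length(rows) < 2L) next
            if (c1 > 1L && length(unique(s[rows, c1 - 1L])) == 1L) next
            if (c2 < nc && length(unique(s[rows, c2 + 1L])) == 1L) next
            bcs[[length(bcs) + 1L]] <-
                CCCBicluster(rownames(s)[rows], c1, c2, s[rows[1L], c1:c2])
        }
    }
    .asBiclusterList(.orderBiclusters(bcs))
}

#' Re-verify a bicluster against its matrix
#'
#' Direct checks of the defining invariants: pattern agreement, row-,
#' left- and right-maximality.
#'
#' @param b a [CCCBicluster-class].
#' @param d the [DiscretizedTS-class] it was derived from.
#' @return `TRUE`, or a character description of the first violated
#'   invariant.
#' @export
verifyBicluster <- function(b, d) {
    s <- symbolMatrix(d)
    rows <- match(b@genes, rownames(s))
    if (anyNA(rows)) return("unknown gene id")
    J <- b@cStart:b@cEnd
    sub <- s[rows, J, drop = FALSE]
    if (!all(t(sub) == b@pattern)) return("pattern mismatch")
    patStr <- paste(b@pattern, collapse = "")
    allPat <- apply(s[, J, drop = FALSE], 1L, paste, collapse = "")
    if (sum(allPat == patStr) != length(rows)) return("not row-maximal")
    if (b@cStart > 1L && length(unique(s[rows, b@cStart - 1L])) == 1L)
        return("not left-maximal")
    if (b@cEnd < ncol(s) && length(unique(s[rows, b@cEnd + 1L])) == 1L)
        return("not right-maximal")
    TRUE
}

#' Export biclusters as JSON and TSV
#'
#' @param bcs a [CCCBiclusterList-class].
#' @param jsonPath,tsvPath output paths (`NULL` to skip either).
#' @return the bicluster table, invisibly.
#' @export
writeBiclusters <- function(bcs, jsonPath = NULL, tsvPath = NULL) {
    tab <- data.frame(
        id = vapply(bcs, function(b) b@id, character(1L)),
        n_genes = vapply(bcs, function(b) length(b@genes), integer(1L)),
        c_start = vapply(bcs, function(b) b@cStart, integer(1L)),
        c_end = vapply(bcs, function(b) b@cEnd, integer(1L)),
        time_start = vapply(bcs, function(b) b@cStart, integer(1L)),
        time_end = vapply(bcs, function(b) b@cEnd + 1L, integer(1L)),
        pattern = vapply(bcs, function(b)
            paste(b@pattern, collapse = ""), character(1L)),
        p_value = vapply(bcs, function(b) b@pValue, numeric(1L)),
        corrected_p = vapply(bcs, function(b) b@correctedP, numeric(1L)),
        genes = vapply(bcs, function(b)
            paste(b@genes, collapse = ","), character(1L)),
        stringsAsFactors = FALSE)
    if (!is.null(jsonPath)) {
        rec <- lapply(seq_along(bcs), function(i) {
            b <- bcs[[i]]
            list(id = b@id, genes = b@genes, c_start = b@cStart,
                 c_end = b@cEnd, time_span = c(b@cStart, b@cEnd + 1L),
                 pattern = paste(b@pattern, collapse = ""),
                 p_value = b@pValue, corrected_p = b@correctedP)
        })
        jsonlite::write_json(rec, jsonPath, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE, na = "null")
    }
    if (!is.null(tsvPath))
        utils::write.table(tab, tsvPath, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    invisible(tab)
}
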