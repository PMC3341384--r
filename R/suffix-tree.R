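.SYMBOLS <- c("D", "N", "U")

# Integer token stream for the C-level builder: stamped symbol (s, c) maps to
# (c - 1) * 3 + index(s); terminator of row i maps to 3 * nColumns + i.
.encodeStream <- function(rows) {
    nc <- rows@nColumns
    # vectorized decode over all rows at once (tokens are "<sym>.<col>")
    flat <- unlist(rows@tokens, use.names = FALSE)
    sym <- match(substr(flat, 1L, 1L), .SYMBOLS)
    col <- as.integer(substring(flat, 3L))
    if (anyNA(sym) || anyNA(col)) stop("not a stamped token stream")
    flatIds <- (col - 1L) * 3L + sym
    ends <- cumsum(lengths(rows@tokens))
    starts <- c(1L, ends[-length(ends)] + 1L)
    ids <- lapply(seq_along(rows@tokens), function(i)
        c(flatIds[starts[i]:ends[i]], 3L * nc + i))
    tokens <- unlist(ids, use.names = FALSE)
    lens <- lengths(ids)
    posRow <- rep.int(seq_along(ids), lens)
    offs <- unlist(lapply(lens, seq_len), use.names = FALSE)
    posCol <- ifelse(offs == lens, NA_integer_, offs)
    labels <- unlist(lapply(seq_along(ids), function(i)
        c(rows@tokens[[i]], rows@terminators[[i]])), use.names = FALSE)
    list(tokens = as.integer(tokens), posRow = as.integer(posRow),
         posCol = as.integer(posCol), labels = labels)
}

#' Build the generalized suffix tree of the stamped rows
#'
#' Concatenates the stamped row strings, each closed by its unique
#' terminator, and builds the suffix tree online (Ukkonen's algorithm,
#' amortized linear time in the total token count) at C level.  Suffix
#' links and subtree leaf counts are populated; they drive the
#' left-maximality test of the bicluster enumeration.
#'
#' @param rows a [StampedRows-class].
#' @return a [SuffixTree-class].
#' @export
buildSuffixTree <- function(rows) {
    stopifnot(is(rows, "StampedRows"))
    if (anyDuplicated(rows@terminators))
        stop("duplicate terminator across rows")
    if (any(lengths(rows@tokens) == 0L))
        stop("every row string must be non-empty")
    enc <- .encodeStream(rows)
    nd <- .cpp_build_gst(enc$tokens)
    new("SuffixTree", nodes = nd, tokens = enc$tokens,
        posRow = enc$posRow, posCol = enc$posCol,
        tokenLabels = enc$labels,
        rowIds = names(rows@tokens), nCols = rows@nColumns)
}

#' Number of leaves under each node
#'
#' @param tree a [SuffixTree-class].
#' @return integer vector over node ids; the root's count equals the total
#'   number of suffixes inserted.
#' @export
leafCounts <- function(tree) {
    nd <- tree@nodes
    nd$leafHi - nd$leafLo + 1L
}

#' Test substring membership via the tree
#'
#' Descends from the root matching stamped tokens; a token sequence is a
#' substring of some row iff the walk succeeds.
#'
#' @param tree a [SuffixTree-class].
#' @param tokens character vector of stamped tokens (e.g. `c("U.2","N.3")`).
#' @return `TRUE` or `FALSE`.
#' @export
hasSubstring <- function(tree, tokens) {
    if (length(tokens) == 0L) return(TRUE)
    dec <- decodeToken(tokens)
    ids <- (dec$column - 1L) * 3L + match(dec$symbol, .SYMBOLS)
    nd <- tree@nodes
    txt <- tree@tokens
    cur <- nd$root
    i <- 1L
    while (i <= length(ids)) {
        kids <- nd$edgeChild[nd$edgeParent == cur]
        nxt <- kids[txt[nd$start[kids]] == ids[i]]
        if (length(nxt) != 1L) return(FALSE)
        lab <- txt[seq.int(nd$start[nxt], nd$end[nxt])]
        k <- min(length(lab), length(ids) - i + 1L)
        if (!identical(lab[seq_len(k)], ids[seq.int(i, i + k - 1L)]))
            return(FALSE)
        i <- i + k
        cur <- nxt
    }
    TRUE
}
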