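#' Construct an expression time series
#'
#' @param values numeric matrix with gene ids as row names and time labels
#'   as column names (chronological order as given).
#' @param missing optional logical mask of missing cells; defaults to
#'   `is.na(values)`.
#' @return an [ExpressionTS-class].
#' @export
ExpressionTS <- function(values, missing = NULL) {
    if (is.null(missing)) missing <- is.na(values)
    dimnames(missing) <- dimnames(values)
    new("ExpressionTS", values = values, missing = missing)
}

.missing_tokens <- c("", "na", "nan", "null")

#' Read an expression time series from TSV
#'
#' Expects a UTF-8 tab-delimited file with a header row of time labels, one
#' gene per line, gene id in the first column.  Cells must be numeric or a
#' missing token (empty, `NA`, `NaN`, `null`; case-insensitive).
#'
#' @param path file path.
#' @return an [ExpressionTS-class] with the missing mask set.
#' @export
readExpressionTSV <- function(path) {
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) < 2L)
        stop("expression file needs a header and at least one gene row")
    header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
    tl <- header[-1L]
    if (length(tl) < 2L)
        stop("at least 2 time columns are required, found ", length(tl))
    body <- strsplit(lines[-1L], "\t", fixed = TRUE)
    nc <- length(header)
    # strsplit drops trailing empty fields; restore them so a trailing
    # missing cell is not miscounted as a ragged row
    nTabs <- nchar(lines[-1L]) - nchar(gsub("\t", "", lines[-1L], fixed = TRUE))
    body <- lapply(seq_along(body), function(i)
        c(body[[i]], rep("", nTabs[i] + 1L - length(body[[i]]))))
    widths <- lengths(body)
    if (any(widths != nc))
        stop(sprintf("ragged row at line %d: %d cells under a %d-column header",
             which(widths != nc)[1L] + 1L, widths[widths != nc][1L], nc))
    ids <- vapply(body, `[[`, character(1L), 1L)
    if (anyDuplicated(ids))
        stop("duplicate gene id: ", ids[duplicated(ids)][1L])
    cells <- t(vapply(body, function(r) r[-1L], character(length(tl))))
    if (length(tl) == 1L) cells <- matrix(cells, ncol = 1L)
    miss <- matrix(tolower(trimws(cells)) %in% .missing_tokens, nrow = nrow(cells))
    vals <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
    bad <- !miss & is.na(vals)
    if (any(bad))
        stop(sprintf("non-numeric cell '%s' for gene %s",
             cells[bad][1L], ids[which(rowSums(bad) > 0)[1L]]))
    vals[miss] <- NA_real_
    dimnames(vals) <- list(ids, tl)
    ExpressionTS(vals, structure(miss, dimnames = dimnames(vals)))
}

#' Write an expression time series to TSV
#'
#' Inverse of [readExpressionTSV()]; missing cells are written as `NA`.
#'
#' @param m an [ExpressionTS-class].
#' @param path output file path.
#' @param digits significant digits used for formatting.
#' @return `path`, invisibly.
#' @export
writeExpressionTSV <- function(m, path, digits = 10L) {
    v <- exprValues(m)
    v[missingMask(m)] <- NA
    txt <- apply(v, 2L, function(col)
        ifelse(is.na(col), "NA", formatC(col, digits = digits, format = "g")))
    if (nrow(v) == 1L) txt <- matrix(txt, nrow = 1L)
    lines <- c(paste(c("gene", timeLabels(m)), collapse = "\t"),
               paste(geneIds(m), apply(txt, 1L, paste, collapse = "\t"),
                     sep = "\t"))
    writeLines(lines, path, useBytes = TRUE)
    invisible(path)
}

#' Drop genes with missing measurements
#'
#' Keeps exactly the genes whose rows are fully observed and reports how
#' many were removed.  Idempotent.
#'
#' @param m an [ExpressionTS-class].
#' @return an [ExpressionTS-class] with no missing cells.
#' @export
filterMissing <- function(m) {
    keep <- rowSums(missingMask(m)) == 0L
    if (!any(keep))
        stop("all genes have missing values; nothing to analyze")
    removed <- sum(!keep)
    if (removed > 0L)
        message(sprintf("filterMissing: removed %d gene(s) with missing values",
                        removed))
    ExpressionTS(exprValues(m)[keep, , drop = FALSE],
                 missingMask(m)[keep, , drop = FALSE])
}

#' Normalize each gene to zero mean and unit standard deviation
#'
#' Rows are centred and scaled gene-wise; the standard deviation uses the
#' sample convention (divisor `|T| - 1`) by default, so `c(1,2,3)` maps to
#' `c(-1,0,1)`.  Constant rows carry no trend signal and are dropped with a
#' warning.
#'
#' @param m an [ExpressionTS-class] with no missing cells.
#' @param convention `"sample"` (divisor `n - 1`) or `"population"`
#'   (divisor `n`).
#' @return a normalized [ExpressionTS-class].
#' @export
normalizeByGene <- function(m, convention = c("sample", "population")) {
    convention <- match.arg(convention)
    if (any(missingMask(m)))
        stop("normalizeByGene requires a fully observed matrix; run filterMissing first")
    v <- exprValues(m)
    mu <- rowMeans(v)
    sdv <- apply(v, 1L, stats::sd)
    if (convention == "population")
        sdv <- sdv * sqrt((ncol(v) - 1) / ncol(v))
    keep <- sdv > 0
    if (!any(keep)) stop("all rows are constant; nothing to analyze")
    if (any(!keep))
        warning(sprintf("normalizeByGene: dropped %d constant row(s)",
                        sum(!keep)))
    out <- (v[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
    ExpressionTS(out)
}

#' Discretize transitions between consecutive time points
#'
#' Encodes each consecutive pair of measurements of a gene as an up-trend
#' (`U`, difference `>= tau`), down-trend (`D`, difference `<= -tau`) or
#' no-trend (`N`, otherwise).  Column `c` of the result describes the
#' transition between time points `c` and `c + 1`.
#'
#' @param m an [ExpressionTS-class] with no missing cells.
#' @param tau non-negative threshold on the difference; default 0 (any
#'   strict increase is `U`, any strict decrease is `D`, exact ties `U` by
#'   the `>=` rule).
#' @return a [DiscretizedTS-class] with `ncol(m) - 1` columns.
#' @export
discretizeTransitions <- function(m, tau = 0) {
    if (length(tau) != 1L || is.na(tau) || tau < 0)
        stop("tau must be a single non-negative number")
    if (any(missingMask(m)))
        stop("discretizeTransitions requires a fully observed matrix")
    v <- exprValues(m)
    d <- v[, -1L, drop = FALSE] - v[, -ncol(v), drop = FALSE]
    s <- matrix("N", nrow = nrow(d), ncol = ncol(d))
    s[d <= -tau] <- "D"
    s[d >= tau] <- "U"   # at tau = 0 an exact tie is U: the >= rule fires first
    dimnames(s) <- list(rownames(v),
                        paste0(colnames(v)[-ncol(v)], "->", colnames(v)[-1L]))
    new("DiscretizedTS", symbols = s, tau = tau)
}

#' Stamp column numbers onto symbols
#'
#' The alphabet transformation: cell `(g, c)` holding symbol `s` becomes
#' the stamped token `(s, c)`, printed `"s.c"`, and each row string receives
#' a terminator unique to that row.  Stamping makes equal symbols in
#' different columns distinct, so common substrings of the row strings are
#' exactly shared patterns over shared contiguous column intervals.
#'
#' @param d a [DiscretizedTS-class].
#' @return a [StampedRows-class].
#' @export
transformAlphabet <- function(d) {
    s <- symbolMatrix(d)
    nc <- ncol(s)
    toks <- lapply(seq_len(nrow(s)), function(i)
        paste0(s[i, ], ".", seq_len(nc)))
    names(toks) <- rownames(s)
    new("StampedRows", tokens = toks,
        terminators = paste0("$", seq_len(nrow(s))),
        nColumns = nc)
}

#' Decode a stamped token
#'
#' @param token character vector of stamped tokens like `"U.12"`.
#' @return data.frame with columns `symbol` and `column`.
#' @export
decodeToken <- function(token) {
    m <- regmatches(token, regexec("^([DNU])\\.([0-9]+)$", token))
    bad <- lengths(m) != 3L
    if (any(bad)) stop("not a stamped token: ", token[bad][1L])
    data.frame(symbol = vapply(m, `[[`, character(1L), 2L),
               column = as.integer(vapply(m, `[[`, character(1L), 3L)))
}

#' Write a discretized matrix as TSV (debug output)
#'
#' @param d a [DiscretizedTS-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeDiscretizedTSV <- function(d, path) {
    s <- symbolMatrix(d)
    lines <- c(paste(c("gene", colnames(s)), collapse = "\t"),
               paste(rownames(s), apply(s, 1L, paste, collapse = "\t"),
                     sep = "\t"))
    writeLines(lines, path, useBytes = TRUE)
    invisible(path)
}
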