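#' Empirical per-column symbol null model
#'
#' The null model for bicluster pattern significance: transition columns are
#' treated as independent, each with the empirical symbol frequencies of
#' the full discretized matrix.  (A matrix-of-equal-size null; a
#' higher-order column dependence model is a documented extension point.)
#'
#' @param d a [DiscretizedTS-class].
#' @return a `PatternNullModel`: numeric matrix of frequencies, symbols
#'   `D`,`N`,`U` in rows, transition columns in columns; each column sums
#'   to 1.
#' @export
patternNullModel <- function(d) {
    s <- symbolMatrix(d)
    f <- vapply(seq_len(ncol(s)), function(c)
        tabulate(match(s[, c], .SYMBOLS), 3L) / nrow(s), numeric(3L))
    rownames(f) <- .SYMBOLS
    colnames(f) <- colnames(s)
    structure(f, class = "PatternNullModel")
}

#' Pattern p-value of a bicluster
#'
#' Probability that at least `|I|` of `nGenes` independent random rows would
#' match the bicluster's pattern on its column interval by chance, in a
#' matrix of equal size drawn from the null model: with
#' `p(P) = prod_c f_c(P_c)`, the p-value is `P(X >= |I|)` for
#' `X ~ Binomial(nGenes, p(P))`, evaluated by the numerically stable upper
#' tail.
#'
#' @param b a [CCCBicluster-class].
#' @param model a `PatternNullModel` covering `b`'s columns.
#' @param nGenes number of rows of the matrix.
#' @return p-value in `[0, 1]`.
#' @export
patternPValue <- function(b, model, nGenes) {
    J <- b@cStart:b@cEnd
    if (max(J) > ncol(model)) stop("bicluster columns outside the null model")
    pP <- prod(model[cbind(match(b@pattern, .SYMBOLS), J)])
    if (pP == 0) {
        message("pattern contains a zero-frequency symbol; p-value 0")
        return(0)
    }
    stats::pbinom(length(b@genes) - 1L, nGenes, pP, lower.tail = FALSE)
}

#' Bonferroni correction
#'
#' @param pvals p-values in `[0, 1]`.
#' @param m number of tests, at least `length(pvals)`.
#' @return `pmin(1, pvals * m)`, order preserved.
#' @export
bonferroni <- function(pvals, m = length(pvals)) {
    if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
        stop("p-values must lie in [0, 1]")
    if (m < length(pvals)) stop("m must be at least the number of p-values")
    pmin(1, pvals * m)
}

#' Score a bicluster list
#'
#' Attaches the pattern p-value and its Bonferroni correction (factor =
#' number of enumerated biclusters, the family of tests performed) to every
#' bicluster.
#'
#' @param bcs a [CCCBiclusterList-class].
#' @param d the [DiscretizedTS-class] they came from.
#' @return the scored [CCCBiclusterList-class].
#' @export
scoreBiclusters <- function(bcs, d) {
    model <- patternNullModel(d)
    n <- nrow(symbolMatrix(d))
    p <- vapply(bcs, patternPValue, numeric(1L), model = model, nGenes = n)
    cp <- bonferroni(p, length(bcs))
    out <- lapply(seq_along(bcs), function(i) {
        b <- bcs[[i]]; b@pValue <- p[i]; b@correctedP <- cp[i]; b
    })
    .asBiclusterList(out)
}

#' Cell-based Jaccard similarity of two biclusters
#'
#' Computed on matrix cells, i.e. (gene, transition-column) pairs, so two
#' biclusters overlap only to the extent that they cover the same genes in
#' the same columns.
#'
#' @param a,b [CCCBicluster-class] objects over the same matrix.
#' @return similarity in `[0, 1]`; 1 iff the `(I, J)` pairs are identical.
#' @export
jaccardSimilarity <- function(a, b) {
    ga <- length(a@genes); gb <- length(b@genes)
    ja <- a@cEnd - a@cStart + 1L; jb <- b@cEnd - b@cStart + 1L
    gi <- length(intersect(a@genes, b@genes))
    ji <- max(0L, min(a@cEnd, b@cEnd) - max(a@cStart, b@cStart) + 1L)
    inter <- gi * ji
    union <- ga * ja + gb * jb - inter
    inter / union
}

#' Filter scored biclusters
#'
#' Removes biclusters with corrected pattern p-value above `pCut`, fewer
#' than `minGenes` genes, or spanning fewer than `minTimepoints` time
#' points; then scans the survivors in ascending corrected-p order and
#' greedily discards any bicluster whose cell Jaccard with an already kept
#' one exceeds `jacCut` (the more significant member of an overlapping pair
#' is kept).
#'
#' @param bcs a scored [CCCBiclusterList-class].
#' @param pCut corrected p-value cutoff (default 0.01).
#' @param jacCut Jaccard overlap cutoff (default 0.25).
#' @param minGenes,minTimepoints size filters (defaults 2 and 2; a module
#'   spanning columns `[cStart, cEnd]` covers `cEnd - cStart + 2` time
#'   points).
#' @return the filtered [CCCBiclusterList-class].
#' @export
filterBiclusters <- function(bcs, pCut = 0.01, jacCut = 0.25,
                             minGenes = 2L, minTimepoints = 2L) {
    cp <- vapply(bcs, function(b) b@correctedP, numeric(1L))
    if (anyNA(cp)) stop("biclusters must be scored first")
    ng <- vapply(bcs, function(b) length(b@genes), integer(1L))
    nt <- vapply(bcs, function(b) b@cEnd - b@cStart + 2L, integer(1L))
    keep <- which(cp <= pCut & ng >= minGenes & nt >= minTimepoints)
    keep <- keep[order(cp[keep], seq_along(keep))]
    kept <- integer(0L)
    for (i in keep) {
        ok <- TRUE
        for (j in kept) {
            if (jaccardSimilarity(bcs[[i]], bcs[[j]]) > jacCut) {
                ok <- FALSE; break
            }
        }
        if (ok) kept <- c(kept, i)
    }
    .asBiclusterList(lapply(sort(kept), function(i) bcs[[i]]))
}

#' Hypergeometric annotation enrichment of a module
#'
#' Per annotation term, the upper-tail hypergeometric probability of
#' drawing at least the observed number of term genes when sampling the
#' module from the background, Bonferroni-corrected over the tested terms.
#' Terms with corrected p below 0.01 are flagged highly significant.
#'
#' @param moduleGenes gene set of the module (subset of `background`).
#' @param annotations named list mapping term id to gene set, or a
#'   two-column data.frame (`gene`, `term`).
#' @param background the gene universe (default: all annotated genes is NOT
#'   assumed — pass the filtered expression genes).
#' @param alpha corrected-p significance flag threshold.
#' @return data.frame with columns `term`, `k`, `K`, `n`, `N_bg`, `p`,
#'   `corrected_p`, `significant`, ordered by ascending p.
#' @export
hypergeomEnrichment <- function(moduleGenes, annotations, background,
                                alpha = 0.01) {
    if (length(background) == 0L) stop("empty background")
    if (!all(moduleGenes %in% background))
        stop("module genes must be a subset of the background")
    if (is.data.frame(annotations))
        annotations <- split(annotations[[1L]], annotations[[2L]])
    Nbg <- length(unique(background))
    n <- length(unique(moduleGenes))
    terms <- names(annotations)
    K <- vapply(annotations, function(g)
        length(intersect(g, background)), integer(1L))
    k <- vapply(annotations, function(g)
        length(intersect(g, moduleGenes)), integer(1L))
    tested <- which(K > 0L)
    p <- stats::phyper(k[tested] - 1L, K[tested], Nbg - K[tested], n,
                       lower.tail = FALSE)
    cp <- bonferroni(p, length(tested))
    out <- data.frame(term = terms[tested], k = k[tested], K = K[tested],
                      n = n, N_bg = Nbg, p = p, corrected_p = cp,
                      significant = cp < alpha, stringsAsFactors = FALSE,
                      row.names = NULL)
    out[order(out$p, out$term), , drop = FALSE]
}

#' Read a gene-to-term annotation map
#'
#' Two-column TSV, one `gene<TAB>term` pair per line.
#'
#' @param path file path.
#' @return data.frame with columns `gene` and `term`.
#' @export
readAnnotations <- function(path) {
    a <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("gene", "term"),
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "#")
    a
}
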