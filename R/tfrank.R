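#' Diffusion parameters
#'
#' @param t heat diffusion coefficient (default 0.25).
#' @param Z iteration count (default 100).
#' @return a [DiffusionParams-class].
#' @export
DiffusionParams <- function(t = 0.25, Z = 100L) {
    new("DiffusionParams", t = t, Z = as.integer(Z))
}

#' Build the per-time-point preference vector of a module
#'
#' Places the expression of each module gene at the given time point on its
#' network vertex: the absolute value by default (the diffusion score is
#' additive, so up- and downregulated seeds both count), or the value
#' clipped at zero in signed mode.  Module genes absent from the network
#' are excluded with a warning.
#'
#' @param moduleGenes gene set of the module.
#' @param expr the [ExpressionTS-class] (normalized).
#' @param timePoint one of `timeLabels(expr)`.
#' @param net the [RegulatoryNetwork-class] (original orientation; only its
#'   vertex set and ordering are used).
#' @param useAbsolute use `|e(u)|` (default `TRUE`) or `max(e(u), 0)`.
#' @return a [PreferenceVector-class] over the network vertex ordering.
#' @export
buildPreferenceVector <- function(moduleGenes, expr, timePoint, net,
                                  useAbsolute = TRUE) {
    tl <- timeLabels(expr)
    if (!timePoint %in% tl) stop("unknown time point: ", timePoint)
    vo <- networkVertices(net)
    inNet <- intersect(moduleGenes, vo)
    excluded <- setdiff(moduleGenes, vo)
    if (length(excluded))
        warning(sprintf("%d module gene(s) absent from the network excluded: %s",
                length(excluded), paste(excluded, collapse = ", ")))
    if (length(inNet) == 0L)
        stop("no module gene is present in the network")
    e <- exprValues(expr)[inNet, timePoint]
    mass <- if (useAbsolute) abs(e) else pmax(e, 0)
    p0 <- stats::setNames(numeric(length(vo)), vo)
    p0[inNet] <- mass
    if (all(p0 == 0))
        stop("preference vector is all zero at time point ", timePoint)
    new("PreferenceVector", values = p0, seeds = inNet,
        excluded = excluded, timeLabel = as.character(timePoint))
}

#' Heat-kernel diffusion of a preference vector
#'
#' Discrete approximation of the heat-kernel ranking `p_0 exp(-t L)` with
#' `L = I - W`: `Z` iterations of
#' `p <- (1 - t/Z) p + (t/Z) (p W)`, i.e. `p_0 (I - (t/Z) L)^Z`, applied as
#' sparse vector-matrix products.  For `t/Z <= 1` every update is a convex
#' combination, so mass stays non-negative; when `W` is row-stochastic with
#' no zero rows total mass is conserved exactly.
#'
#' @param p0 a [PreferenceVector-class] (or bare named numeric).
#' @param W row-stochastic-or-zero transition matrix over the same vertex
#'   ordering (see [transitionMatrix()]); for regulator ranking, the matrix
#'   of the transposed network.
#' @param params a [DiffusionParams-class].
#' @return a [RankingVector-class] holding the diffused scores.
#' @export
heatKernelDiffuse <- function(p0, W, params = DiffusionParams()) {
    tl <- NA_character_
    if (is(p0, "PreferenceVector")) {
        tl <- p0@timeLabel
        p0 <- p0@values
    }
    if (length(p0) != nrow(W)) stop("dimension mismatch between p0 and W")
    if (!is.null(names(p0)) && !identical(names(p0), rownames(W)))
        stop("p0 and W use different vertex orderings")
    a <- params@t / params@Z
    if (a > 1)
        warning("t/Z > 1: the update leaves the simplex and may go negative")
    p <- p0
    for (z in seq_len(params@Z)) {
        p <- (1 - a) * p + a * as.numeric(p %*% W)
    }
    names(p) <- rownames(W)
    new("RankingVector", values = p, ranking = data.frame(),
        timeLabel = tl)
}

#' Restrict diffusion scores to regulators and rank them
#'
#' @param p a [RankingVector-class] (or named numeric of scores).
#' @param net the ORIGINAL (untransposed) [RegulatoryNetwork-class], whose
#'   positive-out-degree vertices define the regulator set.
#' @return a [RankingVector-class] whose `ranking` table lists regulators
#'   by descending score, ties broken lexicographically by id, ranks from 1.
#' @export
rankRegulators <- function(p, net) {
    v <- if (is(p, "RankingVector")) p@values else p
    R <- regulators(net)
    if (length(R) == 0L) stop("network has no regulators")
    sc <- v[R]
    ord <- order(-sc, R)
    rk <- data.frame(regulator = R[ord], score = as.numeric(sc[ord]),
                     rank = seq_along(R), stringsAsFactors = FALSE,
                     row.names = NULL)
    if (anyDuplicated(rk$score))
        message("tied regulator scores broken lexicographically")
    new("RankingVector", values = v, ranking = rk,
        timeLabel = if (is(p, "RankingVector")) p@timeLabel else NA_character_)
}

#' Rank a module's regulators at every time point of its span
#'
#' A bicluster over transition columns `[cStart, cEnd]` spans the original
#' time points `cStart .. cEnd + 1`.  For each of them the module's
#' preference vector is built, diffused over the transposed network (mass
#' flows from targets to their regulators), and the regulators are ranked.
#' Time points with no usable seed mass are skipped with a warning.
#'
#' @param b a [CCCBicluster-class].
#' @param expr the [ExpressionTS-class] the module came from.
#' @param net the [RegulatoryNetwork-class] in its original orientation.
#' @param params a [DiffusionParams-class].
#' @param useAbsolute see [buildPreferenceVector()].
#' @return a [TimeSeriesRanking-class].
#' @export
rankModuleOverTime <- function(b, expr, net, params = DiffusionParams(),
                               useAbsolute = TRUE) {
    tl <- timeLabels(expr)
    idx <- b@cStart:(b@cEnd + 1L)
    if (max(idx) > length(tl))
        stop("module time span exceeds the expression matrix")
    Wt <- transitionMatrix(transposeNetwork(net))
    rankings <- list()
    kept <- character(0L)
    skipped <- character(0L)
    for (tp in tl[idx]) {
        pv <- tryCatch(
            buildPreferenceVector(b@genes, expr, tp, net, useAbsolute),
            error = function(e) e)
        if (inherits(pv, "error")) {
            warning(sprintf("time point %s skipped: %s", tp,
                            conditionMessage(pv)))
            skipped <- c(skipped, tp)
            next
        }
        rk <- rankRegulators(heatKernelDiffuse(pv, Wt, params), net)
        rankings[[length(rankings) + 1L]] <- rk
        kept <- c(kept, tp)
    }
    new("TimeSeriesRanking", moduleId = b@id, timePoints = kept,
        rankings = rankings, skipped = skipped)
}

#' Flatten a time-series ranking to a table
#'
#' @param tsr a [TimeSeriesRanking-class].
#' @return data.frame with columns `module`, `time`, `rank`, `regulator`,
#'   `score`.
#' @export
rankingTable <- function(tsr) {
    do.call(rbind, lapply(seq_along(tsr@rankings), function(i) {
        rk <- tsr@rankings[[i]]@ranking
        data.frame(module = tsr@moduleId, time = tsr@timePoints[i],
                   rank = rk$rank, regulator = rk$regulator,
                   score = rk$score, stringsAsFactors = FALSE)
    }))
}
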