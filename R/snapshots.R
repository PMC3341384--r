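#' Build a regulatory snapshot of a module at one time point
#'
#' Keeps the top `topK` regulators of the ranking (or, in threshold mode,
#' all regulators scoring at least `scoreThreshold`), pairs them with the
#' module's target genes, and collects the network's regulation arcs among
#' the displayed nodes.  Arcs into a highlighted node are labeled
#' `regulated_by`, arcs out of a highlighted node `regulates`; with an
#' empty highlight set every arc is neutral.
#'
#' @param b the [CCCBicluster-class] the frame belongs to.
#' @param ranking a [RankingVector-class] with its ranking table (one time
#'   point).
#' @param net the [RegulatoryNetwork-class] (original orientation).
#' @param topK number of regulators kept (default 30).
#' @param scoreThreshold alternative cutoff: keep regulators with score
#'   `>= scoreThreshold` instead of a rank cutoff (`NA` = top-k mode).
#' @param highlight nodes whose regulations are emphasized.
#' @return a [Snapshot-class].
#' @export
buildSnapshot <- function(b, ranking, net, topK = 30L,
                          scoreThreshold = NA_real_,
                          highlight = character(0L)) {
    rk <- ranking@ranking
    if (is.null(rk) || nrow(rk) == 0L) stop("empty ranking")
    if (is.na(scoreThreshold)) {
        if (topK < 1L) stop("topK must be >= 1")
        tfs <- rk[rk$rank <= topK, , drop = FALSE]
    } else {
        tfs <- rk[rk$score >= scoreThreshold, , drop = FALSE]
    }
    targets <- sort(b@genes)
    nodes <- c(tfs$regulator, targets)
    e <- networkEdges(net)
    e <- e[e$regulator %in% tfs$regulator & e$target %in% nodes, ,
           drop = FALSE]
    relation <- rep("neutral", nrow(e))
    relation[e$regulator %in% highlight] <- "regulates"
    relation[e$target %in% highlight] <- "regulated_by"
    arcs <- data.frame(source = e$regulator, sink = e$target,
                       relation = relation, stringsAsFactors = FALSE,
                       row.names = NULL)
    arcs <- arcs[order(arcs$source, arcs$sink), , drop = FALSE]
    row.names(arcs) <- NULL
    new("Snapshot", moduleId = b@id, timeLabel = ranking@timeLabel,
        tfs = tfs, targets = targets, arcs = arcs,
        topK = if (is.na(scoreThreshold)) as.integer(topK) else NA_integer_,
        scoreThreshold = scoreThreshold, highlight = highlight)
}

# Node anchor positions on the two semicircles.  The top semicircle holds
# regulators left to right in score order with a radius 1.25 times the
# bottom one, which holds the targets.  SVG y grows downward.
.snapshotLayout <- function(nTF, nTargets, cx = 500, cy = 520, rBottom = 336) {
    rTop <- 1.25 * rBottom
    angle <- function(i, n) pi * (1 - (i - 0.5) / n)
    tf <- if (nTF) {
        th <- angle(seq_len(nTF), nTF)
        data.frame(x = cx + rTop * cos(th), y = cy - rTop * sin(th))
    } else data.frame(x = numeric(0), y = numeric(0))
    tg <- if (nTargets) {
        th <- angle(seq_len(nTargets), nTargets)
        data.frame(x = cx + rBottom * cos(th), y = cy + rBottom * sin(th))
    } else data.frame(x = numeric(0), y = numeric(0))
    list(tf = tf, target = tg, cx = cx, cy = cy)
}

.fmt <- function(x) sprintf("%.2f", x)

#' Render a snapshot as a standalone SVG file
#'
#' Double semicircle layout: regulators on the larger top semicircle, left
#' to right in non-increasing score order; targets on the bottom
#' semicircle; regulations as cubic arcs between node anchors.  Orange arcs
#' mark `regulates` and green arcs `regulated_by` relations of highlighted
#' nodes; other arcs are gray.  Output bytes are deterministic for a fixed
#' input.
#'
#' @param s a [Snapshot-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
renderSnapshotSVG <- function(s, path) {
    lay <- .snapshotLayout(nrow(s@tfs), length(s@targets))
    nodes <- rbind(
        if (nrow(s@tfs)) data.frame(id = s@tfs$regulator, x = lay$tf$x,
            y = lay$tf$y, kind = "tf", stringsAsFactors = FALSE),
        if (length(s@targets)) data.frame(id = s@targets, x = lay$target$x,
            y = lay$target$y, kind = "target", stringsAsFactors = FALSE))
    col <- c(regulates = "#e6821e", regulated_by = "#2e9e4f",
             neutral = "#b0b0b0")
    out <- c(
        "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
        "<svg xmlns=\"http://www.w3.org/2000/svg\" version=\"1.1\" width=\"1000\" height=\"1000\" viewBox=\"0 0 1000 1000\">",
        sprintf("<title>module %s at %s</title>", s@moduleId, s@timeLabel),
        "<rect width=\"1000\" height=\"1000\" fill=\"#ffffff\"/>")
    ix <- stats::setNames(seq_len(nrow(nodes)), nodes$id)
    for (k in seq_len(nrow(s@arcs))) {
        a <- s@arcs[k, ]
        p1 <- nodes[ix[[a$source]], ]
        p2 <- nodes[ix[[a$sink]], ]
        mx <- (p1$x + p2$x) / 2
        out <- c(out, sprintf(
            "<path d=\"M %s %s C %s %s, %s %s, %s %s\" fill=\"none\" stroke=\"%s\" stroke-width=\"%s\" opacity=\"0.8\"/>",
            .fmt(p1$x), .fmt(p1$y), .fmt(mx), .fmt(lay$cy),
            .fmt(mx), .fmt(lay$cy), .fmt(p2$x), .fmt(p2$y),
            col[[a$relation]], if (a$relation == "neutral") "1" else "2.5"))
    }
    for (k in seq_len(nrow(nodes))) {
        nd <- nodes[k, ]
        hl <- nd$id %in% s@highlight
        out <- c(out, sprintf(
            "<circle cx=\"%s\" cy=\"%s\" r=\"%s\" fill=\"%s\" stroke=\"#404040\"/>",
            .fmt(nd$x), .fmt(nd$y), if (hl) "7" else "5",
            if (nd$kind == "tf") (if (hl) "#e6821e" else "#4878b0")
            else "#909090"))
        dy <- if (nd$kind == "tf") -10 else 16
        out <- c(out, sprintf(
            "<text x=\"%s\" y=\"%s\" font-size=\"9\" font-family=\"monospace\" text-anchor=\"middle\">%s</text>",
            .fmt(nd$x), .fmt(nd$y + dy), nd$id))
    }
    out <- c(out, "</svg>")
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(out, con, useBytes = TRUE)
    invisible(path)
}

#' Render one snapshot per time point of a module
#'
#' Writes `module_<id>_t<label>.svg` per (non-skipped) time point, with
#' consistent node identity across frames, plus a rank-trajectory TSV
#' (regulator x time matrix of ranks) alongside.
#'
#' @param tsr a [TimeSeriesRanking-class].
#' @param b the corresponding [CCCBicluster-class].
#' @param net the [RegulatoryNetwork-class].
#' @param outDir output directory (created if needed).
#' @param topK,scoreThreshold,highlight see [buildSnapshot()].
#' @return character vector of written SVG paths, invisibly.
#' @export
renderSnapshotSeries <- function(tsr, b, net, outDir, topK = 30L,
                                 scoreThreshold = NA_real_,
                                 highlight = character(0L)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    paths <- character(0L)
    for (i in seq_along(tsr@rankings)) {
        snap <- buildSnapshot(b, tsr@rankings[[i]], net, topK = topK,
                              scoreThreshold = scoreThreshold,
                              highlight = highlight)
        p <- file.path(outDir, sprintf("module_%s_t%s.svg", b@id,
                                       gsub("[^A-Za-z0-9._-]", "_",
                                            tsr@timePoints[i])))
        renderSnapshotSVG(snap, p)
        paths <- c(paths, p)
    }
    tab <- rankingTable(tsr)
    if (!is.null(tab)) {
        regs <- sort(unique(tab$regulator))
        mat <- matrix(NA_integer_, nrow = length(regs),
                      ncol = length(tsr@timePoints),
                      dimnames = list(regs, tsr@timePoints))
        mat[cbind(match(tab$regulator, regs),
                  match(tab$time, tsr@timePoints))] <- tab$rank
        df <- data.frame(regulator = regs, mat, check.names = FALSE,
                         stringsAsFactors = FALSE)
        utils::write.table(df, file.path(outDir,
            sprintf("module_%s_rank_trajectory.tsv", b@id)),
            sep = "\t", quote = FALSE, row.names = FALSE)
    }
    invisible(paths)
}
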