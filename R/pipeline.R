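#' Assemble and validate a pipeline configuration
#'
#' Defaults follow the method's stated parameterization: discretization
#' threshold `tau = 0`, corrected pattern p-value cutoff `pCut = 0.01`,
#' overlap cutoff `jacCut = 0.25`, diffusion `t = 0.25` over `Z = 100`
#' iterations, `topK = 30` regulators per snapshot, absolute expression as
#' seed mass.
#'
#' @param expressionPath path to the expression TSV.
#' @param networkPath path to the network edge-list TSV.
#' @param outDir output directory.
#' @param annotationsPath optional gene-to-term TSV for enrichment.
#' @param tau,pCut,jacCut,minGenes,minTimepoints,t,Z,topK,useAbsolute
#'   method parameters (see the module functions).
#' @param highlight nodes to emphasize in the snapshots.
#' @param maxModules cap on the number of filtered modules taken forward
#'   to ranking/rendering (`Inf` for all).
#' @return validated config list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(expressionPath, networkPath, outDir,
                           annotationsPath = NULL, tau = 0, pCut = 0.01,
                           jacCut = 0.25, minGenes = 2L, minTimepoints = 2L,
                           t = 0.25, Z = 100L, topK = 30L,
                           useAbsolute = TRUE, highlight = character(0L),
                           maxModules = Inf) {
    stopifnot(tau >= 0, pCut >= 0, pCut <= 1, jacCut >= 0, jacCut <= 1,
              minGenes >= 1, minTimepoints >= 2, t >= 0, Z >= 1, topK >= 1)
    structure(list(expressionPath = expressionPath,
                   networkPath = networkPath, outDir = outDir,
                   annotationsPath = annotationsPath, tau = tau,
                   pCut = pCut, jacCut = jacCut,
                   minGenes = as.integer(minGenes),
                   minTimepoints = as.integer(minTimepoints), t = t,
                   Z = as.integer(Z), topK = as.integer(topK),
                   useAbsolute = useAbsolute, highlight = highlight,
                   maxModules = maxModules),
              class = "PipelineConfig")
}

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop(sprintf("pipeline stage '%s' failed: %s", name,
                     conditionMessage(e)), call. = FALSE))
}

#' Run the full pipeline
#'
#' Read, clean and normalize the expression matrix; discretize transitions
#' and stamp columns; enumerate maximal coherent modules via the suffix
#' tree; score and filter them; optionally compute annotation enrichment;
#' rank regulators over each module's time span by heat-kernel diffusion on
#' the transposed network; render per-time-point snapshot SVGs.  Writes
#' `biclusters.json`/`.tsv`, `rankings.tsv`, `enrichment.tsv` (when
#' annotations are given), the SVG frames and a `manifest.json` echoing the
#' configuration and per-stage counts.  All outputs are deterministic:
#' identical inputs and configuration give byte-identical files.
#'
#' @param cfg a `PipelineConfig` from [pipelineConfig()].
#' @return invisible list with the intermediate objects and the manifest.
#' @export
runPipeline <- function(cfg) {
    stopifnot(inherits(cfg, "PipelineConfig"))
    dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
    counts <- list()
    log1 <- function(fmt, ...) message(sprintf(fmt, ...))

    expr0 <- .stage("read_expression", readExpressionTSV(cfg$expressionPath))
    counts$genes_read <- nrow(exprValues(expr0))
    expr1 <- .stage("filter_missing", suppressMessages(filterMissing(expr0)))
    counts$genes_complete <- nrow(exprValues(expr1))
    log1("expression: %d genes read, %d complete", counts$genes_read,
         counts$genes_complete)
    expr <- .stage("normalize", suppressWarnings(normalizeByGene(expr1)))
    counts$genes_normalized <- nrow(exprValues(expr))

    net <- .stage("read_network", suppressMessages(readEdgeList(cfg$networkPath)))
    counts$network_vertices <- length(networkVertices(net))
    counts$network_edges <- nrow(networkEdges(net))
    counts$network_regulators <- length(regulators(net))
    log1("network: %d vertices, %d edges, %d regulators",
         counts$network_vertices, counts$network_edges,
         counts$network_regulators)

    d <- .stage("discretize", discretizeTransitions(expr, cfg$tau))
    bcs <- .stage("enumerate", enumerateBiclusters(d))
    counts$biclusters_enumerated <- length(bcs)
    bcs <- .stage("score", suppressMessages(scoreBiclusters(bcs, d)))
    kept <- .stage("filter", filterBiclusters(bcs, cfg$pCut, cfg$jacCut,
                                              cfg$minGenes, cfg$minTimepoints))
    counts$biclusters_filtered <- length(kept)
    log1("modules: %d enumerated, %d kept after filtering",
         counts$biclusters_enumerated, counts$biclusters_filtered)
    writeBiclusters(kept, file.path(cfg$outDir, "biclusters.json"),
                    file.path(cfg$outDir, "biclusters.tsv"))

    if (!is.null(cfg$annotationsPath)) {
        ann <- .stage("read_annotations", readAnnotations(cfg$annotationsPath))
        enr <- .stage("enrich", do.call(rbind, lapply(seq_along(kept),
            function(i) {
                e <- hypergeomEnrichment(kept[[i]]@genes, ann,
                                         geneIds(expr))
                if (nrow(e)) cbind(module = kept[[i]]@id, e) else NULL
            })))
        if (is.null(enr))
            enr <- data.frame(module = character(0L), term = character(0L))
        utils::write.table(enr, file.path(cfg$outDir, "enrichment.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        counts$enrichment_rows <- nrow(enr)
    }

    params <- DiffusionParams(cfg$t, cfg$Z)
    useModules <- if (is.finite(cfg$maxModules))
        utils::head(seq_along(kept), cfg$maxModules) else seq_along(kept)
    allRanks <- list()
    nSvg <- 0L
    for (i in useModules) {
        b <- kept[[i]]
        tsr <- .stage("rank",
            suppressWarnings(suppressMessages(
                rankModuleOverTime(b, expr, net, params,
                                   useAbsolute = cfg$useAbsolute))))
        tab <- rankingTable(tsr)
        if (!is.null(tab)) allRanks[[length(allRanks) + 1L]] <- tab
        svgs <- .stage("snapshot",
            suppressMessages(renderSnapshotSeries(tsr, b, net,
                file.path(cfg$outDir, "snapshots"), topK = cfg$topK,
                highlight = cfg$highlight)))
        nSvg <- nSvg + length(svgs)
    }
    ranks <- if (length(allRanks)) do.call(rbind, allRanks) else
        data.frame(module = character(0L), time = character(0L),
                   rank = integer(0L), regulator = character(0L),
                   score = numeric(0L))
    utils::write.table(ranks, file.path(cfg$outDir, "rankings.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    counts$rankings_rows <- nrow(ranks)
    counts$snapshots_written <- nSvg
    log1("rankings: %d rows; snapshots: %d frames", nrow(ranks), nSvg)

    cfgEcho <- unclass(cfg)[setdiff(names(cfg), "outDir")]
    if (!is.finite(cfgEcho$maxModules)) cfgEcho$maxModules <- "all"
    manifest <- list(
        package = "tempomod",
        version = as.character(utils::packageVersion("tempomod")),
        config = cfgEcho,
        counts = counts)
    jsonlite::write_json(manifest, file.path(cfg$outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    invisible(list(expression = expr, network = net, discretized = d,
                   biclusters = kept, rankings = ranks, manifest = manifest))
}
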