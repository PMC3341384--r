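make_ranking <- function(regs, scores, time = "t1") {
    ord <- order(-scores, regs)
    new("RankingVector",
        values = setNames(scores, regs)[ord],
        ranking = data.frame(regulator = regs[ord], score = scores[ord],
                             rank = seq_along(regs), stringsAsFactors = FALSE),
        timeLabel = time)
}

snapshot_fixture <- function(nTF = 5L, nTargets = 3L, topK = 30L,
                             highlight = character(0L)) {
    regs <- sprintf("tf%02d", seq_len(nTF))
    targets <- sprintf("g%02d", seq_len(nTargets))
    set.seed(nTF * 100L + nTargets)
    edges <- expand.grid(regulator = regs, target = c(targets, regs),
                         stringsAsFactors = FALSE)
    edges <- edges[edges$regulator != edges$target, ]
    edges <- edges[runif(nrow(edges)) < 0.4, ]
    edges <- rbind(data.frame(regulator = regs[1L], target = targets[1L],
                              stringsAsFactors = FALSE), edges)
    edges <- edges[!duplicated(edges), ]
    net <- RegulatoryNetwork(edges)
    b <- CCCBicluster(targets, 1L, 2L, c("U", "U"), id = "1")
    rk <- make_ranking(regs, seq(1, 0.1, length.out = nTF))
    list(b = b, rk = rk, net = net,
         snap = buildSnapshot(b, rk, net, topK = topK, highlight = highlight))
}

test_that("snapshot keeps top-k regulators in rank order with valid arcs", {
    fx <- snapshot_fixture(nTF = 40L, topK = 30L)
    s <- fx$snap
    expect_identical(nrow(s@tfs), 30L)
    expect_true(all(diff(s@tfs$score) <= 0))
    nodes <- c(s@tfs$regulator, s@targets)
    expect_true(all(c(s@arcs$source, s@arcs$sink) %in% nodes))
    # no emphasis without a highlight set
    expect_true(all(s@arcs$relation == "neutral"))
})

test_that("highlighted nodes get regulates/regulated_by arc relations", {
    fx <- snapshot_fixture(nTF = 6L, highlight = "tf01")
    arcs <- fx$snap@arcs
    expect_true(all(arcs$relation[arcs$source == "tf01"] == "regulates" |
                    arcs$sink[arcs$source == "tf01"] == "tf01"))
    expect_true(all(arcs$relation[arcs$sink == "tf01"] == "regulated_by"))
})

test_that("score-threshold mode keeps exactly the regulators above cutoff", {
    fx <- snapshot_fixture(nTF = 8L)
    s <- buildSnapshot(fx$b, fx$rk, fx$net, scoreThreshold = 0.5)
    expect_true(all(s@tfs$score >= 0.5))
    expect_identical(nrow(s@tfs),
                     sum(fx$rk@ranking$score >= 0.5))
})

test_that("SVG output is well-formed, complete and byte-deterministic", {
    fx <- snapshot_fixture(nTF = 2L, nTargets = 3L)
    p1 <- withr::local_tempfile(fileext = ".svg")
    p2 <- withr::local_tempfile(fileext = ".svg")
    renderSnapshotSVG(fx$snap, p1)
    renderSnapshotSVG(fx$snap, p2)
    expect_identical(readBin(p1, "raw", file.size(p1)),
                     readBin(p2, "raw", file.size(p2)))
    doc <- xml2::read_xml(p1)
    expect_identical(xml2::xml_name(doc), "svg")
    expect_length(xml2::xml_find_all(doc, ".//*[local-name()='circle']"), 5L)
})

test_that("no two node labels share coordinates even when crowded", {
    fx <- snapshot_fixture(nTF = 30L, nTargets = 100L)
    p <- withr::local_tempfile(fileext = ".svg")
    renderSnapshotSVG(fx$snap, p)
    doc <- xml2::read_xml(p)
    texts <- xml2::xml_find_all(doc, ".//*[local-name()='text']")
    coords <- paste(xml2::xml_attr(texts, "x"), xml2::xml_attr(texts, "y"))
    expect_identical(anyDuplicated(coords), 0L)
})

test_that("TF x-positions in the SVG follow the ranking order", {
    fx <- snapshot_fixture(nTF = 10L)
    p <- withr::local_tempfile(fileext = ".svg")
    renderSnapshotSVG(fx$snap, p)
    doc <- xml2::read_xml(p)
    texts <- xml2::xml_find_all(doc, ".//*[local-name()='text']")
    lab <- xml2::xml_text(texts)
    x <- as.numeric(xml2::xml_attr(texts, "x"))
    tfx <- x[match(fx$snap@tfs$regulator, lab)]
    expect_true(all(diff(tfx) > 0))
})

test_that("a series renders one frame per time point plus a trajectory table", {
    st <- generatePlantedStudy(2)
    expr <- suppressWarnings(normalizeByGene(st$expression))
    d <- discretizeTransitions(expr, 0)
    bcs <- enumerateBiclusters(d)
    tm <- st$truth$modules[[1L]]
    b <- bcs[[which.max(vapply(bcs, truthJaccard, numeric(1L),
                               truthModule = tm))]]
    tsr <- suppressMessages(rankModuleOverTime(b, expr, st$network))
    outDir <- withr::local_tempdir()
    paths <- renderSnapshotSeries(tsr, b, st$network, outDir, topK = 5L)
    expect_length(paths, length(tsr@timePoints))
    expect_true(all(file.exists(paths)))
    traj <- read.delim(file.path(outDir,
        sprintf("module_%s_rank_trajectory.tsv", b@id)), check.names = FALSE)
    expect_identical(colnames(traj), c("regulator", tsr@timePoints))
    # trajectory agrees with the flat ranking table
    tab <- rankingTable(tsr)
    for (k in seq_len(nrow(tab)))
        expect_identical(traj[match(tab$regulator[k], traj$regulator),
                              tab$time[k]], tab$rank[k])
})
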