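test_that("preference vector uses absolute expression and flags exclusions", {
    v <- rbind(g1 = c(-1.5, 2), g2 = c(2.0, 1), g3 = c(0.5, 3))
    expr <- expression_from_matrix(v)
    net <- RegulatoryNetwork(data.frame(regulator = "tf",
                                        target = c("g1", "g2")))
    pv <- buildPreferenceVector(c("g1", "g2"), expr, "t1", net)
    expect_equal(unname(pv@values[c("g1", "g2")]), c(1.5, 2.0))
    expect_equal(unname(pv@values["tf"]), 0)
    expect_warning(
        pv2 <- buildPreferenceVector(c("g1", "g3"), expr, "t1", net), "g3")
    expect_identical(pv2@excluded, "g3")
    expect_error(
        suppressWarnings(buildPreferenceVector("g3", expr, "t1", net)),
        "present in the network")
    # signed mode clips negatives to zero
    pvs <- buildPreferenceVector(c("g1", "g2"), expr, "t1", net,
                                 useAbsolute = FALSE)
    expect_equal(unname(pvs@values[c("g1", "g2")]), c(0, 2.0))
})

test_that("diffusion identities: t = 0, homogeneity, mass conservation", {
    set.seed(41)
    net <- random_network(20)
    W <- transitionMatrix(net)
    # fully stochastic variant: add self-loops to dangling vertices
    dang <- which(Matrix::rowSums(W) == 0)
    Wf <- W
    for (d in dang) Wf[d, d] <- 1
    p0 <- setNames(runif(20), rownames(W))

    expect_identical(heatKernelDiffuse(p0, W, DiffusionParams(0, 100L))@values,
                     setNames(p0, rownames(W)))
    a <- heatKernelDiffuse(p0, W, DiffusionParams(0.4, 50L))@values
    b <- heatKernelDiffuse(3.5 * p0, W, DiffusionParams(0.4, 50L))@values
    expect_equal(b, 3.5 * a, tolerance = 1e-14)
    pf <- heatKernelDiffuse(p0, Wf, DiffusionParams(0.7, 200L))@values
    expect_lt(abs(sum(pf) - sum(p0)), 1e-10)
    expect_true(all(pf >= 0))
})

test_that("iterated kernel converges to the matrix exponential as Z grows", {
    set.seed(43)
    for (rep in 1:3) {
        net <- random_network(20)
        W <- transitionMatrix(net)
        p0 <- setNames(runif(20), rownames(W))
        p0 <- p0 / sum(p0)
        ex <- expm_oracle(p0, W, 0.25)
        err <- vapply(c(10L, 100L, 1000L, 10000L), function(Z)
            sum(abs(heatKernelDiffuse(p0, W, DiffusionParams(0.25, Z))@values -
                    ex)), numeric(1L))
        expect_true(all(diff(err) < 0))
        # first-order scheme: error shrinks about tenfold per decade of Z
        expect_lt(err[4L], 1e-5)
    }
})

test_that("chain-network diffusion approaches the exponential oracle", {
    net <- chain_network()
    W <- transitionMatrix(net)
    p0 <- c(a = 0.2, b = 0.3, c = 0.5)
    pz <- heatKernelDiffuse(p0, W, DiffusionParams(0.25, 10000L))@values
    expect_lt(sum(abs(pz - expm_oracle(p0, W, 0.25))), 1e-6)
})

test_that("regulator ranking restricts, sorts and breaks ties by id", {
    net <- RegulatoryNetwork(data.frame(regulator = c("tf1", "tf2", "tf3"),
                                        target = c("g1", "g1", "g2")))
    scores <- c(tf1 = 0.3, tf2 = 0.7, tf3 = 0.3, g1 = 9, g2 = 8)
    rk <- suppressMessages(rankRegulators(scores, net))@ranking
    expect_identical(rk$regulator, c("tf2", "tf1", "tf3"))
    expect_identical(rk$rank, 1:3)
    expect_false(any(c("g1", "g2") %in% rk$regulator))
})

test_that("module ranking yields one ranking per spanned time point", {
    st <- generatePlantedStudy(3)
    expr <- suppressWarnings(normalizeByGene(st$expression))
    d <- discretizeTransitions(expr, 0)
    bcs <- enumerateBiclusters(d)
    tm <- st$truth$modules[[1L]]
    b <- bcs[[which.max(vapply(bcs, truthJaccard, numeric(1L),
                               truthModule = tm))]]
    tsr <- suppressMessages(rankModuleOverTime(b, expr, st$network))
    expect_length(tsr@rankings, b@cEnd - b@cStart + 2L)
    expect_identical(tsr@timePoints,
                     timeLabels(expr)[b@cStart:(b@cEnd + 1L)])
    # identical inputs give bit-identical rankings
    tsr2 <- suppressMessages(rankModuleOverTime(b, expr, st$network))
    expect_identical(lapply(tsr@rankings, function(r) r@ranking),
                     lapply(tsr2@rankings, function(r) r@ranking))
})

test_that("the planted dominant regulator ranks first at every time point", {
    st <- generatePlantedStudy(5)
    expr <- suppressWarnings(normalizeByGene(st$expression))
    d <- discretizeTransitions(expr, 0)
    bcs <- enumerateBiclusters(d)
    for (mi in 1:2) {
        tm <- st$truth$modules[[mi]]
        b <- bcs[[which.max(vapply(bcs, truthJaccard, numeric(1L),
                                   truthModule = tm))]]
        tsr <- suppressMessages(rankModuleOverTime(b, expr, st$network))
        top <- vapply(tsr@rankings, function(r)
            r@ranking$regulator[1L], character(1L))
        expect_true(all(top == st$truth$regulators[mi]))
    }
})
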