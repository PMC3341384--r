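test_that("null model frequencies sum to one per column", {
    set.seed(5)
    f <- patternNullModel(random_discretized(20, 6))
    expect_equal(unname(colSums(f)), rep(1, 6), tolerance = 1e-12)
})

test_that("pattern p-value boundary cases follow the binomial tail", {
    # all rows identical over one column: certain pattern, p-value 1
    d <- make_discretized(matrix("U", 5, 2))
    model <- patternNullModel(d)
    b <- CCCBicluster(rownames(symbolMatrix(d))[1:3], 1L, 1L, "U")
    expect_equal(patternPValue(b, model, 5), 1)

    # |I| = nGenes: point mass q^n
    d2 <- make_discretized(rbind(a = c("U", "D"), b = c("U", "U"),
                                 c = c("U", "D"), d = c("D", "D")))
    model2 <- patternNullModel(d2)
    q <- unname(model2["D", 2L])
    b2 <- CCCBicluster(c("a", "b", "c", "d"), 2L, 2L, "D")
    expect_equal(patternPValue(b2, model2, 4), q^4, tolerance = 1e-12)

    # zero-frequency symbol in the pattern: p-value 0, logged
    b3 <- CCCBicluster(c("a", "b"), 1L, 1L, "N")
    expect_message(p3 <- patternPValue(b3, model2, 4), "zero-frequency")
    expect_identical(p3, 0)
})

test_that("pattern p-value agrees with a Monte-Carlo null simulation", {
    set.seed(42)
    d <- random_discretized(8, 4)
    model <- patternNullModel(d)
    bcs <- enumerateBiclusters(d)
    p_an <- vapply(bcs, patternPValue, numeric(1L), model = model, nGenes = 8)
    b <- bcs[[which.min(abs(p_an - 0.5))]]  # moderate p for MC power
    p <- patternPValue(b, model, 8)
    J <- biclusterColumns(b)
    nrep <- 20000L
    match <- matrix(TRUE, nrep, 8)
    for (k in seq_along(J)) {
        sym <- sample(c("D", "N", "U"), nrep * 8, replace = TRUE,
                      prob = model[, J[k]])
        match <- match & matrix(sym == biclusterPattern(b)[k], nrep, 8)
    }
    phat <- mean(rowSums(match) >= length(biclusterGenes(b)))
    se <- sqrt(phat * (1 - phat) / nrep)
    expect_lt(abs(p - phat), 3 * se)
})

test_that("pattern p-value is monotone non-increasing in the gene count", {
    set.seed(9)
    d <- random_discretized(10, 5)
    model <- patternNullModel(d)
    genes <- rownames(symbolMatrix(d))
    p <- vapply(2:8, function(k)
        patternPValue(CCCBicluster(genes[1:k], 2L, 3L,
                                   symbolMatrix(d)[1L, 2:3]), model, 10),
        numeric(1L))
    expect_true(all(diff(p) <= 1e-15))
})

test_that("bonferroni scales, caps and validates", {
    expect_equal(bonferroni(0.001, 50), 0.05)
    expect_equal(bonferroni(0.5, 10), 1)
    expect_equal(bonferroni(c(0.2, 0.01), 2), c(0.4, 0.02))
    expect_identical(bonferroni(0.3, 1), 0.3)
    expect_error(bonferroni(1.2, 5), "\\[0, 1\\]")
    expect_error(bonferroni(c(0.1, 0.2), 1), "at least")
})

test_that("cell Jaccard counts shared (gene, column) cells", {
    a <- CCCBicluster(c("g1", "g2"), 1L, 2L, c("U", "U"))
    expect_equal(jaccardSimilarity(a, a), 1)
    b <- CCCBicluster(c("g3", "g4"), 3L, 4L, c("D", "D"))
    expect_equal(jaccardSimilarity(a, b), 0)
    # b shares exactly 2 cells with a's 4; union 6
    b2 <- CCCBicluster(c("g2"), 1L, 2L, c("U", "U"))
    expect_equal(jaccardSimilarity(a, b2), 1 / 2)
    b3 <- CCCBicluster(c("g2", "g3"), 2L, 3L, c("U", "D"))
    expect_equal(jaccardSimilarity(a, b3), 1 / 7)
    expect_equal(jaccardSimilarity(b3, a), 1 / 7)
})

test_that("filtering matches an exhaustive pairwise oracle", {
    set.seed(77)
    for (rep in 1:5) {
        d <- random_discretized(12, 6)
        bcs <- suppressMessages(scoreBiclusters(enumerateBiclusters(d), d))
        kept <- filterBiclusters(bcs, pCut = 0.5, jacCut = 0.25)
        cp <- vapply(bcs, function(b) b@correctedP, numeric(1L))
        keptIds <- vapply(kept, function(b) b@id, character(1L))
        # every kept bicluster passes the cutoffs
        for (b in as.list(kept)) expect_lte(b@correctedP, 0.5)
        # no kept pair overlaps beyond the cutoff
        for (i in seq_along(kept)) for (j in seq_len(i - 1L))
            expect_lte(jaccardSimilarity(kept[[i]], kept[[j]]), 0.25)
        # every discarded cutoff-passing bicluster overlaps a kept one
        # that is at least as significant
        for (i in seq_along(bcs)) {
            b <- bcs[[i]]
            if (b@id %in% keptIds || cp[i] > 0.5) next
            ov <- vapply(kept, function(k)
                jaccardSimilarity(b, k) > 0.25 && k@correctedP <= cp[i],
                logical(1L))
            expect_true(any(ov))
        }
    }
})

test_that("size and p-value filters remove what they should", {
    b1 <- CCCBicluster(c("g1", "g2"), 1L, 4L, rep("U", 4L)); b1@correctedP <- 0.02
    b2 <- CCCBicluster(c("g3", "g4", "g5"), 1L, 2L, rep("D", 2L)); b2@correctedP <- 0.001
    bcs <- new("CCCBiclusterList", S4Vectors::SimpleList(list(b1, b2)))
    expect_length(filterBiclusters(bcs, pCut = 0.01), 1L)
    expect_length(filterBiclusters(bcs, pCut = 0.05, minGenes = 3L), 1L)
    expect_length(filterBiclusters(bcs, pCut = 0.05, minTimepoints = 4L), 1L)
    # identical duplicates: only the first survives the overlap scan
    b3 <- b1; b3@correctedP <- 0.03
    dup <- new("CCCBiclusterList", S4Vectors::SimpleList(list(b1, b3)))
    expect_length(filterBiclusters(dup, pCut = 0.05), 1L)
})

test_that("hypergeometric enrichment matches closed-form combinatorics", {
    bg <- sprintf("g%02d", 1:10)
    ann <- list(T1 = bg[1:5], T2 = bg)
    res <- hypergeomEnrichment(bg[1:4], ann, bg)
    # N=10, K=5, n=4, k=4: C(5,4) C(5,0) / C(10,4) = 5/210
    expect_equal(res$p[res$term == "T1"], 5 / 210, tolerance = 1e-12)
    expect_equal(res$p[res$term == "T2"], 1)
    expect_equal(res$corrected_p, pmin(1, res$p * 2))
    # k = 0 has upper-tail probability 1
    res0 <- hypergeomEnrichment(bg[6:9], list(T1 = bg[1:5]), bg)
    expect_equal(res0$p, 1)
    expect_error(hypergeomEnrichment("g01", ann, character(0L)), "background")
})

test_that("enrichment p-values are invariant under gene relabeling", {
    set.seed(13)
    bg <- sprintf("g%02d", 1:20)
    ann <- list(A = sample(bg, 8), B = sample(bg, 5))
    mod <- sample(bg, 6)
    res1 <- hypergeomEnrichment(mod, ann, bg)
    perm <- setNames(sample(bg), bg)
    res2 <- hypergeomEnrichment(unname(perm[mod]),
                                lapply(ann, function(g) unname(perm[g])),
                                unname(perm[bg]))
    expect_equal(res1$p, res2$p)
})
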