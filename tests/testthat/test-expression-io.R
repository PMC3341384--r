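test_that("TSV round trip preserves values, labels and the missing mask", {
    p <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("gene\t0\t5\t15",
                 "YAL001C\t0.5\t-1.25\t2",
                 "YAL002W\tNA\t0.75\t"), p)
    m <- readExpressionTSV(p)
    expect_identical(geneIds(m), c("YAL001C", "YAL002W"))
    expect_identical(timeLabels(m), c("0", "5", "15"))
    expect_equal(exprValues(m)["YAL001C", ], c(`0` = 0.5, `5` = -1.25, `15` = 2))
    expect_identical(unname(missingMask(m)[2L, ]), c(TRUE, FALSE, TRUE))
    p2 <- withr::local_tempfile(fileext = ".tsv")
    writeExpressionTSV(m, p2)
    m2 <- readExpressionTSV(p2)
    expect_equal(exprValues(m2), exprValues(m))
    expect_identical(missingMask(m2), missingMask(m))
})

test_that("malformed expression files are rejected with informative errors", {
    dup <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("gene\tt1\tt2", "YAL001C\t1\t2", "YAL001C\t3\t4"), dup)
    expect_error(readExpressionTSV(dup), "YAL001C")

    ragged <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("gene\tt1\tt2", "g1\t1\t2", "g2\t3"), ragged)
    expect_error(readExpressionTSV(ragged), "line 3")

    narrow <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("gene\tt1", "g1\t1"), narrow)
    expect_error(readExpressionTSV(narrow), "2 time columns")
})

test_that("filterMissing keeps exactly fully observed genes and is idempotent", {
    v <- matrix(1:12, 3, 4)
    v[2, 3] <- NA
    m <- expression_from_matrix(v)
    expect_message(f <- filterMissing(m), "removed 1")
    expect_identical(geneIds(f), c("g001", "g003"))
    expect_identical(exprValues(filterMissing(f)), exprValues(f))
    allNA <- expression_from_matrix(matrix(NA_real_, 2, 3))
    expect_error(filterMissing(allNA), "nothing to analyze")
})

test_that("normalizeByGene centres and scales with the sample convention", {
    m <- expression_from_matrix(rbind(a = c(1, 2, 3), b = c(4, 4, 4),
                                      c = c(-1, 0, 1)))
    expect_warning(nm <- normalizeByGene(m), "constant")
    expect_equal(unname(exprValues(nm)["a", ]), c(-1, 0, 1))
    expect_identical(geneIds(nm), c("a", "c"))
    # already standardized rows are fixed points
    expect_equal(exprValues(normalizeByGene(nm)), exprValues(nm),
                 tolerance = 1e-12)
})

test_that("discretizeTransitions applies the threshold rule on differences", {
    m <- expression_from_matrix(rbind(g1 = c(0, 1, 1.2, 0.2)))
    d <- discretizeTransitions(m, tau = 0.5)
    expect_identical(unname(symbolMatrix(d)[1L, ]), c("U", "N", "D"))
    expect_identical(ncol(symbolMatrix(d)), 3L)

    two <- discretizeTransitions(expression_from_matrix(rbind(g = c(5, 7))), 1)
    expect_identical(unname(symbolMatrix(two)[1L, ]), "U")

    inc <- discretizeTransitions(
        expression_from_matrix(rbind(g = c(1, 2, 4, 8))), 0)
    expect_identical(unname(symbolMatrix(inc)[1L, ]), c("U", "U", "U"))

    expect_error(discretizeTransitions(m, tau = -0.1), "non-negative")
})

test_that("discretization depends only on differences (shift equivariance)", {
    set.seed(11)
    for (i in 1:20) {
        v <- matrix(rnorm(24), 4, 6)
        d1 <- discretizeTransitions(expression_from_matrix(v), 0.3)
        d2 <- discretizeTransitions(expression_from_matrix(v + rnorm(4)), 0.3)
        expect_identical(symbolMatrix(d1), symbolMatrix(d2))
    }
})

test_that("alphabet stamping is invertible and terminators are unique", {
    d <- make_discretized(rbind(a = c("U", "N", "D"), b = c("U", "N", "D")))
    rows <- transformAlphabet(d)
    expect_identical(rows@tokens$a, c("U.1", "N.2", "D.3"))
    expect_identical(rows@tokens$a, rows@tokens$b)
    expect_false(anyDuplicated(rows@terminators) > 0L)
    dec <- decodeToken(rows@tokens$a)
    expect_identical(dec$symbol, c("U", "N", "D"))
    expect_identical(dec$column, 1:3)
    # wide column indices decode unambiguously
    expect_identical(decodeToken("D.123456")$column, 123456L)
})
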