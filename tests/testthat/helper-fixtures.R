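# Shared fixture builders; every test seeds its own RNG use.

make_discretized <- function(symbols, tau = 0) {
    if (is.null(rownames(symbols)))
        rownames(symbols) <- sprintf("g%03d", seq_len(nrow(symbols)))
    new("DiscretizedTS", symbols = symbols, tau = tau)
}

random_discretized <- function(nr, nc) {
    make_discretized(matrix(sample(c("D", "N", "U"), nr * nc, replace = TRUE),
                            nr, nc))
}

# (gene-set, column-interval) signature for comparing bicluster sets
bicluster_signatures <- function(bcs) {
    sort(vapply(bcs, function(b)
        paste(paste(sort(b@genes), collapse = ","), b@cStart, b@cEnd,
              sep = "|"), character(1L)))
}

random_network <- function(n, p = 0.15, weighted = TRUE) {
    repeat {
        adj <- matrix(stats::runif(n * n) < p, n, n) & !diag(n)
        if (any(adj)) break
    }
    e <- which(adj, arr.ind = TRUE)
    v <- sprintf("v%03d", seq_len(n))
    RegulatoryNetwork(data.frame(
        regulator = v[e[, 1L]], target = v[e[, 2L]],
        weight = if (weighted) stats::runif(nrow(e), 0.5, 2) else 1,
        stringsAsFactors = FALSE), vertexOrder = v)
}

chain_network <- function() {
    RegulatoryNetwork(data.frame(regulator = c("a", "b"),
                                 target = c("b", "c"), weight = 1),
                      vertexOrder = c("a", "b", "c"))
}

expm_oracle <- function(p0, net_or_W, t) {
    W <- if (is(net_or_W, "RegulatoryNetwork")) transitionMatrix(net_or_W)
         else net_or_W
    as.numeric(p0 %*% Matrix::expm(-t * (Matrix::Diagonal(nrow(W)) - W)))
}

expression_from_matrix <- function(v) {
    if (is.null(rownames(v))) rownames(v) <- sprintf("g%03d", seq_len(nrow(v)))
    if (is.null(colnames(v))) colnames(v) <- paste0("t", seq_len(ncol(v)))
    ExpressionTS(v)
}

write_study_fixture <- function(study, dir) {
    ep <- file.path(dir, "expression.tsv")
    np <- file.path(dir, "network.tsv")
    writeExpressionTSV(study$expression, ep)
    writeEdgeListTSV(study$network, np)
    list(expression = ep, network = np)
}
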