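#' Generate an expression matrix with planted coherent modules
#'
#' Background genes get i.i.d. standard normal values.  Each planted module
#' follows one real-valued trajectory built by cumulative steps of
#' `+/- (tau + margin)` for `U`/`D` and `0` for `N` over its column
#' interval (and independent normal values outside it), plus per-gene
#' Gaussian noise of sd `noiseSd`.  The step margin (default
#' `max(3 * noiseSd, 1)`) keeps the planted pattern robust to the noise at
#' discretization time; planting `N` symbols requires `tau > 0` large
#' enough to absorb the noise.
#'
#' @param nGenes,nTimepoints matrix size (`nTimepoints - 1` transition
#'   columns).
#' @param modules list of planted modules, each
#'   `list(size =, interval = c(first, last), pattern = c("U", ...))` with
#'   a contiguous transition-column interval and a pattern of matching
#'   length; sizes at least 2.
#' @param noiseSd Gaussian noise standard deviation (default 0).
#' @param tau the discretization threshold the matrix is built for
#'   (default 1).
#' @param margin step margin above `tau`; default `max(3 * noiseSd, 1)`.
#' @param seed integer seed; all randomness derives from it.
#' @return list with elements `expression` (an [ExpressionTS-class]) and
#'   `truth` (planted gene sets, intervals, patterns and the generator
#'   parameters).
#' @export
generatePlantedExpression <- function(nGenes, nTimepoints, modules,
                                      noiseSd = 0, tau = 1,
                                      margin = max(3 * noiseSd, 1),
                                      seed = 1L) {
    nc <- nTimepoints - 1L
    for (m in modules) {
        if (length(m$pattern) != m$interval[2L] - m$interval[1L] + 1L)
            stop("pattern length must match the interval length")
        if (m$interval[1L] < 1L || m$interval[2L] > nc)
            stop("planted interval outside 1..", nc)
        if (m$size < 2L) stop("planted module size must be >= 2")
        if (!all(m$pattern %in% c("D", "N", "U")))
            stop("pattern symbols must be D, N or U")
    }
    if (sum(vapply(modules, `[[`, numeric(1L), "size")) > nGenes)
        stop("planted modules exceed nGenes")
    rng <- .seededRNG(seed)
    v <- matrix(rng$norm(nGenes * nTimepoints), nrow = nGenes)
    step <- tau + margin
    geneAt <- 0L
    truthMods <- list()
    for (mi in seq_along(modules)) {
        m <- modules[[mi]]
        rows <- geneAt + seq_len(m$size)
        geneAt <- geneAt + m$size
        cols <- m$interval[1L]:m$interval[2L]
        incr <- c(D = -step, N = 0, U = step)[m$pattern]
        # shared trajectory over time points interval[1] .. interval[2]+1
        traj <- cumsum(c(0, incr))
        for (r in rows) {
            base <- rng$norm(1L)
            v[r, cols[1L]:(cols[length(cols)] + 1L)] <- base + traj
        }
        if (noiseSd > 0)
            v[rows, ] <- v[rows, ] +
                matrix(rng$norm(length(rows) * nTimepoints, sd = noiseSd),
                       nrow = length(rows))
        truthMods[[mi]] <- list(genes = sprintf("G%04d", rows),
                                interval = m$interval, pattern = m$pattern)
    }
    dimnames(v) <- list(sprintf("G%04d", seq_len(nGenes)),
                        paste0("t", seq_len(nTimepoints)))
    list(expression = ExpressionTS(v),
         truth = list(modules = truthMods,
                      params = list(nGenes = nGenes,
                                    nTimepoints = nTimepoints,
                                    noiseSd = noiseSd, tau = tau,
                                    margin = margin, seed = seed)))
}

#' Generate a regulatory network with planted dominant regulators
#'
#' Each planted regulator gets a weight-1 edge to every gene of its target
#' set; every other (TF, target) pair appears independently with
#' probability `backgroundP`.  Background TFs therefore cover only a
#' random fraction of any module, so the planted regulator dominates the
#' diffusion ranking of its module by construction.
#'
#' @param nTfs number of transcription factors (`TF01`, `TF02`, ...).
#' @param targets character vector of target gene ids.
#' @param planted named list mapping a TF id to its planted target set
#'   (subset of `targets`), e.g. `list(TF01 = c("G0001", "G0002"))`.
#' @param backgroundP probability of a background TF-to-target edge, in
#'   `[0, 1]`.
#' @param seed integer seed.
#' @return list with elements `network` (a [RegulatoryNetwork-class]) and
#'   `truth` (the planted wiring and parameters).
#' @export
generatePlantedNetwork <- function(nTfs, targets, planted,
                                   backgroundP = 0.1, seed = 1L) {
    if (backgroundP < 0 || backgroundP > 1)
        stop("backgroundP must lie in [0, 1]")
    tfs <- sprintf("TF%02d", seq_len(nTfs))
    if (!all(names(planted) %in% tfs))
        stop("planted TF ids must be among TF01..TF", nTfs)
    for (tg in planted)
        if (!all(tg %in% targets)) stop("planted target set outside targets")
    rng <- .seededRNG(seed)
    from <- character(0L); to <- character(0L)
    for (tf in names(planted)) {
        from <- c(from, rep(tf, length(planted[[tf]])))
        to <- c(to, planted[[tf]])
    }
    bgTfs <- setdiff(tfs, names(planted))
    if (backgroundP > 0 && length(bgTfs)) {
        for (tf in bgTfs) {
            hit <- targets[rng$unif(length(targets)) < backgroundP]
            from <- c(from, rep(tf, length(hit)))
            to <- c(to, hit)
        }
    }
    if (length(from) == 0L) stop("generated network has no edges")
    net <- RegulatoryNetwork(
        data.frame(regulator = from, target = to, weight = 1,
                   stringsAsFactors = FALSE),
        vertexOrder = c(tfs[tfs %in% from], unique(to)))
    list(network = net,
         truth = list(planted = planted,
                      params = list(nTfs = nTfs, backgroundP = backgroundP,
                                    seed = seed)))
}

# Local RNG closure: a private state seeded once, never touching (or
# depending on) the session's global RNG.
.seededRNG <- function(seed) {
    env <- new.env()
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(as.integer(seed) %% .Machine$integer.max, kind = "Mersenne-Twister")
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    withState <- function(f) function(...) {
        prev <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
        assign(".Random.seed", env$state, envir = globalenv())
        on.exit({
            env$state <- get(".Random.seed", globalenv())
            if (is.null(prev)) rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", prev, envir = globalenv())
        })
        f(...)
    }
    list(norm = withState(stats::rnorm),
         unif = withState(stats::runif),
         int = withState(function(n, max) sample.int(max, n, replace = TRUE)))
}

#' Cell-based Jaccard between a bicluster and a planted truth record
#'
#' @param b a [CCCBicluster-class].
#' @param truthModule one element of the generator's `truth$modules`.
#' @return Jaccard similarity of the (gene, column) cell sets.
#' @export
truthJaccard <- function(b, truthModule) {
    tb <- CCCBicluster(truthModule$genes, truthModule$interval[1L],
                       truthModule$interval[2L], truthModule$pattern)
    jaccardSimilarity(b, tb)
}

#' Standard planted study for end-to-end validation
#'
#' The package's reference synthetic condition: 50 genes over 20 time
#' points with two planted 20-gene modules (transition columns 2-19 and
#' 1-18, both with strict up/down patterns so that the sign-based default
#' discretization `tau = 0` is invariant to the per-gene normalization),
#' and an 8-TF network in which each module's planted regulator targets
#' the whole module while background TFs hit targets independently with
#' probability 0.1.  The in-code comments spell out why the patterns are
#' complementary, balanced and this long.
#'
#' @param seed integer seed driving both generators.
#' @param noiseSd Gaussian noise sd on the expression values (default 0).
#' @return list with `expression`, `network`, `truth` (planted modules and
#'   the TF wired to each, in order).
#' @export
generatePlantedStudy <- function(seed = 1L, noiseSd = 0) {
    # balanced patterns (cumulative sum zero) keep the trajectory's
    # endpoints near the background scale, so the transitions flanking the
    # planted interval stay random per gene and the planted bicluster is
    # not systematically extendable
    # Identifiability by construction:
    # - the second pattern is the first one's complement on every shared
    #   column, so the two modules can never merge into one chance
    #   bicluster;
    # - patterns are exactly balanced (cumulative sum zero, even length)
    #   so each planted trajectory starts and ends at its baseline and
    #   the transitions flanking the interval are unbiased coin flips per
    #   gene (no systematic extension of the planted interval);
    # - module dimensions (20 genes x 18 columns) are large enough that
    #   any maximal bicluster differing from the truth by one stray gene
    #   or one column keeps a cell Jaccard above 0.9, so a rare chance
    #   coincidence cannot drop recovery below that bound.
    p1 <- c("U","U","D","D", rep(c("U","D"), 7L))          # cols 2..19
    p2 <- c("U", ifelse(p1[1:17] == "U", "D", "U"))        # cols 1..18
    modules <- list(
        list(size = 20L, interval = c(2L, 19L), pattern = p1),
        list(size = 20L, interval = c(1L, 18L), pattern = p2))
    gen <- generatePlantedExpression(50L, 20L, modules, noiseSd = noiseSd,
                                     tau = 0, seed = seed)
    netg <- generatePlantedNetwork(8L, geneIds(gen$expression),
        planted = list(TF01 = gen$truth$modules[[1L]]$genes,
                       TF02 = gen$truth$modules[[2L]]$genes),
        backgroundP = 0.1, seed = seed + 1L)
    list(expression = gen$expression, network = netg$network,
         truth = list(modules = gen$truth$modules,
                      regulators = c("TF01", "TF02"),
                      expressionParams = gen$truth$params,
                      networkParams = netg$truth$params))
}
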