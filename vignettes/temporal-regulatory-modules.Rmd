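---
title: "Mining temporal transcriptional modules and prioritizing their regulators"
author: "tempomod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining temporal transcriptional modules and prioritizing their regulators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tempomod)
```

## The problem

A gene expression time series tells us *what* groups of genes move
together through an experiment; a regulatory network tells us *who* can
drive them. `tempomod` combines the two: it finds maximal groups of genes
sharing an identical discretized expression trend over a contiguous
interval of time points (temporal transcriptional modules), and then, for
each module at each of its time points, ranks transcription factors (TFs)
by diffusing the module's expression signal backwards through the
regulatory network. A per-time-point "snapshot" figure shows the ranked
regulators above the module genes with their regulation arcs, so the rise
and fall of a regulator's relevance can be followed frame by frame.

## Module discovery

### Discretization and stamping

Expression rows are cleaned (`filterMissing`), z-scored per gene
(`normalizeByGene`, sample convention so `c(1,2,3)` becomes `c(-1,0,1)`;
constant rows carry no trend and are dropped), and encoded as transitions:
for consecutive time points, a difference `>= tau` is an up-trend `U`,
`<= -tau` a down-trend `D`, anything else `N`. Transition column `c`
describes the change between time points `c` and `c+1`.

The threshold `tau` defaults to 0: any strict increase is `U`, any strict
decrease `D`, and the `N` symbol only appears for exact ties (with
`tau = 0` a tie resolves to `U` by the `>=` rule). The default is
deliberately assumption-free — a positive `tau` expresses a judgment about
what change is negligible, which depends on the normalization and noise
level of the data at hand, so it is exposed everywhere rather than fixed.
Note one interaction worth knowing: per-gene z-scoring rescales each row,
so a *fixed* positive `tau` means different absolute changes for different
genes, while `tau = 0` (pure sign of change) is invariant to it.

Each symbol then gets its column index stamped onto it (`U` in column 3
becomes the token `(U, 3)`), and every row string receives a terminator
unique to that row. Stamping is what turns two-dimensional structure into
string structure: a substring shared by several row strings is exactly a
shared pattern over a shared *contiguous* column interval. Tokens are
atomic (symbol, column) pairs, so column indices of any width are
unambiguous.

### Suffix-tree enumeration

A generalized suffix tree of the stamped rows is built online (Ukkonen's
algorithm, amortized linear time in the total token count; implemented in
C++ with deterministic child ordering). Every internal node corresponds
to a right- and row-maximal bicluster: its path spells the shared pattern,
the leaves beneath it name the genes, and branching guarantees no uniform
extension to the right. Left-maximality is decided with suffix links: a
node fails it exactly when an incoming suffix link arrives from a node
with an equal subtree leaf count, because then every occurrence of the
pattern extends one column to the left with the same gene set and the
node is redundant. Single-gene patterns are discarded. Output order is
deterministic: descending area (genes x columns), then start column, then
pattern.

A brute-force oracle (`bruteForceBiclusters`) enumerates the same objects
by scanning every contiguous column interval and grouping identical rows;
the test suite requires exact agreement of the two on randomized
instances, and re-verifies each reported bicluster's maximality directly
against the matrix. The enumeration is empirically linear in the gene
count at a fixed number of time points (the suite checks the growth rate
over 500/1000/2000 genes x 20 time points).

### Scoring and filtering

Pattern significance uses a null model of independent transition columns
with the empirical per-column symbol frequencies of the full matrix: a
pattern `P` over columns `J` has chance probability
`p(P) = prod_{c in J} f_c(P_c)`, and the module's p-value is the binomial
upper tail `P(X >= |I|)` with `X ~ Binom(n_genes, p(P))`. The independent
column model is the simplest one consistent with "a matrix of equal
size"; the suite validates it against a Monte-Carlo simulation of the
null. A column-dependent (Markov) null is a documented extension point.
P-values are Bonferroni-corrected by the number of enumerated biclusters
(the family of tests actually performed).

Filtering removes modules with corrected p above `pCut` (default 0.01),
fewer than `minGenes` genes or spanning fewer than `minTimepoints` time
points, and then greedily removes overlaps: scanning in ascending
corrected-p order, a module is dropped when its *cell* Jaccard (shared
(gene, column) cells) with an already kept module exceeds `jacCut`
(default 0.25). Keeping the more significant member of an overlapping
pair is our choice; the equally defensible alternative (larger area) is a
one-line change.

## Regulator prioritization

The network is a directed weighted graph; regulators are the vertices
with outgoing edges. For a module at one time point, the preference
vector places each module gene's expression — its absolute value by
default, because diffusion scores are additive and a strong repression is
as informative as a strong activation — on its vertex; module genes
absent from the network are excluded with a warning, and a time point
whose seed mass is entirely zero is skipped rather than failing the whole
series.

Mass flows *backwards*: the graph is transposed, so a target's mass
splits across its regulators. The row-stochastic transition matrix `W` is
computed on the transposed graph (each target row normalized by its total
incoming regulation weight); vertices without outgoing edges in the
transposed graph keep all-zero rows, so mass reaching them simply decays
instead of teleporting — rankings compare regulator scores, which this
does not distort. Whether to normalize before or after transposition is
genuinely ambiguous in the heat-kernel ranking literature; the
transposed-graph convention implemented here is the one under which "a
target distributes its signal among its regulators in proportion to their
regulation strength".

The ranking vector is the heat-kernel diffusion `p_0 exp(-t L)` with
`L = I - W`, approximated by `Z` discrete steps:

    p <- (1 - t/Z) p + (t/Z) (p W)

i.e. `p_0 (I - (t/Z)L)^Z`. Defaults are `t = 0.25` and `Z = 100`: a small
`t` favours regulators close to the seed genes, larger values weigh
longer regulatory chains. For `t/Z <= 1` every step is a convex
combination, so scores stay non-negative, and when `W` has no zero rows
total mass is conserved exactly. Regulators are ranked by descending
score with lexicographic tie-breaks; one ranking is produced per time
point of the module's span (a module over transition columns
`[c1, c2]` spans time points `c1 .. c2+1`).

### Accuracy of the discrete kernel

The discrete scheme is a first-order approximation of the matrix
exponential: its L1 error against a dense `expm` oracle behaves as
`(t^2 / 2Z) * ||L^2 exp(-tL) p_0||`, decreasing like `1/Z` and growing
like `t^2`. For a unit-mass seed on 20-50-vertex graphs this measures
around `5e-5 * t^2` at `Z = 100` and `5e-7 * t^2` at `Z = 10000`. Users
who need tighter agreement with the exact kernel at large `t` should
raise `Z` proportionally to `t^2`; the ranking itself is insensitive to
this bias well before the scores are, because it only depends on score
order.

## Snapshots

A snapshot frame shows the top `topK = 30` regulators (or, in threshold
mode, those scoring at least a cutoff) on the upper semicircle, left to
right in non-increasing score order, the module genes on the lower
semicircle, and regulation arcs among displayed nodes; arcs out of a
highlighted node ("regulates") are orange, arcs into one
("regulated by") green, all others gray. Geometry is fixed — the top
radius is 1.25x the bottom radius, nodes are evenly spaced by angle — and
output is plain SVG 1.1 written with fixed two-decimal coordinates, so a
given input produces byte-identical files. A rank-trajectory TSV
(regulator x time point matrix of ranks) accompanies each rendered
series.

## Synthetic data: what it emulates, and what it does not

`generatePlantedExpression` plants modules as shared real-valued
trajectories built from cumulative steps of `+/-(tau + margin)` (`0` for
`N`) over a chosen column interval, on an i.i.d. standard normal
background, with optional Gaussian noise; the default margin
`max(3 * noiseSd, 1)` keeps the pattern robust through discretization.
`generatePlantedNetwork` wires a planted TF to every gene of its module
and adds background TF-target edges independently with probability
`backgroundP`. All randomness derives from one explicit seed through a
private RNG stream that never touches the session's generator.

`generatePlantedStudy` fixes the reference condition used across the test
suite: 50 genes x 20 time points, two 20-gene modules over columns 2-19
and 1-18, `tau = 0`, an 8-TF network with `backgroundP = 0.1`. Three
properties of this design are deliberate. The two patterns are
complementary on every shared column, so the modules cannot merge into
one chance bicluster. Each pattern is exactly balanced (as many `U` as
`D`), so a planted trajectory starts and ends at its baseline and the
transitions flanking the interval are unbiased coin flips per gene — an
unbalanced pattern ends displaced from the background range, which makes
the flanking transition nearly deterministic and systematically extends
the discovered interval beyond the planted one. And the module
dimensions are large enough that a maximal bicluster differing from the
truth by one stray gene or one column still has cell Jaccard above 0.9,
so recovery does not hinge on the absence of rare chance coincidences.

What the generator does *not* emulate: heteroscedastic and correlated
measurement noise, missing-value structure, autocorrelated background
profiles, hub structure and shared targets in real regulatory networks,
and modules with partially coherent membership. Passing the planted
recovery tests therefore demonstrates correctness of the machinery under
the model's own assumptions, not performance on real microarray or
RNA-seq data.

## Numerical and degenerate-input choices

* Ties at `tau = 0` discretize to `U` (the `>=` branch is tested first);
  documented, deterministic.
* Regulator score ties break lexicographically by id, so rankings are
  bit-reproducible.
* Dangling vertices get zero transition rows (mass decays); no
  teleportation term is added.
* A module time point with no usable seed mass is skipped with a
  warning; an entirely absent module (no gene in the network) is an
  error.
* Duplicate network edges merge keeping the maximum weight, with a
  warning; non-positive weights are errors.
* All-missing expression input, all-constant rows, and empty enrichment
  backgrounds are errors, not silent empties.

## Problem sizes used by the test suite

The bundled tests run the brute-force cross-validation on 100 random 8x6
matrices, the scaling check at 500/1000/2000 genes x 20 time points, the
diffusion-vs-exponential comparison on 20 random 20-50-vertex graphs,
a 100,000-replicate Monte-Carlo check of the pattern p-value on an 8x4
matrix, and the full pipeline twice on the reference planted study for
byte-level determinism. These sizes keep the whole suite in the
low-minutes range on one CPU while leaving each property enough power to
fail loudly when broken.

## Worked example

```{r example, eval = FALSE}
st <- generatePlantedStudy(seed = 1)
dir.create("study")
writeExpressionTSV(st$expression, "study/expression.tsv")
writeEdgeListTSV(st$network, "study/network.tsv")

cfg <- pipelineConfig("study/expression.tsv", "study/network.tsv",
                      outDir = "study/out")
res <- runPipeline(cfg)

res$biclusters          # filtered modules, most significant structure first
head(res$rankings)      # module x time point x regulator table
```

## Limitations

Patterns must be exactly coherent: a gene missing a module's trend at a
single time point is excluded (error-tolerant bicluster variants are out
of scope). Overlap filtering is greedy, not optimal. The pattern null
model ignores column dependence. Enrichment uses plain Bonferroni over
tested terms, with no annotation-graph propagation. Rankings share the
general caveat of absolute-value seeding: activation and repression are
not distinguished.
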