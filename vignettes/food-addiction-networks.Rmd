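---
title: "Methods: mixed-type networks, hypergraph centrality and stability in fanet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mixed-type networks, hypergraph centrality and stability in fanet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fanet)
```

`fanet` analyzes how a food-addiction (FA) diagnosis is embedded in networks
of sociodemographic, anthropometric and metabolic variables measured on a
pediatric cohort. This vignette is the package's account of the methods: the
models and their assumptions, the defaults and why they were chosen, the
numerical details, and what the accompanying tests do and do not establish.

## The association model

Cohort variables are mixed-type, so no single correlation coefficient
applies. `build_matrix()` dispatches per pair on the declared kinds:

* **continuous–continuous**: Pearson's $r$, signed, in $[-1, 1]$;
* **categorical–categorical**: Cramér's
  $V = \sqrt{\chi^2 / (N \min(r-1, c-1))}$, in $[0, 1]$, with $\chi^2$
  computed *without* continuity correction;
* **continuous–categorical**: $\eta^2 = SS_{between}/SS_{total}$ from
  one-way ANOVA, in $[0, 1]$.

Two dialect decisions deserve emphasis. First, the uncorrected $\chi^2$: on
the cohort's FA-by-sex table (8/34 girls, 16/35 boys) it yields $p = 0.176$,
whereas the Yates-corrected statistic yields $p \approx 0.27$; the
uncorrected form is the one consistent with the published descriptive table,
so it is the package default everywhere ($\chi^2$ entries of the matrix and
`group_compare()`). Second, $\eta^2$ is stored as is, not as the correlation
ratio $\sqrt{\eta^2}$. This preserves the published convention but has a
structural consequence discussed below: $\eta^2$ is a *squared* quantity, so
a continuous–categorical pair whose latent correlation is $0.3$ contributes
only $\eta^2 \approx 0.09$ and will not cross a $0.2$ edge threshold. A
configuration preferring scale comparability can take square roots before
thresholding; the default keeps the published scale.

**Missing data.** The default policy is pairwise complete-case for
continuous variables (each matrix entry uses every subject observed on both
variables, recorded in `n_used`), with missing *binary* cells replaced by the
reference level — reading an absent record as absence of the condition.
Listwise deletion and mean imputation are available; `centrality_shift()`
reports the per-node centrality change between two policies, the shape of a
mean-imputation sensitivity analysis.

**Collinearity.** Before network construction, pairs with
$|\rho| \ge 0.90$ are resolved by removing *one* member: the variable with
the larger mean absolute association to the remaining variables (ties go to
the later variable in declared order), repeated greedily until no violation
remains. Removing both members of each violating pair would be the literal
alternative, but it discards information unnecessarily and would empty
tightly coupled anthropometric panels; one-of-pair removal is the standard
practice and is idempotent here by construction.

## Graphs, hypergraphs and the hyperedge rule

`build_graph()` joins $i, j$ when $|a_{ij}| \ge \tau$. The domain presets are
$\tau = 0.2$ (sociodemographic), $0.2$ (nutritional status) and $0.3$
(metabolic), with $0.5$ reserved for visualization exports. Undefined
(sentinel) entries never form edges; isolated nodes are retained. Thresholds
above 1 are allowed with a warning so degenerate configurations propagate as
empty networks rather than failures.

How hyperedges should be derived from a thresholded association matrix is
genuinely open — it is the largest under-specification in this family of
analyses, and results depend on it. `build_hypergraph()` offers two rules:

* **maximal_clique** (default): hyperedges are the maximal cliques (size
  $\ge 2$) of the thresholded graph. This is the canonical reading of
  "polyadic interaction": every member pair is itself associated, and the
  two-section (clique-expansion) of the hypergraph reconstructs the graph
  exactly — a property the test suite verifies on random matrices.
* **ego**: one hyperedge per non-isolated node, the node plus its
  neighbors, duplicates collapsed. This reproduces star-like structures and
  is the other dialect seen in applied work.

Because the two-section of a maximal-clique hypergraph *is* the graph,
graph and hypergraph centralities coincide under the default rule; they
diverge under `ego` or the bipartite representation. Published analyses that
report different graph and hypergraph centrality tables for the same data
are therefore implicitly using a non-clique rule; the package surfaces the
choice rather than hiding it.

## Centrality: definitions and numerics

All four measures use the unweighted thresholded graph (edge weights are
retained for reporting, not for paths):

* **Degree**: $k_i/(n-1)$.
* **Closeness** (Wasserman–Faust): for node $i$ in a component of size
  $n_i$, $\frac{n_i - 1}{n - 1}\cdot\frac{n_i - 1}{\sum_j d_{ij}}$ — the
  component-size scaling makes values comparable across disconnected graphs.
  An isolated node has no defined closeness and is reported as missing
  (rendered `-`/`NA`), matching how such rows appear in published tables.
* **Betweenness**: shortest-path betweenness via Brandes' accumulation,
  endpoints excluded, normalized by $(n-1)(n-2)/2$.
* **Eigenvector**: principal eigenvector of the adjacency, nonnegative,
  unit Euclidean norm; power iteration from a uniform start with tolerance
  $10^{-10}$ and a 1000-iteration cap. The iteration runs on $A + I$ rather
  than $A$: the two share eigenvectors, but on bipartite graphs (a star,
  for instance) the extreme eigenvalues of $A$ are $\pm\lambda_{max}$ and
  plain power iteration oscillates with period two instead of converging;
  the shift makes the dominant eigenvalue strictly largest in magnitude.
  A graph with no edges has no meaningful eigenvector; an all-zero vector is
  returned with a warning. The fixed point $Ae = \lambda e$ is verified to
  $10^{-8}$ in the tests.

**Strength labels.** Values $\le 0.3$ are *weak*, $\ge 0.7$ *strong*, and
$0.4$–$0.6$ *moderate* per the published bands. The bands leave
$(0.3, 0.4)$ and $(0.6, 0.7)$ unspecified; `classify_strength()` completes
them to *moderate* (nearest-band completion) so every value in $[0,1]$ has a
label. This is a labeling convention only; no computation branches on it.

Hypergraph centralities default to the two-section graph with identical
normalizations; a bipartite variant (measures computed on the node–hyperedge
incidence graph, restricted back to the variable nodes) sits behind
`representation = "bipartite"`.

## Bootstrap stability

`bootstrap_centrality()` implements two resampling schemes. The default,
`matrix_nodes`, resamples the rows/columns of the association matrix with
replacement and rebuilds the hypergraph on the unique set of drawn
variables — a duplicated node adds no structure to an unweighted graph, so
duplicates are collapsed. The alternative, `subjects`, resamples subjects
and rebuilds the matrix from scratch, which is the bootnet-style practice;
it is the right scheme when a cohort (not just a matrix) is available, and
the test suite confirms that its stability improves with cohort size. An
`identity` hook returns the original network every replicate (summaries then
equal 1 exactly), anchoring the index's scale in tests.

The **stability index** is the Spearman rank correlation (ties mid-ranked)
between original and replicate centralities over the *intersection* of nodes
defined in both. Dropped or undefined nodes are excluded pairwise;
replicates sharing fewer than 3 defined nodes are flagged and excluded from
summaries, as are degenerate replicates (fewer than 2 unique nodes).
Small intersections are also why strongly negative indices can occur at all
— with 3–4 shared ranks a single inversion swings $r_s$ far below zero, so
negative minima in stability tables are a small-sample signature, not
evidence of systematic rank reversal. `summarize_stability()` reports mean,
sample SD, median, P25/P75 (linear interpolation, type-7 quantiles), min,
max and $n$ per measure plus a pooled row whose $n$ is the sum of valid
replicates across the four measures. (Published pooled counts that do not
equal the sum of their per-measure counts cannot be reproduced by any
consistent bookkeeping; the package keeps its arithmetic internally
consistent instead of imitating them.)

Every replicate draws from an independent substream of the master seed
(a pre-drawn vector of replicate seeds), so runs are bit-reproducible and
insensitive to evaluation order.

## YFAS-C scoring

Items map to the seven dependence symptoms as printed on the instrument:
$\{1,2,3\}$, $\{4,17,18,25\}$, $\{5,6,7\}$, $\{8,9,10,11\}$, $\{21\}$,
$\{22,23\}$, $\{12,13,14\}$; impairment/distress from $\{15,16\}$; items 19,
20 and 24 administered but unscored. A symptom is present when any mapped
item is endorsed; the diagnosis requires $\ge 3$ symptoms *and* impairment.
Two instrument details are not published and are therefore configuration
with documented defaults: which five items are dichotomous (default: the
impairment pair and the three unscored items) and the per-item Likert
endorsement cut (default: responses $\ge 3$, "often"). The scoring pipeline
is deliberately two-stage — raw responses → endorsement vector → symptoms —
so every downstream result is invariant to those defaults, and the tests
operate at the endorsement level. Whether impairment requires item 15 *or*
16 versus both is likewise unstated; the package uses OR (any-endorsed),
flagged here rather than asserted as the instrument's intent. Missing scored
items are rejected by default; an explicit zero-fill policy (missing = not
endorsed) is available and flags its output.

## The synthetic cohort generator

The study's raw data are not deposited, so the generator is a first-class
module: every downstream stage is exercised on cohorts whose *marginals*
match the published descriptive table (n = 93; FA 24/93; 51 boys; means/SDs
and medians/ranges as printed) and whose *dependence* is configurable.

* **Mechanism.** A latent Gaussian copula: draw $Z \sim N(0, R)$, push each
  column through its marginal. One mechanism covers all mixed-type pairs,
  and categorical variables arise by thresholding latent normals at the
  quantiles of the published frequencies.
* **Symmetric continuous marginals** (reported mean ± SD) are rescaled
  normals. Sex-stratified values are pooled as two-component mixtures
  (mixture mean; within + between variance), since pooled SDs are not
  printed for all variables.
* **Skewed marginals** (reported median (min–max)) are shifted log-normals:
  shift = printed minimum, $\mu = \log(\mathrm{median} - \mathrm{min})$
  (the log-normal median), and $\sigma$ set so the printed maximum sits at
  the fitted 99th percentile. This preserves support ($x > \mathrm{min}$)
  and skew using only the printed numbers. The 99th-percentile anchor is a
  choice: anchoring at the exact sample maximum of 93 draws would make
  $\sigma$ depend on $n$; at $n \gg 93$ the synthetic tail exceeds the
  printed maximum, which is the expected behavior of an unbounded model.
* **Dependence** is declared as a latent correlation matrix
  (`dependence_spec`), validated and PSD-repaired by eigenvalue clipping
  (tolerated only while no entry moves more than `repair_tol`).
  `plant_block()` injects a known mutually correlated block for
  parameter-recovery experiments. The packaged default
  (`default_study_dependence()`) is a six-factor model — body size,
  adiposity, two lipid axes (providing the HDL–triglyceride inversion),
  blood pressure, and a social factor shared by socioeconomic class and
  FA — with loadings at conventional pediatric magnitudes, PSD by
  construction, chosen once and not fitted to anything.
* **What it does not emulate**: the real joint distribution (unknown),
  sex-stratified dependence, measurement error structure, informative
  missingness (injection is MCAR), or lipid arithmetic coherence
  (LDL is drawn marginally, not derived). Consequently, passing tests
  demonstrate correctness of the *machinery* under a controlled data model,
  not recovery of the study's actual networks — which, with the raw data
  unavailable, are shape/format targets only. Under the default weak FA
  links, the sociodemographic network at n = 93 is typically sparse or
  empty: an honest consequence of $\eta^2$'s squared scale at that sample
  size, not a defect.

## Problem sizes and reproducibility

Defaults mirror the study: cohort n = 93, B = 500 bootstrap replicates,
thresholds 0.2/0.2/0.3, pruning cutoff 0.90. The test suite uses n = 20 000
draws for marginal-fidelity checks (binomial/CLT tolerances), 100 seeded
runs at n = 5 000 for planted-block recovery (the four planted variables
must occupy the top-4 degree ranks in at least 95 of 100 runs), exhaustive
enumeration of all graphs on up to 6 nodes against independent
igraph-based oracles for betweenness and closeness, and B = 100 for the
scaled-down bootstrap shape check. All randomness flows from explicit seeds;
`run_pipeline()` writes a manifest (config, substream seeds, versions,
per-domain counts) sufficient to reproduce every artifact byte-for-byte.

## Known limitations

* Centrality values from the original cohort cannot be validated
  numerically without its raw data; published tables constrain only shapes
  (4/9/8-node domains, summary layouts). The published normalization
  dialect is itself not fully recoverable from those tables.
* The KS normality test with estimated parameters is anti-conservative;
  it is the default for fidelity to the published analysis chain, with
  Lilliefors available (`method = "lilliefors"`).
* Weighted-path centralities, weighted hyperedges, edge-weight confidence
  intervals and s-walk hypergraph distances are out of scope.
* The descriptive table's confidence-interval column as published is not a
  standard interval and is not reproduced.
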