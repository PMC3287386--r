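---
title: "Finding phenotype-related functional modules across organism networks"
author: "abmotif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding phenotype-related functional modules across organism networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abmotif)
```

## The problem

A microbial phenotype — hydrogen production, acid tolerance, motility —
is typically realised by a *functional module*: a set of proteins that
work together and are therefore mutually functionally associated. If a
module drives the phenotype, evolution should conserve it in organisms
that express the phenotype and not in organisms that do not. Given
genome-scale functional association networks for a cohort of organisms,
each labelled phenotype-positive or phenotype-negative, `abmotif` finds
the modules that are conserved in at least $\alpha$ positive organisms
and at most $\beta$ negative organisms, scores how improbable each
module's phenotype bias is under a hypergeometric null, and scores how
phylogenetically diverse its carriers are.

The naive route — enumerate the maximal cliques of every organism's
network, then compare clique sets across all organisms — is intractable:
per-network clique counts can be exponential, and the cross-organism
comparison multiplies them. The approach implemented here avoids the
multi-way comparison entirely by folding all organisms into one graph.

## The two-typed, divided network

Proteins are first projected onto clusters of orthologous groups (COGs),
so vertex identity is shared across organisms
(`project_proteins_to_cogs()`; when several protein pairs collapse onto
one COG pair we keep the maximum confidence score — the source data do
not dictate an aggregation rule, and the maximum preserves "any evidence
of association"). The *divided network* then has one vertex per
(organism, COG) pair, partitioned into per-organism divisions, with three
edge kinds:

* **intra-organismal**: the organism's own associations whose combined
  score survives the edge threshold;
* **orthology** (inter-organismal): $(A,c)$–$(B,c)$ whenever organisms
  $A \ne B$ both contain COG $c$ — co-presence only, no score condition;
* **conserved association** (inter-organismal): $(A,c_1)$–$(B,c_2)$ with
  $c_1 \ne c_2$ exists *iff* the association $c_1$–$c_2$ survives the
  threshold in both $A$ and $B$.

Each division is typed positive or negative by its organism's phenotype.
For a vertex set $S$ the type count $c(S,t)$ is the number of organisms
of type $t$ contributing at least one vertex to $S$. A module conserved
across organisms appears as a single maximal clique of this graph, and
an *$(\alpha,\beta)$-clique* is a maximal clique with
$c(S,p) \ge \alpha$ and $c(S,n) \le \beta$.

```{r toy}
links <- tibble::tibble(
  organism = c("A", "B"), node1 = "c1", node2 = "c2",
  combined_score = c(900L, 900L)
)
ann <- tibble::tibble(
  organism = c("A", "B", "C"),
  phenotype = c("positive", "positive", "negative")
)
net <- build_divided_network(links, ann, edge_threshold = 800,
                             nodes = tibble::tibble(organism = "C", cog = "c1"))
enumerate_ab_cliques(net, alpha = 2, beta = 0)
```

### What a maximal clique is — and is not

When every participating organism carries the full COG set, the clique
is the Cartesian product (organism set) × (COG set); this is the
textbook picture and holds for every conserved module the synthetic
generator plants. It is *not* guaranteed in general: if organism $A$
carries the full association triangle $c_1c_2c_3$ while organism $B$
carries only the associations $c_1$–$c_2$ and $c_1$–$c_3$, then
$\{(A,c_1),(A,c_2),(A,c_3),(B,c_1)\}$ is a maximal clique in which $B$
contributes a strict subset of $A$'s COGs. `abmotif` therefore reports
each module as the *union* COG set plus the participating organism sets
(this matches the type-count semantics: one vertex is enough to count an
organism as a carrier), keeps the exact per-organism contribution in the
`org_cogs` list-column, and flags the clean case with `is_product`.
Deduplication and canonical ordering always use the exact vertex sets,
so two distinct cliques are never merged.

## The bounded search

Enumeration is a pivotless Bron–Kerbosch recursion over
(CLIQUE, CAND, NOT) states, iterating candidates in lexicographic
(organism, COG) order for determinism, with the classical maximality
cut of the base algorithm: a branch is abandoned once some NOT vertex is
adjacent to every remaining candidate, since every clique reachable in
that branch could still be extended by that vertex. Without this cut a
single planted module spanning 7 carriers × 4 COGs is a 28-vertex clique
and the recursion would visit all $2^{28}$ of its sub-cliques; with it,
complete graphs cost quadratically many nodes. The cut depends only on
CAND and NOT, which evolve identically under all bound modes, so it
never interferes with the comparisons below.

Two phenotype-aware bounds prune further, without changing the output:

* **β-bound** (`bound_mode = "beta_only"`): prune a branch as soon as
  the clique extended by the current candidate already touches more than
  $\beta$ negative organisms — type counts only grow along a branch. We
  test CLIQUE ∪ {current} rather than CLIQUE alone; both are sound and
  produce identical outputs, the former prunes one level earlier.
* **α-bound** (`bound_mode = "alpha_beta"`, the default): additionally
  prune when even CLIQUE ∪ CAND of the child touches fewer than $\alpha$
  positive organisms, an upper bound on what the subtree can achieve.
  (The positive type count is the quantity this bound must use; using
  the negative count here would be unsound.)

Pruned candidates still migrate from CAND to NOT, so the maximality
certificate at the leaves stays valid. `benchmark_bounds()` runs all
three modes, asserts identical outputs, and reports the deterministic
search-tree node counts; wall times are informational only. At
$(\alpha=0,\ \beta=n_{neg})$ the criterion accepts everything, the
bounds never fire, and the output is exactly the set of all maximal
cliques — on a single-organism complete multipartite network with $k$
parts of 3 COGs that is the worst-case $3^k$:

```{r worst}
cogs <- sprintf("c%02d", 1:9)
part <- rep(1:3, each = 3)
idx <- t(combn(9, 2)); idx <- idx[part[idx[, 1]] != part[idx[, 2]], ]
tri <- tibble::tibble(organism = "X", node1 = cogs[idx[, 1]],
                      node2 = cogs[idx[, 2]], combined_score = 900L)
tri_net <- build_divided_network(
  tri, tibble::tibble(organism = "X", phenotype = "positive"), 800
)
nrow(enumerate_ab_cliques(tri_net, 0, 0))
```

An exhaustive oracle (`oracle_ab_cliques()`) — igraph's unmodified
maximal-clique enumeration followed by the $(\alpha,\beta)$ filter —
provides the independent reference the test suite compares against on
hundreds of seeded random cohorts; it refuses networks above 60 vertices.

## Choosing α and β: the hypergeometric selection

Which $(\alpha,\beta)$ pairs are worth enumerating? Treat the
$\alpha+\beta$ organisms carrying a hypothetical module as a sample
drawn without replacement from the cohort of $|P|$ organisms containing
$|S|$ positives; the pair's p-value is the inclusive upper tail
$P(X \ge \alpha)$ of the hypergeometric distribution. `select_ab_pairs()`
scans $\alpha$ from 1 to $|S|$ and $\beta$ from 0 to $|P|-|S|$, keeps
pairs with $\alpha \ge \beta$ and $p \le$ the threshold (ties at the
threshold are kept), and for each $\beta$ retains only the smallest
qualifying $\alpha$ — any clique found at a larger $\alpha$ is also
found at the smaller one, so larger values are redundant. For a cohort
of 9 positives and 8 negatives at 0.005:

```{r pairs}
select_ab_pairs(n_pos = 9, n_neg = 8, p_threshold = 0.005)
```

The upper tail is computed with `stats::phyper()` (stable log-space
summation); the suite cross-checks it against direct combinatorial
summation of $\sum_i \binom{|S|}{i}\binom{|P|-|S|}{X-i}/\binom{|P|}{X}$
to below $10^{-12}$ relative error for populations up to 200. The same
tail, with the module's own carrier counts as the sample, is attached to
every reported module by `clique_significance()`. No multiple-testing
correction is applied; the p-value ranks modules rather than gating
them. The test treats organisms as exchangeable and deliberately ignores
relatedness — that is what the phylogenetic score is for.

## Phylogenetic diversity score

A module carried by nine closely related positives is weaker evidence
than one carried by nine distant ones. With $\delta(i,j)$ an organism
distance matrix and $Org_P$, $Org_N$ the module's positive/negative
carriers:

$$PP = \sum_{i \in Org_P}\sum_{j \in Org_P} \delta(i,j),\quad
  PN = \sum_{i \in Org_P}\sum_{j \in Org_N} \delta(i,j),\quad
  NN = \sum_{i \in Org_N}\sum_{j \in Org_N} \delta(i,j)$$

$$S_p = \frac{PP - PN - NN}{PP + PN + NN} \in [-1, 1]$$

The sums run over *ordered* pairs exactly as written: $PP$ and $NN$
count each unordered pair twice while $PN$ counts each cross pair once.
That asymmetry is part of the score's definition and is implemented as
printed, not "corrected" — halving $PP$ and $NN$ would change mixed-case
values (the hand-checked case below would move from $1/3$ to $0$).
$S_p = 1$ rewards modules confined to spread-out positives; $S_p = -1$
marks modules with no positive spread at all; the score is invariant to
rescaling all distances. When every involved distance is zero (a module
carried by one organism, say) the ratio is undefined and `phylo_score()`
returns 0 as a neutral sentinel with a warning. Input matrices are
validated: symmetric within $10^{-9}$ relative tolerance (then
symmetrised by averaging), zero diagonal, non-negative; anything worse
is an error, not a repair.

```{r phylo}
dm <- matrix(c(0, 2, 1, 2, 0, 1, 1, 1, 0), 3,
             dimnames = list(c("p1", "p2", "n1"), c("p1", "p2", "n1")))
phylo_score(c("p1", "p2"), "n1", dm) # (4 - 2 - 0) / (4 + 2 + 0)
```

## The synthetic cohort generator

Real STRING-derived cohorts need downloads and curation; every stage of
`abmotif` is instead testable against seeded synthetic cohorts
(`generate_cohort()`). The generator emulates: a cohort of
phenotype-labelled organisms over a shared COG universe; sparse random
background associations with uniform confidence scores; and planted
conserved modules — complete cliques at a fixed score inserted into
exactly their chosen carrier organisms, merged with background edges by
maximum score. Each organism draws from its own RNG stream (seeded from
the cohort seed and the organism index), so growing a cohort never
perturbs existing organisms' networks.

Defaults mirror a hydrogen-production-sized study: 9 positive and 8
negative organisms, a universe of 25 COGs, COG presence probability 0.6,
background association probability 0.08 per present pair with scores
uniform on 400–999 (so roughly half of background edges survive a
high-confidence threshold), planted edges at 900. These are deliberately
modest sizes — the point is end-to-end verifiability, not load testing.

What the generator does *not* emulate: STRING's evidence channels and
score calibration, realistic degree distributions or network modularity,
correlated COG presence along a phylogeny, and orthology errors. Passing
tests therefore demonstrate algorithmic correctness (the planted truth
is recovered under the stated conditions), not field performance on real
cohorts.

## Pipeline, thresholds, robustness

`run_pipeline()` chains the steps: build the network, take explicit
pairs or auto-select them, enumerate per pair, deduplicate by exact
vertex set (the union over pairs), attach significance and phylogenetic
scores, apply the `min_cogs` reporting filter (default 1 — orthology-only
single-COG modules are kept and left to the user to filter), and write a
canonical TSV plus JSON mirror and a run manifest. Outputs are sorted by
(COG-set size descending, lexicographic COG set, lexicographic organism
set), all set fields sorted in C-locale order, so identical inputs give
byte-identical outputs.

`select_edge_threshold()` walks a descending ladder of confidence
thresholds (default 999, 950, …, 500; the ladder is configurable and 999
is always a sensible anchor) and picks the first whose *accuracy*
reaches the target (default 75%). Accuracy here is validation-set
recall: the fraction of known phenotype-related COGs that appear in at
least one output module — the natural reading for a procedure that
optimises recovery of prior knowledge. The per-threshold count of COGs
incident to a surviving edge, and its successive differences, are
reported as a secondary diagnostic but never auto-applied; that step is
human judgment.

`subsample_robustness()` checks that top-ranked modules do not hinge on
phylogenetically redundant organisms: per trial it keeps one organism
per group (e.g. genus), draws a random sub-cohort size, reruns the
pipeline, ranks modules by (p-value, then phylogenetic score), and
reports the pairwise overlap of the top-10 lists across trials.

## Numerical and design choices

* All identifier ordering uses C-locale (radix) sorting; output order is
  locale-independent.
* Scores are integers in [0, 999]; reversed duplicate edges merge by
  maximum; self-loops are dropped.
* `alpha` larger than the number of positive organisms is valid and
  yields an empty result (the grid and the all-cliques limit rely on
  evaluating such cells) rather than an error.
* Module tables serialise set fields semicolon-joined and sorted;
  unset scores render as `NA`; numeric fields use `%.17g` so
  `read_modules(write_modules(x))` reproduces `x` exactly.
* The clique-count grid (`scan_parameter_grid()`) enumerates all maximal
  cliques once at the loosest cell and counts each cell by filtering
  type counts, which is equivalent cell-by-cell and far cheaper than
  re-running the search per cell.
* Tests verify the search against the igraph oracle on 200+ seeded
  cohorts of up to 6 organisms × 8 COGs (every feasible pair, all three
  bound modes) and recovery of planted modules over 50 seeds; those
  problem sizes keep the whole suite in the minutes range while still
  exercising every branch of the criterion.

## Known limitations

* The hypergeometric selection ignores phylogenetic structure by design;
  correlated carriers inflate significance. Use the diversity score and
  the subsampling check alongside it.
* Missing edges in real networks fragment true modules; quasi-clique
  post-processing of the reported modules (with the exact per-organism
  contributions in `org_cogs` as seeds) is the natural follow-up and is
  out of scope here.
* The search is exact and single-threaded; worst-case inputs are
  exponential as for any maximal-clique enumeration. The two bounds make
  the biologically interesting regime (large $\alpha$, small $\beta$)
  cheap, but the all-cliques limit on a large dense cohort is not.
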