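---
title: "Centrality-corrected minimum dominating sets: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Centrality-corrected minimum dominating sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccmds)
```

## The problem

A protein–protein interaction (PPI) network is an undirected graph
$G = (V, E)$ with $n = |V|$ proteins. A *dominating set* $S \subseteq V$ is a
node set such that every protein is either in $S$ or adjacent to a member of
$S$; a *minimum dominating set* (MDS) is a smallest such set. From a
controllability standpoint the MDS is a minimum set of *driver proteins* from
which every other protein can be reached in one step.

Finding an MDS is the binary integer program

$$\min \sum_{j=1}^{n} x_j \quad \text{s.t.} \quad
  \sum_{j=1}^{n} A_{ij} x_j \ge 1 \;\; (i = 1,\dots,n), \qquad
  x_j \in \{0,1\},$$

where $A$ is the adjacency matrix with the convention $A_{ii} = 1$, so each
node covers itself (closed neighborhoods $N[i] = \{i\} \cup \Gamma(i)$).

The MDS optimum is usually far from unique: even the 10-node toy network
built by `make_figure1_fixture()` has four tied optima, and different exact
solvers legitimately return different ones. The *centrality-corrected* model
(CC-MDS) breaks these ties by the biological prior that high-degree,
high-betweenness proteins are the more plausible controllers. It keeps the
constraints and replaces the objective with $\min \sum_j \omega_j x_j$, with
weights

$$\omega_j = \left( d_j\, b_j \right)^{-\gamma}, \qquad \gamma \ge 0,$$

where $d_j$ is the degree, $b_j$ the betweenness normalized by
$(n-1)(n-2)/2$, and $\gamma$ controls how strongly centrality discounts a
node's cost. $\gamma = 0$ recovers the plain MDS; any $\gamma > 0$ makes the
weighted objective generically injective over the tied optima, so the
solution becomes (nearly) solver-independent.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `gamma` | selected by grid search | Exponent of the centrality discount (dimensionless). |
| grid | $\{0, 0.05, \dots, 1\}$ | Candidate $\gamma$ values scanned by `gamma_scan()`. |
| `betweenness_floor` | $0.5 / \binom{n-1}{2}$ | Stand-in for $b_j = 0$ in the weight formula. |
| `alpha` | 0.01 | Bonferroni-corrected significance level in `term_enrichment()`. |

**Selecting $\gamma$.** As $\gamma$ grows, cheap central nodes may be picked
redundantly and the corrected optimum can exceed the domination number.
`select_gamma()` applies two criteria: $\gamma^*$ must be as large as
possible (strongest centrality preference) while the corrected optimum still
has the plain MDS cardinality. All grid points are checked against the
$\gamma = 0$ size — the size profile is usually non-decreasing in $\gamma$
but this is an empirical regularity, not an assumption. If no positive grid
point qualifies, $\gamma^* = 0$ is returned with a warning rather than
guessing; the corrected model then degenerates to the plain one.

**The zero-betweenness floor.** $\omega_j = (d_j b_j)^{-\gamma}$ is undefined
at $b_j = 0$, which happens for every degree-1 node (and many others). We use
$b_j' = \max(b_j, \varepsilon)$ with $\varepsilon$ equal to *half* the
smallest achievable positive normalized betweenness,
$\varepsilon = 0.5 / \tbinom{n-1}{2}$. This keeps all weights finite and
positive while guaranteeing that a zero-betweenness node always ranks
strictly below any positive-betweenness node of the same degree. The
$\varepsilon$ actually applied is stored in the weight object and in the
pipeline manifest. For degenerate networks with $n < 3$ the normalizer is 0;
betweenness is then defined as 0 for all nodes and the floor is set to 0.5.

## The exact solver

Both programs are solved by an exhaustive branch-and-bound over "which node
dominates the currently hardest-to-cover vertex", implemented in C++ with
bitset neighborhoods. An initial upper bound comes from a weighted greedy
cover; the lower bound packs uncovered vertices with pairwise disjoint closed
neighborhoods and sums the cheapest allowed dominator of each; candidates
whose residual coverage is contained in a no-costlier sibling's are pruned
(some optimum always survives the swap). Because the search is exhaustive,
returned solutions are proven optimal — `proven_optimal` is only ever `TRUE`
for `solve_mds()`/`solve_ccmds()` results. The search is deterministic
(canonical node order, fixed tie-breaks), so identical inputs give identical
outputs across runs; when distinct optima share the same weighted objective
(e.g. nodes with identical neighborhoods and centralities), the solver's
deterministic choice stands, and the residual degeneracy can be inspected
with `enumerate_minimum_dominating_sets()` on small graphs.

Numerical choices: objective comparisons use an absolute tolerance of
$10^{-9}$ (weights are $O(1)$–$O(10^2)$ after flooring on the graph sizes we
target, so this is far below any genuine objective gap); weight equality in
the pruning rule uses $10^{-12}$.

## Evaluation battery

* **Overlap** between driver sets is the Jaccard index
  $|A \cap B| / |A \cup B|$ (two empty sets: 1).
* **Attack curves** delete a node list in decreasing-degree order (ties by
  label, `attack_order()`) and record the number of components and the
  largest-component fraction *of the original* $n$ after each single
  deletion. Deleting an absent label is an error, not a no-op.
* **Rank-sum comparisons** of centrality (or membership-count) populations
  use the two-sided Wilcoxon rank-sum with mid-ranks. When
  $n_1 n_2 \le 400$ the p-value is exact, from the permutation distribution
  of the rank sum computed by a count-by-sum dynamic program (equivalent to
  enumerating all $\binom{n}{n_1}$ assignments, exact under ties too);
  otherwise a normal approximation with tie and continuity corrections is
  used. Direction is reported as the difference of medians.
* **Enrichment** of a driver set in an annotated gene list is the one-sided
  Fisher's exact test, i.e. the hypergeometric upper tail $P(X \ge k)$. All
  uses here test over-representation, so the one-sided upper tail is fixed by
  design. The universe is the analyzed network's node set, and annotation
  lists are intersected with it before testing; the sample odds ratio gets a
  0.5 cell correction only when a zero cell occurs.
* **Per-term enrichment** applies Bonferroni with $m$ equal to the number of
  terms actually tested (at least one annotated member inside the universe),
  not the full ontology; significance is called at corrected $p < 0.01$.

## Synthetic data: what it emulates and what it does not

`make_figure1_fixture()` constructs the worked 10-node toy example from the
behavioural constraints it must satisfy: the topology is two 5-node communities,
each with a dominant hub (5 and 6) and a secondary hub (1 and 10), bridged by
the single edge 5–6. The tests verify the constraints themselves against the
enumeration oracle — exactly four minimum dominating sets
$\{1,6\}, \{1,10\}, \{5,6\}, \{5,10\}$, indistinguishable to the plain
objective, with the corrected model at $\gamma = 0.05$ selecting $\{5,6\}$ —
rather than trusting the drawing; unpublished quantities of the original
figure (exact betweenness values) are not claimed.

`random_network()` generates seeded Barabási–Albert graphs (default
attachment 2, matching the toy scale-free regime of sparse PPI maps with
heavy-tailed degree) or Erdős–Rényi graphs, returning the largest connected
component; a single integer seed fully determines the output.
`planted_annotation()` draws an annotated gene list with a chosen inside/
outside annotation rate over a target node set, giving enrichment tests a
known truth (and, with equal rates, a null for type-I checks). The defaults
exercised in the tests — 500-node graphs, 50-node targets, inside rate 0.5
versus outside 0.1 (sample odds ratio near 8) — are the regime where a
practitioner would demand near-certain detection, and the type-I check uses
the same geometry with no signal.

These generators emulate the *topological* conditions the method cares about
(sparse, connected, heavy-tailed) but not other features of real PPI data:
no spoke-model bait–prey artefacts, no degree-correlated study bias in the
annotations, no false-positive interactions. Passing tests therefore
demonstrate algorithmic correctness and statistical calibration under the
stated generative conditions, not biological validity on any particular
interactome.

## Problem sizes

The test-suite and the reproduction script run entirely on synthetic inputs:
exhaustive-oracle comparisons use 200 random connected graphs of 4–12 nodes;
gamma scans and pipeline checks use scale-free networks of 60–200 nodes;
enrichment simulations use a 500-node network with 100 detection and 1,000
null replicates. These sizes were chosen so that the brute-force oracles
remain exhaustive and the whole battery stays interactive; the solver itself
handles networks of a few hundred nodes in seconds, and nothing in the model
is specific to that scale.

## Known limitations

* Weighted branch-and-bound is exponential in the worst case; very large or
  dense networks may require long runtimes (the greedy comparator
  `greedy_dominating_set()` always terminates quickly but is not minimal).
* The critical/intermittent/redundant classification of driver nodes (which
  needs $n$ re-solves), 2-cover "robust control" variants, bipartite-network
  domination, and graphlet-degree-centrality heuristics are out of scope.
* GO-style annotation handling is flat: no DAG propagation or evidence-code
  filtering — curate annotation files upstream.
* Identifier mapping is not performed; node identity is the trimmed label
  string.
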