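# ccmds

Driver-protein discovery in protein–protein interaction (PPI) networks via
**centrality-corrected minimum dominating sets**.

## The problem

A dominating set of an undirected network $G=(V,E)$ is a node set $S$ such
that every node is in $S$ or adjacent to a member of $S$; a minimum
dominating set (MDS) is a smallest one, interpretable as a minimum set of
*driver proteins* able to reach the whole interactome in one step. The MDS
is found by the binary integer program

$$\min \textstyle\sum_j x_j \quad \text{s.t.} \quad \sum_j A_{ij} x_j \ge 1
\;\forall i, \quad x_j \in \{0,1\},$$

with $A_{ii}=1$ so each node covers itself. The trouble is degeneracy: many
optima tie, so different solvers report different "driver" sets. The
centrality-corrected model (CC-MDS) swaps the objective for
$\sum_j \omega_j x_j$ with

$$\omega_j = (d_j\, b_j)^{-\gamma},$$

where $d_j$ is node degree, $b_j$ betweenness normalized by $(n-1)(n-2)/2$,
and $\gamma \ge 0$. Central nodes become cheap, ties break toward
high-degree/high-betweenness proteins, and the optimum becomes nearly
solver-independent. $\gamma$ is chosen by grid search as the largest value
whose corrected optimum still has minimum cardinality, so a CC-MDS is always
also an MDS.

The package provides: an exact branch-and-bound solver with proven
optimality for both programs (`solve_mds()`, `solve_ccmds()`), the
$\gamma$ grid scan and selection rule (`gamma_scan()`, `select_gamma()`), a
brute-force enumeration oracle for small graphs
(`enumerate_minimum_dominating_sets()`), the greedy degree-ranked comparator
(`greedy_dominating_set()`), and an evaluation battery — Jaccard overlap,
degree-targeted attack curves, exact Wilcoxon rank-sum comparisons,
one-sided Fisher/hypergeometric enrichment with Bonferroni correction, and
annotation membership counts — plus seeded synthetic networks and
planted-enrichment annotation generators for fully offline testing.

## Worked example

The built-in 10-node toy network has four tied minimum dominating sets that
the plain objective cannot distinguish; the corrected objective picks the
two-hub pair `{5, 6}`:

```r
library(ccmds)
g <- make_figure1_fixture()

enumerate_minimum_dominating_sets(g)
#> [[1]] "1"  "10"
#> [[2]] "1"  "6"
#> [[3]] "10" "5"
#> [[4]] "5"  "6"

cc <- solve_ccmds(g, compute_weights(node_centrality(g), gamma = 0.05))
cc
#> Dominating set: 2 members, objective = 1.893541, gamma = 0.05
#>   solver: bnb (proven optimal)
#>   members: 5, 6

scan <- gamma_scan(g)          # grid 0, 0.05, ..., 1
scan$size_profile              # stays at 2 across the whole grid
#> [1] 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 2
select_gamma(scan)
#> [1] 1

attack_curve(g, attack_order(g, cc$members))
#>   k components lcc_fraction
#> 1 0          1          1.0
#> 2 1          2          0.5
#> 3 2          2          0.4
```

Reading: hubs 5 and 6 have the largest degree–betweenness products
(`node_centrality(g)` shows $d_5 = d_6 = 5$, $b_5 = b_6 \approx 0.597$), so
they carry the smallest weights and the weighted program selects them among
the four tied optima. Deleting them splits the network into two components
with the largest holding 40% of the nodes — drivers sit at the network's
articulation core.

The full pipeline (read network → largest connected component → centralities
→ $\gamma$ selection → solve → enrichment and attack reports → manifest)
runs as:

```r
run_pipeline("network.tsv", out_dir = "results",
             annotations = c(essential = "essential_genes.txt"))
```

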