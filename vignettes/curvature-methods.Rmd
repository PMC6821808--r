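---
title: "Graph curvature and robustness of structural brain networks: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph curvature and robustness of structural brain networks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riccinet)
```

## The model

riccinet analyzes structural brain networks represented as undirected
weighted graphs $G = (V, E, W)$: nodes are parcellated cortical areas,
edge weights $w_{xy} \ge 0$ are streamline counts or densities from
tractography, the diagonal is zero, and adjacency is implied by positive
weight ($y \in N(x) \iff w_{xy} > 0$). The central quantity is the
Ollivier–Ricci curvature of an edge,

$$\kappa(x, y) = 1 - \frac{W_1(p_x, p_y)}{d(x, y)},$$

where each node carries the neighborhood probability measure
$p_x(y) = w_{xy} / d_x$ with $d_x = \sum_{y \in N(x)} w_{xy}$ (the node
strength), $d(x, y)$ is the hop distance (shortest path counting edges),
and $W_1$ is the Wasserstein-1 / earth mover's distance: the minimal cost
of transporting $p_x$ onto $p_y$ when moving one unit of mass across one
hop costs one. Positively curved edges sit in well-triangulated,
redundantly connected neighborhoods — mass can slide between the two
neighborhoods cheaply — while negatively curved edges are bridges whose
endpoints' neighbors are far from each other. This is what links curvature
to robustness: redundancy of pathways around an edge is exactly what makes
the network tolerant of local failures, and positive curvature also
controls how fast the weight-proportional random walk mixes.

Two conventions deserve emphasis because they are easy to get wrong:

* **Weights enter only through the measures.** The transport cost is the
  purely topological hop metric; $w_{xy}$ shapes $p_x$ but never the
  geodesic. A consequence is exact scale invariance: multiplying all
  weights by any $c > 0$ changes no curvature value, which the test suite
  asserts at $10^{-9}$.
* **Transport may leave the two neighborhoods.** The cost matrix between
  $\mathrm{supp}(p_x)$ and $\mathrm{supp}(p_y)$ is the hop distance in the
  full graph, so optimal routes may pass through nodes outside
  $N(x) \cup N(y)$.

For an adjacent pair $d(x,y) = 1$, so $\kappa = 1 - W_1$. Since supports
of adjacent nodes lie within three hops of each other, $W_1 \le 3$ and
$\kappa \in [-2, 1]$.

Node-level summaries are the scalar node curvature
$\kappa_x = \sum_{y \in N(x)} \kappa(x, y)$ and the weighted variant
$\tilde\kappa_x = \sum_y p_x(y)\,\kappa(x, y)$; the sum in
$\tilde\kappa_x$ effectively runs over $N(x)$ because $p_x$ vanishes
elsewhere. Both are implemented and every user-facing entry point lets the
caller choose; the scalar form is the default because it is the headline
nodal quantity of this methodology. The network average is the mean of
$\kappa_x$ over non-isolated nodes (`node_mean`, default) or the mean of
$\kappa(x,y)$ over edges (`edge_mean`).

## Exact optimal transport

$W_1$ is the value of the balanced transportation linear program

$$W_1(p, q) = \min_{\pi \ge 0} \sum_{i,j} c_{ij}\,\pi_{ij}
  \quad\text{s.t.}\quad \sum_j \pi_{ij} = p_i,\ \ \sum_i \pi_{ij} = q_j.$$

The solver (`emd()`) is an exact transportation simplex (MODI / u–v
method) implemented in C++: north-west-corner initial basis, duals
propagated over the basis spanning tree, Dantzig entering rule with
deterministic lowest-index tie-breaking, and cycle pivots with degenerate
(zero-$\theta$) pivots allowed. The result contract is the optimal value
within $10^{-9}$ together with *a* feasible plan attaining it — optimal
plans need not be unique, so tests check feasibility and cost, never a
particular vertex. Zero-mass support points are dropped before solving to
keep the polytope nondegenerate. An iteration cap (10^5^) turns any
pathological cycling into a hard error rather than a silent wrong answer;
it has never been reached in practice, where neighborhood-sized problems
(tens of support points) solve in well under a millisecond.

Correctness is anchored by `emd_bruteforce()`, an independent oracle that
rounds masses to multiples of $1/L$ and exhaustively enumerates integer
transport plans in those units (recursively, with exact branch-and-bound
pruning that discards only provably suboptimal branches). When $L$ is a
common denominator of the masses the enumeration optimum equals the LP
optimum; the suite verifies agreement on hundreds of random instances and
on every edge of every small graph it touches. The oracle is guarded to
supports of at most 6 points, which is what makes exhaustive enumeration
affordable while still covering every neighborhood arising in graphs of up
to 6 nodes.

## Classical measures

As comparators the package computes node strength
$s_i = \sum_{j \in N(i)} w_{ij}$, betweenness centrality
$g_i = \sum_{j \ne i \ne k} \sigma_{jk}(i)/\sigma_{jk}$ (unordered pairs,
unnormalized, all co-optimal geodesics counted), the binarized clustering
coefficient $C_i = 2 T_i / (k_i (k_i - 1))$ with $T_i$ the number of edges
realized among $i$'s neighbors ($C_i = 0$ for degree $< 2$), global
efficiency $E = \frac{1}{N(N-1)} \sum_{i \ne j} \ell_{ij}^{-1}$
(disconnected pairs contribute 0), and a network entropy.

Two genuinely open choices were settled as follows:

* **Path length for betweenness and efficiency.** For weighted
  connectivity matrices the standard convention treats strong connections
  as short: edge length $1/w$. That is the default (`inverse_weight`);
  `hop` is available for binarized analyses, and every result records
  which mode produced it. Deletion cascades default to `hop` for their
  global efficiency record so that the trajectory is comparable across the
  shrinking graph on the fixed $[0, 1]$ scale.
* **Network entropy.** The package uses the entropy rate of the
  weight-proportional random walk,
  $S = -\sum_x \pi_x \sum_y p_x(y) \ln p_x(y)$ with stationary
  distribution $\pi_x = d_x / \sum_z d_z$, isolated nodes excluded. This
  is a deliberate, documented choice of a discrete entropy on the same
  transition measures that define curvature; it is $0$ when every walk
  step is forced and $\ln(n-1)$ on $K_n$, and it is bounded by the log of
  the maximum degree.

Clustering follows the textual definition — the realized *fraction of
edges* among a node's neighbors — i.e. the numerator is twice the
neighbor-neighbor edge count, which is the only reading under which
$C_i \in [0, 1]$.

## Degenerate nodes

Isolated nodes (zero-weight rows) are accepted everywhere and handled by
one convention: they have no neighborhood measure (`node_distribution()`
errors, since no probability measure exists), but their *node curvature is
0*, they carry zero stationary mass in the entropy, contribute nothing to
efficiency, and sort last among ties in deletion cascades. The convention
keeps cascades and cohort tests total, because targeted deletion produces
isolated nodes routinely; the curvature table flags them so downstream
analyses can exclude them explicitly.

## Robustness cascades

`deletion_cascade()` repeats until the graph is empty: compute the chosen
nodal measure (strength, betweenness, scalar node curvature, or a
seed-controlled random score) on the *current* graph, delete the
highest-valued node, and record largest-component size, global efficiency
and walk entropy on the remainder. Metrics are recorded *after* each
removal, on the remaining graph with its current node count — the network
genuinely shrinks, and efficiency is renormalized by the current $N$ at
every step. Ties break deterministically (isolated nodes last, then lowest
node index), so trajectories are exactly reproducible. With
`recompute = FALSE` the initial ranking is frozen (ablation mode); the
suite checks that the frozen strength cascade equals the descending sort
of initial strengths.

The rank-preserving Gaussian transform reassigns each positive weight with
average-tie rank $r$ among $m$ positive weights the value
$\mu + \sigma\,\Phi^{-1}(r/(m+1))$; zeros and symmetry are preserved, and
the defaults $\mu = 0.5$, $\sigma = 0.1$ follow the established convention
for this normalization in connectome robustness analyses. The transform is
rank-exact (Spearman correlation 1 by construction) but can move weights
to a completely different range, which changes strengths and any
weight-sensitive measure — it is applied only when asked, and the clipping
of any nonpositive transformed value to a small $\varepsilon$ (possible
only for extreme $\mu, \sigma$) warns loudly.

## Cohort statistics

Group comparison is per node: an unpaired two-sided $t$-test assuming
equal group variances (pooled variance, matching the homoscedasticity
convention; Welch is available behind `var_equal = FALSE`), followed by
Holm–Šidák step-down control of the family-wise error rate with $m$ equal
to the number of nodes. The step-down is implemented by its exact
thresholds — reject the $i$-th smallest p-value iff
$p_{(j)} \le 1 - (1-\alpha)^{1/(m-j+1)}$ for all $j \le i$ — with
Šidák-adjusted p-values reported only as a derived convenience. A node
with zero pooled variance gets $t = 0$, $p = 1$ and a flag instead of a
division by zero. Holm–Šidák rejects a superset of Holm–Bonferroni at the
same level, which the suite checks on random p-vectors.

Consistency maps mark each subject's top $\lceil f N \rceil$ nodes by a
measure ($f = 0.25$ by default; ties at the cutoff resolved by node index
for determinism) and count per node how many subjects mark it.
Cross-measure correlation histograms compute a per-subject Pearson $r$
across nodes with across-subject mean and variance; subjects with a
constant measure are skipped with a flag. The same correlation operation
serves for correlating a nodal measure against any per-subject covariate
vector.

## The synthetic generator

Everything above is exercised end to end on synthetic connectomes, so the
generator's defaults *are* the study conditions of the test suite:

* `n_nodes = 116` (a common low-resolution parcellation size; cohort
  statistics use 333, a common high-resolution one),
* `density = 0.3`, typical of streamline-count connectomes at this scale,
* positive weights i.i.d. exponential with mean `weight_scale = 50` — the
  empirical distribution of tractography streamline counts is
  exponential, and all curvature results are invariant to the scale,
* a modular block model (`n_modules = 4`,
  `within_between_ratio = 4`) rather than pure Erdős–Rényi, so that
  curvature and the classical measures are heterogeneous across nodes and
  top-25% consistency maps are nontrivial, as in real connectomes.

Cohorts share one edge backbone per master seed (a common anatomical
scaffold) and redraw independent exponential weights per subject from
deterministically spawned per-subject seeds — this is the within-group
variance the $t$-tests operate on. Group differences are injected by
scaling (or removing) every edge incident to chosen target nodes in group
B.

What the generator does **not** emulate: spatial embedding and
distance-dependent connection probabilities, hemispheric symmetry,
heavy-tailed hub structure beyond what the block model induces,
measurement noise correlated across edges, and subject-level global
scaling differences. Passing tests therefore demonstrate that the
*computations* are correct and that the *statistical pipeline* controls
its error rates under realistic marginal distributions — not that any
particular neuroscientific effect generalizes to real tractography data.

## Numerical choices and problem sizes

* LP optimality tolerance $10^{-11}$ on reduced costs; results asserted at
  $10^{-9}$; oracle agreement at $10^{-7}$.
* Measures validate to mass $1$ within $10^{-12}$; matrices are dense (the
  method targets $N \lesssim 1000$).
* File input follows the averaging rule for asymmetric tables (mean of the
  two triangles, with a warning when material); programmatic construction
  rejects relative asymmetry above $10^{-6}$ as a corrupted matrix.
  Disconnected distances are `Inf`, never a large finite sentinel.
* All TSV output is written at 12 significant digits and round-trips
  losslessly at that precision.
* The test battery runs the transport oracle on 200 random instances,
  verifies curvature against brute-force enumeration on all small named
  graphs plus 15 random 4–6-node graphs, checks bounds/scale-invariance/
  symmetry on 100 random connectomes of 50–116 nodes, compares
  strength-targeted against random deletion on 20 connectomes of 116
  nodes, and evaluates the Holm–Šidák pipeline on 500 null and 100
  effect cohorts of 333 nodes with 20+20 subjects. These sizes were chosen
  to give stable Monte-Carlo estimates (e.g. the family-wise rejection
  rate is tested against $\alpha + 2\sqrt{\alpha(1-\alpha)/R}$) while
  remaining comfortable on a laptop.

## Known limitations

* Curvature of all edges is $O(|E|)$ linear programs of size
  $\deg \times \deg$; dense graphs beyond a few thousand nodes would call
  for the entropic (Sinkhorn) approximation, which is deliberately not the
  reference path here — the definition is exact and so is the solver.
* The hop-distance geodesic makes $\kappa$ insensitive to weighted path
  structure; this is the methodology's explicit convention, not an
  implementation shortcut.
* Holm–Šidák assumes (for exactness) independence across nodes; under the
  positive dependence typical of strength-type measures it is
  conservative, which the null-cohort battery confirms empirically but
  does not prove.
* The random-walk entropy rate is one principled discrete entropy among
  several; comparisons with other entropy notions should recompute rather
  than reinterpret.
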