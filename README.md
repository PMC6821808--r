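# riccinet

Ollivier–Ricci curvature and robustness analysis of brain structural
networks.

Structural connectomes — graphs whose nodes are parcellated brain areas
and whose edge weights count tractography streamlines — are routinely
summarized by strength, betweenness centrality, clustering and global
efficiency. Those measures say little about *redundancy*: how many
alternative routes surround a connection, and hence how tolerant the
network is of local damage. riccinet adds the geometric view. For an
undirected weighted graph $G=(V,E,W)$ each node carries the neighborhood
measure $p_x(y)=w_{xy}/d_x$ (with strength $d_x=\sum_{y\in N(x)} w_{xy}$),
and each edge gets the Ollivier–Ricci curvature

$$\kappa(x,y) \;=\; 1-\frac{W_1(p_x,p_y)}{d(x,y)},$$

where $d$ is the hop distance and $W_1$ is the Wasserstein-1 (earth
mover's) distance, computed here by an exact transportation-simplex linear
program written in C++. Positive curvature marks well-triangulated,
redundant neighborhoods; negative curvature marks fragile bridges. On top
of the curvature core the package provides:

- node curvature $\kappa_x=\sum_{y\in N(x)}\kappa(x,y)$ and the
  measure-weighted variant $\tilde\kappa_x=\sum_y p_x(y)\kappa(x,y)$,
  network averages, and the classical nodal measures for comparison;
- targeted node-deletion cascades (by strength, betweenness, curvature or
  random order) tracking largest component, global efficiency and
  random-walk entropy after every removal, plus the rank-preserving
  Gaussian weight transform;
- two-group cohort comparison: per-node pooled-variance t-tests with
  Holm–Šidák step-down family-wise error control, cross-subject top-25%
  consistency maps, and cross-measure correlation histograms;
- a synthetic connectome/cohort generator (exponential weights, modular
  block structure, injectable localized group effects) so the whole
  pipeline runs end to end without imaging data;
- a command line (`rn_main()` / `inst/cli/riccinet`) with `curvature`,
  `measures`, `robustness`, `compare` and `simulate` subcommands, TSV
  output at 12 significant digits and a JSON manifest per run.

The intended users are researchers analyzing connectivity matrices
(N ≈ 100–1000 nodes) who want curvature-based fragility maps alongside the
standard graph metrics, with every numerical claim backed by an
independent oracle in the test suite.

## Worked example

```r
library(riccinet)

spec <- synthetic_spec(n_nodes = 116, density = 0.3, seed = 42)
g <- generate_connectome(spec)
g
#> weighted_graph: 116 nodes, 1995 edges, density 0.299

ct <- ricci_curvature(g)
ct
#> curvature_table: 1995 edges, 116 nodes; network average 5.4555 (node), 0.1586 (edge)
head(ct$edges, 3)
#>    x  y     kappa
#> 1 n1 n6 0.1623443
#> 2 n1 n8 0.2014098
#> 3 n1 n9 0.2134094
```

Each `kappa` row is one edge's curvature: `n1–n6` at 0.16 sits in a mildly
redundant neighborhood (transporting `n1`'s neighbor measure onto `n6`'s
costs 0.84 hops on average). The network averages summarize overall
integration; 0.16 per edge is typical for a modular graph at this density.

```r
measure_correlation(node_curvature(g, table = ct), node_strength(g))
#> [1] 0.5482406
```

Node curvature correlates with strength (r = 0.55) but is not reducible to
it — the complementary information is the point of the measure.

```r
traj <- deletion_cascade(g, "strength")
head(as.data.frame(traj), 3)
#>   step removed measure_value n_remaining largest_component efficiency  entropy
#> 1    1     n57      2680.497         115               115  0.6490465 3.125127
#> 2    2     n59      2563.075         114               114  0.6487347 3.113437
#> 3    3     n68      2391.469         113               113  0.6483881 3.101295
```

Each cascade step removes the currently strongest node and re-measures the
remaining graph; comparing the efficiency/entropy decay across targeting
measures (and against `measure = "random"`) quantifies which nodes the
network can least afford to lose.

```r
eff <- effect_spec(c(5, 20, 60), "weight_scale_down", 0.3)
co  <- generate_cohort(synthetic_spec(116, 0.3, seed = 7), 10, effect = eff)
res <- group_compare(co, "strength", alpha = 0.05)
res
#> group_comparison: measure 'strength', 116 nodes, 3 significant at FWER 0.05
as.data.frame(res)[res$significant,
                   c("node_id", "mean_a", "mean_b", "t_statistic", "p_value")]
#>    node_id   mean_a   mean_b t_statistic      p_value
#> 5       n5 2303.150 619.4476    21.43233 2.908952e-14
#> 20     n20 1231.035 371.5660    15.34980 8.759403e-12
#> 60     n60 1531.926 517.2012    12.47133 2.707471e-10
```

A cohort of 10+10 synthetic subjects with incident weights scaled to 30%
at nodes 5, 20 and 60 in group B: the Holm–Šidák-corrected comparison
recovers exactly the three injected nodes and nothing else.

The same pipeline from a shell:

```sh
Rscript inst/cli/riccinet simulate --out cohort_a --n-nodes 116 --n-per-group 10 --seed 7
Rscript inst/cli/riccinet curvature --input cohort_a/sub001.tsv --out out/
```

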