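# vwclust

Network-based clustering of multi-omics samples with the **vector-valued
W1 (Earth Mover's) distance**.

Cancer cohorts are profiled on several omics platforms at once — gene
expression, copy-number variation (CNV), DNA methylation — and the signal
in those platforms is often concordant. `vwclust` is for analysts who want
to integrate such layers *on a gene-interaction network* rather than by
concatenating features: each sample becomes a vector-valued probability
distribution (mass indexed by gene × layer, total mass 1), samples are
compared by optimal transport on the network, and the resulting distance
matrix drives hierarchical clustering into candidate subtypes.

## The method

For a gene network $G=(V_G,E_G)$ with edge lengths $\ell$ and a layer graph
$F=(V_F,E_F)$ connecting the omics types, the distance between two samples
$\vec\rho_0,\vec\rho_1$ is

$$
W(\vec\rho_0,\vec\rho_1)=\min_{u,w}\ \sum_{e\in E_G}\sum_{j\in V_F}\ell_e|u_{ej}|
+\gamma\sum_{i\in V_G}\sum_{f\in E_F}|w_{if}|
\quad \text{s.t.} \quad \vec\rho_0-\vec\rho_1=D_1u+D_2w,
$$

with $u$ the flux along network edges within layers, $w$ the flux between
layers at a gene (cost $\gamma$ per unit), and $D_1,D_2$ the incidence
operators. This equals the scalar W1 on a weighted super-graph (one copy of
$G$ per layer plus $\gamma$-length cross-layer edges), and is solved exactly
in compiled code as an uncapacitated minimum-cost flow (primal-dual
successive shortest paths).

Per-sample node masses are not raw values: each layer is first made
strictly positive (CNV exponentiated, methylation flipped to $1-\beta$) and
then converted to the stationary distribution of a weighted random walk on
the network, $\pi_i \propto g_i \sum_{k\in N(i)} g_k$, which removes
between-platform scale differences and folds in each gene's neighbourhood.

## Worked example

Simulate a two-layer study with two planted groups and cluster it:

```r
library(vwclust)

cfg <- simulation_config(n_genes = 50, n_samples = 12, n_clusters = 2,
                         module_fraction = 0.2, seed = 42)
sim <- simulate_dataset(cfg)

lg     <- layer_graph(c("expression", "cnv"), preset = "pair")
layers <- list(expression = preprocess_layer(sim$layers$expression, "expression"),
               cnv        = preprocess_layer(sim$layers$cnv, "cnv"))
mv <- invariant_measures(sim$graph, layers, lg)

D <- pairwise_distance_matrix(mv, sim$graph, lg, gamma = 1)
round(D[1:4, 1:4], 4)
#>        s001   s002   s003   s004
#> s001 0.0000 0.4439 0.1706 0.4562
#> s002 0.4439 0.0000 0.4713 0.1417
#> s003 0.1706 0.4713 0.0000 0.4785
#> s004 0.4562 0.1417 0.4785 0.0000

hierarchical_cluster(D, k = 2)
#> <cluster_assignment> 12 samples, k = 2 (average linkage)
#> cluster
#> 1 2
#> 6 6
```

Samples 1 and 3 share a planted group (distance 0.17) while 1 and 2 do not
(0.44): within-group transport is cheap because the planted module genes
carry similar mass. The `k = 2` cut recovers the two groups of six exactly
(adjusted Rand index 1 against the planted labels). `export_dendrogram()`
writes the tree as Newick; `run_pipeline()` does all of the above from TSV
files plus a YAML config, and `inst/cli/vwclust.R` exposes `simulate`,
`distances`, `cluster` and `run` subcommands for shell use.

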