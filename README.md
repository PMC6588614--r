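# sparselap

Topology effects on the cost of sparse feedback control for networks with
Laplacian dynamics.

Structural controllability ranks network topologies by how many driver nodes
they need, and by that yardstick sparse, heterogeneous networks look hard to
control. `sparselap` takes the feedback view instead: every node of an
undirected network with Laplacian dynamics

```
dx/dt = -(L + F) x + B1 d,     L = D - A,   u = -F x
```

can be actuated, but every nonzero entry of the feedback gain `F` — every
sensor-to-actuator channel — carries a price `γ`. The design objective is

```
minimize   J(F) + γ · card(F)
```

where `J(F) = trace(B1ᵀ P(F) B1)` is the closed-loop H2 performance cost
(`P` solves `-(L+F)ᵀP - P(L+F) + (I + FᵀF) = 0`) and `card(F)` counts the
feedback channels. The package provides:

* **`rewire_ensemble()`** — heat-kernel adaptive rewiring: one diffusion
  parameter `τ` morphs 100-node, 300-edge graphs from random (`τ = 0`)
  through modular (`τ ≈ 1`) to centralized star-like (`τ = 10`), plus
  degree-preserving null models.
* **`sparse_gain_admm()` / `sparse_gain_path()`** — the sparsity-promoting
  design: ADMM with elementwise hard thresholding (the proximal operator of
  the cardinality penalty), Anderson–Moore F-steps, structured polishing on
  the identified pattern, and a warm-started homotopy over a `γ` grid.
* **`degree_stats()`, `modularity_q()`, `find_communities()`,
  `normalized_modularity()`** — degree-spread centralization measure and
  Newman–Girvan modularity with null normalization.
* **`min_driver_nodes()`** — the PBH driver-node count: the maximum
  multiplicity among adjacency eigenvalues.
* **`run_sweep()`, `regime_ordering()`, `correlate_metrics()`** — the
  τ-by-γ study as a tidy table, with rank-correlation and
  which-topology-wins summaries, and ggplot helpers
  (`autoplot()`, `plot_regime_costs()`, `plot_metric_cost()`).

All results are tibbles; fitted objects support `tidy()` and `glance()`.

## Worked example

Generate one modular network at the study scale, measure it, and price its
controllers:

```r
library(sparselap)

g <- rewire_ensemble(tau = 1, n_steps = 600, n_samples = 1,
                     seed = 42)$graph[[1]]
degree_stats(g)
#> # A tibble: 1 × 5
#>   n_nodes n_edges mean_degree degree_std density
#>     <dbl>   <dbl>       <dbl>      <dbl>   <dbl>
#> 1     100     300           6       1.07  0.0606

mb <- find_communities(g, seed = 1)
modularity_q(g, mb)
#> [1] 0.8445667

min_driver_nodes(g)
#> <driver_result> n_D = 23 of 100 nodes (78 distinct eigenvalues, tol = 6.51e-06)

sys <- laplacian_system(g)
sols <- sparse_gain_path(sys, c(1e-4, 1e-2, 1e-1))
dplyr::bind_rows(lapply(sols, glance))
#> # A tibble: 3 × 6
#>    gamma     J  card total iterations converged
#>    <dbl> <dbl> <int> <dbl>      <int> <lgl>
#> 1 0.0001  16.5  3122  16.8          3 TRUE
#> 2 0.01    16.5  1449  31.0          3 TRUE
#> 3 0.1     16.6   847 101.           3 TRUE
```

Read: after 600 rewiring steps at `τ = 1` the graph has 11 communities with
modularity `Q = 0.84` and a narrow degree distribution (`σ = 1.07`), yet
already needs 23 driver nodes. Its controller keeps 3,122 of the 10,000
possible channels when they cost `1e-4` each, and retreats to 847
channels — concentrated inside the communities — at `1e-1`, paying only a
0.6% performance premium (`J` 16.5 → 16.6) for a 73% channel reduction.
Comparing mean totals across topology classes (`run_sweep()` +
`regime_ordering()`) shows random networks cheapest at `γ = 1e-4`, modular
at `1e-2`, and centralized at `1e-1`.

Because the objective is nonconvex, isolated single-`γ` solves can land in
different local optima; run the homotopy over the default seven-point grid
(`default_gamma_grid()`) as above, which is how the solver is meant to be
used.

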