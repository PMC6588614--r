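---
title: "Network topology and the cost of sparse feedback control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network topology and the cost of sparse feedback control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparselap)
```

## The question

Structural controllability says sparse, heterogeneous networks are hard to
control: they need many driver nodes. But biological regulation is feedback
control, and feedback channels — the sensor-to-actuator communication links —
are not free. `sparselap` studies undirected networks with Laplacian node
dynamics and asks: once each feedback channel carries a price, which network
topology is cheapest to control?

The pipeline has three legs:

1. **Generate** ensembles of simple undirected graphs (default 100 nodes,
   300 edges) spanning distinct topology classes with a single knob, the
   diffusion parameter $\tau$ of heat-kernel adaptive rewiring.
2. **Design** a state-feedback controller for each graph that trades H2
   disturbance-rejection performance against the number of feedback channels,
   at a per-channel price $\gamma$.
3. **Relate** topology metrics — degree spread, modularity, driver-node
   count — to the resulting performance cost, channel count, and total cost.

## The control model

Each node carries a scalar state, and states relax by diffusion on the graph:
$$\dot{x} = -Lx + B_1 d + B_2 u, \qquad L = D - A,$$
with $L$ the combinatorial Laplacian, $d$ exogenous disturbances, and $u$ the
control input. All of $B_1$, $B_2$ and the quadratic performance weights are
identity: every node can be disturbed and actuated, and no node is privileged.
Under state feedback $u = -Fx$ the closed loop is $\dot{x} = -(L+F)x + B_1 d$,
and the performance cost is the squared H2 norm from $d$ to $[x\; u]^T$:
$$J(F) = \mathrm{trace}\,(B_1^T P(F) B_1), \qquad
 -(L+F)^T P - P(L+F) + (I + F^T F) = 0 .$$
$P$ is the closed-loop observability Gramian; `observability_gramian()` solves
the Lyapunov equation by diagonalizing the closed loop (with a dense
vectorized fallback for near-defective cases at small sizes) and enforces a
residual below $10^{-8}\lVert I + F^TF\rVert$.

Each nonzero entry of $F$ is a feedback channel. Pricing channels at $\gamma$
per entry gives the design objective
$$\min_F\; J(F) + \gamma\,\mathrm{card}(F),$$
whose minimizer moves from the dense centralized gain ($\gamma \to 0$) to
highly sparse structured controllers as $\gamma$ grows. Diagonal entries
(self-feedback) count like any other channel.

Because $L$ is symmetric and all weights are identity, the $\gamma = 0$ limit
has a closed form used throughout as an oracle and as the solver
initialization: $F^\* = -L + (L^2+I)^{1/2}$ with
$J^\* = \sum_i \big(\sqrt{\lambda_i^2+1} - \lambda_i\big)$ over the
eigenvalues of $L$. Its closed loop $-(L^2+I)^{1/2}$ is Hurwitz for any graph,
including disconnected ones, so no connectivity filtering is needed anywhere.

## The sparse design algorithm

`sparse_gain_admm()` splits the objective as $J(F) + \gamma\,\mathrm{card}(G)$
subject to $F = G$ and applies ADMM:

* **F-step** — minimize $J(F) + \tfrac{\rho}{2}\lVert F - G + \Lambda/\rho
  \rVert_F^2$ by Anderson–Moore iterations: at the current Gramians the
  stationarity condition is linear in $F$, and a backtracking step toward its
  solution keeps the loop stable and the objective decreasing.
* **G-step** — the proximal operator of the cardinality penalty: elementwise
  hard thresholding keeping $|v| > \sqrt{2\gamma/\rho}$.
* **Dual update**, stopping when $\lVert F - G\rVert_F \le
  \varepsilon_{\mathrm{abs}} N$.
* **Polishing** — on the identified support, minimize $J$ by projected
  gradient (Barzilai–Borwein steps, Armijo backtracking, gradient
  $2(F - P)W$ masked to the pattern).

Defaults (`admm_options()`): $\rho = 100$, $\varepsilon_{\mathrm{abs}} =
10^{-4}$, 100 ADMM iterations, inner tolerance $10^{-6}$ — the published
defaults of the solver family this design follows.

The objective is nonconvex, so *the path matters*. `sparse_gain_path()` solves
an increasing $\gamma$ grid, warm-starting each solve from the previous gain;
the default grid (`default_gamma_grid()`) is seven log-spaced points from
$10^{-4}$ to $10^{-1}$. A grid this fine keeps every solve in the basin of its
predecessor. Solving isolated $\gamma$ values cold (or with a very coarse
path) lets the iteration jump basins, typically landing homogeneous random
networks on much sparser local optima, and the regime structure described
below washes out. This is a property of the algorithm, not a numerical
accident, and the warm-started fine grid is the intended way to run it.

During ADMM the recorded consensus objective $J(F) + \gamma\,\mathrm{card}(G)$
may rise by a few percent while the dual variable is still enforcing
$F = G$; it settles once the support stabilizes. The solver history keeps
these per-iteration records for auditing.

## The network generator

`rewire_ensemble()` starts from a uniform random graph with the target edge
count and applies 600 adaptive rewiring steps. Each step picks a pivot node
with at least one neighbor and one non-neighbor (ineligible pivots are
redrawn, capped at $10N$); with probability 0.1 the rewiring is uniformly
random, otherwise the pivot drops the neighbor with the smallest heat-kernel
entry $h_{ij}$ and connects the non-neighbor with the largest, where
$h = \exp(-\tau \hat{\mathcal{L}})$ and $\hat{\mathcal{L}} =
I - D^{-1/2} A D^{-1/2}$ is the symmetric normalized Laplacian (isolated
nodes' rows and columns are zeroed). Ties at the extremal kernel value are
broken uniformly; the kernel is recomputed after every step by default
(`kernel_refresh` relaxes this). Edge and node counts are conserved exactly;
connectivity is *not* enforced — the control layer handles disconnected
graphs.

The single parameter $\tau$ spans the topology classes: at $\tau = 0$ the
kernel is the identity, every step is effectively random, and snapshots stay
Erdős–Rényi-like; near $\tau = 1$ diffusion is local and communities
crystallize (modularity $Q \approx 0.84$ after 600 steps at the default
size); by $\tau = 10$ diffusion is global and edges pile onto a few hubs,
driving the degree-distribution standard deviation to $\sigma \approx 12$ —
a centralized, star-like network. Degree-preserving double-edge-swap nulls
(`degree_preserving_null()`) provide the reference for `normalized_modularity()`.

Snapshots are taken at a constant rate ($n$ samples over the run means one
every $n_{\mathrm{steps}}/n$ steps). Two ensemble readings are useful and
`sweep_config(sampling = )` exposes both:

* `"replicates"` — independent seeded runs, final snapshot each: clean,
  well-separated topology classes per $\tau$ (how the exemplar comparisons
  are run);
* `"trajectory"` — snapshots of a single run: a sweep from random towards the
  $\tau$-limit, giving each $\tau$ a wide *range* of metric values (how the
  production-scale ensembles are built, and what the metric–cost correlations
  are computed on).

What the generator does **not** emulate about real networks: weighted or
directed interactions, degree correlations beyond what rewiring induces,
growth, and any domain-specific wiring constraints. Conclusions from these
ensembles are about topology classes of sparse homogeneous-size graphs, not
about any particular biological network.

## Topology metrics and driver nodes

`degree_stats()` reports mean degree $2E/N$, sample standard deviation
(denominator $N-1$) as the centralization measure, and density
$2E/(N^2-N)$. `modularity_q()` implements
$Q = \sum_c [e_c/E - (d_c/2E)^2]$; `find_communities()` maximizes it with
greedy agglomeration plus seeded multilevel restarts (5 by default), keeping
the best candidate — on graphs of up to 8 nodes it matches exhaustive search
over all partitions to $10^{-12}$ in the test suite. Null normalization is
the ratio of $Q$ to the null-ensemble mean (a z-score is reported alongside;
at least 10 nulls are required).

`min_driver_nodes()` implements the PBH-based count for undirected networks:
the minimum number of independent control inputs equals the maximum geometric
multiplicity of the adjacency eigenvalues, which for symmetric matrices is
the maximum algebraic multiplicity. Sorted eigenvalues are clustered with gap
tolerance $10^{-8} N \max|\lambda|$; integer symmetric matrices at these
sizes have distinct eigenvalues separated by far more than this, so the
default is safe, and it is exposed for experimentation. Driver nodes are a
count, not an identified node set.

## The sweep and its desk scale

`run_sweep()` ties the legs together: per $\tau$, generate networks; per
network, compute $Q$ (optionally null-normalized), $\sigma$, and $n_D$ once;
then run the warm-started homotopy and report $J$, card, and total at each
requested $\gamma$. Everything is seeded deterministically per
$(\tau, \text{replicate})$, solver failures become flagged rows, and the
identity $\mathrm{total} = J + \gamma\,\mathrm{card}$ holds row by row.

Problem sizes used by the test suite (chosen to keep a full run in minutes on
one core; the production scale of 100 networks per $\tau \in \{0,\dots,10\}$
with 1,000 nulls each is a configuration change, not code):

* exemplar ensemble statistics: 10 independent runs per $\tau$ at the full
  100-node, 300-edge, 600-step setting;
* regime orderings: 10 replicate networks per $\tau \in \{0, 1, 10\}$ at 50
  nodes, 150 edges, $\gamma \in \{10^{-4}, 10^{-2}, 10^{-1}\}$;
* correlations: trajectory ensembles at the full 100-node size — 10 snapshots
  per $\tau \in \{9, 10\}$, and 4 per $\tau \in \{0,\dots,4\}$ at
  $\gamma = 10^{-2}$. Correlations use Spearman rank $\rho$, since the claims
  under test are monotone-association claims.

The correlation ensembles use trajectory sampling at the full 100-node size
deliberately: at half size the structural transient completes within the
first ~100 steps, so late snapshots span too narrow a metric range to carry a
rank correlation, while at 100 nodes the 600-step run *is* the transient.

## What comes out

At $\gamma = 10^{-4}$ channels are nearly free: gains are dense and the
homogeneous random networks, whose Laplacian spectrum is cheapest to damp,
win on total cost. At $\gamma = 10^{-2}$ modular networks win: their
controllers retreat into the communities, shedding channels faster than the
performance cost rises. At $\gamma = 10^{-1}$ centralized star-like networks
win with very sparse hub-dominated controllers, despite the worst performance
cost — and despite needing by far the most driver nodes ($n_D$ rises with
$\sigma$, and with $Q$ past roughly 0.5). Ease of structural control and
cheapness of priced feedback control order topologies in opposite ways.

```{r, eval = FALSE}
cfg <- sweep_config(tau_grid = c(0, 1, 10), networks_per_tau = 10,
                    nulls_per_network = 0, n_nodes = 50, n_edges = 150,
                    seed = 7)
tab <- run_sweep(cfg)
regime_ordering(tab)
plot_regime_costs(tab)
```

## Numerical choices and limitations

* Lyapunov solves diagonalize the (generally nonsymmetric) closed loop;
  residuals are checked and a vectorized dense solve covers near-defective
  cases up to $n = 60$. Gains are not constrained symmetric.
* `card` counts entries above $10^{-10}$ in magnitude; thresholding produces
  exact zeros, so this only guards polish round-off.
* The ADMM + hard-threshold + polish pipeline is a heuristic for a nonconvex
  combinatorial objective: it returns good local optima whose character
  depends on the homotopy path (see above). The brute-force pattern oracle in
  the tests confirms global optimality only on 2-node systems.
* Dense eigendecompositions bound practical sizes to a few hundred nodes.
* Weighted, directed, growing networks and non-identity weights are out of
  scope (the system container stores the weight matrices, but only identity
  is exercised).
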