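# ricciflock

Agent-based simulation of collective motion driven by discrete Ricci
curvature, with the topological observables needed to characterise the
resulting swarms.

## The problem

Flocking models of the Vicsek family align each agent with the *average*
heading of its neighbours — metric variants average over everyone within a
radius, topological variants over a fixed number of nearest agents (field
observations on starling flocks put that number near seven). `ricciflock`
implements a different, more economical selection principle: at every time
step the whole swarm is embedded in a weighted Vietoris–Rips complex, and
each agent follows the `k` agents with the **lowest Forman–Ricci
curvature** found in an annular region `rmin <= r <= rmax` around it.
Strongly negative curvature marks "funnel" vertices through which many
independent paths run — the best-informed agents in the network. With
`rmin > 0` the closest agents are excluded and the interaction becomes
non-local. Even `k = 1` — following a single well-chosen neighbour —
produces near-complete order at zero noise.

It is intended for researchers in collective animal behaviour and active
matter who want a CPU-only, fully reproducible implementation of
curvature-guided alignment plus the standard topological diagnostics.

## Model summary

For agent `i` with annulus candidate set `A_i`:

- Rips complex: edge `(i, j)` iff minimum-image distance `d_ij <= rmax`.
- Weights: `w_i = 1 + degree(i)`, `w_ij = (w_i + w_j) / (1 + d_ij)`.
- Edge curvature (dimension-1 weighted Forman form):
  `R_ij = w_ij [ (w_i + w_j)/w_ij - sum_{e' ~ (i,j)} w_shared / sqrt(w_ij w_e') ]`,
  summing over edges `e'` sharing exactly one vertex; with unit weights
  this is the classical `4 - deg(i) - deg(j)`.
- Vertex curvature: `R_i = sum_j R_ij` over incident edges.
- Update: `v_i(t+1) = v0 * S / ||S|| + v0 * eta * r_hat`, with
  `S = sum w_j v_j(t)` over the `k` lowest-`R` candidates, then rescaled
  to exact speed `v0`; positions advance one step and wrap.

Observables: polar order parameter
`phi_v = ||sum_i v_i/||v_i|| || / N`, mean vertex Forman–Ricci curvature,
Hodge spectral entropies `S_n = -Tr(rho_n log rho_n)` with
`rho_n = exp(-beta L[n]) / Tr exp(-beta L[n])`, Betti numbers, Euler
characteristic and the radial distribution function `g(r)`.

## Worked example

A noise sweep of the 2D local model (`N = 40` for a quick desk run;
defaults elsewhere):

```r
library(ricciflock)
base <- sim_config(N = 40, d = 2, steps = 100, samples = 1, seed = 7)
run_sweep(sweep_spec("eta", c(0, 0.3), base), "sweep-out")
```

```
  param value     phi_v    mean_R   ok
1   eta   0.0 1.0000000 -8296.344 TRUE
2   eta   0.3 0.8812149  -517.130 TRUE
```

At zero noise the swarm reaches complete order (`phi_v = 1`) and collapses
into a dense cluster — hence the strongly negative mean vertex curvature
(hubs everywhere). Noise `eta = 0.3` disrupts both: order drops to 0.88
and the looser swarm has far milder curvature. `sweep-out/` contains
per-value observable CSVs, `config.json` echoes and a `summary.csv` of
the terminal-window means shown above.

Standalone topological analysis of a point cloud (three mutually close
points plus an outlier):

```sh
$ printf '0,0\n1,0\n0.5,0.6\n2.5,2.5\n' > cloud.csv
$ inst/cli/ricciflock analyze-cloud --input cloud.csv --radius 1
Simplicial complex: 4 vertices, 3 edges (r = 1, max_dim = 1)
Topology: b0 = 2, b1 = 1, Euler characteristic = 1
Curvature report: 3 edges, 4 vertices, mean vertex FRC = -0.0101
S0 = 0.884012, S1 = 0.366594 (beta = 1)
```

Two components (the triangle and the isolated point), one loop, and the
entropies of the vertex- and edge-level Hodge Laplacians at damping 1.

The CLI (`inst/cli/ricciflock`) also offers `simulate`, `sweep` and
`fixtures`; the methods vignette (`vignettes/curvature-flocking.Rmd`)
documents the model, parameters and every numerical choice.

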