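---
title: "Curvature-driven collective motion: model, observables and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curvature-driven collective motion: model, observables and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ricciflock)
```

## The model

`ricciflock` simulates `N` self-propelled agents moving at constant speed
`v0` in a periodic cubic box of edge `L = (N / rho)^(1/d)`, `d = 2` or 3.
The classical Vicsek model updates each heading towards the *average*
heading of all metric neighbours. Here the alignment partner set is chosen
topologically instead:

1. At every step the whole swarm is embedded in a Vietoris–Rips complex at
   filtration radius `rmax`: every pair of agents at minimum-image distance
   `<= rmax` is joined by an edge. The complex is built over the *entire*
   system, including pairs closer than `rmin` — non-locality restricts
   neighbour candidacy, not complex membership (the flag
   `exclude_short_edges` inverts this for sensitivity analysis).
2. Vertices are weighted by connectivity, `w_i = 1 + degree(i)`, and edges
   by connectivity and proximity, `w_ij = (w_i + w_j) / (1 + r_ij)`.
3. Each edge receives its weighted Forman–Ricci curvature (FRC). With the
   complex restricted to dimension 1 the curvature of edge `a = (u, v)` is

   `R(a) = w_a [ (w_u + w_v)/w_a  -  sum over edges a' sharing one vertex g
   with a of  w_g / sqrt(w_a w_a') ]`,

   which reduces to the classical `4 - deg(u) - deg(v)` when all weights
   are 1. Vertex curvature is the sum over incident edges,
   `R_i = sum_j R_ij`. Strongly negative `R_i` marks funnel-like vertices
   with many distinct routes through them — the best-connected conduits of
   directional information.
4. Agent `i` looks at its annular candidate set — all `j != i` with
   `rmin <= d(i, j) <= rmax` (closed interval; the boundary has measure
   zero, the convention is fixed for determinism) — and follows the `k`
   candidates with the *lowest* `R_j`, weighting their velocities by the
   vertex weights:

   `v_i(t+1) = v0 * sum(w_j v_j) / ||sum(w_j v_j)|| + v0 * eta * r_hat`,

   with `r_hat` an isotropic unit vector. For `k = 1` and `eta = 0` this
   is an exact copy of the most-curved candidate's velocity.

`rmin = 0` is the *local* model; `rmin > 0` excludes the closest agents
and makes the interaction *non-local*. All agents update synchronously,
positions advance by one step of the new velocity (`dt = 1`) and are
wrapped into `[0, L)`.

### Choices the update rule forced

* **Constant speed.** Adding vectorial noise does not preserve speed, but
  the agents are defined to move at constant `v0`; after the noise kick the
  velocity is rescaled to exactly `v0`, so `eta` controls the size of a
  *heading* perturbation. Speed is conserved to 1e-9 at every step (tested).
* **Weights in the update.** The weights applied to the selected
  neighbours' velocities are their *vertex* weights `w_j = 1 + degree(j)`:
  the sum runs over the `k` selected neighbours.
* **Empty candidate set.** An agent with no one in its annulus keeps its
  own heading (plus noise). This preserves speed and continuity; nothing
  else is obviously defensible. The same fallback handles the
  measure-zero case of an exactly cancelling weighted sum.
* **Ties.** Equal vertex curvatures are broken by ascending agent index,
  and `k` is truncated to the candidate-set size. The package always takes
  the `k` *smallest* `R_i`, even if every candidate curvature happens to
  be positive (sparse configurations).
* **Curvature cadence.** The complex, weights and curvatures are recomputed
  at every time step; no caching across steps.

## Topological observables

* **Order parameter** `phi_v`: norm of the mean heading unit vector; 1 is
  perfect alignment, `~ N^(-1/2)` is disorder (for isotropic headings in
  2D the expectation is `sqrt(pi)/2/sqrt(N)`, a tested null).
* **Mean FRC**: grand mean of `R_i` over agents and recorded steps (vertex
  level, as used for the crossover analysis; edge-level values are also
  exported for diagnostics).
* **Hodge spectral entropies** `S0`, `S1`: von Neumann entropy of
  `rho = exp(-beta L[n]) / Tr exp(-beta L[n])` for the Hodge Laplacians
  `L[0] = B1 B1^T` (the graph Laplacian) and `L[1] = B1^T B1 + B2 B2^T`.
  We use the convention in which `L[n]` *acts on n-simplices*
  (`L[n]down = B_n^T B_n`, `L[n]up = B_{n+1} B_{n+1}^T`), which is what
  "diffusion from n-simplices to n-simplices" requires; sources that write
  the transposes the other way round describe the same operators up to
  this bookkeeping. With the default `max_dim = 1` no triangles exist and
  `L[1]` is its down-part only; building the complex with `max_dim = 2`
  adds the up-term.
* **Betti numbers / Euler characteristic**: `b0 = V - rank(B1)` counts
  components, `b1 = E - rank(B1) - rank(B2)` independent loops; `chi` is
  computed both from simplex counts and from Betti numbers and the two are
  asserted to agree.
* **Radial distribution function** `g(r)`: pair counts in shells of width
  `delta_r`, normalised by `rho` times the *exact* shell volume computed
  from the bin edges (midpoint approximations bias small-`r` bins by
  `O(delta_r)`). Distances are capped at `L/2`, the validity bound of the
  minimum-image convention. `g = 1` for an ideal gas (tested at ±0.1 per
  bin).

### Damping `beta`

The entropies need a damping factor `beta > 0` (`hodge_beta`, default 1).
Quantitative entropy *levels* depend on it: `beta -> 0` drives every
`S_n` to `log(#n-simplices)` and `beta -> Inf` to `log(Betti number)`,
both of which are tested limits. Comparisons between model variants should
therefore be made at a fixed `beta`; the default 1 sits well inside the
informative range for the spectra that N ~ 100–1000 swarms produce.

## Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `N` | 100 (2D), 1000 (3D) | agent count |
| `rho` | 1 | number density; sets `L = (N/rho)^(1/d)` |
| `v0` | 0.5 | speed, length per step |
| `eta` | 0 | noise strength (heading perturbation scale) |
| `rmin`, `rmax` | 0, `rmin + 1` | annulus; width 1 throughout the protocol |
| `k` | 1 | effective topological neighbours followed |
| `steps` | 5000 | steps per run (see below) |
| `samples` | 10 | independent runs averaged |
| `hodge_beta` | 1 | entropy damping |
| `record_every` | 10 | observable cadence |
| `window_frac` | 0.2 | terminal window for time averages |
| `delta_r` | 0.1 | g(r) shell width |

The reference protocol runs 1e5 steps; the package default is 5000 because
the order parameter saturates within the first few thousand steps at these
sizes — terminal-window means are indistinguishable at far lower cost, and
the full-length protocol is a one-line config change (`steps = 1e5`). The
3D experiments here use `N = 200` (L ≈ 5.85) as the desk-scale preset; the
full `N = 1000` setting is `sim_config(d = 3)`. The `g(r)` accumulation
window and `delta_r` are exposed in the config since no canonical values
exist for them; the terminal 20% of steps is used for all "saturated"
summaries.

## What the generator emulates — and what it does not

Initial conditions are uniform random positions in the box and isotropic
headings at speed `v0`; each of the `samples` runs uses seed
`seed + sample - 1`, making ensembles bitwise reproducible. This emulates
a structureless, well-mixed swarm. It does *not* emulate: finite
sensory/reaction delays, heterogeneous agents, attraction/repulsion
forces, obstacles or predators, or open boundaries. Passing tests
therefore validate the curvature-selection mechanism under idealised
conditions, not its robustness in real animal groups.

Small hand-checkable complexes (isolated edge, 3-path, 3-star, unfilled
and filled triangles, two components) are built by `make_fixture()` with
their closed-form curvatures, Betti numbers and entropy limits attached;
the test suite checks the implementation against those values and against
independent brute-force oracles (looped minimum-image distances, the
double-loop curvature sum, density-matrix entropies, igraph circuit
ranks).

## Numerical choices

* Coordinates live in `[0, L)` (half-open); wrapping after every update
  keeps a canonical representative. Minimum image per axis is
  `delta - L * round(delta / L)`, exact for cubic boxes.
* 2D unit vectors from a uniform angle, 3D from normalised normal triples:
  exactly isotropic (chi-square tested at 1e5 draws).
* The Rips threshold is inclusive (`<= r`); edges are ordered
  lexicographically so boundary orientations are reproducible.
* Eigenvalues come from a dense symmetric solver (complexes of up to a few
  thousand simplices); entropy is evaluated in the eigenbasis through the
  partition function with the spectrum shifted by its minimum, so the
  largest Gibbs weight is exactly 1 and `beta = 50` remains accurate to
  1e-6. An empty simplex order has entropy defined as 0, with a warning.
* Betti numbers use QR ranks of the (small, integer) boundary matrices.
* `run_simulation` records topology only when `record_topology = TRUE`:
  the `L[1]` eigendecomposition is cubic in the edge count and dominates
  everything else at 3D densities (thousands of edges), while the dynamics
  itself never needs it.

## Known limitations

* **Zero-noise freezing at small `N`.** With `eta = 0` and a non-local
  annulus, an internally aligned subcluster whose members all sit closer
  than `rmin` to each other receives no further input and moves
  ballistically; if the swarm splits into such groups with different
  headings the configuration is absorbing and `phi_v` stays below 1
  forever (longer runs cannot help). At the desk-scale 3D setting
  (`N = 200`) roughly one zero-noise run in twenty freezes this way;
  ensemble means over a handful of seeds therefore occasionally fall a
  few percent short of complete order. Larger `N` (richer inter-cluster
  encounters) and any `eta > 0` (which anneals frozen domains) both
  remove the effect.
* Simplices above dimension 2 are not built; `S1` with the up-term
  requires `max_dim = 2`, and `S2` is down-part only.
* The dense eigensolver limits entropy tracking to complexes of a few
  thousand simplices; the dynamics itself scales as `O(N^2)` per step
  from the distance matrix.
* Persistent homology, Ollivier–Ricci curvature, normalised Laplacians
  and velocity-correlation observables are out of scope.

## A complete run

```{r, eval = FALSE}
cfg <- sim_config(d = 2, eta = 0.2, k = 7, steps = 5000, samples = 10,
                  record_topology = TRUE, record_gr = TRUE)
run <- run_simulation(cfg)
terminal_order(run)            # saturated order parameter
terminal_order(run, "mean_R")  # saturated mean vertex FRC
head(run$mean)                 # cross-sample mean ± SE series
head(run$gr)                   # radial distribution over the last 20%
```

Sweeps over `eta`, `k`, `rmin` or `d` write per-value experiment
directories plus a `summary.csv` of terminal-window means via
`run_sweep(sweep_spec("eta", seq(0, 1, 0.1), cfg), "outdir")`, which is
how order–disorder transition curves and curvature crossover plots are
regenerated.
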