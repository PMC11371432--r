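#' Simulation configuration
#'
#' All parameters of the curvature-driven flocking model. Defaults follow
#' the study protocol: number density `rho = 1`, speed `v0 = 0.5`, annulus
#' width `rmax - rmin = 1`, one effective topological neighbour, 10
#' independent samples, with `N = 100` in 2D and `N = 1000` in 3D. The box
#' length is derived as `L = (N / rho)^(1/d)`.
#'
#' @param d Spatial dimension, 2 or 3.
#' @param N Agent count. Defaults to 100 (d = 2) or 1000 (d = 3).
#' @param rho Number density, agents per unit area/volume.
#' @param v0 Constant agent speed (length per step).
#' @param eta Noise strength (dimensionless, >= 0).
#' @param rmin,rmax Inner and outer radii of the annular interaction region.
#'   `rmin = 0` is the local model, `rmin > 0` the non-local one. `rmax`
#'   defaults to `rmin + 1`.
#' @param k Number of effective topological neighbours followed (lowest
#'   vertex curvature).
#' @param steps Number of time steps per sample.
#' @param samples Number of independent runs averaged together.
#' @param seed Base RNG seed; sample `s` uses `seed + s - 1`.
#' @param mode `"curvature"` (follow most-curved annulus neighbours) or
#'   `"vicsek"` (average over the metric ball, classical baseline).
#' @param hodge_beta Damping factor for the Hodge spectral entropies.
#' @param record_every Observable recording cadence in steps.
#' @param record_topology If `TRUE`, record Betti numbers and spectral
#'   entropies S0/S1 at every recorded step (costs an eigendecomposition on
#'   the edge set; leave off for large 3D runs).
#' @param record_gr If `TRUE`, accumulate the radial distribution function
#'   over the terminal window.
#' @param delta_r Shell width for the radial distribution function.
#' @param window_frac Fraction of the run (from the end) treated as the
#'   terminal window for time-averaged observables.
#' @param exclude_short_edges If `TRUE`, edges shorter than `rmin` are also
#'   removed from the Rips complex itself (sensitivity analysis; the default
#'   keeps the complex built over the whole swarm at `r = rmax`).
#'
#' @return A validated object of class `sim_config` (a named list, with the
#'   derived box length `L`).
#' @examples
#' cfg <- sim_config(d = 2, steps = 100, samples = 1)
#' cfg$L  # 10, from (100 / 1)^(1/2)
#' @export
sim_config <- function(d = 2, N = NULL, rho = 1, v0 = 0.5, eta = 0,
                       rmin = 0, rmax = rmin + 1, k = 1, steps = 5000,
                       samples = 10, seed = 1, mode = c("curvature", "vicsek"),
                       hodge_beta = 1, record_every = 10,
                       record_topology = FALSE, record_gr = FALSE,
                       delta_r = 0.1, window_frac = 0.2,
                       exclude_short_edges = FALSE) {
  mode <- match.arg(mode)
  if (is.null(N)) N <- if (d == 3) 1000L else 100L
  cfg <- list(N = as.integer(N), d = as.integer(d), rho = as.numeric(rho),
              v0 = as.numeric(v0), eta = as.numeric(eta),
              rmin = as.numeric(rmin), rmax = as.numeric(rmax),
              k = as.integer(k), steps = as.integer(steps),
              samples = as.integer(samples), seed = as.integer(seed),
              mode = mode, hodge_beta = as.numeric(hodge_beta),
              record_every = as.integer(record_every),
              record_topology = isTRUE(record_topology),
              record_gr = isTRUE(record_gr),
              delta_r = as.numeric(delta_r),
              window_frac = as.numeric(window_frac),
              exclude_short_edges = isTRUE(exclude_short_edges))
  cfg$L <- (cfg$N / cfg$rho)^(1 / cfg$d)
  class(cfg) <- "sim_config"
  validate_config(cfg)
}

#' Validate a simulation configuration
#'
#' Checks every invariant and reports all offending fields at once.
#'
#' @param cfg A `sim_config`.
#' @return The config, invisibly unchanged, if valid; otherwise an error
#'   listing every violated field.
#' @export
validate_config <- function(cfg) {
  bad <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) bad <<- c(bad, msg)
  chk(cfg$N >= 1, "N: must be >= 1")
  chk(cfg$d %in% c(2L, 3L), "d: must be 2 or 3")
  chk(is.finite(cfg$rho) && cfg$rho > 0, "rho: must be positive")
  chk(is.finite(cfg$v0) && cfg$v0 > 0, "v0: must be positive")
  chk(is.finite(cfg$eta) && cfg$eta >= 0, "eta: must be >= 0")
  chk(is.finite(cfg$rmin) && cfg$rmin >= 0, "rmin: must be >= 0")
  chk(is.finite(cfg$rmax) && cfg$rmax > cfg$rmin, "rmax: must exceed rmin")
  chk(cfg$k >= 1, "k: must be >= 1")
  chk(cfg$steps >= 0, "steps: must be >= 0")
  chk(cfg$samples >= 1, "samples: must be >= 1")
  chk(cfg$mode %in% c("curvature", "vicsek"), "mode: must be 'curvature' or 'vicsek'")
  chk(is.finite(cfg$hodge_beta) && cfg$hodge_beta > 0, "hodge_beta: must be positive")
  chk(cfg$record_every >= 1, "record_every: must be >= 1")
  chk(is.finite(cfg$delta_r) && cfg$delta_r > 0, "delta_r: must be positive")
  chk(is.finite(cfg$window_frac) && cfg$window_frac > 0 && cfg$window_frac <= 1,
      "window_frac: must be in (0, 1]")
  if (length(bad))
    stop("invalid configuration:\n  ", paste(bad, collapse = "\n  "), call. = FALSE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "Simulation config: N = %d, d = %d, L = %.3f (rho = %g), v0 = %g, eta = %g\n",
    x$N, x$d, x$L, x$rho, x$v0, x$eta))
  cat(sprintf("  annulus [%g, %g], k = %d, mode = %s, steps = %d, samples = %d, seed = %d\n",
              x$rmin, x$rmax, x$k, x$mode, x$steps, x$samples, x$seed))
  invisible(x)
}

#' Initial agent state
#'
#' Positions uniform in the periodic box, headings isotropic at speed `v0`.
#' Uses the global RNG.
#'
#' @param cfg A `sim_config`.
#' @return An object of class `agent_state`: list with `positions` (N x d,
#'   in `[0, L)`), `velocities` (N x d, each row of norm `v0`) and `time`.
#' @export
init_state <- function(cfg) {
  positions <- matrix(stats::runif(cfg$N * cfg$d, 0, cfg$L), cfg$N, cfg$d)
  velocities <- cfg$v0 * random_unit_vector(cfg$d, cfg$N)
  structure(list(positions = positions, velocities = velocities, time = 0L),
            class = "agent_state")
}

#' @export
print.agent_state <- function(x, ...) {
  cat(sprintf("Agent state: %d agents in %dD at t = %d\n",
              nrow(x$positions), ncol(x$positions), x$time))
  invisible(x)
}

#' Candidate neighbours in the annular interaction region
#'
#' All agents `j != i` with `rmin <= d(i, j) <= rmax` (closed interval).
#' With `rmin = 0` this is the usual metric ball minus the agent itself.
#'
#' @param agent Focal agent index.
#' @param distances `N x N` minimum-image distance matrix.
#' @param rmin,rmax Annulus radii.
#' @return Integer vector of candidate indices (possibly empty).
#' @export
annulus_candidates <- function(agent, distances, rmin, rmax) {
  d_i <- distances[agent, ]
  out <- which(d_i >= rmin & d_i <= rmax)
  out[out != agent]
}

#' Select the most-curved topological neighbours
#'
#' Picks the `min(k, length(candidates))` candidates with the smallest
#' vertex Forman-Ricci curvature (most negative first; negative curvature
#' marks funnel-like, information-rich vertices). Ties are broken by
#' ascending agent index, so selection is deterministic.
#'
#' @param candidates Integer vector of candidate agent indices.
#' @param vertex_frc Per-vertex curvature on the global complex.
#' @param k Number of neighbours to keep.
#' @return Ordered integer vector of selected indices.
#' @export
select_topological_neighbours <- function(candidates, vertex_frc, k) {
  if (length(candidates) == 0L) return(integer(0))
  ord <- order(vertex_frc[candidates], candidates)
  candidates[ord][seq_len(min(k, length(candidates)))]
}

#' Single-agent velocity update
#'
#' Reference per-agent form of the update rule. In curvature mode the new
#' velocity is the vertex-weight-weighted sum of the selected neighbours'
#' velocities, normalised to speed `v0`, plus vectorial noise
#' `v0 * eta * r_hat`, then rescaled so the speed is exactly `v0` (agents
#' move at constant speed; noise perturbs the heading only). With `k = 1`
#' and `eta = 0` this is an exact copy of the selected neighbour's velocity.
#' In vicsek mode the unweighted mean over `selected` is used. An empty
#' selection, or an exactly cancelling weighted sum, falls back to the
#' agent's own heading plus noise.
#'
#' Draws from the global RNG when `eta > 0`.
#'
#' @param agent Focal agent index.
#' @param state An `agent_state`.
#' @param selected Indices of the neighbours to follow (for vicsek mode,
#'   the metric-ball membership including the agent itself).
#' @param weights A `weight_assignment` (vertex weights are used).
#' @param cfg A `sim_config`.
#' @return A d-vector of the new velocity (norm `v0`).
#' @export
update_velocity <- function(agent, state, selected, weights, cfg) {
  v <- state$velocities
  if (length(selected) == 0L) {
    a <- v[agent, ]
  } else if (cfg$mode == "vicsek") {
    a <- colMeans(v[selected, , drop = FALSE])
  } else {
    a <- colSums(weights$vertex[selected] * v[selected, , drop = FALSE])
  }
  nrm <- sqrt(sum(a^2))
  if (nrm < 1e-12) {      # exact cancellation: keep own heading
    a <- v[agent, ]
    nrm <- sqrt(sum(a^2))
  }
  vnew <- cfg$v0 * a / nrm
  if (cfg$eta > 0) {
    vnew <- vnew + cfg$v0 * cfg$eta * drop(random_unit_vector(cfg$d, 1L))
    vnew <- cfg$v0 * vnew / sqrt(sum(vnew^2))
  }
  vnew
}

# --- internal fast step ----------------------------------------------------

# per-run context: precomputed upper-triangle indexing for edge extraction
.sim_context <- function(N) {
  ut <- which(upper.tri(matrix(0L, N, N)))
  list(N = N,
       ut_lin = ut,
       iu = ((ut - 1L) %% N) + 1L,
       ju = ((ut - 1L) %/% N) + 1L)
}

# One synchronous step operating on bare matrices. Returns list(x, v, D,
# edges_i, edges_j, edge_dist, vertex_frc) so callers can record observables
# without recomputing the complex.
.step_core <- function(x, v, cfg, ctx) {
  D <- .pairwise_sq(x, cfg$L, sqrt_out = TRUE)
  dvec <- D[ctx$ut_lin]
  keep <- dvec <= cfg$rmax
  if (cfg$exclude_short_edges) keep <- keep & dvec >= cfg$rmin
  keep <- which(keep)
  i <- ctx$iu[keep]; j <- ctx$ju[keep]; de <- dvec[keep]
  N <- ctx$N

  if (cfg$mode == "curvature") {
    deg <- tabulate(c(i, j), N)
    w <- 1 + deg
    we <- (w[i] + w[j]) / (1 + de)
    inv_sqrt <- 1 / sqrt(we)
    S <- .accumulate(c(inv_sqrt, inv_sqrt), c(i, j), N)
    Re <- 2 * (w[i] + w[j]) - sqrt(we) * (w[i] * S[i] + w[j] * S[j])
    Rv <- .accumulate(c(Re, Re), c(i, j), N)

    mask <- D >= cfg$rmin & D <= cfg$rmax
    diag(mask) <- FALSE
    has <- rowSums(mask) > 0L
    A <- v                              # fallback: own heading
    if (cfg$k == 1L) {
      Rm <- matrix(Rv, N, N, byrow = TRUE)
      Rm[!mask] <- Inf
      sel <- max.col(-Rm, ties.method = "first")
      A[has, ] <- v[sel[has], , drop = FALSE]
    } else {
      for (a in which(has)) {
        cand <- which(mask[a, ])
        sel <- cand[order(Rv[cand])]
        sel <- sel[seq_len(min(cfg$k, length(sel)))]
        A[a, ] <- colSums(w[sel] * v[sel, , drop = FALSE])
      }
    }
  } else {                              # metric Vicsek baseline, self included
    mask <- D <= cfg$rmax
    A <- mask %*% v
    Rv <- numeric(N)
    w <- rep(1, N); Re <- numeric(length(i))
  }

  nrm <- sqrt(rowSums(A^2))
  dead <- nrm < 1e-12
  if (any(dead)) {
    A[dead, ] <- v[dead, , drop = FALSE]
    nrm[dead] <- sqrt(rowSums(A[dead, , drop = FALSE]^2))
  }
  vnew <- cfg$v0 * A / nrm
  if (cfg$eta > 0) {
    vnew <- vnew + cfg$v0 * cfg$eta * random_unit_vector(cfg$d, N)
    vnew <- cfg$v0 * vnew / sqrt(rowSums(vnew^2))
  }
  xnew <- x + vnew
  xnew <- xnew - cfg$L * floor(xnew / cfg$L)
  list(x = xnew, v = vnew, D = D, edges_i = i, edges_j = j, edge_dist = de,
       vertex_frc = Rv)
}

#' Advance the simulation by one synchronous step
#'
#' Rebuilds the Rips complex at `r = rmax` over the whole swarm, assigns
#' weights, computes edge and vertex Forman-Ricci curvature, selects each
#' agent's annulus candidates and updates all velocities simultaneously
#' from the time-t state; positions then advance by one step of the new
#' velocity and are wrapped.
#'
#' @param state An `agent_state`.
#' @param cfg A `sim_config`.
#' @return The updated `agent_state` (time incremented).
#' @export
step <- function(state, cfg) {
  stopifnot(inherits(state, "agent_state"), inherits(cfg, "sim_config"))
  ctx <- .sim_context(nrow(state$positions))
  out <- .step_core(state$positions, state$velocities, cfg, ctx)
  structure(list(positions = out$x, velocities = out$v,
                 time = state$time + 1L),
            class = "agent_state")
}

#' Run the curvature-driven flocking simulation
#'
#' Runs `cfg$samples` independent realisations (sample `s` seeded with
#' `cfg$seed + s - 1`), each initialised uniformly at random and iterated
#' for `cfg$steps` synchronous steps. Observables -- polar order parameter
#' and mean vertex curvature, plus Betti numbers and Hodge spectral
#' entropies when `record_topology` is on -- are recorded every
#' `record_every` steps (plus the initial and final step). When `record_gr`
#' is on, the radial distribution function is accumulated over the terminal
#' window.
#'
#' @param cfg A `sim_config`.
#' @param keep_state If `TRUE`, the final `agent_state` of each sample is
#'   returned as well.
#' @return An object of class `ricci_run`: list with `samples` (one
#'   observable data frame per run: columns `step`, `phi_v`, `mean_R`, and
#'   `S0`, `S1`, `betti0`, `betti1` if recorded), `mean` (pointwise
#'   mean/standard error across samples), `gr` (radial distribution data
#'   frame or `NULL`), `config`, and optionally `final_states`.
#' @examples
#' cfg <- sim_config(N = 30, d = 2, steps = 50, samples = 2, record_every = 10)
#' run <- run_simulation(cfg)
#' terminal_order(run)
#' @export
run_simulation <- function(cfg, keep_state = FALSE) {
  validate_config(cfg)
  ctx <- .sim_context(cfg$N)
  rec_steps <- unique(c(0L, seq(0L, cfg$steps, by = cfg$record_every), cfg$steps))
  rec_steps <- sort(rec_steps)
  window_start <- cfg$steps - cfg$window_frac * cfg$steps   # t > this is terminal
  gr_breaks <- .rdf_breaks(cfg$L, cfg$delta_r)
  gr_counts <- numeric(length(gr_breaks) - 1L)
  gr_snapshots <- 0L

  sample_series <- vector("list", cfg$samples)
  final_states <- if (keep_state) vector("list", cfg$samples) else NULL

  for (s in seq_len(cfg$samples)) {
    set.seed(cfg$seed + s - 1L)
    x <- matrix(stats::runif(cfg$N * cfg$d, 0, cfg$L), cfg$N, cfg$d)
    v <- cfg$v0 * random_unit_vector(cfg$d, cfg$N)

    nr <- length(rec_steps)
    phi <- numeric(nr); meanR <- numeric(nr)
    if (cfg$record_topology) {
      S0 <- numeric(nr); S1 <- numeric(nr)
      b0 <- integer(nr); b1 <- integer(nr)
    }
    ri <- 1L

    record <- function(idx, info) {
      phi[idx] <<- order_parameter(v)
      meanR[idx] <<- mean(info$vertex_frc)
      if (cfg$record_topology) {
        sc <- simplicial_complex(cfg$N, cbind(info$edges_i, info$edges_j),
                                 info$edge_dist, r = cfg$rmax)
        ts <- betti_numbers(sc)
        b0[idx] <<- ts$betti[["b0"]]; b1[idx] <<- ts$betti[["b1"]]
        S0[idx] <<- suppressWarnings(spectral_entropy(hodge_laplacian(sc, 0L), cfg$hodge_beta))
        S1[idx] <<- suppressWarnings(spectral_entropy(hodge_laplacian(sc, 1L), cfg$hodge_beta))
      }
    }

    # observables at t = 0 need the complex of the initial configuration
    info0 <- .complex_info(x, cfg, ctx)
    record(ri, info0); ri <- ri + 1L

    for (t in seq_len(cfg$steps)) {
      out <- .step_core(x, v, cfg, ctx)
      x <- out$x; v <- out$v
      if (ri <= nr && t == rec_steps[ri]) {
        # curvature of the complex the update was computed on (time t-1 cloud);
        # re-derive for the new positions so records describe the current state
        info <- .complex_info(x, cfg, ctx)
        record(ri, info); ri <- ri + 1L
        if (cfg$record_gr && t > window_start) {
          D <- .pairwise_sq(x, cfg$L, sqrt_out = TRUE)
          gr_counts <- gr_counts + .rdf_counts(D[ctx$ut_lin], gr_breaks)
          gr_snapshots <- gr_snapshots + 1L
        }
      }
    }
    df <- data.frame(step = rec_steps, phi_v = phi, mean_R = meanR)
    if (cfg$record_topology) {
      df$S0 <- S0; df$S1 <- S1; df$betti0 <- b0; df$betti1 <- b1
    }
    sample_series[[s]] <- df
    if (keep_state)
      final_states[[s]] <- structure(list(positions = x, velocities = v,
                                          time = cfg$steps),
                                     class = "agent_state")
  }

  gr <- NULL
  if (cfg$record_gr && gr_snapshots > 0L)
    gr <- .rdf_normalize(gr_counts, gr_breaks, gr_snapshots, cfg$N, cfg$rho, cfg$d)

  structure(list(samples = sample_series,
                 mean = aggregate_samples(sample_series),
                 gr = gr, config = cfg, final_states = final_states),
            class = "ricci_run")
}

# curvature/complex summary of a static configuration (no velocity update)
.complex_info <- function(x, cfg, ctx) {
  D <- .pairwise_sq(x, cfg$L, sqrt_out = TRUE)
  dvec <- D[ctx$ut_lin]
  keep <- dvec <= cfg$rmax
  if (cfg$exclude_short_edges) keep <- keep & dvec >= cfg$rmin
  keep <- which(keep)
  i <- ctx$iu[keep]; j <- ctx$ju[keep]; de <- dvec[keep]
  N <- ctx$N
  deg <- tabulate(c(i, j), N)
  w <- 1 + deg
  we <- (w[i] + w[j]) / (1 + de)
  inv_sqrt <- 1 / sqrt(we)
  S <- .accumulate(c(inv_sqrt, inv_sqrt), c(i, j), N)
  Re <- 2 * (w[i] + w[j]) - sqrt(we) * (w[i] * S[i] + w[j] * S[j])
  Rv <- .accumulate(c(Re, Re), c(i, j), N)
  list(edges_i = i, edges_j = j, edge_dist = de, vertex_frc = Rv)
}

#' @export
print.ricci_run <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Curvature-flocking run: %d sample(s), %d steps, N = %d, d = %d\n",
              cfg$samples, cfg$steps, cfg$N, cfg$d))
  cat(sprintf("  mode = %s, eta = %g, annulus [%g, %g], k = %d\n",
              cfg$mode, cfg$eta, cfg$rmin, cfg$rmax, cfg$k))
  cat(sprintf("  terminal-window <phi_v> = %.4f\n", terminal_order(x)))
  invisible(x)
}

#' Terminal-window mean of a recorded observable
#'
#' Mean of an observable over the recorded steps in the terminal window
#' (the last `window_frac` of the run), averaged across samples. This is
#' the "saturated" value used for phase-transition summaries.
#'
#' @param run A `ricci_run`.
#' @param var Column name in the observable series (default `"phi_v"`).
#' @return A single number.
#' @export
terminal_order <- function(run, var = "phi_v") {
  stopifnot(inherits(run, "ricci_run"))
  cfg <- run$config
  cutoff <- cfg$steps - cfg$window_frac * cfg$steps
  vals <- vapply(run$samples, function(df) {
    sel <- df$step > cutoff
    if (!any(sel)) sel <- df$step == max(df$step)
    mean(df[[var]][sel])
  }, numeric(1))
  mean(vals)
}
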