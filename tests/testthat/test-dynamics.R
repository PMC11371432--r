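test_that("annulus candidates are the closed-interval shell minus self", {
  D <- rbind(c(0, 0.5, 0.9, 1.5),
             c(0.5, 0, 1.2, 2.0),
             c(0.9, 1.2, 0, 0.3),
             c(1.5, 2.0, 0.3, 0))
  expect_equal(annulus_candidates(1, D, 0, 1), c(2L, 3L))
  expect_equal(annulus_candidates(1, D, 1, 2), 4L)
  expect_equal(annulus_candidates(4, D, 0.9, 1.4), integer(0))
  # boundary values are included
  expect_true(2L %in% annulus_candidates(1, D, 0.5, 0.5))
})

test_that("neighbour selection takes the k most negative curvatures deterministically", {
  R <- c(-5, -2, 0, -3, -3)
  expect_equal(select_topological_neighbours(1:3, R, 1), 1L)
  expect_equal(select_topological_neighbours(1:3, R, 7), c(1L, 2L, 3L))   # truncates
  # tie at R = -3: lower index wins
  expect_equal(select_topological_neighbours(4:5, R, 1), 4L)
  expect_equal(select_topological_neighbours(integer(0), R, 3), integer(0))
  expect_equal(select_topological_neighbours(c(3L, 1L, 4L), R, 2), c(1L, 4L))
})

make_state <- function(pos, vel) {
  structure(list(positions = pos, velocities = vel, time = 0L),
            class = "agent_state")
}

test_that("single-neighbour zero-noise update copies the neighbour exactly", {
  cfg <- sim_config(N = 3, d = 2, steps = 1, samples = 1, eta = 0)
  st <- make_state(rbind(c(0, 0), c(0.5, 0), c(1, 0)),
                   0.5 * rbind(c(1, 0), c(0, 1), c(-1, 0)))
  w <- structure(list(vertex = c(2, 3, 2), edge = NULL), class = "weight_assignment")
  expect_equal(update_velocity(1, st, 2L, w, cfg), c(0, 0.5))
})

test_that("equal-weight neighbours at +/-45 degrees average to heading zero", {
  cfg <- sim_config(N = 3, d = 2, steps = 1, samples = 1, eta = 0)
  v0 <- 0.5
  st <- make_state(matrix(0, 3, 2),
                   v0 * rbind(c(1, 0),
                              c(cos(pi / 4), sin(pi / 4)),
                              c(cos(-pi / 4), sin(-pi / 4))))
  w <- structure(list(vertex = c(1, 2, 2), edge = NULL), class = "weight_assignment")
  out <- update_velocity(1, st, c(2L, 3L), w, cfg)
  expect_equal(out, c(v0, 0))
})

test_that("empty selection keeps the agent's own heading", {
  cfg <- sim_config(N = 2, d = 2, steps = 1, samples = 1, eta = 0)
  st <- make_state(rbind(c(0, 0), c(5, 5)), 0.5 * rbind(c(0, 1), c(1, 0)))
  w <- structure(list(vertex = c(1, 1), edge = NULL), class = "weight_assignment")
  expect_equal(update_velocity(1, st, integer(0), w, cfg), c(0, 0.5))
})

test_that("exact cancellation falls back to the agent's own heading", {
  cfg <- sim_config(N = 3, d = 2, steps = 1, samples = 1, eta = 0)
  st <- make_state(matrix(0, 3, 2),
                   0.5 * rbind(c(0, 1), c(1, 0), c(-1, 0)))
  w <- structure(list(vertex = c(1, 1, 1), edge = NULL), class = "weight_assignment")
  expect_equal(update_velocity(1, st, c(2L, 3L), w, cfg), c(0, 0.5))
})

test_that("a lone agent moves ballistically at speed v0", {
  cfg <- sim_config(N = 1, d = 2, rho = 0.01, steps = 1, samples = 1, eta = 0)
  expect_equal(cfg$L, 10)   # single agent in a roomy box
  st <- make_state(matrix(c(1, 1), 1), matrix(c(0.5, 0), 1))
  for (t in 1:4) st <- step(st, cfg)
  expect_equal(st$positions, matrix(c(3, 1), 1))
  expect_equal(st$velocities, matrix(c(0.5, 0), 1))
  expect_equal(st$time, 4L)
})

test_that("trajectories are bitwise reproducible under the same seed", {
  cfg <- sim_config(N = 30, d = 2, steps = 50, samples = 2, eta = 0.3,
                    record_every = 10, seed = 9)
  r1 <- run_simulation(cfg)
  r2 <- run_simulation(cfg)
  expect_identical(r1$samples, r2$samples)
})

test_that("every agent moves at exactly speed v0 throughout a noisy run", {
  cfg <- sim_config(N = 25, d = 3, steps = 30, samples = 1, eta = 0.4,
                    rmin = 0.5, rmax = 1.5, k = 2, seed = 4)
  r <- run_simulation(cfg, keep_state = TRUE)
  v <- r$final_states[[1]]$velocities
  expect_equal(sqrt(rowSums(v^2)), rep(cfg$v0, 25), tolerance = 1e-9)
  expect_true(all(r$final_states[[1]]$positions >= 0 &
                  r$final_states[[1]]$positions < cfg$L))
})

test_that("the synchronous step matches the per-agent reference composition", {
  # independently recompute one zero-noise step agent by agent through the
  # exported primitives and compare with step()
  set.seed(77)
  for (k in c(1L, 3L)) {
    cfg <- sim_config(N = 20, d = 2, steps = 1, samples = 1, eta = 0,
                      rmin = 0.4, rmax = 1.4, k = k)
    box <- periodic_box(cfg$L, cfg$d)
    pos <- matrix(runif(40, 0, cfg$L), 20)
    vel <- cfg$v0 * random_unit_vector(2, 20)
    st <- make_state(pos, vel)

    D <- pairwise_distances(pos, box)
    sc <- build_rips(pos, box, r = cfg$rmax)
    w <- assign_weights(sc)
    Rv <- vertex_frc(sc, edge_frc_weighted(sc, w))
    vref <- t(vapply(1:20, function(i) {
      cand <- annulus_candidates(i, D, cfg$rmin, cfg$rmax)
      sel <- select_topological_neighbours(cand, Rv, cfg$k)
      update_velocity(i, st, sel, w, cfg)
    }, numeric(2)))

    out <- step(st, cfg)
    expect_equal(out$velocities, vref)
    expect_equal(out$positions, wrap_positions(pos + vref, box))
  }
})

test_that("relabelling agents permutes the zero-noise trajectory consistently", {
  set.seed(83)
  cfg <- sim_config(N = 15, d = 2, steps = 5, samples = 1, eta = 0)
  pos <- matrix(runif(30, 0, cfg$L), 15)
  vel <- cfg$v0 * random_unit_vector(2, 15)
  st <- make_state(pos, vel)
  perm <- sample(15)
  stp <- make_state(pos[perm, ], vel[perm, ])
  for (t in 1:5) { st <- step(st, cfg); stp <- step(stp, cfg) }
  expect_equal(stp$positions, st$positions[perm, ])
  expect_equal(stp$velocities, st$velocities[perm, ])
})

test_that("all-to-all zero-noise Vicsek reaches perfect order in one step", {
  set.seed(91)
  cfg <- sim_config(N = 40, d = 2, steps = 1, samples = 1, eta = 0,
                    rmax = 5, mode = "vicsek")
  # rmax = 5 >= L * sqrt(2) / 2 for L = sqrt(40): every pair interacts
  expect_gte(5, cfg$L * sqrt(2) / 2)
  st <- init_state(cfg)
  st <- step(st, cfg)
  expect_equal(order_parameter(st$velocities), 1.0, tolerance = 1e-12)
})

test_that("overwhelming noise leaves the swarm near the disordered null", {
  cfg <- sim_config(N = 100, d = 2, eta = 5, steps = 300, samples = 3,
                    record_every = 20, seed = 6)
  r <- run_simulation(cfg)
  # random-heading null is ~ N^(-1/2) ~ 0.1; allow generous sampling slack
  expect_lt(terminal_order(r), 0.3)
  b0 <- run_simulation(sim_config(N = 30, d = 2, eta = 5, steps = 20,
                                  samples = 1, record_every = 5, seed = 8,
                                  record_topology = TRUE))$samples[[1]]
  expect_true(all(b0$betti0 >= 1 & b0$betti0 <= 30))
  expect_true(all(b0$phi_v >= 0 & b0$phi_v <= 1))
})

test_that("a zero-step run records only the initial state", {
  cfg <- sim_config(N = 10, d = 2, steps = 0, samples = 1, seed = 2)
  r <- run_simulation(cfg)
  expect_equal(nrow(r$samples[[1]]), 1L)
  expect_equal(r$samples[[1]]$step, 0L)
})

test_that("invalid configurations report every offending field", {
  err <- expect_error(sim_config(N = 10, rmin = 2, rmax = 1, eta = -1),
                      "invalid configuration")
  expect_match(conditionMessage(err), "rmax")
  expect_match(conditionMessage(err), "eta")
  expect_error(sim_config(d = 4), "d: must be 2 or 3")
})
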