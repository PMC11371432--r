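test_that("boundary matrices carry the vertex-order orientation", {
  fx <- make_fixture("isolated_edge")
  expect_equal(boundary_matrix(fx$complex, 1), matrix(c(-1L, 1L), 2))

  ft <- make_fixture("filled_triangle")
  B1 <- boundary_matrix(ft$complex, 1)
  B2 <- boundary_matrix(ft$complex, 2)
  expect_equal(B2, matrix(c(1L, -1L, 1L), 3))  # edges (1,2), (1,3), (2,3)
  expect_equal(B1 %*% B2, matrix(0L, 3, 1))    # boundary of a boundary vanishes
  expect_true(all(abs(B1) <= 1L))
  expect_equal(colSums(B1), rep(0L, 3))        # each column one +1, one -1

  # empty edge set: zero columns
  lone <- simplicial_complex(4)
  expect_equal(dim(boundary_matrix(lone, 1)), c(4L, 0L))
  expect_error(boundary_matrix(lone, 2), "unavailable")
})

test_that("boundary of boundary is exactly zero on random filled complexes", {
  set.seed(19)
  for (rep in 1:10) {
    sc <- build_rips(random_cloud(15, 2, 4), periodic_box(4, 2),
                     r = 1.2, max_dim = 2)
    if (is.null(sc$triangles)) next
    B1 <- boundary_matrix(sc, 1)
    B2 <- boundary_matrix(sc, 2)
    expect_true(all(B1 %*% B2 == 0L))
  }
})

test_that("order-0 Hodge Laplacian is the graph Laplacian", {
  fx <- make_fixture("isolated_edge")
  L0 <- hodge_laplacian(fx$complex, 0)
  expect_equal(L0, matrix(c(1, -1, -1, 1), 2))
  expect_equal(sort(eigen(L0, symmetric = TRUE)$values), c(0, 2))

  tri <- make_fixture("triangle")
  lam <- eigen(hodge_laplacian(tri$complex, 0), symmetric = TRUE)$values
  expect_equal(sort(lam), c(0, 3, 3))

  # m isolated vertices: zero matrix
  expect_equal(hodge_laplacian(simplicial_complex(5), 0), matrix(0L, 5, 5))

  # degree-minus-adjacency identity on a random complex
  set.seed(23)
  sc <- build_rips(random_cloud(20, 2, 5), periodic_box(5, 2), r = 1.3)
  L0 <- hodge_laplacian(sc, 0)
  A <- matrix(0, 20, 20); A[sc$edges] <- 1; A <- A + t(A)
  expect_equal(unname(L0), diag(degree_sequence(sc)) - A)
})

test_that("Hodge Laplacians are symmetric positive semi-definite", {
  set.seed(29)
  for (rep in 1:5) {
    sc <- build_rips(random_cloud(15, 2, 4), periodic_box(4, 2),
                     r = 1.2, max_dim = 2)
    for (n in 0:1) {
      L <- hodge_laplacian(sc, n)
      if (nrow(L) == 0) next
      expect_equal(L, t(L))
      expect_gte(min(eigen(L, symmetric = TRUE, only.values = TRUE)$values), -1e-9)
    }
  }
})

test_that("spectral entropy reproduces hand-evaluated and limiting values", {
  # single edge, beta = 1: Z = 1 + e^-2, <lambda> = 2 e^-2 / Z, S = 0.365334
  fx <- make_fixture("isolated_edge")
  expect_equal(spectral_entropy(hodge_laplacian(fx$complex, 0), 1),
               fx$expected$S0_beta1, tolerance = 1e-6)

  # m disconnected vertices: uniform density matrix, S = log m at any beta
  expect_equal(spectral_entropy(hodge_laplacian(simplicial_complex(7), 0), 2.5),
               log(7))

  # beta -> 0: uniform over all simplices
  tri <- make_fixture("triangle")
  expect_equal(spectral_entropy(hodge_laplacian(tri$complex, 0), 1e-9),
               log(3), tolerance = 1e-6)

  # beta -> infinity: log of the kernel dimension (the Betti number)
  tc <- make_fixture("two_components")
  expect_equal(spectral_entropy(hodge_laplacian(tc$complex, 0), 50),
               tc$expected$S0_large_beta, tolerance = 1e-6)

  expect_error(spectral_entropy(c(0, 1), beta = 0), "invalid parameter")
  expect_error(spectral_entropy(c(0, 1), beta = -1), "invalid parameter")
  expect_warning(s <- spectral_entropy(matrix(0, 0, 0), 1), "empty")
  expect_equal(s, 0)
})

test_that("partition-function entropy agrees with the density-matrix trace form", {
  set.seed(43)
  for (rep in 1:20) {
    lam <- sort(c(0, rexp(sample(3:12, 1), rate = 0.5)))
    beta <- runif(1, 0.1, 5)
    expect_equal(spectral_entropy(lam, beta),
                 bf_entropy_density_matrix(lam, beta), tolerance = 1e-8)
  }
})

test_that("entropy is bounded by log of the simplex count", {
  set.seed(47)
  for (rep in 1:10) {
    sc <- build_rips(random_cloud(15, 2, 4), periodic_box(4, 2), r = 1.2)
    for (n in 0:1) {
      L <- hodge_laplacian(sc, n)
      if (nrow(L) == 0) next
      S <- spectral_entropy(L, 1)
      expect_gte(S, 0)
      expect_lte(S, log(nrow(L)) + 1e-10)
    }
  }
})

test_that("Betti numbers and Euler characteristic match on the fixtures", {
  for (nm in fixture_names()) {
    fx <- make_fixture(nm)
    ts <- betti_numbers(fx$complex)
    expect_equal(ts$betti, fx$expected$betti, info = nm)
    expect_equal(ts$euler, fx$expected$euler, info = nm)
  }
})

test_that("kernel dimension of the Hodge Laplacian equals the Betti number", {
  set.seed(53)
  for (rep in 1:20) {
    sc <- build_rips(random_cloud(sample(5:20, 1), 2, 4), periodic_box(4, 2),
                     r = runif(1, 0.8, 1.6), max_dim = sample(1:2, 1))
    ts <- betti_numbers(sc)
    for (n in 0:1) {
      L <- hodge_laplacian(sc, n)
      if (nrow(L) == 0) {
        expect_equal(unname(ts$betti[n + 1]), 0)
        next
      }
      lam <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
      expect_equal(sum(abs(lam) < 1e-8), unname(ts$betti[n + 1]))
    }
  }
})

test_that("graph Betti numbers agree with the igraph circuit-rank oracle", {
  skip_if_not_installed("igraph")
  set.seed(59)
  for (rep in 1:10) {
    sc <- build_rips(random_cloud(18, 2, 5), periodic_box(5, 2), r = 1.2)
    ts <- betti_numbers(sc)
    expect_equal(ts$betti, bf_betti_graph(18, sc$edges))
  }
})

test_that("hodge_spectrum bundles a consistent record", {
  fx <- make_fixture("isolated_edge")
  hs <- hodge_spectrum(fx$complex, 0, beta = 1)
  expect_equal(hs$Z, 1 + exp(-2))
  expect_equal(hs$mean_lambda, 2 * exp(-2) / (1 + exp(-2)))
  expect_equal(hs$entropy, hs$beta * hs$mean_lambda + log(hs$Z))
})
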