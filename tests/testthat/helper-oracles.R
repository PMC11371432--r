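# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's vectorised code paths.

# minimum-image distance by explicit enumeration of the 3^d nearest images
bf_min_image <- function(p, q, L) {
  d <- length(p)
  shifts <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), d))) * L
  min(apply(shifts, 1L, function(s) sqrt(sum((p - q + s)^2))))
}

bf_pairwise <- function(pos, L) {
  n <- nrow(pos)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    D[i, j] <- bf_min_image(pos[i, ], pos[j, ], L)
  D
}

# direct evaluation of the weighted edge curvature: lower faces are the two
# endpoints; parallel edges share exactly one vertex; each contributes
# w_gamma / sqrt(w_a w_abar), scaled by w_a
bf_edge_frc <- function(edges, edge_dist, n, wv, we) {
  E <- nrow(edges)
  out <- numeric(E)
  for (a in seq_len(E)) {
    u <- edges[a, 1L]; v <- edges[a, 2L]
    lower <- (wv[u] + wv[v]) / we[a]
    par <- 0
    for (b in seq_len(E)) {
      if (b == a) next
      shared <- intersect(edges[a, ], edges[b, ])
      if (length(shared) == 1L)
        par <- par + wv[shared] / sqrt(we[a] * we[b])
    }
    out[a] <- we[a] * (lower - par)
  }
  out
}

# von Neumann entropy through the density matrix itself: rho = expm(-beta L)/Z,
# S = -sum p log p over rho's eigenvalues (independent of the partition-
# function route used by the package)
bf_entropy_density_matrix <- function(lambda, beta) {
  p <- exp(-beta * lambda)
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log(p))
}

# graph Betti numbers via igraph: components and circuit rank
bf_betti_graph <- function(n, edges) {
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(edges) > 0L) g <- igraph::add_edges(g, t(edges))
  c0 <- igraph::components(g)$no
  c(b0 = c0, b1 = nrow(edges) - n + c0)
}

# all graphs on n labelled vertices as edge subsets of K_n
all_graphs <- function(n) {
  pairs <- t(combn(n, 2L))
  m <- nrow(pairs)
  lapply(seq_len(2^m) - 1L, function(code) {
    sel <- as.logical(bitwAnd(code, 2^(seq_len(m) - 1L)))
    pairs[sel, , drop = FALSE]
  })
}

# build a simplicial_complex from an explicit edge list with unit distances
graph_complex <- function(n, edges, dist = rep(1, nrow(edges))) {
  simplicial_complex(n, if (nrow(edges)) edges else NULL, dist, r = 1)
}

random_cloud <- function(n, d, L) matrix(runif(n * d, 0, L), n, d)
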