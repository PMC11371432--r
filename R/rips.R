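#' Construct a simplicial complex explicitly
#'
#' Low-level constructor used by [build_rips()] and by the hand-checkable
#' fixtures. Edges are stored as an `E x 2` integer matrix with `i < j` in
#' lexicographic order; triangles (2-simplices), if any, as a `T x 3` matrix
#' with `i < j < k`.
#'
#' @param n_vertices Number of vertices.
#' @param edges `E x 2` integer matrix of vertex index pairs (1-based, i < j),
#'   or `NULL` for an edgeless complex.
#' @param edge_dist Numeric vector of the pairwise distances `r_ij` backing
#'   each edge, aligned with `edges`.
#' @param r Filtration radius the complex was built at.
#' @param triangles Optional `T x 3` integer matrix of filled triangles.
#' @param max_dim Maximal simplex dimension kept, 1 or 2.
#'
#' @return An object of class `simplicial_complex`.
#' @export
simplicial_complex <- function(n_vertices, edges = NULL, edge_dist = NULL,
                               r = 1, triangles = NULL, max_dim = 1L) {
  n_vertices <- as.integer(n_vertices)
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- matrix(integer(0), 0L, 2L)
    edge_dist <- numeric(0)
  } else {
    edges <- matrix(as.integer(edges), ncol = 2L)
    edge_dist <- as.numeric(edge_dist)
  }
  if (!is.null(triangles) && NROW(triangles) > 0L) {
    triangles <- matrix(as.integer(triangles), ncol = 3L)
    max_dim <- 2L
  } else {
    triangles <- NULL
  }
  sc <- structure(
    list(n_vertices = n_vertices, edges = edges, edge_dist = edge_dist,
         triangles = triangles, r = as.numeric(r), max_dim = as.integer(max_dim)),
    class = "simplicial_complex")
  .validate_sc(sc)
  sc
}

.validate_sc <- function(sc) {
  e <- sc$edges
  if (nrow(e) > 0L) {
    if (any(e[, 1L] >= e[, 2L])) stop("edges must satisfy i < j", call. = FALSE)
    if (any(e < 1L) || any(e > sc$n_vertices)) stop("edge index out of range", call. = FALSE)
    if (length(sc$edge_dist) != nrow(e))
      stop("`edge_dist` must align with `edges`", call. = FALSE)
    if (any(sc$edge_dist > sc$r + 1e-12))
      stop("edge distance exceeds filtration radius", call. = FALSE)
    key <- .edge_key(e[, 1L], e[, 2L], sc$n_vertices)
    if (anyDuplicated(key)) stop("duplicate edges", call. = FALSE)
  }
  tr <- sc$triangles
  if (!is.null(tr)) {
    if (any(tr[, 1L] >= tr[, 2L] | tr[, 2L] >= tr[, 3L]))
      stop("triangles must satisfy i < j < k", call. = FALSE)
    key <- .edge_key(e[, 1L], e[, 2L], sc$n_vertices)
    need <- c(.edge_key(tr[, 1L], tr[, 2L], sc$n_vertices),
              .edge_key(tr[, 1L], tr[, 3L], sc$n_vertices),
              .edge_key(tr[, 2L], tr[, 3L], sc$n_vertices))
    if (!all(need %in% key))
      stop("triangle present without all three supporting edges", call. = FALSE)
  }
  invisible(sc)
}

# unique integer key for an (i, j) pair, i < j <= n
.edge_key <- function(i, j, n) (as.numeric(i) - 1) * n + as.numeric(j)

#' Vietoris-Rips complex of a point cloud in a periodic box
#'
#' Builds the Rips complex at filtration radius `r`: every pair of points at
#' minimum-image distance `<= r` (inclusive) becomes an edge, and with
#' `max_dim = 2` every triple whose three pairwise distances are all `<= r`
#' becomes a filled triangle. Simplices are ordered lexicographically so that
#' boundary-matrix orientations are reproducible.
#'
#' In the flocking model the complex is built over the entire swarm at
#' `r = rmax`; the annular interaction region only restricts which vertices
#' are *candidate neighbours*, not complex membership. Set `exclude_below`
#' to a positive radius to drop short edges from the complex itself
#' (sensitivity analysis only; off by default).
#'
#' @param positions `N x d` coordinate matrix.
#' @param box A [periodic_box()].
#' @param r Filtration radius, positive.
#' @param max_dim Maximal simplex dimension, 1 (default) or 2.
#' @param exclude_below Drop edges with distance strictly below this value
#'   (default 0, i.e. keep all).
#'
#' @return A `simplicial_complex`.
#' @examples
#' b <- periodic_box(10, 2)
#' pts <- rbind(c(0, 0), c(1, 0), c(0, 1))
#' build_rips(pts, b, r = 1.5)
#' @export
build_rips <- function(positions, box, r, max_dim = 1L, exclude_below = 0) {
  .check_box(box)
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0)
    stop("invalid parameter: `r` must be a single positive number", call. = FALSE)
  if (!(max_dim %in% c(1L, 2L))) stop("`max_dim` must be 1 or 2", call. = FALSE)
  positions <- .as_positions(positions, box$d)
  n <- nrow(positions)
  D <- .pairwise_sq(positions, box$L, sqrt_out = TRUE)
  sel <- which(upper.tri(D) & D <= r & (exclude_below <= 0 | D >= exclude_below))
  i <- ((sel - 1L) %% n) + 1L   # row index (< col for upper triangle)
  j <- ((sel - 1L) %/% n) + 1L
  ord <- order(i, j)
  i <- i[ord]; j <- j[ord]
  edges <- cbind(i, j, deparse.level = 0)
  edge_dist <- D[cbind(i, j)]
  triangles <- NULL
  if (max_dim == 2L && nrow(edges) >= 3L) {
    adj <- matrix(FALSE, n, n)
    adj[edges] <- TRUE
    adj <- adj | t(adj)
    tri <- list()
    for (e in seq_len(nrow(edges))) {
      a <- edges[e, 1L]; b <- edges[e, 2L]
      common <- which(adj[a, ] & adj[b, ])
      common <- common[common > b]    # enumerate each triangle once, a < b < c
      if (length(common))
        tri[[length(tri) + 1L]] <- cbind(a, b, common, deparse.level = 0)
    }
    if (length(tri)) {
      triangles <- do.call(rbind, tri)
      triangles <- triangles[order(triangles[, 1L], triangles[, 2L], triangles[, 3L]), ,
                             drop = FALSE]
    }
  }
  sc <- structure(
    list(n_vertices = n, edges = edges, edge_dist = edge_dist,
         triangles = triangles, r = as.numeric(r), max_dim = as.integer(max_dim)),
    class = "simplicial_complex")
  .validate_sc(sc)
  sc
}

#' @export
print.simplicial_complex <- function(x, ...) {
  nt <- if (is.null(x$triangles)) 0L else nrow(x$triangles)
  cat(sprintf("Simplicial complex: %d vertices, %d edges%s (r = %g, max_dim = %d)\n",
              x$n_vertices, nrow(x$edges),
              if (x$max_dim == 2L) sprintf(", %d triangles", nt) else "",
              x$r, x$max_dim))
  invisible(x)
}

#' Vertex degree sequence of a complex
#'
#' @param sc A `simplicial_complex`.
#' @return Integer vector: number of incident edges per vertex.
#' @export
degree_sequence <- function(sc) {
  stopifnot(inherits(sc, "simplicial_complex"))
  tabulate(c(sc$edges[, 1L], sc$edges[, 2L]), sc$n_vertices)
}

#' Vertex and edge weights of the swarm complex
#'
#' The weighting scheme couples connectivity and proximity: each vertex
#' carries `w_i = 1 + degree(i)`, and each edge carries
#' `w_ij = (w_i + w_j) / (1 + r_ij)`, so edges between highly connected,
#' nearby agents are heaviest.
#'
#' @param sc A `simplicial_complex`.
#' @return An object of class `weight_assignment`: list with `vertex`
#'   (length `n_vertices`) and `edge` (aligned with `sc$edges`).
#' @export
assign_weights <- function(sc) {
  stopifnot(inherits(sc, "simplicial_complex"))
  w <- 1 + degree_sequence(sc)
  we <- (w[sc$edges[, 1L]] + w[sc$edges[, 2L]]) / (1 + sc$edge_dist)
  structure(list(vertex = as.numeric(w), edge = as.numeric(we)),
            class = "weight_assignment")
}

#' @export
print.weight_assignment <- function(x, ...) {
  cat(sprintf("Weight assignment: %d vertex weights (range %g-%g), %d edge weights\n",
              length(x$vertex), min(x$vertex), max(x$vertex), length(x$edge)))
  invisible(x)
}

# accumulate `values` into `n` bins indexed by `index` (sparse sum)
.accumulate <- function(values, index, n) {
  out <- numeric(n)
  if (length(values)) {
    rs <- rowsum(values, index)
    out[as.integer(rownames(rs))] <- rs
  }
  out
}
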