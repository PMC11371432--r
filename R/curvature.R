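#' Combinatorial Forman-Ricci curvature of edges
#'
#' For an unweighted graph (no filled triangles) the Forman-Ricci curvature
#' of an edge (u, v) is `4 - deg(u) - deg(v)`: the two endpoint faces plus
#' the two "+1" contributions, minus one for every other edge sharing an
#' endpoint. Strongly negative edges sit between hubs and act as information
#' funnels.
#'
#' @param sc A `simplicial_complex` with `max_dim = 1`.
#' @return Numeric vector of curvatures aligned with `sc$edges` (exact
#'   integers stored as doubles).
#' @export
edge_frc_combinatorial <- function(sc) {
  stopifnot(inherits(sc, "simplicial_complex"))
  if (!is.null(sc$triangles))
    stop("unsupported: combinatorial edge curvature is defined for the graph case only (no triangles)",
         call. = FALSE)
  deg <- degree_sequence(sc)
  4 - deg[sc$edges[, 1L]] - deg[sc$edges[, 2L]]
}

#' Weighted Forman-Ricci curvature of edges
#'
#' Curvature of edge `a = (u, v)` on a weighted complex restricted to
#' dimension <= 1:
#' \deqn{R(a) = w_a \left( \sum_{\gamma < a} \frac{w_\gamma}{w_a}
#'   - \sum_{a' \parallel a} \frac{w_\gamma}{\sqrt{w_a w_{a'}}} \right)}
#' where the first sum runs over the two endpoint vertices and the second
#' over edges `a'` sharing exactly one vertex `gamma` with `a`. With all
#' weights 1 this reduces to the combinatorial `4 - deg(u) - deg(v)`.
#' Filled triangles, if present in the complex, are deliberately not fed
#' into edge curvature: the dynamics uses the dimension-1 reduction.
#'
#' @param sc A `simplicial_complex`.
#' @param weights A `weight_assignment` aligned with `sc` (defaults to
#'   [assign_weights()] of `sc`).
#' @return Numeric vector of curvatures aligned with `sc$edges`.
#' @export
edge_frc_weighted <- function(sc, weights = assign_weights(sc)) {
  stopifnot(inherits(sc, "simplicial_complex"))
  w <- weights$vertex
  we <- weights$edge
  if (length(w) != sc$n_vertices || length(we) != nrow(sc$edges))
    stop("invalid input: weights do not align with the complex", call. = FALSE)
  if (nrow(sc$edges) == 0L) return(numeric(0))
  i <- sc$edges[, 1L]; j <- sc$edges[, 2L]
  # Closed form of the parallel sum: with S_i = sum over edges at i of
  # 1/sqrt(w_e), R_e = 2 (w_i + w_j) - sqrt(w_e) (w_i S_i + w_j S_j).
  inv_sqrt <- 1 / sqrt(we)
  S <- .accumulate(c(inv_sqrt, inv_sqrt), c(i, j), sc$n_vertices)
  2 * (w[i] + w[j]) - sqrt(we) * (w[i] * S[i] + w[j] * S[j])
}

#' Vertex Forman-Ricci curvature
#'
#' `R_i` is the sum of the curvatures of all edges incident to vertex i;
#' isolated vertices get 0. Summing over vertices double-counts every edge,
#' so `sum(R_i) = 2 * sum(R_e)` always.
#'
#' @param sc A `simplicial_complex`.
#' @param edge_frc Per-edge curvatures aligned with `sc$edges`.
#' @return Numeric vector of length `sc$n_vertices`.
#' @export
vertex_frc <- function(sc, edge_frc) {
  stopifnot(inherits(sc, "simplicial_complex"))
  if (length(edge_frc) != nrow(sc$edges))
    stop("invalid input: `edge_frc` does not align with the edge list", call. = FALSE)
  .accumulate(c(edge_frc, edge_frc), c(sc$edges[, 1L], sc$edges[, 2L]), sc$n_vertices)
}

#' Full curvature report for a complex
#'
#' Convenience wrapper computing weighted edge curvatures, vertex curvatures
#' and their mean in one pass.
#'
#' @inheritParams edge_frc_weighted
#' @return An object of class `curvature_report`: list with `edge_frc`,
#'   `vertex_frc`, `mean_vertex_frc`.
#' @export
curvature_report <- function(sc, weights = assign_weights(sc)) {
  re <- edge_frc_weighted(sc, weights)
  ri <- vertex_frc(sc, re)
  structure(list(edge_frc = re, vertex_frc = ri, mean_vertex_frc = mean(ri)),
            class = "curvature_report")
}

#' @export
print.curvature_report <- function(x, ...) {
  cat(sprintf("Curvature report: %d edges, %d vertices, mean vertex FRC = %.4f\n",
              length(x$edge_frc), length(x$vertex_frc), x$mean_vertex_frc))
  invisible(x)
}
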