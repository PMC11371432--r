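#' Hand-checkable fixture complexes
#'
#' Small complexes whose curvatures, Betti numbers and entropies are known
#' in closed form, used throughout the test suite and available for
#' exploration. All edges have unit length. Available fixtures:
#'
#' * `isolated_edge` -- two vertices, one edge.
#' * `path3` -- path a-b-c.
#' * `star3` -- one centre, three leaves.
#' * `triangle` -- unfilled 3-cycle.
#' * `filled_triangle` -- 3-cycle with its 2-simplex.
#' * `two_components` -- two disjoint edges.
#'
#' @param name Fixture name (see above).
#' @return An object of class `fixture_complex`: list with `name`,
#'   `complex` (a `simplicial_complex`) and `expected`, a list of known
#'   values (combinatorial/weighted edge curvatures, vertex curvatures,
#'   Betti numbers, Euler characteristic, and entropy limits where simple).
#' @examples
#' fx <- make_fixture("isolated_edge")
#' edge_frc_weighted(fx$complex)   # 4, as expected
#' @export
make_fixture <- function(name) {
  e <- function(...) matrix(c(...), ncol = 2L, byrow = TRUE)
  fx <- switch(name,
    isolated_edge = list(
      complex = simplicial_complex(2L, e(1, 2), 1),
      expected = list(
        comb_edge_frc = 2,                 # 4 - 1 - 1
        weighted_edge_frc = 4,             # w_u + w_v with w = 2, parallel sum empty
        vertex_frc = c(4, 4),
        betti = c(b0 = 1L, b1 = 0L), euler = 1L,
        l0_eigenvalues = c(2, 0),
        S0_beta1 = 0.3653338)),            # beta<lambda> + log Z at beta = 1
    path3 = list(
      complex = simplicial_complex(3L, e(1, 2, 2, 3), c(1, 1)),
      expected = list(
        comb_edge_frc = c(1, 1),           # 4 - 1 - 2
        weighted_edge_frc = c(2, 2),       # (2+3) - 2.5 * 3/2.5
        vertex_frc = c(2, 4, 2),
        betti = c(b0 = 1L, b1 = 0L), euler = 1L)),
    star3 = list(
      complex = simplicial_complex(4L, e(1, 2, 1, 3, 1, 4), c(1, 1, 1)),
      expected = list(
        comb_edge_frc = c(0, 0, 0),        # 4 - 3 - 1
        betti = c(b0 = 1L, b1 = 0L), euler = 1L)),
    triangle = list(
      complex = simplicial_complex(3L, e(1, 2, 1, 3, 2, 3), c(1, 1, 1)),
      expected = list(
        comb_edge_frc = c(0, 0, 0),        # 4 - 2 - 2
        betti = c(b0 = 1L, b1 = 1L), euler = 0L,
        l0_eigenvalues = c(3, 3, 0))),
    filled_triangle = list(
      complex = simplicial_complex(3L, e(1, 2, 1, 3, 2, 3), c(1, 1, 1),
                                   triangles = matrix(c(1L, 2L, 3L), 1L)),
      expected = list(
        betti = c(b0 = 1L, b1 = 0L, b2 = 0L), euler = 1L)),
    two_components = list(
      complex = simplicial_complex(4L, e(1, 2, 3, 4), c(1, 1)),
      expected = list(
        comb_edge_frc = c(2, 2),
        betti = c(b0 = 2L, b1 = 0L), euler = 2L,
        S0_large_beta = log(2))),          # kernel dimension = number of components
    stop("unknown fixture: ", name, call. = FALSE)
  )
  structure(c(list(name = name), fx), class = "fixture_complex")
}

#' @export
print.fixture_complex <- function(x, ...) {
  cat(sprintf("Fixture '%s':\n", x$name))
  print(x$complex)
  invisible(x)
}

#' Names of all available fixtures
#' @return Character vector.
#' @export
fixture_names <- function() {
  c("isolated_edge", "path3", "star3", "triangle", "filled_triangle",
    "two_components")
}
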