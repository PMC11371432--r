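#' Periodic simulation box
#'
#' A cubic box of edge length `L` in dimension `d` with periodic (toroidal)
#' boundary conditions. All distances in the package are minimum-image
#' distances measured on this torus.
#'
#' @param L Edge length of the box (length units). Must be positive.
#' @param d Spatial dimension, 2 or 3.
#'
#' @return An object of class `periodic_box` with fields `L` and `d`.
#' @examples
#' b <- periodic_box(10, 2)
#' min_image_distance(c(0.5, 0), c(9.5, 0), b) # wraps around: 1
#' @export
periodic_box <- function(L, d) {
  if (!is.numeric(L) || length(L) != 1L || !is.finite(L) || L <= 0)
    stop("`L` must be a single positive finite number", call. = FALSE)
  if (!is.numeric(d) || length(d) != 1L || !(d %in% c(2, 3)))
    stop("`d` must be 2 or 3", call. = FALSE)
  structure(list(L = as.numeric(L), d = as.integer(d)), class = "periodic_box")
}

#' @export
print.periodic_box <- function(x, ...) {
  cat(sprintf("Periodic box: L = %g, d = %d\n", x$L, x$d))
  invisible(x)
}

.check_box <- function(box) {
  if (!inherits(box, "periodic_box")) stop("`box` must be a periodic_box", call. = FALSE)
  box
}

#' Minimum-image distance between two points
#'
#' Euclidean distance on the torus: per axis the displacement is reduced to
#' its nearest periodic image, `delta - L * round(delta / L)`, so the result
#' never exceeds `(L/2) * sqrt(d)`.
#'
#' @param p,q Numeric coordinate vectors of length `box$d`.
#' @param box A [periodic_box()].
#'
#' @return A single non-negative number.
#' @export
min_image_distance <- function(p, q, box) {
  .check_box(box)
  p <- as.numeric(p); q <- as.numeric(q)
  if (length(p) != box$d || length(q) != box$d)
    stop("`p` and `q` must have length box$d", call. = FALSE)
  if (!all(is.finite(p)) || !all(is.finite(q)))
    stop("coordinates must be finite", call. = FALSE)
  delta <- p - q
  delta <- delta - box$L * round(delta / box$L)
  sqrt(sum(delta^2))
}

#' Minimum-image pairwise distance matrix
#'
#' @param positions Numeric matrix, one row per point, `box$d` columns.
#' @param box A [periodic_box()].
#'
#' @return A symmetric `N x N` matrix with zero diagonal.
#' @export
pairwise_distances <- function(positions, box) {
  .check_box(box)
  positions <- .as_positions(positions, box$d)
  .pairwise_sq(positions, box$L, sqrt_out = TRUE)
}

# shared kernel: accumulates squared per-axis minimum-image displacements
.pairwise_sq <- function(positions, L, sqrt_out = TRUE) {
  n <- nrow(positions)
  M <- matrix(0, n, n)
  for (a in seq_len(ncol(positions))) {
    delta <- outer(positions[, a], positions[, a], "-")
    delta <- delta - L * round(delta / L)
    M <- M + delta * delta
  }
  if (sqrt_out) sqrt(M) else M
}

.as_positions <- function(positions, d) {
  positions <- as.matrix(positions)
  if (nrow(positions) < 1L) stop("`positions` must contain at least one point", call. = FALSE)
  if (ncol(positions) != d)
    stop(sprintf("`positions` must have %d columns", d), call. = FALSE)
  if (!all(is.finite(positions))) stop("coordinates must be finite", call. = FALSE)
  storage.mode(positions) <- "double"
  positions
}

#' Random unit vectors (isotropic noise directions)
#'
#' Draws isotropically distributed unit vectors: in 2D via a uniform angle,
#' in 3D by normalising standard-normal triples. Uses R's global RNG, so
#' results are reproducible under [set.seed()].
#'
#' @param d Dimension, 2 or 3.
#' @param n Number of draws.
#'
#' @return An `n x d` matrix whose rows have Euclidean norm 1.
#' @export
random_unit_vector <- function(d, n = 1L) {
  if (!(d %in% c(2, 3))) stop("unsupported dimension: `d` must be 2 or 3", call. = FALSE)
  n <- as.integer(n)
  if (d == 2) {
    theta <- stats::runif(n, 0, 2 * pi)
    cbind(cos(theta), sin(theta))
  } else {
    g <- matrix(stats::rnorm(3L * n), n, 3L)
    g / sqrt(rowSums(g^2))
  }
}

#' Wrap positions into the primary box
#'
#' Maps every coordinate into `[0, L)`. Wrapping changes nothing observable:
#' minimum-image pairwise distances are invariant under it.
#'
#' @inheritParams pairwise_distances
#' @return A matrix of the same shape with all coordinates in `[0, L)`.
#' @export
wrap_positions <- function(positions, box) {
  .check_box(box)
  positions <- .as_positions(positions, box$d)
  positions - box$L * floor(positions / box$L)
}
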