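#' Boundary operator of a simplicial complex
#'
#' Signed incidence matrix mapping n-chains to (n-1)-chains, with simplices
#' lexicographically ordered and oriented by increasing vertex index. The
#' column of `B1` for edge (i, j), i < j, has -1 at row i and +1 at row j;
#' the column of `B2` for triangle (i, j, k) has +1 on edge (j, k), -1 on
#' (i, k) and +1 on (i, j). Consecutive boundary operators compose to zero.
#'
#' @param sc A `simplicial_complex`.
#' @param n Order of the operator, 1 or 2 (requires `max_dim = 2` for 2).
#' @return An integer matrix with rows indexed by (n-1)-simplices and
#'   columns by n-simplices.
#' @export
boundary_matrix <- function(sc, n) {
  stopifnot(inherits(sc, "simplicial_complex"))
  if (!(n %in% c(1L, 2L))) stop("`n` must be 1 or 2", call. = FALSE)
  if (n > sc$max_dim)
    stop(sprintf("unavailable order: complex has max_dim = %d", sc$max_dim), call. = FALSE)
  if (n == 1L) {
    E <- nrow(sc$edges)
    B <- matrix(0L, sc$n_vertices, E)
    if (E > 0L) {
      B[cbind(sc$edges[, 1L], seq_len(E))] <- -1L
      B[cbind(sc$edges[, 2L], seq_len(E))] <- 1L
    }
    B
  } else {
    E <- nrow(sc$edges)
    tr <- sc$triangles
    nt <- if (is.null(tr)) 0L else nrow(tr)
    B <- matrix(0L, E, nt)
    if (nt > 0L) {
      key <- .edge_key(sc$edges[, 1L], sc$edges[, 2L], sc$n_vertices)
      row_of <- function(a, b) match(.edge_key(a, b, sc$n_vertices), key)
      cols <- seq_len(nt)
      B[cbind(row_of(tr[, 2L], tr[, 3L]), cols)] <- 1L
      B[cbind(row_of(tr[, 1L], tr[, 3L]), cols)] <- -1L
      B[cbind(row_of(tr[, 1L], tr[, 2L]), cols)] <- 1L
    }
    B
  }
}

#' Hodge Laplacian on n-simplices
#'
#' `L[0] = B1 B1^T` (the graph Laplacian: degree matrix minus adjacency),
#' `L[1] = B1^T B1 + B2 B2^T` (the up-part present only when triangles are),
#' `L[2] = B2^T B2`. Always symmetric positive semi-definite; by the Hodge
#' theorem the kernel dimension equals the n-th Betti number.
#'
#' @param sc A `simplicial_complex`.
#' @param n Order, 0, 1 or 2.
#' @return A dense symmetric matrix on the n-simplices (possibly 0 x 0).
#' @export
hodge_laplacian <- function(sc, n) {
  stopifnot(inherits(sc, "simplicial_complex"))
  if (!(n %in% 0:2)) stop("`n` must be 0, 1 or 2", call. = FALSE)
  if (n == 0L) {
    B1 <- boundary_matrix(sc, 1L)
    B1 %*% t(B1)
  } else if (n == 1L) {
    E <- nrow(sc$edges)
    if (E == 0L) return(matrix(0, 0L, 0L))
    B1 <- boundary_matrix(sc, 1L)
    L <- crossprod(B1)
    if (!is.null(sc$triangles) && nrow(sc$triangles) > 0L) {
      B2 <- boundary_matrix(sc, 2L)
      L <- L + tcrossprod(B2)
    }
    L
  } else {
    if (is.null(sc$triangles) || sc$max_dim < 2L) return(matrix(0, 0L, 0L))
    B2 <- boundary_matrix(sc, 2L)
    crossprod(B2)
  }
}

#' Hodge spectral entropy
#'
#' Von Neumann entropy of the Gibbs-like density matrix
#' `rho = exp(-beta L) / Tr(exp(-beta L))` built from a Hodge Laplacian.
#' Computed in the eigenbasis via the partition function:
#' `S = beta * <lambda> + log(Z)` with `Z = sum(exp(-beta * lambda))` and
#' `<lambda>` the Gibbs-weighted mean eigenvalue. Bounded by
#' `0 <= S <= log(m)` for `m` simplices; as `beta -> 0` it tends to `log(m)`
#' and as `beta -> Inf` to the log of the kernel dimension (the Betti
#' number).
#'
#' @param x A symmetric Laplacian matrix, or a numeric vector of its
#'   eigenvalues.
#' @param beta Positive damping factor (default 1).
#' @return The entropy (a single number). An empty spectrum yields 0 with a
#'   warning.
#' @export
spectral_entropy <- function(x, beta = 1) {
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0)
    stop("invalid parameter: `beta` must be a single positive number", call. = FALSE)
  lam <- if (is.matrix(x)) {
    if (nrow(x) == 0L) numeric(0) else eigen(x, symmetric = TRUE, only.values = TRUE)$values
  } else as.numeric(x)
  if (length(lam) == 0L) {
    warning("empty spectrum: entropy defined as 0", call. = FALSE)
    return(0)
  }
  # shift by the smallest eigenvalue so the largest Gibbs weight is exactly 1
  lam0 <- min(lam)
  wts <- exp(-beta * (lam - lam0))
  Z <- sum(wts)
  mean_lambda <- sum(wts * lam) / Z
  beta * mean_lambda + log(Z) - beta * lam0
}

#' Full Hodge spectrum record for one order
#'
#' Bundles the Laplacian eigenvalues, partition function, Gibbs mean
#' eigenvalue and spectral entropy for order `n`.
#'
#' @param sc A `simplicial_complex`.
#' @param n Order, 0, 1 or 2.
#' @param beta Positive damping factor.
#' @return Object of class `hodge_spectrum`: list with `order`,
#'   `eigenvalues`, `beta`, `Z`, `mean_lambda`, `entropy`, `n_simplices`.
#' @export
hodge_spectrum <- function(sc, n, beta = 1) {
  L <- hodge_laplacian(sc, n)
  lam <- if (nrow(L) == 0L) numeric(0)
         else eigen(L, symmetric = TRUE, only.values = TRUE)$values
  if (length(lam) == 0L) {
    warning(sprintf("no %d-simplices: entropy defined as 0", n), call. = FALSE)
    ent <- 0; Z <- 0; ml <- NA_real_
  } else {
    wts <- exp(-beta * lam)
    Z <- sum(wts)
    ml <- sum(wts * lam) / Z
    ent <- spectral_entropy(lam, beta)
  }
  structure(list(order = as.integer(n), eigenvalues = lam, beta = beta,
                 Z = Z, mean_lambda = ml, entropy = ent,
                 n_simplices = length(lam)),
            class = "hodge_spectrum")
}

#' @export
print.hodge_spectrum <- function(x, ...) {
  cat(sprintf("Hodge spectrum (order %d): %d simplices, beta = %g, S = %.6f\n",
              x$order, x$n_simplices, x$beta, x$entropy))
  invisible(x)
}

.matrix_rank <- function(B) {
  if (ncol(B) == 0L || nrow(B) == 0L) return(0L)
  qr(B)$rank
}

#' Betti numbers and Euler characteristic
#'
#' Betti numbers as ranks: `beta_0 = V - rank(B1)` (connected components),
#' `beta_1 = E - rank(B1) - rank(B2)` (independent loops), and with filled
#' triangles `beta_2 = T - rank(B2)`. The Euler characteristic is computed
#' both as the alternating sum of simplex counts and of Betti numbers; the
#' two are verified to agree.
#'
#' @param sc A `simplicial_complex`.
#' @return Object of class `topology_summary`: list with `betti` (named
#'   vector) and `euler`.
#' @export
betti_numbers <- function(sc) {
  stopifnot(inherits(sc, "simplicial_complex"))
  V <- sc$n_vertices
  E <- nrow(sc$edges)
  nt <- if (is.null(sc$triangles)) 0L else nrow(sc$triangles)
  r1 <- if (E > 0L) .matrix_rank(boundary_matrix(sc, 1L)) else 0L
  r2 <- if (nt > 0L) .matrix_rank(boundary_matrix(sc, 2L)) else 0L
  b0 <- V - r1
  b1 <- E - r1 - r2
  betti <- c(b0 = b0, b1 = b1)
  if (sc$max_dim == 2L) betti <- c(betti, b2 = nt - r2)
  chi_counts <- V - E + nt
  chi_betti <- sum(betti * c(1, -1, 1)[seq_along(betti)])
  if (chi_counts != chi_betti)
    stop("internal error: Euler characteristic mismatch between simplex counts and Betti numbers")
  structure(list(betti = betti, euler = chi_counts), class = "topology_summary")
}

#' @export
print.topology_summary <- function(x, ...) {
  cat(sprintf("Topology: %s, Euler characteristic = %d\n",
              paste(names(x$betti), x$betti, sep = " = ", collapse = ", "),
              x$euler))
  invisible(x)
}
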