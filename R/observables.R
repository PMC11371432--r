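#' Polar order parameter
#'
#' Norm of the mean heading unit vector,
#' `phi_v = || sum_i v_i / ||v_i|| || / N`: 1 for perfect alignment, of
#' order `N^(-1/2)` for isotropic headings. Invariant under global rotation
#' of all velocities.
#'
#' @param velocities `N x d` velocity matrix with no zero rows.
#' @return A number in `[0, 1]`.
#' @export
order_parameter <- function(velocities) {
  velocities <- as.matrix(velocities)
  speeds <- sqrt(rowSums(velocities^2))
  if (any(speeds < 1e-12))
    stop("invalid state: zero-speed agent in order parameter", call. = FALSE)
  sqrt(sum(colSums(velocities / speeds)^2)) / nrow(velocities)
}

# shell edges covering (0, L/2]
.rdf_breaks <- function(L, delta_r) {
  breaks <- seq(0, L / 2, by = delta_r)
  if (breaks[length(breaks)] < L / 2) breaks <- c(breaks, L / 2)
  breaks
}

# histogram of i<j distances over the shells (each unordered pair once)
.rdf_counts <- function(dvec, breaks) {
  dvec <- dvec[dvec <= breaks[length(breaks)]]
  bin <- findInterval(dvec, breaks, rightmost.closed = TRUE, left.open = TRUE)
  tabulate(bin, length(breaks) - 1L)
}

# g = ordered-pair count per agent / (rho * exact shell volume)
.rdf_normalize <- function(counts, breaks, n_snapshots, N, rho, d) {
  lo <- breaks[-length(breaks)]
  hi <- breaks[-1L]
  vol <- if (d == 2) pi * (hi^2 - lo^2) else (4 / 3) * pi * (hi^3 - lo^3)
  g <- 2 * counts / (n_snapshots * N * rho * vol)
  structure(data.frame(r_lo = lo, r_hi = hi, g = g),
            class = c("radial_distribution", "data.frame"))
}

#' Radial distribution function
#'
#' Shell-normalised pair density `g(r)`: the volume is divided into shells
#' of width `delta_r`; the number of minimum-image pairs falling in each
#' shell, per agent, is divided by `rho` times the exact shell volume
#' (annulus area `pi (r_hi^2 - r_lo^2)` in 2D, `4/3 pi (r_hi^3 - r_lo^3)`
#' in 3D, from the bin edges rather than a midpoint approximation). For a
#' uniform ideal gas `g(r) = 1`; peaks indicate clustering. Distances are
#' capped at `L/2`, the validity bound of the minimum-image convention.
#'
#' @param positions `N x d` coordinate matrix.
#' @param box A [periodic_box()].
#' @param delta_r Shell width (positive).
#' @param rho Number density used for normalisation; defaults to
#'   `N / L^d`.
#' @return A data frame (class `radial_distribution`) with columns `r_lo`,
#'   `r_hi`, `g`.
#' @export
radial_distribution <- function(positions, box, delta_r = 0.1, rho = NULL) {
  .check_box(box)
  if (!is.numeric(delta_r) || length(delta_r) != 1L || !is.finite(delta_r) || delta_r <= 0)
    stop("invalid parameter: `delta_r` must be a single positive number", call. = FALSE)
  positions <- .as_positions(positions, box$d)
  N <- nrow(positions)
  if (is.null(rho)) rho <- N / box$L^box$d
  D <- .pairwise_sq(positions, box$L, sqrt_out = TRUE)
  breaks <- .rdf_breaks(box$L, delta_r)
  counts <- .rdf_counts(D[upper.tri(D)], breaks)
  .rdf_normalize(counts, breaks, 1L, N, rho, box$d)
}

#' Grand mean vertex curvature over a series of reports
#'
#' Flat mean of the per-vertex Forman-Ricci curvature over all agents and
#' all recorded steps.
#'
#' @param reports A list of `curvature_report` objects (or numeric vectors
#'   of vertex curvatures), one per recorded step.
#' @return A single number.
#' @export
mean_vertex_frc <- function(reports) {
  if (length(reports) == 0L)
    stop("invalid input: empty series of curvature reports", call. = FALSE)
  vals <- unlist(lapply(reports, function(r) {
    if (inherits(r, "curvature_report")) r$vertex_frc else as.numeric(r)
  }))
  mean(vals)
}

#' Pointwise mean and standard error across sample series
#'
#' Aggregates equal-length observable series from independent runs into
#' per-step means and standard errors (`sd / sqrt(n_samples)`).
#'
#' @param series_list A list of data frames sharing a `step` column and
#'   identical numeric observable columns.
#' @return A data frame with `step` and, for every observable `x`, columns
#'   `x_mean` and `x_se`.
#' @export
aggregate_samples <- function(series_list) {
  stopifnot(is.list(series_list), length(series_list) >= 1L)
  steps <- series_list[[1L]]$step
  for (df in series_list) {
    if (nrow(df) != length(steps) || !all(df$step == steps))
      stop("invalid input: sample series have mismatched lengths or steps", call. = FALSE)
  }
  vars <- setdiff(names(series_list[[1L]]), "step")
  out <- data.frame(step = steps)
  n <- length(series_list)
  for (v in vars) {
    m <- vapply(series_list, function(df) as.numeric(df[[v]]), numeric(length(steps)))
    m <- matrix(m, nrow = length(steps))
    out[[paste0(v, "_mean")]] <- rowMeans(m)
    out[[paste0(v, "_se")]] <- apply(m, 1L, stats::sd) / sqrt(n)
  }
  out
}
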