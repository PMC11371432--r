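#' Load a simulation configuration from a file
#'
#' Reads a flat JSON (`.json`) or YAML (`.yml`/`.yaml`) key-value file and
#' builds a validated [sim_config()]. Keys not known to `sim_config()` are
#' rejected rather than silently ignored.
#'
#' @param path Path to the config file.
#' @return A `sim_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    # YAML 1.1 would resolve a bare key like `N` to a boolean; keep the
    # single-letter spellings as literal strings so `N: 50` means agent count
    yaml::read_yaml(path, handlers = list(
      "bool#yes" = function(x) if (x %in% c("y", "Y")) x else TRUE,
      "bool#no"  = function(x) if (x %in% c("n", "N")) x else FALSE))
  } else {
    tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
             error = function(e) stop("malformed config file ", path, ": ",
                                      conditionMessage(e), call. = FALSE))
  }
  if (!is.list(vals)) stop("malformed config file ", path, call. = FALSE)
  known <- setdiff(names(formals(sim_config)), "...")
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  do.call(sim_config, vals)
}

#' Run one experiment and write its outputs
#'
#' Runs [run_simulation()] and writes, under `outdir`: one observable CSV
#' per sample (`observables_sample_<s>.csv`), the cross-sample mean series
#' (`observables_mean.csv`), the radial distribution (`gr.csv`, when
#' recorded), a JSON echo of the configuration (`config.json`) and a small
#' log with seed provenance and complex-size timing (`log.txt`).
#'
#' @param cfg A `sim_config`.
#' @param outdir Output directory (created if missing).
#' @return The `ricci_run`, invisibly.
#' @export
run_experiment <- function(cfg, outdir) {
  validate_config(cfg)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(outdir, 2L) != 0L)
    stop("output directory not writable: ", outdir, call. = FALSE)
  t0 <- proc.time()[["elapsed"]]
  run <- run_simulation(cfg)
  elapsed <- proc.time()[["elapsed"]] - t0
  for (s in seq_along(run$samples)) {
    utils::write.csv(run$samples[[s]],
                     file.path(outdir, sprintf("observables_sample_%d.csv", s)),
                     row.names = FALSE)
  }
  utils::write.csv(run$mean, file.path(outdir, "observables_mean.csv"),
                   row.names = FALSE)
  if (!is.null(run$gr))
    utils::write.csv(run$gr, file.path(outdir, "gr.csv"), row.names = FALSE)
  jsonlite::write_json(unclass(cfg), file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c(
    sprintf("samples: %d (seeds %d..%d)", cfg$samples, cfg$seed,
            cfg$seed + cfg$samples - 1L),
    sprintf("steps per sample: %d", cfg$steps),
    sprintf("elapsed_seconds: %.2f", elapsed),
    sprintf("terminal_phi_v: %.6f", terminal_order(run))
  ), file.path(outdir, "log.txt"))
  invisible(run)
}

#' Parameter sweep specification
#'
#' @param param Name of the swept parameter: `"eta"`, `"k"`, `"rmin"` or
#'   `"d"`.
#' @param values Numeric vector of values to sweep over (non-empty, finite).
#' @param base A `sim_config` supplying all other parameters.
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(param, values, base) {
  if (!param %in% c("eta", "k", "rmin", "d"))
    stop("`param` must be one of eta, k, rmin, d", call. = FALSE)
  values <- as.numeric(values)
  if (length(values) == 0L || !all(is.finite(values)))
    stop("invalid sweep: `values` must be a non-empty finite vector", call. = FALSE)
  validate_config(base)
  structure(list(param = param, values = values, base = base),
            class = "sweep_spec")
}

#' Run a parameter sweep
#'
#' Runs one experiment per sweep value (for `rmin` sweeps the annulus width
#' `rmax - rmin` of the base config is preserved) and writes a summary CSV
#' of terminal-window means -- order parameter and mean vertex curvature
#' versus the swept value -- suitable for plotting order-disorder
#' transition and curvature crossover curves. A failing value is recorded
#' in the summary (`ok = FALSE`) and the sweep continues.
#'
#' @param spec A [sweep_spec()].
#' @param outdir Output directory; per-value results go to subdirectories.
#' @return Data frame summary (also written to `summary.csv`), invisibly.
#' @export
run_sweep <- function(spec, outdir) {
  stopifnot(inherits(spec, "sweep_spec"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  width <- spec$base$rmax - spec$base$rmin
  rows <- lapply(seq_along(spec$values), function(idx) {
    val <- spec$values[idx]
    cfg <- unclass(spec$base)
    cfg[[spec$param]] <- val
    if (spec$param == "rmin") cfg$rmax <- val + width
    cfg$L <- NULL
    cfg <- do.call(sim_config, cfg)
    sub <- file.path(outdir, sprintf("%s_%g", spec$param, val))
    res <- tryCatch({
      run <- run_experiment(cfg, sub)
      data.frame(param = spec$param, value = val,
                 phi_v = terminal_order(run, "phi_v"),
                 mean_R = terminal_order(run, "mean_R"),
                 ok = TRUE, error = "")
    }, error = function(e) {
      data.frame(param = spec$param, value = val, phi_v = NA_real_,
                 mean_R = NA_real_, ok = FALSE, error = conditionMessage(e))
    })
    res
  })
  summary <- do.call(rbind, rows)
  utils::write.csv(summary, file.path(outdir, "summary.csv"), row.names = FALSE)
  invisible(summary)
}

#' Read a point cloud from CSV
#'
#' One row per point, 2 or 3 coordinate columns, with or without a header.
#'
#' @param path CSV path.
#' @param header Whether the file has a header row.
#' @return A numeric matrix.
#' @export
read_point_cloud <- function(path, header = FALSE) {
  if (!file.exists(path)) stop("point-cloud file not found: ", path, call. = FALSE)
  m <- as.matrix(utils::read.csv(path, header = header))
  storage.mode(m) <- "double"
  if (!ncol(m) %in% c(2L, 3L))
    stop("point cloud must have 2 or 3 coordinate columns", call. = FALSE)
  m
}

#' Standalone topological analysis of a point cloud
#'
#' Builds the Rips complex of a static point cloud in a periodic box and
#' reports its weights, Forman-Ricci curvatures, Betti numbers, Euler
#' characteristic and Hodge spectral entropies.
#'
#' @param positions `N x d` matrix (or a CSV path, read via
#'   [read_point_cloud()]).
#' @param box A [periodic_box()]; defaults to a box enclosing the cloud
#'   with `L = max coordinate + r` (effectively non-periodic).
#' @param r Filtration radius.
#' @param max_dim Maximal simplex dimension (1 or 2).
#' @param beta Damping for the spectral entropies.
#' @return A list with `complex`, `weights`, `curvature`
#'   (`curvature_report`), `topology` (`topology_summary`), `S0`, `S1`.
#' @examples
#' cloud <- system.file("extdata", "example_cloud.csv", package = "ricciflock")
#' res <- analyze_cloud(cloud, r = 1)
#' res$topology   # two components, one loop
#' @export
analyze_cloud <- function(positions, r, box = NULL, max_dim = 1L, beta = 1) {
  if (is.character(positions)) positions <- read_point_cloud(positions)
  positions <- as.matrix(positions)
  if (is.null(box))
    box <- periodic_box(max(positions) + r + 1, ncol(positions))
  sc <- build_rips(positions, box, r, max_dim = max_dim)
  weights <- assign_weights(sc)
  list(complex = sc,
       weights = weights,
       curvature = curvature_report(sc, weights),
       topology = betti_numbers(sc),
       S0 = suppressWarnings(spectral_entropy(hodge_laplacian(sc, 0L), beta)),
       S1 = suppressWarnings(spectral_entropy(hodge_laplacian(sc, 1L), beta)))
}
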