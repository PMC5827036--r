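#' Simulation configuration
#'
#' Collects every run parameter. Diffusion `D` is given in mm^2/s as in the
#' parameter tables of the underlying model study (typical values 2.5e-6,
#' 2.5e-5, 2.5e-4 mm^2/s) and converted internally to um^2/s. `K_A` labels
#' the binding-probability level (100, 10 or 1 for probabilities 1.0, 0.1,
#' 0.01); the per-receptor affinities stored in the tissue are multiplied by
#' `K_A`/100 at run time. The simulated horizon defaults to 6 hours with
#' observables recorded at 1.5, 10, 20, 30, 45, 90, 180, 270 and 360 min.
#'
#' @param D diffusion coefficient (mm^2/s).
#' @param K_A pseudo-association constant in (0, 100\].
#' @param L_total number of ligand molecules released (typical 500-10,000).
#' @param scheme release scheme: `"slow"` (3 h) or `"fast"` (1 min).
#' @param dt time step (s). The default 0.1 s balances fidelity and runtime;
#'   at the largest studied D the per-step displacement (~7 um) can overstep
#'   receptor capture zones, so fine-grained studies may reduce `dt`.
#' @param T_end simulated horizon (s); must cover the release duration.
#' @param r_min capture radius (um); `NULL` = [default_r_min()] of the tissue.
#' @param residency_s minimum membrane residency before endocytosis (s).
#' @param seed integer seed; a run is fully reproducible given
#'   (config, tissue, seed).
#' @param record_times_min times (minutes) at which observables are recorded.
#' @param step_mode `"gaussian"` (default) or `"fixed"` step realization of
#'   the Brownian increments (see [brownian_step()]).
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(D = 2.5e-5, K_A = 100, L_total = 5000,
                              scheme = c("slow", "fast"), dt = 0.1,
                              T_end = 21600, r_min = NULL,
                              residency_s = 1200, seed = 1L,
                              record_times_min = c(1.5, 10, 20, 30, 45, 90,
                                                   180, 270, 360),
                              step_mode = c("gaussian", "fixed")) {
  scheme <- match.arg(scheme)
  step_mode <- match.arg(step_mode)
  if (dt <= 0) stop("dt must be positive")
  duration <- if (scheme == "fast") 60 else 10800
  if (T_end < duration)
    stop("T_end (", T_end, " s) must cover the ", scheme,
         " release duration (", duration, " s)")
  record_times_min <- sort(unique(record_times_min))
  if (any(record_times_min < 0) || any(record_times_min * 60 > T_end))
    stop("record times must lie in [0, T_end]")
  ka_to_probability(K_A) # validates K_A
  structure(list(D = D, K_A = K_A, L_total = as.integer(L_total),
                 scheme = scheme, dt = dt, T_end = T_end, r_min = r_min,
                 residency_s = residency_s, seed = as.integer(seed),
                 record_times_min = record_times_min, step_mode = step_mode),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(paste0("<simulation_config> D = %g mm^2/s, K_A = %g, [L] = %d, ",
                     "%s release, dt = %g s, T_end = %g min, seed = %d\n"),
              x$D, x$K_A, x$L_total, x$scheme, x$dt, x$T_end / 60, x$seed))
  invisible(x)
}

#' Run one full simulation
#'
#' Executes `ceiling(T_end/dt)` steps. Within each step, in fixed order:
#' molecules scheduled for the step are released at the vessel edge (x = 0.5
#' um, uniform random y); every free molecule, in molecule-id order, makes a
#' Brownian proposal resolved by the move rule (boundaries, then binding,
#' then membrane rejection); then every bound complex whose membrane
#' residency is complete is internalized. Sequential per-molecule binding
#' prevents two molecules claiming the same last slot in one step.
#'
#' @param config a [simulation_config()].
#' @param tissue a `tissue_domain`.
#' @return an object of class `uptake_series` with elements:
#'   `times_min` (recording grid), `tissue_saturation` (% of total slot
#'   capacity cumulatively bound + internalized), `per_cell_saturation`
#'   (matrix, time x cell, %), `receptor_occupancy` (matrix, time x
#'   receptor), `census` (data frame of molecule counts by state), and
#'   `molecules` (final per-molecule table with state codes 0 vascular,
#'   1 free, 2 bound, 3 internalized, 4 cleared and bind/internalize times).
#' @export
run_simulation <- function(config, tissue) {
  validate_tissue(tissue)
  stopifnot(inherits(config, "simulation_config"))
  D_um <- config$D * 1e6 # mm^2/s -> um^2/s
  r_min <- if (is.null(config$r_min)) default_r_min(tissue) else config$r_min

  step_len <- sqrt(2 * D_um * config$dt)
  diam <- vapply(tissue$cells, function(cl) {
    b <- polygon_ring(cl$boundary); max(dist(b))
  }, numeric(1))
  if (length(diam) && step_len >= min(diam))
    warning(sprintf("step length %.2f um exceeds the smallest cell diameter %.2f um; consider a smaller dt",
                    step_len, min(diam)))

  sched <- build_release_schedule(config$L_total, config$scheme, config$dt)
  n_steps <- ceiling(config$T_end / config$dt)
  record_steps <- as.integer(round(config$record_times_min * 60 / config$dt))
  record_steps <- pmin(record_steps, n_steps)

  rec <- tissue_receptor_table(tissue)
  rec$affinity <- rec$affinity * ka_to_probability(config$K_A)
  rec_mat <- as.matrix(rec[, c("x", "y", "affinity", "capacity", "cell")])
  polys <- tissue_cell_polygons(tissue)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  raw <- cpp_run_simulation(polys, rec_mat, tissue$width, tissue$height,
                            D_um, config$dt, n_steps,
                            sched$per_step_counts, 0.5,
                            r_min, config$residency_s, record_steps)

  caps <- tissue_cell_capacities(tissue)
  per_cell <- sweep(raw$cell_uptake, 2, caps, "/") * 100
  colnames(per_cell) <- vapply(tissue$cells, function(cl) as.character(cl$id),
                               character(1))
  tissue_sat <- rowSums(raw$cell_uptake) / sum(caps) * 100
  census <- data.frame(t_min = config$record_times_min,
                       released = raw$census[, 1], free = raw$census[, 2],
                       bound = raw$census[, 3], internalized = raw$census[, 4],
                       cleared = raw$census[, 5])

  # molecule conservation must hold exactly at every recorded time
  stopifnot(all(census$released ==
                  census$free + census$bound + census$internalized + census$cleared))

  structure(list(times_min = config$record_times_min,
                 tissue_saturation = tissue_sat,
                 per_cell_saturation = per_cell,
                 receptor_occupancy = raw$occupancy,
                 census = census,
                 molecules = raw$molecules,
                 cell_capacities = caps,
                 r_min = r_min,
                 config = config),
            class = "uptake_series")
}

#' @export
print.uptake_series <- function(x, ...) {
  cat(sprintf("<uptake_series> %d record times, %d cells; final tissue saturation %.1f%%\n",
              length(x$times_min), ncol(x$per_cell_saturation),
              x$tissue_saturation[length(x$tissue_saturation)]))
  invisible(x)
}

#' Run replicate simulations
#'
#' Runs `n` simulations whose seeds are derived deterministically from
#' `config$seed` (seed + 0, 1, ..., n-1, or an explicit `seeds` override)
#' and returns element-wise means and sample standard deviations of the
#' tissue and per-cell saturation series.
#'
#' @param config a [simulation_config()].
#' @param tissue a `tissue_domain`.
#' @param n number of replicates (>= 2).
#' @param seeds optional explicit seed vector of length `n` (e.g. identical
#'   seeds for degenerate checks).
#' @return list with `times_min`, `mean_tissue_saturation`,
#'   `sd_tissue_saturation`, `mean_per_cell` and `sd_per_cell` (matrices,
#'   time x cell), and `replicates` (list of `uptake_series`).
#' @export
run_replicates <- function(config, tissue, n = 3, seeds = NULL) {
  if (n < 2) stop("n must be at least 2")
  if (is.null(seeds)) seeds <- config$seed + seq_len(n) - 1L
  stopifnot(length(seeds) == n)
  reps <- lapply(seeds, function(s) {
    cfg <- config
    cfg$seed <- as.integer(s)
    run_simulation(cfg, tissue)
  })
  ts <- vapply(reps, function(r) r$tissue_saturation,
               numeric(length(config$record_times_min)))
  pc <- lapply(reps, function(r) r$per_cell_saturation)
  mean_pc <- Reduce(`+`, pc) / n
  sd_pc <- sqrt(Reduce(`+`, lapply(pc, function(m) (m - mean_pc)^2)) / (n - 1))
  list(times_min = config$record_times_min,
       mean_tissue_saturation = rowMeans(ts),
       sd_tissue_saturation = apply(ts, 1, stats::sd),
       mean_per_cell = mean_pc,
       sd_per_cell = sd_pc,
       replicates = reps)
}

#' Sweep a parameter grid with replicates
#'
#' Runs [run_replicates()] for every row of a parameter grid and returns a
#' flat result table. When `out_dir` is given, each grid point's summary is
#' written to a CSV named after its parameters and existing files are
#' skipped, making an interrupted sweep resumable.
#'
#' @param grid data frame with columns `D`, `K_A`, `L_total`, `scheme` (one
#'   row per grid point); [default_sweep_grid()] builds the full study grid.
#' @param tissue a `tissue_domain`.
#' @param n replicates per grid point.
#' @param base_config template [simulation_config()] supplying all other
#'   parameters (dt, T_end, seed, record times).
#' @param out_dir optional directory for per-point CSV checkpoints.
#' @return data frame with one row per (grid point, record time):
#'   parameters, `t_min`, `mean_saturation`, `sd_saturation`, and per-cell
#'   mean saturations in columns `cell_<id>`.
#' @export
sweep_simulations <- function(grid, tissue, n = 3,
                              base_config = simulation_config(),
                              out_dir = NULL) {
  stopifnot(nrow(grid) >= 1,
            all(c("D", "K_A", "L_total", "scheme") %in% names(grid)))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    tag <- sprintf("D%g_KA%g_L%d_%s", g$D, g$K_A, as.integer(g$L_total),
                   g$scheme)
    csv <- if (!is.null(out_dir)) file.path(out_dir, paste0(tag, ".csv")) else NULL
    if (!is.null(csv) && file.exists(csv))
      return(utils::read.csv(csv, check.names = FALSE))
    cfg <- unclass(base_config)
    cfg$D <- g$D; cfg$K_A <- g$K_A
    cfg$L_total <- as.integer(g$L_total); cfg$scheme <- as.character(g$scheme)
    cfg <- do.call(simulation_config, cfg) # re-validate the combination
    rep <- run_replicates(cfg, tissue, n = n)
    out <- data.frame(D = g$D, K_A = g$K_A, L_total = as.integer(g$L_total),
                      scheme = as.character(g$scheme),
                      t_min = rep$times_min,
                      mean_saturation = rep$mean_tissue_saturation,
                      sd_saturation = rep$sd_tissue_saturation,
                      check.names = FALSE)
    pc <- rep$mean_per_cell
    colnames(pc) <- paste0("cell_", colnames(pc))
    out <- cbind(out, as.data.frame(pc, check.names = FALSE))
    if (!is.null(csv)) utils::write.csv(out, csv, row.names = FALSE)
    out
  })
  do.call(rbind, rows)
}

#' The full study grid of ligand properties
#'
#' Three diffusion coefficients x three affinities x seven doses x two
#' release schemes (126 points).
#'
#' @return data frame with columns `D`, `K_A`, `L_total`, `scheme`.
#' @export
default_sweep_grid <- function() {
  expand.grid(D = c(2.5e-6, 2.5e-5, 2.5e-4), K_A = c(100, 10, 1),
              L_total = c(500, 1000, 1500, 2500, 5000, 7500, 10000),
              scheme = c("slow", "fast"), stringsAsFactors = FALSE)
}

#' Write the observables of a run to CSV files, with a manifest
#'
#' Emits `per_cell_saturation.csv` (wide per-cell table), `ligand_census.csv`
#' (counts by state per record time), `receptor_occupancy.csv` (one row per
#' record time and receptor) and a `manifest.json` sidecar holding the full
#' configuration, seed, tissue hash, package version and output file list,
#' so a run is reconstructible from its manifest.
#'
#' @param series an `uptake_series`.
#' @param dir output directory (created if needed).
#' @param tissue_path optional path of the tissue file used (hashed into the
#'   manifest).
#' @return the manifest, invisibly.
#' @export
write_series_csv <- function(series, dir, tissue_path = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pc <- data.frame(t_min = series$times_min,
                   tissue_saturation = series$tissue_saturation,
                   series$per_cell_saturation, check.names = FALSE)
  utils::write.csv(pc, file.path(dir, "per_cell_saturation.csv"),
                   row.names = FALSE)
  utils::write.csv(series$census, file.path(dir, "ligand_census.csv"),
                   row.names = FALSE)
  occ <- series$receptor_occupancy
  occ_long <- data.frame(t_min = rep(series$times_min, ncol(occ)),
                         receptor_row = rep(seq_len(ncol(occ)),
                                            each = nrow(occ)),
                         occupancy = as.vector(occ))
  utils::write.csv(occ_long, file.path(dir, "receptor_occupancy.csv"),
                   row.names = FALSE)
  manifest <- list(
    config = unclass(series$config),
    r_min = series$r_min,
    seed = series$config$seed,
    tissue_hash = if (!is.null(tissue_path)) unname(tools::md5sum(tissue_path)) else NULL,
    version = as.character(utils::packageVersion("uptakesim")),
    outputs = c("per_cell_saturation.csv", "ligand_census.csv",
                "receptor_occupancy.csv"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
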