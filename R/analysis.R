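#' Per-cell cumulative receptor saturation at a recorded time
#'
#' For each cell, 100 x (bound + internalized ligands attributed to the
#' cell) / (cell slot capacity). The capacity-weighted mean of the per-cell
#' values recomposes the tissue saturation exactly.
#'
#' @param series an `uptake_series`.
#' @param t_min a recorded time (minutes).
#' @return named numeric vector, one percentage per cell.
#' @export
per_cell_saturation <- function(series, t_min) {
  i <- match(t_min, series$times_min)
  if (is.na(i))
    stop("time ", t_min, " min was not recorded; available: ",
         paste(series$times_min, collapse = ", "))
  series$per_cell_saturation[i, ]
}

#' Per-cell saturation difference between release schemes
#'
#' `Delta B_l = B_fast,l - B_slow,l` at the final recorded time, in
#' percentage points, one value per cell. Both series must come from the
#' same tissue and matched configurations differing only in scheme.
#'
#' @param fast,slow `uptake_series` from the fast and slow release runs, or
#'   the `mean_per_cell` matrices of [run_replicates()] output.
#' @return named numeric vector of percentage-point differences.
#' @export
compare_release_schemes <- function(fast, slow) {
  pc_fast <- if (inherits(fast, "uptake_series")) fast$per_cell_saturation else fast
  pc_slow <- if (inherits(slow, "uptake_series")) slow$per_cell_saturation else slow
  if (!all(dim(pc_fast) == dim(pc_slow)) ||
      !identical(colnames(pc_fast), colnames(pc_slow)))
    stop("fast and slow series do not match (different tissue or record grid)")
  if (inherits(fast, "uptake_series") && inherits(slow, "uptake_series") &&
      !isTRUE(all.equal(fast$cell_capacities, slow$cell_capacities)))
    stop("fast and slow series were run on different tissues")
  pc_fast[nrow(pc_fast), ] - pc_slow[nrow(pc_slow), ]
}

#' Classify the spatial pattern of receptor saturation
#'
#' Splits cells into a near-vessel group (centroid x below the domain
#' midpoint) and a far group, compares the final mean saturation of the two
#' regions, and labels the tissue `near_dominant`, `far_dominant` or
#' `uniform` (region means within `similarity_pp` percentage points), with
#' degree `full` when the dominant region's mean reaches `fullness_pct` and
#' `partial` otherwise. Only the x coordinate matters, so the classification
#' is invariant to cell relabeling and to reflection of the y axis.
#'
#' @param series an `uptake_series`, or the `mean_per_cell` matrix of
#'   [run_replicates()] output.
#' @param tissue the `tissue_domain` the series was run on (>= 2 cells).
#' @param similarity_pp region means closer than this are `uniform` (pp).
#' @param fullness_pct dominant-region mean at or above this is `full` (%).
#' @return list with `near_mean`, `far_mean`, `category`, `degree` and the
#'   cell-id partition (`near_cells`, `far_cells`).
#' @export
classify_spatial_saturation <- function(series, tissue, similarity_pp = 5,
                                        fullness_pct = 95) {
  if (length(tissue$cells) < 2) stop("classification needs at least 2 cells")
  pc <- if (inherits(series, "uptake_series")) series$per_cell_saturation else series
  final <- pc[nrow(pc), ]
  ids <- vapply(tissue$cells, function(cl) as.integer(cl$id), integer(1))
  cx <- vapply(tissue$cells, function(cl) polygon_centroid(cl$boundary)[1],
               numeric(1))
  near <- ids[cx < tissue$width / 2]
  far <- setdiff(ids, near)
  if (length(near) == 0 || length(far) == 0)
    stop("all cells lie on one side of the domain midpoint")
  near_mean <- mean(final[as.character(near)])
  far_mean <- mean(final[as.character(far)])
  category <- if (abs(near_mean - far_mean) < similarity_pp) "uniform"
  else if (near_mean > far_mean) "near_dominant" else "far_dominant"
  dominant <- switch(category, uniform = max(near_mean, far_mean),
                     near_dominant = near_mean, far_dominant = far_mean)
  list(near_mean = near_mean, far_mean = far_mean, category = category,
       degree = if (dominant >= fullness_pct) "full" else "partial",
       near_cells = near, far_cells = far)
}

#' Replicate-robustness report of a sweep
#'
#' For each grid point of a sweep run with replicates, the maximum over
#' recorded times of the replicate standard deviation of tissue saturation,
#' flagged when it reaches `flag_pp` percentage points.
#'
#' @param sweep_results table from [sweep_simulations()] (which runs n >= 2
#'   replicates per point).
#' @param flag_pp flag threshold (percentage points).
#' @return data frame with one row per grid point: parameters, `max_sd` and
#'   `flagged`.
#' @export
replicate_sd_report <- function(sweep_results, flag_pp = 5) {
  key <- interaction(sweep_results$D, sweep_results$K_A,
                     sweep_results$L_total, sweep_results$scheme, drop = TRUE)
  rows <- lapply(split(sweep_results, key), function(sl) {
    data.frame(D = sl$D[1], K_A = sl$K_A[1], L_total = sl$L_total[1],
               scheme = sl$scheme[1], max_sd = max(sl$sd_saturation),
               flagged = max(sl$sd_saturation) >= flag_pp)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plot a tissue, optionally colored by per-cell saturation
#'
#' Draws the domain rectangle, cell polygons (filled by saturation when
#' given), and receptor positions. A quick visual check of tissue geometry
#' and simulation output; not a publication rendering.
#'
#' @param tissue a `tissue_domain`.
#' @param saturation optional named vector of per-cell saturations (%) used
#'   to fill cells on a white-to-red ramp.
#' @param show_receptors draw receptor positions as points.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `NULL`.
#' @export
plot_tissue <- function(tissue, saturation = NULL, show_receptors = TRUE, ...) {
  graphics::plot(NA, xlim = c(0, tissue$width), ylim = c(0, tissue$height),
                 xlab = "x (um), vessel at x = 0", ylab = "y (um)",
                 asp = 1, ...)
  graphics::rect(0, 0, tissue$width, tissue$height, border = "grey40")
  ramp <- grDevices::colorRamp(c("white", "gold", "red"))
  for (cl in tissue$cells) {
    b <- polygon_ring(cl$boundary)
    fill <- if (!is.null(saturation)) {
      v <- min(max(saturation[as.character(cl$id)] / 100, 0), 1)
      grDevices::rgb(ramp(v), maxColorValue = 255)
    } else "grey90"
    graphics::polygon(b[, 1], b[, 2], col = fill, border = "grey30")
    ctr <- polygon_centroid(cl$boundary)
    graphics::text(ctr[1], ctr[2], labels = cl$id, cex = 0.8)
    if (show_receptors)
      graphics::points(cl$receptors$x, cl$receptors$y, pch = 16, cex = 0.25,
                       col = "steelblue")
  }
  invisible(NULL)
}
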