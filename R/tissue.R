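#' Construct a tissue domain
#'
#' A tissue domain is a rectangular patch of interstitial space with the
#' capillary (ligand source) along the left boundary (`x = 0`), tissue
#' clearance along the right boundary (`x = width`), non-leaking top and
#' bottom boundaries, and a set of non-overlapping cells. Each cell is a
#' closed boundary polygon carrying membrane pseudo-receptors: coarse-grained
#' binding sites with a position on the membrane, a binding-probability
#' affinity in \[0, 1\], and a ligand capacity (number of slots).
#'
#' @param width,height domain size in micrometres.
#' @param cells list of cells, each a list with elements `id` (integer),
#'   `boundary` (n x 2 matrix of vertices, counter-clockwise, um) and
#'   `receptors` (data frame with columns `x`, `y`, `affinity`, `capacity`).
#' @param validate if `TRUE` (default), check all structural invariants.
#' @return an object of class `tissue_domain`.
#' @seealso [generate_fixture_tissue()], [read_tissue()], [validate_tissue()]
#' @export
tissue_domain <- function(width, height, cells, validate = TRUE) {
  tissue <- structure(
    list(width = as.numeric(width), height = as.numeric(height),
         units = "um", cells = cells),
    class = "tissue_domain")
  if (validate) validate_tissue(tissue)
  tissue
}

#' @export
print.tissue_domain <- function(x, ...) {
  caps <- tissue_cell_capacities(x)
  cat(sprintf("<tissue_domain> %g x %g um, %d cells, %d receptors, %d ligand slots\n",
              x$width, x$height, length(x$cells),
              nrow(tissue_receptor_table(x)), sum(caps)))
  invisible(x)
}

# ---- polygon helpers --------------------------------------------------------

polygon_ring <- function(boundary) {
  b <- as.matrix(boundary)
  n <- nrow(b)
  if (n > 1 && all(b[1, ] == b[n, ])) b <- b[-n, , drop = FALSE]
  b
}

polygon_signed_area <- function(boundary) {
  b <- polygon_ring(boundary)
  x <- b[, 1]; y <- b[, 2]
  j <- c(2:nrow(b), 1)
  sum(x * y[j] - x[j] * y) / 2
}

polygon_area <- function(boundary) abs(polygon_signed_area(boundary))

polygon_centroid <- function(boundary) {
  b <- polygon_ring(boundary)
  x <- b[, 1]; y <- b[, 2]
  j <- c(2:nrow(b), 1)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  c(sum((x + x[j]) * cr) / (6 * a), sum((y + y[j]) * cr) / (6 * a))
}

polygon_perimeter <- function(boundary) {
  b <- polygon_ring(boundary)
  j <- c(2:nrow(b), 1)
  sum(sqrt((b[j, 1] - b[, 1])^2 + (b[j, 2] - b[, 2])^2))
}

# points at given arc lengths (measured from vertex 1) along the polygon ring
polygon_arc_points <- function(boundary, s) {
  b <- polygon_ring(boundary)
  j <- c(2:nrow(b), 1)
  seg_len <- sqrt((b[j, 1] - b[, 1])^2 + (b[j, 2] - b[, 2])^2)
  cum <- c(0, cumsum(seg_len))
  total <- cum[length(cum)]
  s <- s %% total
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx[idx > nrow(b)] <- nrow(b)
  frac <- (s - cum[idx]) / seg_len[idx]
  frac[!is.finite(frac)] <- 0
  cbind(b[idx, 1] + frac * (b[j[idx], 1] - b[idx, 1]),
        b[idx, 2] + frac * (b[j[idx], 2] - b[idx, 2]))
}

# simple-polygon check: no two non-adjacent edges intersect
polygon_is_simple <- function(boundary) {
  b <- polygon_ring(boundary)
  n <- nrow(b)
  if (n < 3) return(FALSE)
  j <- c(2:n, 1)
  for (e1 in seq_len(n - 1)) {
    for (e2 in (e1 + 1):n) {
      # skip adjacent edges (sharing a vertex)
      if (e2 == e1 + 1 || (e1 == 1 && e2 == n)) next
      if (segments_intersect(b[e1, ], b[j[e1], ], b[e2, ], b[j[e2], ])) return(FALSE)
    }
  }
  TRUE
}

segments_intersect <- function(a0, a1, b0, b1) {
  o <- function(p, q, r) (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
  d1 <- o(b0, b1, a0); d2 <- o(b0, b1, a1)
  d3 <- o(a0, a1, b0); d4 <- o(a0, a1, b1)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  on_seg <- function(p, q, r) {
    min(p[1], q[1]) <= r[1] && r[1] <= max(p[1], q[1]) &&
      min(p[2], q[2]) <= r[2] && r[2] <= max(p[2], q[2])
  }
  (d1 == 0 && on_seg(b0, b1, a0)) || (d2 == 0 && on_seg(b0, b1, a1)) ||
    (d3 == 0 && on_seg(a0, a1, b0)) || (d4 == 0 && on_seg(a0, a1, b1))
}

# ---- accessors --------------------------------------------------------------

#' Flat receptor table of a tissue
#'
#' @param tissue a `tissue_domain`.
#' @return data frame with one row per receptor: `x`, `y`, `affinity`,
#'   `capacity`, `cell` (cell id) and `receptor` (index within the cell),
#'   ordered by (cell, receptor).
#' @export
tissue_receptor_table <- function(tissue) {
  out <- lapply(tissue$cells, function(cl) {
    r <- cl$receptors
    data.frame(x = r$x, y = r$y, affinity = r$affinity,
               capacity = r$capacity, cell = cl$id,
               receptor = seq_len(nrow(r)))
  })
  do.call(rbind, out)
}

tissue_cell_polygons <- function(tissue) {
  lapply(tissue$cells, function(cl) polygon_ring(cl$boundary))
}

#' Per-cell ligand slot capacity
#'
#' @param tissue a `tissue_domain`.
#' @return named integer vector, one total slot count per cell.
#' @export
tissue_cell_capacities <- function(tissue) {
  vapply(tissue$cells, function(cl) sum(cl$receptors$capacity), numeric(1))
}

#' Default capture radius for a tissue
#'
#' The binding condition requires a ligand to come within a capture radius
#' `r_min` of a receptor. The default is half the inter-receptor arc spacing
#' of the most densely covered cell, so that capture zones tile the membrane
#' without overlapping, with an absolute floor of 0.5 um.
#'
#' @param tissue a `tissue_domain`.
#' @param floor_um smallest allowed radius (um).
#' @return capture radius in um.
#' @export
default_r_min <- function(tissue, floor_um = 0.5) {
  spacing <- vapply(tissue$cells, function(cl) {
    polygon_perimeter(cl$boundary) / nrow(cl$receptors)
  }, numeric(1))
  max(min(spacing) / 2, floor_um)
}

# ---- validation -------------------------------------------------------------

#' Validate the structural invariants of a tissue
#'
#' Checks: positive domain size; unique cell ids ordered by increasing
#' centroid x; simple, pairwise non-overlapping cell polygons strictly inside
#' the domain; at least one receptor per cell, all receptor coordinates on
#' their cell boundary (within 1e-6 um), affinities in \[0, 1\] and integer
#' capacities >= 1.
#'
#' @param tissue a `tissue_domain`.
#' @return the tissue, invisibly; errors name the offending cell/receptor.
#' @export
validate_tissue <- function(tissue) {
  if (!is.numeric(tissue$width) || tissue$width <= 0 ||
      !is.numeric(tissue$height) || tissue$height <= 0)
    stop("domain width and height must be positive")
  if (length(tissue$cells) == 0) return(invisible(tissue))

  ids <- vapply(tissue$cells, function(cl) as.integer(cl$id), integer(1))
  if (anyDuplicated(ids)) stop("duplicate cell id: ", ids[duplicated(ids)][1])

  cx <- vapply(tissue$cells, function(cl) polygon_centroid(cl$boundary)[1], numeric(1))
  if (is.unsorted(cx[order(ids)]))
    stop("cell ids must be ordered by increasing centroid x (cell nearest the vessel first)")

  polys <- tissue_cell_polygons(tissue)
  for (k in seq_along(tissue$cells)) {
    cl <- tissue$cells[[k]]
    b <- polys[[k]]
    if (nrow(b) < 3) stop("cell ", cl$id, ": boundary needs at least 3 vertices")
    if (!polygon_is_simple(b)) stop("cell ", cl$id, ": boundary polygon self-intersects")
    if (polygon_signed_area(b) <= 0)
      stop("cell ", cl$id, ": boundary must be counter-clockwise")
    if (any(b[, 1] <= 0) || any(b[, 1] >= tissue$width) ||
        any(b[, 2] <= 0) || any(b[, 2] >= tissue$height))
      stop("cell ", cl$id, ": polygon must lie strictly inside the domain")

    r <- cl$receptors
    if (is.null(r) || nrow(r) < 1) stop("cell ", cl$id, ": needs at least one receptor")
    if (any(r$affinity < 0 | r$affinity > 1))
      stop("cell ", cl$id, ": receptor affinity outside [0, 1]")
    if (any(r$capacity < 1))
      stop("cell ", cl$id, ", receptor ", which(r$capacity < 1)[1],
           ": capacity must be >= 1")
    on_b <- cpp_on_any_boundary(cbind(r$x, r$y), list(b), 1e-6)
    if (!all(on_b))
      stop("cell ", cl$id, ", receptor ", which(!on_b)[1],
           ": coordinates are not on the cell boundary")
  }

  # pairwise disjoint interiors: no vertex of one inside another, no edge crossings
  n <- length(polys)
  if (n > 1) {
    for (a in seq_len(n - 1)) {
      for (b in (a + 1):n) {
        inside_ab <- cpp_point_in_cell(polys[[a]], list(polys[[b]]))
        inside_ba <- cpp_point_in_cell(polys[[b]], list(polys[[a]]))
        pa <- polys[[a]]
        ja <- c(2:nrow(pa), 1)
        edge_hit <- any(cpp_segment_crosses(pa, pa[ja, , drop = FALSE],
                                            list(polys[[b]])))
        if (any(inside_ab > 0) || any(inside_ba > 0) || edge_hit)
          stop("cells ", ids[a], " and ", ids[b], " overlap")
      }
    }
  }
  invisible(tissue)
}

# ---- fixture generator ------------------------------------------------------

#' Generate the default virtual tissue fixture
#'
#' Builds a small virtual tumor tissue emulating a digitized xenograft patch:
#' `n_cells` convex-ish polygonal cells of roughly 15-25 um diameter arranged
#' in two loose rows, separated by narrow (2-5 um) interstitial channels,
#' strictly inside a rectangular domain whose left edge acts as the capillary
#' and right edge as tissue clearance. Pseudo-receptors are placed at equal
#' arc-length spacing along each cell's circumference; per-cell receptor
#' counts are proportional to circumference (largest-remainder rounding) and
#' the total ligand slot capacity sums exactly to `total_slot_capacity`. With
#' the defaults this yields 286 receptors of capacity 5 = 1,430 binding
#' slots over 8 cells.
#'
#' @param width,height domain size (um).
#' @param n_cells number of cells.
#' @param total_slot_capacity total number of ligand-binding slots summed
#'   over all receptors of all cells.
#' @param capacity_per_receptor slots per pseudo-receptor (default 5).
#' @param affinity binding probability assigned to every receptor.
#' @param seed integer seed; the tissue is deterministic given the seed.
#' @param max_attempts layout attempts before giving up.
#' @return a validated `tissue_domain`.
#' @export
generate_fixture_tissue <- function(width = 120, height = 120, n_cells = 8,
                                    total_slot_capacity = 1430,
                                    capacity_per_receptor = 5,
                                    affinity = 1.0, seed = 1L,
                                    max_attempts = 200L) {
  stopifnot(n_cells >= 1, total_slot_capacity >= 1, capacity_per_receptor >= 1,
            affinity >= 0, affinity <= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  polys <- NULL
  for (attempt in seq_len(max_attempts)) {
    polys <- try(.fixture_layout(width, height, n_cells), silent = TRUE)
    if (!inherits(polys, "try-error")) break
    polys <- NULL
  }
  if (is.null(polys))
    stop("could not place ", n_cells, " non-overlapping cells in a ",
         width, " x ", height, " um domain after ", max_attempts,
         " attempts (seed ", seed, ")")

  # order cells by increasing centroid x (cell #1 nearest the vessel)
  cx <- vapply(polys, function(p) polygon_centroid(p)[1], numeric(1))
  polys <- polys[order(cx)]

  cells <- .allocate_receptors(polys, total_slot_capacity,
                               capacity_per_receptor, affinity)
  tissue_domain(width, height, cells)
}

# two loose rows of perturbed-circle polygons with 2-5 um channels
.fixture_layout <- function(width, height, n_cells) {
  n_top <- ceiling(n_cells / 2)
  n_bot <- n_cells - n_top
  rows <- list(top = n_top, bot = n_bot)
  margin <- 2.0
  polys <- list()
  for (rname in names(rows)) {
    k <- rows[[rname]]
    if (k == 0) next
    ycenter <- if (rname == "top") 0.72 * height else 0.28 * height
    radii <- stats::runif(k, 8.2, 10.8)      # base radius; diameter ~15-24 um
    gaps <- stats::runif(max(k - 1, 0), 2, 5) # inter-cell channel widths
    need <- 2 * sum(radii) * 1.12 + sum(gaps) + 2 * margin
    if (need > width) stop("row does not fit")
    x0 <- margin + stats::runif(1, 0, width - need)
    xc <- numeric(k)
    cursor <- x0
    for (i in seq_len(k)) {
      xc[i] <- cursor + radii[i] * 1.12
      cursor <- xc[i] + radii[i] * 1.12 + if (i < k) gaps[i] else 0
    }
    for (i in seq_len(k)) {
      yc <- ycenter + stats::runif(1, -0.04, 0.04) * height
      polys[[length(polys) + 1]] <-
        .blob_polygon(xc[i], yc, radii[i], n_vertices = 24)
    }
  }
  # vertical channel between rows must stay open and inside the domain
  for (p in polys) {
    if (any(p[, 1] <= 0.5) || any(p[, 1] >= width - 0.5) ||
        any(p[, 2] <= 0.5) || any(p[, 2] >= height - 0.5))
      stop("cell outside domain")
  }
  if (length(polys) > 1) {
    for (a in seq_len(length(polys) - 1)) {
      for (b in (a + 1):length(polys)) {
        da <- polys[[a]]; db <- polys[[b]]
        dmin <- min(outer(seq_len(nrow(da)), seq_len(nrow(db)), function(i, j) {
          sqrt((da[i, 1] - db[j, 1])^2 + (da[i, 2] - db[j, 2])^2)
        }))
        if (dmin < 1.5) stop("cells too close")
      }
    }
  }
  polys
}

# smooth radially perturbed circle, counter-clockwise
.blob_polygon <- function(xc, yc, r, n_vertices = 24) {
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  phase <- stats::runif(1, 0, 2 * pi)
  amp <- stats::runif(1, 0.04, 0.10)
  rr <- r * (1 + amp * sin(3 * theta + phase) +
               stats::runif(n_vertices, -0.02, 0.02))
  cbind(xc + rr * cos(theta), yc + rr * sin(theta))
}

# receptor allocation: counts proportional to circumference with
# largest-remainder rounding; slot remainder (when total is not a multiple of
# the per-receptor capacity) becomes one reduced-capacity receptor on the
# largest cell, so the slot total is exact
.allocate_receptors <- function(polys, total_slot_capacity, capacity, affinity) {
  n_full <- total_slot_capacity %/% capacity
  rem_slots <- total_slot_capacity - n_full * capacity
  n_cells <- length(polys)
  if (n_full < n_cells)
    stop("total_slot_capacity too small: need at least one capacity-",
         capacity, " receptor per cell")

  circ <- vapply(polys, polygon_perimeter, numeric(1))
  quota <- n_full * circ / sum(circ)
  counts <- floor(quota)
  counts <- pmax(counts, 1)
  short <- n_full - sum(counts)
  if (short > 0) {
    extra <- order(quota - floor(quota), decreasing = TRUE)
    counts[extra[seq_len(short)]] <- counts[extra[seq_len(short)]] + 1
  } else if (short < 0) {
    donors <- order(counts, decreasing = TRUE)
    i <- 1
    while (short < 0) {
      if (counts[donors[i]] > 1) { counts[donors[i]] <- counts[donors[i]] - 1; short <- short + 1 }
      i <- if (i == n_cells) 1 else i + 1
    }
  }

  largest <- which.max(circ)
  cells <- vector("list", n_cells)
  for (l in seq_len(n_cells)) {
    m <- counts[l]
    C <- circ[l]
    pts <- polygon_arc_points(polys[[l]], (seq_len(m) - 0.5) * C / m)
    rec <- data.frame(x = pts[, 1], y = pts[, 2],
                      affinity = affinity, capacity = capacity)
    if (l == largest && rem_slots > 0) {
      # one extra receptor carrying the slot remainder, at arc position 0
      p0 <- polygon_arc_points(polys[[l]], 0)
      rec <- rbind(data.frame(x = p0[, 1], y = p0[, 2],
                              affinity = affinity, capacity = rem_slots), rec)
    }
    cells[[l]] <- list(id = l, boundary = polys[[l]], receptors = rec)
  }
  cells
}

# ---- geometric queries ------------------------------------------------------

#' Which cell contains a point?
#'
#' Boundary points count as outside (interstitial): cell membranes belong to
#' the interstitium for transport purposes.
#'
#' @param p numeric length-2 vector or an n x 2 matrix of points (um).
#' @param tissue a `tissue_domain`.
#' @return integer vector of cell ids, `NA` where the point is in no cell.
#' @export
point_in_cell <- function(p, tissue) {
  p <- rbind(p)
  hit <- cpp_point_in_cell(p, tissue_cell_polygons(tissue))
  ids <- vapply(tissue$cells, function(cl) as.integer(cl$id), integer(1))
  out <- rep(NA_integer_, nrow(p))
  out[hit > 0] <- ids[hit[hit > 0]]
  out
}

#' Does a move cross a cell membrane?
#'
#' `TRUE` iff the segment `p0 -> p1` intersects any cell's boundary polygon
#' or `p1` lies strictly inside a cell. Cell membranes are impenetrable to
#' free ligand, so such a move is rejected by the move rule.
#'
#' @param p0,p1 length-2 vectors or matched n x 2 matrices (um).
#' @param tissue a `tissue_domain`.
#' @return logical vector.
#' @export
segment_crosses_membrane <- function(p0, p1, tissue) {
  p0 <- rbind(p0); p1 <- rbind(p1)
  stopifnot(nrow(p0) == nrow(p1))
  cpp_segment_crosses(p0, p1, tissue_cell_polygons(tissue))
}

# save/restore the global RNG state so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
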