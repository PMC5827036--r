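#' Binding parameters
#'
#' The binding condition (BC) between a ligand molecule and a membrane
#' pseudo-receptor requires that (i) the molecule is within the capture
#' radius `r_min` of the receptor (strict Euclidean distance), (ii) the
#' receptor is not saturated (occupancy below capacity), and (iii) a
#' Bernoulli draw at the receptor's affinity succeeds. The affinity level is
#' labeled by a pseudo-association constant `K_A`: 100, 10 and 1 correspond
#' to binding probabilities 1.0, 0.1 and 0.01 (strong, moderate, weak).
#' There is no dissociation: occupancy is append-only. A bound complex is
#' internalized by receptor-mediated endocytosis once it has resided on the
#' membrane for at least `residency_s` seconds (default 20 min).
#'
#' @param K_A pseudo-association constant: 100, 10 or 1.
#' @param r_min capture radius (um); `NULL` defers to [default_r_min()] of
#'   the tissue at simulation time.
#' @param residency_s minimum membrane residency before endocytosis (s).
#' @return an object of class `binding_params`.
#' @export
binding_params <- function(K_A = 100, r_min = NULL, residency_s = 1200) {
  prob <- ka_to_probability(K_A)
  if (!is.null(r_min) && r_min <= 0) stop("r_min must be positive")
  if (residency_s < 0) stop("residency_s must be non-negative")
  structure(list(K_A = K_A, probability = prob, r_min = r_min,
                 residency_s = residency_s),
            class = "binding_params")
}

#' Map a pseudo-association constant to a binding probability
#'
#' `K_A` = 100, 10, 1 map to probabilities 1.0, 0.1, 0.01 (i.e. `K_A`/100);
#' intermediate positive values up to 100 are allowed on the same scale.
#'
#' @param K_A pseudo-association constant.
#' @return binding probability in (0, 1\].
#' @export
ka_to_probability <- function(K_A) {
  if (!is.numeric(K_A) || K_A <= 0 || K_A > 100)
    stop("K_A must be in (0, 100]")
  K_A / 100
}

#' Find the candidate receptor for a binding attempt
#'
#' Returns the nearest receptor with Euclidean distance strictly below
#' `r_min`, regardless of its occupancy (saturation is checked by
#' [attempt_binding()]). Distance ties break toward the lowest
#' (cell id, receptor index). The spatial hash used internally returns
#' answers identical to exhaustive search.
#'
#' @param p length-2 point or n x 2 matrix (um).
#' @param tissue a `tissue_domain`.
#' @param r_min capture radius (um).
#' @return data frame with one row per query point: `cell`, `receptor`
#'   (both `NA` when no receptor is in range) and `row` (index into
#'   [tissue_receptor_table()]).
#' @export
find_candidate_receptor <- function(p, tissue, r_min) {
  p <- rbind(p)
  rec <- tissue_receptor_table(tissue)
  hit <- cpp_nearest_receptor(p, as.matrix(rec[, c("x", "y", "affinity",
                                                   "capacity", "cell")]),
                              r_min, tissue$width, tissue$height)
  out <- data.frame(cell = rep(NA_integer_, nrow(p)),
                    receptor = NA_integer_, row = NA_integer_)
  found <- hit > 0
  out$cell[found] <- rec$cell[hit[found]]
  out$receptor[found] <- rec$receptor[hit[found]]
  out$row[found] <- hit[found]
  out
}

#' Attempt to bind a ligand to a receptor
#'
#' Proximity is assumed already established. Binding succeeds iff the
#' receptor has a free slot and a Bernoulli draw at its affinity succeeds;
#' binding to one receptor does not alter neighboring receptors.
#'
#' @param affinity receptor binding probability in \[0, 1\].
#' @param occupancy current number of ligands bound to the receptor.
#' @param capacity receptor slot capacity.
#' @return `TRUE` if the ligand binds.
#' @export
attempt_binding <- function(affinity, occupancy, capacity) {
  if (occupancy >= capacity) return(FALSE)
  stats::runif(1) < affinity
}

#' Resolve one composite move of a free ligand molecule
#'
#' Applies the move rule for a single free molecule, in precedence order:
#' (1) domain boundaries (clearance at the right edge, reflection elsewhere);
#' (2) binding: if a receptor lies within `r_min` of the post-boundary
#' proposal and the binding condition succeeds, the molecule snaps to the
#' receptor's coordinates and becomes bound; (3) membrane rejection: a move
#' that would cross a cell boundary or end inside a cell leaves the position
#' unchanged; (4) otherwise the proposal is accepted. A failed affinity draw
#' alone does not reject the move -- the molecule stays in the interstitium
#' under rule (4) unless the path crosses a membrane.
#'
#' This is the single-molecule reference implementation of the rule the
#' compiled simulation loop applies to every free molecule at every step.
#'
#' @param position length-2 current position (um), outside all cells.
#' @param proposed length-2 proposed position.
#' @param tissue a `tissue_domain`.
#' @param params a [binding_params()] object (with `r_min` set).
#' @param t current time (s).
#' @param occupancy integer vector of current occupancies, one per row of
#'   [tissue_receptor_table()].
#' @return list with `position`, `state` (one of `"free"`, `"bound"`,
#'   `"cleared"`), `receptor_row` (`NA` unless bound), `bind_time` and the
#'   updated `occupancy` vector.
#' @export
resolve_move <- function(position, proposed, tissue, params, t, occupancy) {
  bc <- apply_boundaries(position, proposed, tissue)
  if (bc$cleared[1]) {
    return(list(position = c(NA_real_, NA_real_), state = "cleared",
                receptor_row = NA_integer_, bind_time = NA_real_,
                occupancy = occupancy))
  }
  prop <- bc$position[1, ]
  rec <- tissue_receptor_table(tissue)
  cand <- find_candidate_receptor(prop, tissue, params$r_min)
  if (!is.na(cand$row[1])) {
    i <- cand$row[1]
    # effective binding probability: per-receptor affinity scaled by K_A
    if (attempt_binding(rec$affinity[i] * params$probability,
                        occupancy[i], rec$capacity[i])) {
      occupancy[i] <- occupancy[i] + 1L
      return(list(position = c(rec$x[i], rec$y[i]), state = "bound",
                  receptor_row = i, bind_time = t, occupancy = occupancy))
    }
  }
  if (segment_crosses_membrane(position, prop, tissue)[1]) {
    return(list(position = position, state = "free",
                receptor_row = NA_integer_, bind_time = NA_real_,
                occupancy = occupancy))
  }
  list(position = prop, state = "free", receptor_row = NA_integer_,
       bind_time = NA_real_, occupancy = occupancy)
}

#' Internalize bound ligands that have completed membrane residency
#'
#' Every bound ligand whose time since binding has reached `residency_s`
#' transitions to the internalized state and is placed uniformly at random
#' strictly inside its cell's polygon (rejection sampling over the bounding
#' box), mimicking endosomal distribution. The receptor slot stays consumed
#' (no recycling), so cumulative saturation is unchanged by internalization.
#'
#' @param molecules data frame with columns `x`, `y`, `state`, `bind_t` and
#'   `receptor` (1-based row into [tissue_receptor_table()], 0 = none), as
#'   returned in the `molecules` element of [run_simulation()] output.
#' @param tissue a `tissue_domain`.
#' @param t current time (s).
#' @param residency_s minimum membrane residency (s).
#' @return the updated molecules data frame (`state` code 3 = internalized).
#' @export
internalize_due <- function(molecules, tissue, t, residency_s = 1200) {
  rec <- tissue_receptor_table(tissue)
  polys <- tissue_cell_polygons(tissue)
  ids <- vapply(tissue$cells, function(cl) as.integer(cl$id), integer(1))
  due <- which(molecules$state == 2 & (t - molecules$bind_t) >= residency_s)
  for (i in due) {
    cell_id <- rec$cell[molecules$receptor[i]]
    poly <- polys[[match(cell_id, ids)]]
    pt <- cpp_sample_in_polygon(poly, 1L)
    molecules$x[i] <- pt[1, 1]
    molecules$y[i] <- pt[1, 2]
    molecules$state[i] <- 3L
    molecules$internalize_t[i] <- t
  }
  molecules
}
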