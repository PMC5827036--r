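// Simulation core: polygon geometry predicates, receptor spatial hash, and
// the per-step Brownian / binding / endocytosis loop. All lengths in um,
// times in seconds. Randomness comes from R's RNG (RNGScope), so runs are
// reproducible under set.seed().
#include <Rcpp.h>
#include <vector>
#include <deque>
#include <cmath>
using namespace Rcpp;

static const double BOUNDARY_TOL = 1e-9; // points this close to an edge count as "on boundary"

static inline double cross3(double ax, double ay, double bx, double by,
                            double cx, double cy) {
  return (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
}

// squared distance from p to segment ab
static double pt_seg_d2(double px, double py, double ax, double ay,
                        double bx, double by) {
  double dx = bx - ax, dy = by - ay;
  double L2 = dx * dx + dy * dy;
  double t = (L2 > 0.0) ? ((px - ax) * dx + (py - ay) * dy) / L2 : 0.0;
  if (t < 0.0) t = 0.0;
  if (t > 1.0) t = 1.0;
  double qx = ax + t * dx - px, qy = ay + t * dy - py;
  return qx * qx + qy * qy;
}

static bool on_segment_collinear(double px, double py, double ax, double ay,
                                 double bx, double by) {
  return std::min(ax, bx) - BOUNDARY_TOL <= px && px <= std::max(ax, bx) + BOUNDARY_TOL &&
         std::min(ay, by) - BOUNDARY_TOL <= py && py <= std::max(ay, by) + BOUNDARY_TOL;
}

// segment p0p1 vs segment p2p3; touching counts as intersecting
static bool seg_seg_intersect(double p0x, double p0y, double p1x, double p1y,
                              double p2x, double p2y, double p3x, double p3y) {
  double d1 = cross3(p2x, p2y, p3x, p3y, p0x, p0y);
  double d2 = cross3(p2x, p2y, p3x, p3y, p1x, p1y);
  double d3 = cross3(p0x, p0y, p1x, p1y, p2x, p2y);
  double d4 = cross3(p0x, p0y, p1x, p1y, p3x, p3y);
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
    return true;
  if (std::abs(d1) <= BOUNDARY_TOL && on_segment_collinear(p0x, p0y, p2x, p2y, p3x, p3y)) return true;
  if (std::abs(d2) <= BOUNDARY_TOL && on_segment_collinear(p1x, p1y, p2x, p2y, p3x, p3y)) return true;
  if (std::abs(d3) <= BOUNDARY_TOL && on_segment_collinear(p2x, p2y, p0x, p0y, p1x, p1y)) return true;
  if (std::abs(d4) <= BOUNDARY_TOL && on_segment_collinear(p3x, p3y, p0x, p0y, p1x, p1y)) return true;
  return false;
}

struct Poly {
  std::vector<double> x, y; // open ring (first vertex not repeated)
  double xmin, xmax, ymin, ymax;
  int n;

  void build(const NumericMatrix &m) {
    n = m.nrow();
    // drop a repeated closing vertex if present
    if (n > 1 && m(0, 0) == m(n - 1, 0) && m(0, 1) == m(n - 1, 1)) n--;
    x.resize(n); y.resize(n);
    xmin = ymin = R_PosInf; xmax = ymax = R_NegInf;
    for (int i = 0; i < n; ++i) {
      x[i] = m(i, 0); y[i] = m(i, 1);
      xmin = std::min(xmin, x[i]); xmax = std::max(xmax, x[i]);
      ymin = std::min(ymin, y[i]); ymax = std::max(ymax, y[i]);
    }
  }

  bool on_boundary(double px, double py, double tol) const {
    double t2 = tol * tol;
    for (int i = 0, j = n - 1; i < n; j = i++)
      if (pt_seg_d2(px, py, x[j], y[j], x[i], y[i]) <= t2) return true;
    return false;
  }

  // strictly inside; boundary points count as outside (interstitial)
  bool contains_strict(double px, double py) const {
    if (px < xmin || px > xmax || py < ymin || py > ymax) return false;
    if (on_boundary(px, py, BOUNDARY_TOL)) return false;
    bool inside = false;
    for (int i = 0, j = n - 1; i < n; j = i++) {
      if (((y[i] > py) != (y[j] > py)) &&
          (px < (x[j] - x[i]) * (py - y[i]) / (y[j] - y[i]) + x[i]))
        inside = !inside;
    }
    return inside;
  }

  // does segment p0->p1 touch/cross the boundary, or end strictly inside?
  bool blocks_segment(double p0x, double p0y, double p1x, double p1y) const {
    double sxmin = std::min(p0x, p1x), sxmax = std::max(p0x, p1x);
    double symin = std::min(p0y, p1y), symax = std::max(p0y, p1y);
    if (sxmax < xmin || sxmin > xmax || symax < ymin || symin > ymax) return false;
    for (int i = 0, j = n - 1; i < n; j = i++)
      if (seg_seg_intersect(p0x, p0y, p1x, p1y, x[j], y[j], x[i], y[i])) return true;
    return contains_strict(p1x, p1y);
  }
};

static std::vector<Poly> build_polys(const List &polys) {
  std::vector<Poly> out(polys.size());
  for (int i = 0; i < polys.size(); ++i) {
    NumericMatrix m = polys[i];
    out[i].build(m);
  }
  return out;
}

// ---- exported geometry predicates -----------------------------------------

// For each point, 1-based index of the cell polygon strictly containing it,
// 0 if none (boundary points count as outside).
// [[Rcpp::export]]
IntegerVector cpp_point_in_cell(NumericMatrix pts, List polys) {
  std::vector<Poly> P = build_polys(polys);
  int np = pts.nrow();
  IntegerVector out(np, 0);
  for (int k = 0; k < np; ++k) {
    for (size_t c = 0; c < P.size(); ++c) {
      if (P[c].contains_strict(pts(k, 0), pts(k, 1))) { out[k] = c + 1; break; }
    }
  }
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_segment_crosses(NumericMatrix p0, NumericMatrix p1, List polys) {
  std::vector<Poly> P = build_polys(polys);
  int np = p0.nrow();
  LogicalVector out(np);
  for (int k = 0; k < np; ++k) {
    bool hit = false;
    for (size_t c = 0; c < P.size() && !hit; ++c)
      hit = P[c].blocks_segment(p0(k, 0), p0(k, 1), p1(k, 0), p1(k, 1));
    out[k] = hit;
  }
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_on_any_boundary(NumericMatrix pts, List polys, double tol) {
  std::vector<Poly> P = build_polys(polys);
  int np = pts.nrow();
  LogicalVector out(np);
  for (int k = 0; k < np; ++k) {
    bool hit = false;
    for (size_t c = 0; c < P.size() && !hit; ++c)
      hit = P[c].on_boundary(pts(k, 0), pts(k, 1), tol);
    out[k] = hit;
  }
  return out;
}

// ---- receptor spatial hash -------------------------------------------------

struct RecGrid {
  double bin, W, H;
  int nx, ny, nrec;
  const double *rx, *ry;
  std::vector<std::vector<int> > cells;

  void build(const NumericMatrix &rec, double width, double height, double r_min) {
    nrec = rec.nrow();
    const double *base = REAL(rec);
    rx = base; ry = base + nrec;
    W = width; H = height;
    bin = std::max(r_min, 1e-6);
    nx = std::max(1, (int)std::ceil(W / bin));
    ny = std::max(1, (int)std::ceil(H / bin));
    cells.assign((size_t)nx * ny, std::vector<int>());
    for (int i = 0; i < nrec; ++i) {
      int cx = std::min(nx - 1, std::max(0, (int)(rx[i] / bin)));
      int cy = std::min(ny - 1, std::max(0, (int)(ry[i] / bin)));
      cells[(size_t)cy * nx + cx].push_back(i);
    }
  }

  // nearest receptor row (0-based) with distance strictly < r_min, else -1;
  // ties in distance broken by lowest row index (rows ordered by cell then
  // receptor index)
  int nearest_within(double px, double py, double r_min) const {
    int cx = std::min(nx - 1, std::max(0, (int)(px / bin)));
    int cy = std::min(ny - 1, std::max(0, (int)(py / bin)));
    double best = r_min * r_min;
    int besti = -1;
    for (int gy = std::max(0, cy - 1); gy <= std::min(ny - 1, cy + 1); ++gy)
      for (int gx = std::max(0, cx - 1); gx <= std::min(nx - 1, cx + 1); ++gx) {
        const std::vector<int> &v = cells[(size_t)gy * nx + gx];
        for (size_t k = 0; k < v.size(); ++k) {
          int i = v[k];
          double dx = rx[i] - px, dy = ry[i] - py;
          double d2 = dx * dx + dy * dy;
          if (d2 < best || (d2 == best && besti >= 0 && i < besti)) {
            best = d2; besti = i;
          }
        }
      }
    return besti;
  }
};

// Nearest receptor within r_min (strict) for each point; 0 if none, else
// 1-based row into the receptor table. Uses the same spatial hash as the
// simulation loop.
// [[Rcpp::export]]
IntegerVector cpp_nearest_receptor(NumericMatrix pts, NumericMatrix receptors,
                                   double r_min, double width, double height) {
  RecGrid g;
  g.build(receptors, width, height, r_min);
  int np = pts.nrow();
  IntegerVector out(np, 0);
  for (int k = 0; k < np; ++k) {
    int i = g.nearest_within(pts(k, 0), pts(k, 1), r_min);
    out[k] = i + 1;
  }
  return out;
}

// uniform rejection sampling over the polygon's bounding box
// [[Rcpp::export]]
NumericMatrix cpp_sample_in_polygon(NumericMatrix poly, int n) {
  Poly P; P.build(poly);
  NumericMatrix out(n, 2);
  for (int k = 0; k < n; ++k) {
    double px = 0, py = 0; bool ok = false;
    for (int it = 0; it < 100000; ++it) {
      px = P.xmin + unif_rand() * (P.xmax - P.xmin);
      py = P.ymin + unif_rand() * (P.ymax - P.ymin);
      if (P.contains_strict(px, py)) { ok = true; break; }
    }
    if (!ok) stop("could not sample a point inside the polygon");
    out(k, 0) = px; out(k, 1) = py;
  }
  return out;
}

// domain boundary handling: absorbing right edge (clearance), specular
// reflection on left/top/bottom; returns cleared flag
static inline bool reflect_or_clear(double &px, double &py, double W, double H) {
  for (int it = 0; it < 64; ++it) {
    if (px > W) return true;
    bool inside = true;
    if (px < 0) { px = -px; inside = false; }
    if (py < 0) { py = -py; inside = false; }
    else if (py > H) { py = 2 * H - py; inside = false; }
    if (inside) return false;
  }
  // pathological step length: clamp
  px = std::min(std::max(px, 0.0), W);
  py = std::min(std::max(py, 0.0), H);
  return false;
}

// [[Rcpp::export]]
List cpp_apply_boundaries(NumericMatrix proposed, double width, double height) {
  int np = proposed.nrow();
  NumericMatrix pos(np, 2);
  LogicalVector cleared(np);
  for (int k = 0; k < np; ++k) {
    double px = proposed(k, 0), py = proposed(k, 1);
    bool cl = reflect_or_clear(px, py, width, height);
    pos(k, 0) = px; pos(k, 1) = py;
    cleared[k] = cl;
  }
  return List::create(_["position"] = pos, _["cleared"] = cleared);
}

// ---- full simulation loop ---------------------------------------------------
//
// polys: list of cell boundary matrices (CCW, open or closed ring)
// receptors: matrix with columns x, y, affinity, capacity, cell (1-based),
//            rows ordered by (cell, receptor index)
// release_counts: molecules entering at each step (length <= n_steps)
// record_steps: sorted 1-based step indices at which to snapshot observables
//
// State codes: 0 vascular, 1 free, 2 bound, 3 internalized, 4 cleared.
// [[Rcpp::export]]
List cpp_run_simulation(List polys, NumericMatrix receptors,
                        double width, double height,
                        double D, double dt, int n_steps,
                        IntegerVector release_counts, double entry_x,
                        double r_min, double residency_s,
                        IntegerVector record_steps) {
  std::vector<Poly> P = build_polys(polys);
  int n_cells = P.size();
  int n_rec = receptors.nrow();
  RecGrid grid;
  grid.build(receptors, width, height, r_min);

  const double *rbase = REAL(receptors);
  const double *raff = rbase + 2 * (size_t)n_rec;
  const double *rcap = rbase + 3 * (size_t)n_rec;
  const double *rcell = rbase + 4 * (size_t)n_rec;

  long total = 0;
  for (int i = 0; i < release_counts.size(); ++i) total += release_counts[i];

  std::vector<double> mx(total), my(total);
  std::vector<int> mstate(total, 0), mrec(total, -1);
  std::vector<double> mrel(total, NA_REAL), mbind(total, NA_REAL), mint(total, NA_REAL);

  std::vector<int> occ(n_rec, 0);
  std::vector<int> cell_uptake(n_cells, 0); // cumulative bound + internalized per cell

  std::vector<int> freeIds;
  freeIds.reserve(4096);
  std::deque<int> boundQueue; // FIFO: bind times are non-decreasing

  int n_released = 0, n_cleared = 0, n_bound = 0, n_intern = 0;

  int n_recpts = record_steps.size();
  IntegerMatrix occ_snap(n_recpts, n_rec);
  IntegerMatrix cell_snap(n_recpts, n_cells);
  IntegerMatrix census(n_recpts, 5); // released, free, bound, internalized, cleared
  int ri = 0;

  double step_sd = std::sqrt(2.0 * D * dt);
  int sched_len = release_counts.size();

  // snapshot at step 0 if requested
  while (ri < n_recpts && record_steps[ri] == 0) {
    census(ri, 0) = 0; census(ri, 1) = 0; census(ri, 2) = 0;
    census(ri, 3) = 0; census(ri, 4) = 0;
    ri++;
  }

  for (int s = 1; s <= n_steps; ++s) {
    double t = s * dt;

    // 1. release
    if (s <= sched_len) {
      int k = release_counts[s - 1];
      for (int i = 0; i < k; ++i) {
        int id = n_released++;
        mx[id] = entry_x;
        my[id] = unif_rand() * height;
        mstate[id] = 1;
        mrel[id] = t;
        freeIds.push_back(id);
      }
    }

    // 2. move free molecules in id order
    size_t keep = 0;
    for (size_t f = 0; f < freeIds.size(); ++f) {
      int id = freeIds[f];
      double px = mx[id] + step_sd * norm_rand();
      double py = my[id] + step_sd * norm_rand();

      if (reflect_or_clear(px, py, width, height)) {
        mstate[id] = 4; n_cleared++;
        continue; // leaves the free list
      }

      // binding condition at the post-boundary endpoint
      int cand = (n_rec > 0) ? grid.nearest_within(px, py, r_min) : -1;
      if (cand >= 0 && occ[cand] < (int)rcap[cand] &&
          unif_rand() < raff[cand]) {
        mx[id] = grid.rx[cand]; my[id] = grid.ry[cand];
        mstate[id] = 2; mbind[id] = t; mrec[id] = cand;
        occ[cand]++;
        cell_uptake[(int)rcell[cand] - 1]++;
        n_bound++;
        boundQueue.push_back(id);
        continue;
      }

      // membrane check: reject moves that cross a cell boundary or end inside
      bool blocked = false;
      for (int c = 0; c < n_cells && !blocked; ++c)
        blocked = P[c].blocks_segment(mx[id], my[id], px, py);
      if (!blocked) { mx[id] = px; my[id] = py; }
      freeIds[keep++] = id;
    }
    freeIds.resize(keep);

    // 3. receptor-mediated endocytosis after the minimum membrane residency
    while (!boundQueue.empty()) {
      int id = boundQueue.front();
      if (t - mbind[id] < residency_s) break;
      boundQueue.pop_front();
      int c = (int)rcell[mrec[id]] - 1;
      const Poly &poly = P[c];
      bool ok = false;
      for (int it = 0; it < 100000; ++it) {
        double px = poly.xmin + unif_rand() * (poly.xmax - poly.xmin);
        double py = poly.ymin + unif_rand() * (poly.ymax - poly.ymin);
        if (poly.contains_strict(px, py)) { mx[id] = px; my[id] = py; ok = true; break; }
      }
      if (!ok) stop("internalization placement failed for cell %d", c + 1);
      mstate[id] = 3; mint[id] = t;
      n_bound--; n_intern++;
    }

    // 4. record
    while (ri < n_recpts && record_steps[ri] == s) {
      for (int i = 0; i < n_rec; ++i) occ_snap(ri, i) = occ[i];
      for (int c = 0; c < n_cells; ++c) cell_snap(ri, c) = cell_uptake[c];
      census(ri, 0) = n_released;
      census(ri, 1) = (int)freeIds.size();
      census(ri, 2) = n_bound;
      census(ri, 3) = n_intern;
      census(ri, 4) = n_cleared;
      ri++;
    }
  }

  IntegerVector ids((int)total), recs((int)total);
  for (long i = 0; i < total; ++i) {
    ids[i] = (int)i + 1;
    recs[i] = mrec[i] + 1; // 1-based row into receptor table, 0 = none
  }
  DataFrame mol = DataFrame::create(
    _["id"] = ids,
    _["x"] = wrap(mx), _["y"] = wrap(my),
    _["state"] = wrap(mstate),
    _["release_t"] = wrap(mrel),
    _["bind_t"] = wrap(mbind),
    _["internalize_t"] = wrap(mint),
    _["receptor"] = recs);

  return List::create(
    _["occupancy"] = occ_snap,
    _["cell_uptake"] = cell_snap,
    _["census"] = census,
    _["molecules"] = mol,
    _["final_occupancy"] = wrap(occ));
}
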