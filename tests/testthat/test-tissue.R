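test_that("default fixture carries exactly 1430 binding slots over 8 cells", {
  tis <- default_tissue()
  expect_length(tis$cells, 8)
  expect_identical(sum(tissue_cell_capacities(tis)), 1430)
  expect_identical(nrow(tissue_receptor_table(tis)), 286L)
})

test_that("slot totals are exact for any seed and awkward capacity splits", {
  for (seed in c(2, 17, 99)) {
    tis <- generate_fixture_tissue(total_slot_capacity = 1433,
                                   capacity_per_receptor = 5, seed = seed)
    expect_equal(sum(tissue_cell_capacities(tis)), 1433)
  }
  # forced arithmetic: one cell, 5 slots, capacity 5 -> exactly 1 receptor
  tis1 <- generate_fixture_tissue(n_cells = 1, total_slot_capacity = 5,
                                  capacity_per_receptor = 5, seed = 3)
  expect_identical(nrow(tissue_receptor_table(tis1)), 1L)
})

test_that("fixture generation is deterministic: same seed, byte-identical JSON", {
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_tissue(generate_fixture_tissue(seed = 5), f1)
  write_tissue(generate_fixture_tissue(seed = 5), f2)
  expect_identical(readLines(f1), readLines(f2))
  f3 <- tempfile(fileext = ".json")
  write_tissue(generate_fixture_tissue(seed = 6), f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("fixture cells are ordered by centroid x and receptors uniformly spaced", {
  tis <- generate_fixture_tissue(seed = 8)
  cx <- vapply(tis$cells, function(cl) uptakesim:::polygon_centroid(cl$boundary)[1],
               numeric(1))
  expect_false(is.unsorted(cx))
  # equal arc spacing: successive receptor gaps within one vertex interval
  for (cl in tis$cells) {
    r <- cl$receptors[cl$receptors$capacity == max(cl$receptors$capacity), ]
    gaps <- sqrt(diff(r$x)^2 + diff(r$y)^2)
    expect_lt(stats::sd(gaps) / mean(gaps), 0.25)
  }
})

test_that("tissue JSON round trip reproduces all fields exactly", {
  tis <- default_tissue()
  f <- tempfile(fileext = ".json")
  write_tissue(tis, f)
  back <- read_tissue(f)
  expect_equal(back$width, tis$width)
  expect_equal(back$height, tis$height)
  expect_length(back$cells, length(tis$cells))
  for (k in seq_along(tis$cells)) {
    expect_identical(back$cells[[k]]$id, as.integer(tis$cells[[k]]$id))
    expect_equal(uptakesim:::polygon_ring(back$cells[[k]]$boundary),
                 uptakesim:::polygon_ring(tis$cells[[k]]$boundary),
                 tolerance = 0)
    expect_equal(back$cells[[k]]$receptors$x, tis$cells[[k]]$receptors$x,
                 tolerance = 0)
    expect_equal(back$cells[[k]]$receptors$affinity,
                 tis$cells[[k]]$receptors$affinity, tolerance = 0)
  }
})

test_that("validation rejects off-boundary receptors, duplicate ids, bad capacity, overlaps", {
  tis <- default_tissue()

  bad <- tis
  bad$cells[[2]]$receptors$x[1] <- bad$cells[[2]]$receptors$x[1] + 1 # 1 um off
  expect_error(validate_tissue(bad), "cell 2, receptor 1")

  bad <- tis
  bad$cells[[2]]$id <- 1L
  expect_error(validate_tissue(bad), "duplicate cell id")

  bad <- tis
  bad$cells[[1]]$receptors$capacity[3] <- 0
  expect_error(validate_tissue(bad), "capacity")

  bad <- tis
  # translate cell 2 onto cell 1
  c1 <- uptakesim:::polygon_centroid(bad$cells[[1]]$boundary)
  c2 <- uptakesim:::polygon_centroid(bad$cells[[2]]$boundary)
  shift <- c1 - c2
  bad$cells[[2]]$boundary <- sweep(uptakesim:::polygon_ring(bad$cells[[2]]$boundary),
                                   2, shift, "+")
  bad$cells[[2]]$receptors$x <- bad$cells[[2]]$receptors$x + shift[1]
  bad$cells[[2]]$receptors$y <- bad$cells[[2]]$receptors$y + shift[2]
  # ordering may also break; overlap or ordering must be caught either way
  expect_error(validate_tissue(bad))
})

test_that("point_in_cell matches a ray-casting oracle on 1e4 random points", {
  tis <- default_tissue()
  polys <- uptakesim:::tissue_cell_polygons(tis)
  set.seed(99)
  pts <- cbind(runif(10000, 0, tis$width), runif(10000, 0, tis$height))
  got <- point_in_cell(pts, tis)
  want <- rep(NA_integer_, nrow(pts))
  for (k in seq_len(nrow(pts))) {
    for (l in seq_along(polys)) {
      if (oracle_point_in_polygon(pts[k, ], polys[[l]])) { want[k] <- l; break }
    }
  }
  expect_identical(got, want)
  # centroids are inside their own cells; boundary points are outside
  for (l in seq_along(tis$cells)) {
    ctr <- uptakesim:::polygon_centroid(tis$cells[[l]]$boundary)
    expect_identical(point_in_cell(ctr, tis), l)
    r1 <- unlist(tis$cells[[l]]$receptors[1, c("x", "y")])
    expect_true(is.na(point_in_cell(r1, tis)))
  }
})

test_that("segment_crosses_membrane matches an all-edges oracle on 1e4 segments", {
  tis <- default_tissue()
  polys <- uptakesim:::tissue_cell_polygons(tis)
  set.seed(123)
  n <- 10000
  p0 <- cbind(runif(n, 0, tis$width), runif(n, 0, tis$height))
  p1 <- p0 + matrix(rnorm(2 * n, sd = 8), ncol = 2)
  got <- segment_crosses_membrane(p0, p1, tis)
  want <- logical(n)
  for (k in seq_len(n)) {
    hit <- FALSE
    for (poly in polys) {
      m <- nrow(poly)
      jj <- c(2:m, 1)
      for (e in seq_len(m)) {
        if (uptakesim:::segments_intersect(p0[k, ], p1[k, ],
                                           poly[e, ], poly[jj[e], ])) {
          hit <- TRUE; break
        }
      }
      if (!hit && oracle_point_in_polygon(p1[k, ], poly) &&
          !uptakesim:::cpp_on_any_boundary(rbind(p1[k, ]), list(poly), 1e-9)[1])
        hit <- TRUE
      if (hit) break
    }
    want[k] <- hit
  }
  expect_identical(as.logical(got), want)
  # degenerate segment and a move into a centroid
  ctr <- uptakesim:::polygon_centroid(tis$cells[[3]]$boundary)
  expect_false(segment_crosses_membrane(c(1, 1), c(1, 1), tis))
  expect_true(segment_crosses_membrane(c(1, 1), ctr, tis))
})

test_that("placement failure reports the seed", {
  expect_error(generate_fixture_tissue(width = 30, height = 30, n_cells = 8,
                                       seed = 4, max_attempts = 5),
               "seed 4")
})
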