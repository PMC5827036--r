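test_that("candidate search is strict in r_min and matches exhaustive search", {
  tis <- default_tissue()
  rec <- tissue_receptor_table(tis)
  r_min <- 0.8

  # exactly at a receptor -> that receptor
  hit <- find_candidate_receptor(c(rec$x[10], rec$y[10]), tis, r_min)
  expect_identical(hit$row[1], 10L)

  # at distance exactly r_min -> none (strict inequality)
  p <- c(rec$x[10] + r_min, rec$y[10])
  d_others <- sqrt((rec$x - p[1])^2 + (rec$y - p[2])^2)
  if (min(d_others[-10]) >= r_min)
    expect_true(is.na(find_candidate_receptor(p, tis, r_min)$row[1]))

  # 1e4 random points vs the brute-force oracle
  set.seed(7)
  pts <- cbind(runif(1e4, 0, tis$width), runif(1e4, 0, tis$height))
  got <- find_candidate_receptor(pts, tis, r_min)$row
  want <- vapply(seq_len(nrow(pts)), function(k) {
    oracle_nearest_receptor(pts[k, ], rec, r_min)
  }, integer(1))
  expect_identical(got, want)
})

test_that("binding respects saturation and is Bernoulli in the affinity", {
  expect_false(attempt_binding(affinity = 1, occupancy = 5, capacity = 5))
  set.seed(11)
  expect_true(all(replicate(50, attempt_binding(1, 0, 5))))
  # empirical rate at affinity 0.01 within 3 binomial standard errors
  n <- 1e4; a <- 0.01
  hits <- sum(replicate(n, attempt_binding(a, 0, 5)))
  expect_lt(abs(hits / n - a), 3 * sqrt(a * (1 - a) / n))
})

test_that("the move rule follows clearance > binding > membrane > acceptance", {
  tis <- square_cell_tissue()
  params <- binding_params(K_A = 100, r_min = 1)
  occ <- rep(0L, 4)

  # proposal within r_min of an unsaturated affinity-1 receptor -> bound at it
  res <- resolve_move(c(13.5, 14), c(14.8, 14.8), tis, params, t = 5, occ)
  expect_identical(res$state, "bound")
  expect_equal(res$position, c(15, 15))
  expect_identical(res$occupancy[1], 1L)
  expect_equal(res$bind_time, 5)

  # proposal inside the cell, away from receptors -> position unchanged
  res <- resolve_move(c(20, 13), c(20, 20), tis, params, t = 5, occ)
  expect_identical(res$state, "free")
  expect_equal(res$position, c(20, 13))

  # open interstitium -> proposal accepted
  res <- resolve_move(c(5, 5), c(6, 6), tis, params, t = 5, occ)
  expect_identical(res$state, "free")
  expect_equal(res$position, c(6, 6))

  # beyond the clearance edge -> cleared even if a receptor were in range
  res <- resolve_move(c(39, 20), c(41, 20), tis, params, t = 5, occ)
  expect_identical(res$state, "cleared")

  # saturated receptor never binds regardless of affinity
  res <- resolve_move(c(13.5, 14), c(14.8, 14.8), tis, params, t = 5,
                      rep(5L, 4))
  expect_false(res$state == "bound")
})

test_that("internalization waits for the residency time, then places inside the cell", {
  tis <- square_cell_tissue()
  mol <- data.frame(x = 15, y = 15, state = 2L, bind_t = 0,
                    internalize_t = NA_real_, receptor = 1L)
  # one second early: still bound
  out <- internalize_due(mol, tis, t = 1199, residency_s = 1200)
  expect_identical(out$state, 2L)
  # at the threshold: internalized, strictly inside the cell
  set.seed(3)
  out <- internalize_due(mol, tis, t = 1200, residency_s = 1200)
  expect_identical(out$state, 3L)
  expect_identical(point_in_cell(c(out$x, out$y), tis), 1L)
})

test_that("internalized positions are uniform over the cell interior", {
  tis <- square_cell_tissue()
  set.seed(5)
  pts <- uptakesim:::cpp_sample_in_polygon(
    uptakesim:::tissue_cell_polygons(tis)[[1]], 1000L)
  # chi-square over a 4x4 grid of equal-area bins of the 10x10 square
  bx <- cut(pts[, 1], seq(15, 25, length.out = 5), include.lowest = TRUE)
  by <- cut(pts[, 2], seq(15, 25, length.out = 5), include.lowest = TRUE)
  tab <- table(bx, by)
  p <- stats::chisq.test(as.vector(tab), p = rep(1 / 16, 16))$p.value
  expect_gt(p, 0.01)
})
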