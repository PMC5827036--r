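test_that("molecule conservation holds exactly at every recorded time", {
  tis <- default_tissue()
  s <- run_simulation(quick_config(), tis)
  with(s$census, expect_identical(released,
                                  free + bound + internalized + cleared))
  expect_identical(s$census$released[nrow(s$census)], 300L)
})

test_that("runs are bitwise reproducible for a fixed seed", {
  tis <- default_tissue()
  s1 <- run_simulation(quick_config(), tis)
  s2 <- run_simulation(quick_config(), tis)
  expect_identical(s1$tissue_saturation, s2$tissue_saturation)
  expect_identical(s1$receptor_occupancy, s2$receptor_occupancy)
  expect_identical(s1$molecules, s2$molecules)
  s3 <- run_simulation(quick_config(seed = 43), tis)
  expect_false(identical(s1$molecules, s3$molecules))
})

test_that("cumulative saturation is monotone and occupancy within capacity", {
  tis <- default_tissue()
  s <- run_simulation(quick_config(K_A = 10), tis)
  expect_true(all(diff(s$tissue_saturation) >= 0))
  expect_true(all(apply(s$per_cell_saturation, 2, function(x) all(diff(x) >= 0))))
  caps <- tissue_receptor_table(tis)$capacity
  expect_true(all(sweep(s$receptor_occupancy, 2, caps, "<=")))
  expect_true(all(s$per_cell_saturation >= 0 & s$per_cell_saturation <= 100))
})

test_that("zero-affinity ligand produces zero saturation", {
  tis <- generate_fixture_tissue(affinity = 0, seed = 2)
  s <- run_simulation(quick_config(), tis)
  expect_true(all(s$tissue_saturation == 0))
})

test_that("free molecules never sit strictly inside a cell", {
  tis <- default_tissue()
  s <- run_simulation(quick_config(K_A = 10, D = 2.5e-4), tis)
  mol <- s$molecules
  free <- mol[mol$state == 1L, ]
  if (nrow(free) > 0)
    expect_true(all(is.na(point_in_cell(cbind(free$x, free$y), tis))))
  intern <- mol[mol$state == 3L, ]
  expect_true(all(!is.na(point_in_cell(cbind(intern$x, intern$y), tis))))
})

test_that("replicates: identical seeds give sd 0; means of monotone series are monotone", {
  tis <- default_tissue()
  cfg <- quick_config()
  r <- run_replicates(cfg, tis, n = 3, seeds = c(42, 42, 42))
  expect_true(all(r$sd_tissue_saturation == 0))
  r2 <- run_replicates(cfg, tis, n = 3)
  expect_true(all(diff(r2$mean_tissue_saturation) >= 0))
})

test_that("sweep produces one block per grid point and resumes from disk", {
  tis <- default_tissue()
  grid <- expand.grid(D = c(2.5e-5, 2.5e-4), K_A = 100, L_total = 300,
                      scheme = "fast", stringsAsFactors = FALSE)
  out <- tempfile()
  sw <- sweep_simulations(grid, tis, n = 2, base_config = quick_config(),
                          out_dir = out)
  expect_identical(nrow(sw), 2L * length(quick_config()$record_times_min))
  files <- list.files(out, pattern = "csv$")
  expect_length(files, 2)
  # resumability: tamper with one checkpoint; rerun must pick it up unchanged
  tampered <- file.path(out, files[1])
  d <- utils::read.csv(tampered, check.names = FALSE)
  d$mean_saturation <- -1
  utils::write.csv(d, tampered, row.names = FALSE)
  sw2 <- sweep_simulations(grid, tis, n = 2, base_config = quick_config(),
                           out_dir = out)
  expect_true(any(sw2$mean_saturation == -1)) # reread, not recomputed
  single <- sweep_simulations(grid[1, ], tis, n = 2,
                              base_config = quick_config())
  expect_identical(unique(single$D), grid$D[1])
})

test_that("the default study grid has 3 x 3 x 7 x 2 = 126 points", {
  expect_identical(nrow(default_sweep_grid()), 126L)
})

test_that("run outputs round-trip through the CSV writer with a manifest", {
  tis <- default_tissue()
  s <- run_simulation(quick_config(), tis)
  dir <- tempfile()
  tjson <- tempfile(fileext = ".json")
  write_tissue(tis, tjson)
  man <- write_series_csv(s, dir, tissue_path = tjson)
  expect_true(all(file.exists(file.path(dir, man$outputs))))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  pc <- utils::read.csv(file.path(dir, "per_cell_saturation.csv"),
                        check.names = FALSE)
  expect_equal(pc$tissue_saturation, s$tissue_saturation)
  man2 <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  expect_identical(man2$seed, 42L)
  expect_identical(man2$tissue_hash, unname(tools::md5sum(tjson)))
})
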