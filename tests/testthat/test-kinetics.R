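test_that("one-phase association recovers noiseless parameters exactly", {
  t <- c(1.5, 10, 20, 30, 45, 90, 180, 270, 360)
  truth <- list(B0 = 0, Bmax = 100, k = 0.02)
  B <- truth$B0 + (truth$Bmax - truth$B0) * (1 - exp(-truth$k * t))
  f <- fit_one_phase_association(t, B)
  expect_equal(f$B0, truth$B0, tolerance = 1e-6)
  expect_equal(f$Bmax, truth$Bmax, tolerance = 1e-6)
  expect_equal(f$k, truth$k, tolerance = 1e-6)
  expect_equal(f$r2, 1, tolerance = 1e-9)
  # with B0 pinned
  f0 <- fit_one_phase_association(t, B, fix_b0 = 0)
  expect_equal(f0$k, truth$k, tolerance = 1e-6)
})

test_that("a constant series is flagged unidentifiable", {
  f <- fit_one_phase_association(c(1, 2, 3, 4), rep(40, 4))
  expect_true(f$k_unidentifiable)
  expect_equal(f$B0, 40)
  expect_equal(f$Bmax, 40)
  expect_error(time_to_occupancy(f), "unidentifiable")
})

test_that("time_to_occupancy matches the closed form", {
  t <- seq(0, 300, by = 20)
  B <- 100 * (1 - exp(-0.02 * t))
  f <- fit_one_phase_association(t, B)
  expect_equal(time_to_occupancy(f, 0.9), log(10) / 0.02, tolerance = 1e-5)
  expect_equal(time_to_occupancy(f, 0.5), log(2) / 0.02, tolerance = 1e-5)
  expect_equal(time_to_occupancy(f, 1e-9), 0, tolerance = 1e-4)
})

test_that("rate recovery from noisy curves: median relative error under 10%", {
  t <- c(1.5, 10, 20, 30, 45, 90, 180, 270, 360)
  k_true <- 0.02
  set.seed(17)
  err <- replicate(100, {
    B <- 100 * (1 - exp(-k_true * t)) + rnorm(length(t), sd = 2)
    f <- fit_one_phase_association(t, B)
    abs(f$k - k_true) / k_true
  })
  expect_lt(median(err), 0.10)
})

test_that("Hill fit recovers noiseless parameters and halves at K_D", {
  L <- c(500, 1000, 1500, 2500, 5000, 7500, 10000)
  B <- 100 * L / (1500 + L) # h = 1
  f <- fit_specific_binding_linear(L, B)
  expect_equal(f$Bmax, 100, tolerance = 1e-6)
  expect_equal(f$K_D, 1500, tolerance = 1e-6)
  expect_equal(f$h, 1, tolerance = 1e-6)
  expect_equal(f$r2, 1, tolerance = 1e-9)
  expect_equal(f$predict(f$K_D), f$Bmax / 2, tolerance = 1e-8)
  # h = 1 Hill curve equals the rectangular hyperbola to machine precision
  expect_equal(f$predict(L), 100 * L / (1500 + L), tolerance = 1e-10)
  # steeper curve
  B2 <- 100 * L^2 / (3000^2 + L^2)
  f2 <- fit_specific_binding_linear(L, B2)
  expect_equal(f2$h, 2, tolerance = 1e-5)
  expect_equal(f2$K_D, 3000, tolerance = 1e-4)
})

test_that("log-dose sigmoid recovers noiseless parameters and its midpoint", {
  L <- c(500, 1000, 1500, 2500, 5000, 7500, 10000)
  lkd <- log10(1500)
  B <- 0 + (100 - 0) / (1 + 10^(lkd - log10(L)))
  f <- fit_specific_binding_log(L, B)
  expect_equal(f$B0, 0, tolerance = 1e-6)
  expect_equal(f$Bmax, 100, tolerance = 1e-6)
  expect_equal(f$K_D, 1500, tolerance = 1e-4)
  expect_equal(f$r2, 1, tolerance = 1e-9)
  expect_equal(f$predict(f$K_D), (f$B0 + f$Bmax) / 2, tolerance = 1e-8)
})

test_that("constant binding data are flagged unidentifiable", {
  L <- c(500, 1000, 2000, 4000)
  f <- fit_specific_binding_linear(L, rep(50, 4))
  expect_true(f$unidentifiable)
  f <- fit_specific_binding_log(L, rep(50, 4))
  expect_true(f$unidentifiable)
})

test_that("binding curves are monotone in dose and evaluated at a common t90", {
  # synthetic sweep table from known association curves
  t <- c(1.5, 10, 20, 30, 45, 90, 180, 270, 360)
  Ls <- c(500, 1000, 2500, 5000)
  rows <- lapply(Ls, function(l) {
    bmax <- 100 * l / (1500 + l)
    data.frame(D = 2.5e-5, K_A = 100, L_total = l, scheme = "slow",
               t_min = t, mean_saturation = bmax * (1 - exp(-0.03 * t)),
               sd_saturation = 0)
  })
  sw <- do.call(rbind, rows)
  bc <- build_binding_curve(sw, "slow", 100, 2.5e-5)
  expect_identical(bc$L, Ls)
  expect_true(all(diff(bc$B) > 0))
  expect_equal(attr(bc, "t_eval_min"), log(10) / 0.03, tolerance = 1e-4)
  # missing dose is reported by name
  expect_error(build_binding_curve(sw, "slow", 100, 2.5e-5,
                                   L_values = c(500, 750)), "750")
  # single dose: the point is its own fitted value at t90
  bc1 <- build_binding_curve(sw[sw$L_total == 5000, ], "slow", 100, 2.5e-5)
  expect_identical(nrow(bc1), 1L)
  expect_equal(bc1$B, (100 * 5000 / 6500) * 0.9, tolerance = 1e-6)
})
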