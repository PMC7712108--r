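test_that("parameter error measures follow their definitions", {
  expect_equal(unlist(parameter_errors(rep(2, 5), 2)),
               c(me = 0, rmse = 0, mae = 0))
  expect_equal(unlist(parameter_errors(c(1, 2, 3) + 0.4, c(1, 2, 3) * 0 + 2)),
               unlist(parameter_errors(c(1.4, 2.4, 3.4), 2)))
  expect_equal(unlist(parameter_errors(5 + c(1, 1, 1) * -0.3, 5)),
               c(me = -0.3, rmse = 0.3, mae = 0.3))
  expect_equal(unlist(parameter_errors(c(1, 3), 2)),
               c(me = 0, rmse = 1, mae = 1))
  expect_error(parameter_errors(numeric(0), 1), "estimates")
})

test_that("CDF distances detect offsets and respect their bounds", {
  spec <- baseline_spec("exponential", rate = 1)
  k <- 50
  truthH <- function(x) kth_power_cdf(x, spec, k)
  z <- cdf_distances(truthH, spec, k, s = 2000, seed = 1)
  expect_equal(unlist(z), c(d = 0, ad = 0, rsd = 0))
  # constant artificial shift: all three collapse to the offset
  off <- cdf_distances(function(x) truthH(x) + 0.01, spec, k,
                       s = 2000, seed = 1)
  expect_equal(unlist(off), c(d = 0.01, ad = 0.01, rsd = 0.01),
               tolerance = 1e-12)
  # a wrong estimate: |D| <= AD <= 1 and RSD <= 1
  wrong <- cdf_distances(function(x) pgumbel(x, 2, 0.5), spec, k,
                         s = 2000, seed = 2)
  expect_lte(abs(wrong$d), wrong$ad)
  expect_lte(wrong$ad, 1)
  expect_lte(wrong$rsd, 1)
  # grid evaluation points are supported too
  gridded <- cdf_distances(function(x) truthH(x) + 0.01, spec, k,
                           s = 500, points = "grid")
  expect_equal(gridded$ad, 0.01, tolerance = 1e-12)
})

test_that("the default study grid has the designed extent", {
  grid <- sim_grid(baseline_spec("gumbel"))
  expect_identical(nrow(grid$cells), 21L)
  expect_identical(nrow(grid$cells) * grid$reps, 2100L)
  m <- grid$cells$n * grid$cells$k
  expect_identical(range(m), c(20L, 128000L))
  expect_identical(sort(unique(grid$cells$n)), as.integer(2^(1:7)))
  expect_identical(sort(unique(grid$cells$k)), as.integer(10^(1:3)))
})

test_that("a smoke study emits a well-formed, coherent report", {
  grid <- sim_grid(baseline_spec("exponential"), n_values = c(2, 4),
                   k_values = 10, reps = 5)
  rep <- run_study(grid, cfg = tiny_cfg(seed = 31), s = 1000)
  expect_s3_class(rep, "bmb_error_report")
  expect_identical(nrow(rep$cells), 2L * 3L)     # 2 cells x 3 methods
  expect_identical(nrow(rep$replicates), 2L * 5L * 3L)
  expect_true(all(rep$cells$reps_ok == 5))
  # Jensen: RMSE >= |ME| and MAE >= |ME| for every cell, both error families
  with(rep$cells, {
    expect_true(all(mu_rmse >= abs(mu_me) - 1e-12))
    expect_true(all(sigma_rmse >= abs(sigma_me) - 1e-12))
    expect_true(all(sigma_mae >= abs(sigma_me) - 1e-12))
    expect_true(all(cdf_rmse >= abs(cdf_me) - 1e-12))
    expect_true(all(cdf_mae >= abs(cdf_me) - 1e-12))
  })
  # reproducible under the master seed
  rep2 <- run_study(grid, cfg = tiny_cfg(seed = 31), s = 1000)
  expect_equal(rep$cells, rep2$cells)
  # tidy long format
  long <- tidy(rep)
  expect_setequal(unique(long$measure), c("me", "rmse", "mae"))
  expect_setequal(unique(long$quantity), c("mu", "sigma", "cdf"))
})

test_that("the contaminated-normal scenario ranks the methods as expected", {
  rep <- mixture_scenario(n_values = c(2, 64), k = 100, reps = 25,
                          cfg = quick_cfg(seed = 9), s = 2000)
  mae <- dplyr::select(rep$cells, n, method, cdf_mae)
  expect_identical(nrow(mae), 2L * 3L)           # one MAE per (method, n)
  at <- function(nn, mm) mae$cdf_mae[mae$n == nn & mae$method == mm]
  # scarce extremes: the informative-proposal method beats the
  # maxima-only fit
  expect_lt(at(2, "IBDM"), at(2, "MHM"))
  # plentiful extremes under misspecification: IBDM beats BDM, whose
  # misspecification bias does not shrink with n
  expect_lt(at(64, "IBDM"), at(64, "BDM"))
})
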