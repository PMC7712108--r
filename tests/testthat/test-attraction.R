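test_that("normalizing constants match the closed forms", {
  e <- norm_constants(baseline_spec("exponential", rate = 2), 100)
  expect_equal(e$a, 0.5, tolerance = 1e-12)
  expect_equal(e$b, 0.5 * log(100), tolerance = 1e-12)

  g <- norm_constants(baseline_spec("gumbel", mu = 0, sigma = 4), 1000)
  expect_equal(g$a, 4)
  expect_equal(g$b, 4 * log(1000), tolerance = 1e-12)

  n <- norm_constants(baseline_spec("normal"), 1000)
  expect_equal(n$a, (2 * log(1000))^(-1 / 2), tolerance = 1e-10)
  # b_N = sqrt(2 ln k) - (ln ln k + ln 4 pi) / (2 sqrt(2 ln k))
  expect_equal(n$b, 3.11647, tolerance = 2e-5)
  expect_equal(n$a, 0.26904, tolerance = 2e-5)

  r <- norm_constants(baseline_spec("rayleigh", sigma = 2), 100)
  expect_equal(r$b, 2 * sqrt(2 * log(100)), tolerance = 1e-12)
  expect_equal(r$a * r$b, 4, tolerance = 1e-12)  # a = sigma^2 / b

  expect_error(norm_constants(baseline_spec("normal_mixture"), 100),
               "closed")
  expect_error(norm_constants(baseline_spec("normal"), 1), "k")
})

test_that("affine transfer rescales constants and reproduces family rows", {
  base <- structure(list(a = 1, b = 0, k = 10, family = "test"),
                    class = "norm_constants")
  tr <- affine_transfer(base, 5, 2)
  expect_equal(c(tr$a, tr$b), c(2, 5))
  id <- affine_transfer(base, 0, 1)
  expect_equal(c(id$a, id$b), c(1, 0))
  expect_error(affine_transfer(base, 0, -1), "sigma")

  # normal(mu, sigma) constants = affine transfer of standard-normal ones
  for (k in c(10, 1000)) {
    std <- norm_constants(baseline_spec("normal"), k)
    got <- norm_constants(baseline_spec("normal", mean = -2, sd = 3), k)
    tr <- affine_transfer(std, -2, 3)
    expect_equal(c(got$a, got$b), c(tr$a, tr$b), tolerance = 1e-12)
  }
  # lognormal row is the exp change of variables of the standard-normal row:
  # b = e^(mu + sigma b_N), a = sigma a_N b
  std <- norm_constants(baseline_spec("normal"), 1000)
  ln <- norm_constants(baseline_spec("lognormal", meanlog = 1, sdlog = 0.5),
                       1000)
  expect_equal(ln$b, exp(1 + 0.5 * std$b), tolerance = 1e-12)
  expect_equal(ln$a, std$a * 0.5 * ln$b, tolerance = 1e-12)
})

test_that("b_k is the 1 - 1/k baseline quantile", {
  # exact for the exponential family
  for (k in c(10, 100, 1e4)) {
    spec <- baseline_spec("exponential", rate = 0.7)
    expect_equal(norm_constants(spec, k)$b, qbaseline(1 - 1 / k, spec),
                 tolerance = 1e-10)
  }
  # the gumbel family uses the exact-closure constants, which agree with
  # the quantile only asymptotically (difference O(sigma/k)); the closure
  # itself is exact at every k
  spec <- baseline_spec("gumbel", mu = 1, sigma = 2)
  for (k in c(100, 1e4)) {
    cst <- norm_constants(spec, k)
    expect_lt(abs(cst$b - qbaseline(1 - 1 / k, spec)), 2 * 2 / k)
    xs <- seq(-3, 25, length.out = 40)
    expect_equal(kth_power_cdf(xs, spec, k), pgumbel(xs, cst$b, cst$a),
                 tolerance = 1e-12)
  }
})

test_that("von Mises h matches the tail behaviour of each family", {
  # exponential: h constant = 1/lambda
  spec <- baseline_spec("exponential", rate = 2)
  expect_equal(von_mises_h(spec, c(0, 1, 50)), rep(0.5, 3),
               tolerance = 1e-10)
  # standard normal at t = 5: Mills ratio regime, h ~ 1/t within 5%
  expect_lt(abs(von_mises_h(baseline_spec("normal"), 5) - 1 / 5), 0.05 / 5)
  # deep in the tail it must still evaluate (log-space stability)
  expect_true(is.finite(von_mises_h(baseline_spec("normal"), 40)))
  # gumbel: h -> sigma for large t
  expect_equal(von_mises_h(baseline_spec("gumbel", sigma = 1), 30), 1,
               tolerance = 1e-6)
  expect_error(von_mises_h(baseline_spec("exponential"), -1), "support")
})

test_that("the normalized maxima law approaches its Gumbel limit", {
  # exact closure for a gumbel baseline at every block size
  for (k in c(10, 1000)) {
    expect_lt(convergence_gap(baseline_spec("gumbel", sigma = 2), k), 1e-12)
  }
  # monotone decay along k for every family with closed constants
  ks <- 10^(1:4)
  fams <- list(baseline_spec("exponential"), baseline_spec("normal"),
               baseline_spec("rayleigh"), baseline_spec("lognormal"),
               baseline_spec("gamma", shape = 2, scale = 1))
  for (spec in fams) {
    gaps <- vapply(ks, function(k) convergence_gap(spec, k), numeric(1))
    expect_true(all(diff(gaps) <= 1e-12),
                info = paste("family", spec$family))
  }
  expect_lt(convergence_gap(baseline_spec("exponential"), 1000),
            convergence_gap(baseline_spec("exponential"), 10))
  # normal convergence is notoriously slow: still 3% off at k = 1e6
  expect_lt(convergence_gap(baseline_spec("normal"), 1e6), 0.05)
})
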