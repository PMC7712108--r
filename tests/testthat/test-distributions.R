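test_that("Gumbel CDF has the closed form and its limits", {
  expect_equal(pgumbel(0, 0, 1), exp(-1), tolerance = 1e-12)
  expect_equal(pgumbel(27.63, 27.63, 4), exp(-1), tolerance = 1e-12)
  expect_equal(pgumbel(1e8, 0, 1), 1)
  expect_equal(pgumbel(-1e8, 0, 1), 0)
  # strictly increasing
  xs <- seq(-5, 15, length.out = 50)
  expect_true(all(diff(pgumbel(xs, 2, 3)) > 0))
  expect_error(pgumbel(NaN), "non-finite")
  expect_error(pgumbel(0, 0, -1), "sigma")
})

test_that("Gumbel CDF matches numeric integration of the density", {
  for (p in list(c(0, 1), c(27.63, 4), c(-3, 0.5))) {
    got <- pgumbel(p[1] + 1.2, p[1], p[2])
    ref <- integrate(function(t) dgumbel(t, p[1], p[2]),
                     -Inf, p[1] + 1.2, rel.tol = 1e-10)$value
    expect_equal(got, ref, tolerance = 1e-8)
  }
})

test_that("log-likelihood equals the log product of pointwise densities", {
  # single point at the location, unit scale: Delta = -1
  expect_equal(gumbel_loglik(0, 0, 1), -1, tolerance = 1e-12)
  expect_equal(gumbel_loglik(c(0, 0), 0, 2),
               sum(dgumbel(c(0, 0), 0, 2, log = TRUE)), tolerance = 1e-12)
  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(sample(1:30, 1), sd = 5)
    mu <- rnorm(1); sigma <- rexp(1) + 0.1
    expect_equal(gumbel_loglik(x, mu, sigma),
                 sum(dgumbel(x, mu, sigma, log = TRUE)), tolerance = 1e-10)
  }
  expect_error(gumbel_loglik(1:3, 0, 0), "sigma")
  expect_error(gumbel_loglik(numeric(0), 0, 1), "at least one")
})

test_that("baseline sampling is reproducible and has the right moments", {
  spec <- baseline_spec("exponential", rate = 1)
  y <- sample_baseline(spec, 1e6, seed = 7)
  expect_equal(sample_baseline(spec, 1e6, seed = 7), y)   # determinism
  expect_lt(abs(mean(y) - 1), 3 / sqrt(1e6))              # LLN
  mix <- baseline_spec("normal_mixture")
  z <- sample_baseline(mix, 1e6, seed = 8)
  # E[Y] = 0.9 * 0 + 0.1 * 1 under the component-mixture reading
  expect_lt(abs(mean(z) - 0.1), 3 * sd(z) / sqrt(1e6))
  expect_error(baseline_spec("weibull"), "arg")
  expect_error(sample_baseline(spec, 0), ">= 1")
})

test_that("the literal-sum mixture variant collapses to a single normal", {
  spec <- baseline_spec("normal_mixture", as_sum = TRUE)
  # 0.9 N(0,1) + 0.1 N(1,1.5) as a sum: N(0.1, sqrt(0.81 + 0.0225))
  expect_equal(pbaseline(0.5, spec),
               pnorm(0.5, 0.1, sqrt(0.81 + 0.0225)), tolerance = 1e-12)
  y <- sample_baseline(spec, 2e5, seed = 3)
  expect_lt(abs(mean(y) - 0.1), 3 * sd(y) / sqrt(2e5))
})

test_that("block maxima are per-block maxima over consecutive blocks", {
  expect_equal(block_maxima(c(1, 3, 2, 5), 2), c(3, 5))
  y <- rnorm(30)
  expect_equal(block_maxima(y, 1), y)
  expect_length(block_maxima(rnorm(20), 10), 2)
  expect_error(block_maxima(rnorm(7), 3), "m = 7.*k = 3")
  # against a direct split-based evaluation
  y <- rnorm(60)
  ref <- vapply(split(y, rep(1:12, each = 5)), max, numeric(1))
  expect_equal(block_maxima(y, 5), unname(ref))
})

test_that("kth power CDF matches the maxima law", {
  spec <- baseline_spec("exponential", rate = 1)
  xs <- c(0.5, 2, 7)
  expect_equal(kth_power_cdf(xs, spec, 1), pbaseline(xs, spec))
  # gumbel closure: F^k is a Gumbel with shifted location
  g <- baseline_spec("gumbel", mu = 0, sigma = 3)
  expect_equal(kth_power_cdf(xs, g, 50), pgumbel(xs, 3 * log(50), 3),
               tolerance = 1e-12)
  # exponential at ln k: (1 - 1/k)^k -> e^-1
  for (k in c(10, 1000)) {
    expect_equal(kth_power_cdf(log(k), spec, k), (1 - 1 / k)^k,
                 tolerance = 1e-12)
  }
  expect_lt(abs(kth_power_cdf(log(1e6), spec, 1e6) - exp(-1)), 1e-6)
})

test_that("empirical block maxima follow the kth power CDF", {
  set.seed(21)
  for (spec in list(baseline_spec("exponential"),
                    baseline_spec("normal"),
                    baseline_spec("normal_mixture"))) {
    k <- 20
    n <- 4000
    x <- block_maxima(rbaseline(n * k, spec), k)
    ks <- ks_distance(x, function(t) kth_power_cdf(t, spec, k))
    expect_lt(ks, 3 / sqrt(n))
  }
})

test_that("mixture quantile inverts the mixture CDF", {
  spec <- baseline_spec("normal_mixture")
  p <- c(0.01, 0.3, 0.9, 0.999)
  expect_equal(pbaseline(qbaseline(p, spec), spec), p, tolerance = 1e-8)
})
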