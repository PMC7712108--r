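# Shared oracles and utilities, independent of the implementation paths
# they check.

# Kolmogorov sup-distance between a sample and a CDF
ks_distance <- function(draws, cdf) {
  s <- sort(draws)
  n <- length(s)
  u <- cdf(s)
  max(abs(u - (seq_len(n) - 1) / n), abs(u - seq_len(n) / n))
}

# unnormalized log conditional posterior of mu (sigma fixed): Gumbel
# likelihood times the Gumbel location prior, assembled from densities
# rather than the closed-form ratio
oracle_logcond_mu <- function(x, mu, sigma, priors) {
  gumbel_loglik(x, mu, sigma) +
    dgumbel(mu, priors$mu0, priors$sigma0, log = TRUE)
}

# unnormalized log conditional posterior of sigma (mu fixed): likelihood
# times the Rayleigh scale prior
oracle_logcond_sigma <- function(x, sigma, mu, priors) {
  gumbel_loglik(x, mu, sigma) +
    log(sigma) - sigma^2 / (2 * priors$lambda0^2)
}

# normalized grid posterior: returns the CDF on the grid (trapezoid rule)
grid_posterior_cdf <- function(grid, log_density) {
  ld <- log_density - max(log_density)
  d <- exp(ld)
  h <- diff(grid)
  cum <- c(0, cumsum((d[-1] + d[-length(d)]) / 2 * h))
  cum / cum[length(cum)]
}

# bare chain holding given draws, for transform tests
new_chain_for_test <- function(draws, family) {
  n <- length(draws[[1]])
  ch <- blockmaxbayes:::new_bmb_chain(
    draws, acceptance = c(x = 0.5),
    config = chain_config(0, 1, n), method = "test")
  ch$info$family <- family
  ch
}

# reduced protocols for quick runs
quick_cfg <- function(seed = NULL) chain_config(500, 2, 500, seed = seed)
tiny_cfg <- function(seed = NULL) chain_config(200, 1, 300, seed = seed)
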