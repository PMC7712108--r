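#' Conjugate hyperparameters for the exponential baseline
#'
#' Gamma(`alpha0`, `beta0`) prior on the exponential rate
#' \eqn{\lambda_b}: \eqn{\pi(\lambda_b) \propto \lambda_b^{\alpha_0 - 1}
#' e^{-\beta_0 \lambda_b}}. The default (0.01, 0.01) is vague: the data
#' dominate once a couple of dozen observations are available.
#'
#' @param alpha0,beta0 positive shape and rate.
#' @return object of class `conjugate_hyper_exp`.
#' @export
conjugate_hyper_exp <- function(alpha0 = 0.01, beta0 = 0.01) {
  if (alpha0 <= 0 || beta0 <= 0) abort("`alpha0`, `beta0` must be > 0.")
  structure(list(alpha0 = alpha0, beta0 = beta0),
            class = "conjugate_hyper_exp")
}

#' Conjugate hyperparameters for the normal baseline
#'
#' Normal prior on the mean with precision multiplier `kappa0`
#' (\eqn{\mu_b \mid \sigma_b^2 \sim N(\mu_0, \sigma_b^2/\kappa_0)}) and an
#' inverse-gamma(`alpha0`, `beta0`) prior on the variance. `kappa0` plays
#' the role of a prior pseudo-sample size.
#'
#' @param mu0 prior mean centre.
#' @param kappa0 positive precision multiplier.
#' @param alpha0,beta0 positive inverse-gamma shape and scale.
#' @return object of class `conjugate_hyper_norm`.
#' @export
conjugate_hyper_norm <- function(mu0 = 0, kappa0 = 0.01,
                                 alpha0 = 0.01, beta0 = 0.01) {
  if (kappa0 <= 0 || alpha0 <= 0 || beta0 <= 0) {
    abort("`kappa0`, `alpha0`, `beta0` must be > 0.")
  }
  structure(list(mu0 = mu0, kappa0 = kappa0, alpha0 = alpha0, beta0 = beta0),
            class = "conjugate_hyper_norm")
}

#' Baseline posterior for exponential data
#'
#' The Gamma prior is conjugate: with all `m` baseline values,
#' \deqn{\lambda_b \mid y \sim
#'   \Gamma\!\left(\alpha_0 + m,\; \beta_0 + \sum_j y_j\right),}
#' so the "Gibbs" sampler degenerates to exact i.i.d. sampling. The full
#' raw chain is drawn and the burn-in/thinning protocol applied, keeping
#' the bookkeeping identical across methods.
#'
#' @param y non-negative baseline sample.
#' @param hyper a [conjugate_hyper_exp()].
#' @param cfg a [chain_config()].
#' @return a `bmb_chain` with parameter `lambda`; `info` records the exact
#'   posterior shape and rate.
#' @examples
#' y <- sample_baseline(baseline_spec("exponential"), 200, seed = 1)
#' coef(bdm_exponential(y, cfg = chain_config(100, 1, 500, seed = 1)))
#' @export
bdm_exponential <- function(y, hyper = conjugate_hyper_exp(),
                            cfg = chain_config()) {
  if (length(y) < 1) abort("`y` must be non-empty.")
  if (any(y < 0)) abort("exponential baseline data must be non-negative.")
  shape <- hyper$alpha0 + length(y)
  rate <- hyper$beta0 + sum(y)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  raw <- rgamma(raw_iterations(cfg), shape = shape, rate = rate)
  new_bmb_chain(list(lambda = apply_protocol(raw, cfg)),
                acceptance = c(lambda = 1),
                config = cfg, method = "BDM",
                info = list(family = "exponential", hyper = hyper,
                            posterior = c(shape = shape, rate = rate),
                            m = length(y)))
}

#' Baseline posterior for normal data
#'
#' Two-block Gibbs sampler alternating the conjugate conditionals
#' \deqn{\mu_b \mid y, \sigma_b^2 \sim
#'  N\!\left(\frac{\kappa_0\mu_0 + \sum_j y_j}{\kappa_0 + m},
#'           \frac{\sigma_b^2}{\kappa_0 + m}\right), \qquad
#'  \sigma_b^2 \mid y, \mu_b \sim
#'  \mathrm{InvGamma}\!\left(\frac{m}{2} + \alpha_0,
#'   \beta_0 + \tfrac12\sum_j (y_j - \mu_b)^2\right).}
#' Sufficient statistics are precomputed, so each sweep is O(1).
#'
#' @param y baseline sample, `length(y) >= 2`, non-constant.
#' @param hyper a [conjugate_hyper_norm()].
#' @param cfg a [chain_config()].
#' @return a `bmb_chain` with parameters `mu` (baseline mean) and `sigma`
#'   (baseline standard deviation).
#' @export
bdm_normal <- function(y, hyper = conjugate_hyper_norm(),
                       cfg = chain_config()) {
  m <- length(y)
  if (m < 2) abort("need at least 2 baseline values.")
  if (var(y) == 0) abort("baseline data have zero variance.")
  sy <- sum(y)
  ssy <- sum(y^2)
  k0 <- hyper$kappa0
  post_mean_num <- k0 * hyper$mu0 + sy
  post_prec <- k0 + m
  shape <- m / 2 + hyper$alpha0
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n_raw <- raw_iterations(cfg)
  mu_raw <- numeric(n_raw)
  s2_raw <- numeric(n_raw)
  mu <- mean(y)
  s2 <- var(y)
  for (j in seq_len(n_raw)) {
    mu <- rnorm(1, post_mean_num / post_prec, sqrt(s2 / post_prec))
    rate <- hyper$beta0 + 0.5 * (ssy - 2 * mu * sy + m * mu^2)
    s2 <- 1 / rgamma(1, shape = shape, rate = rate)
    mu_raw[j] <- mu
    s2_raw[j] <- s2
  }
  new_bmb_chain(list(mu = apply_protocol(mu_raw, cfg),
                     sigma = sqrt(apply_protocol(s2_raw, cfg))),
                acceptance = c(mu = 1, sigma = 1),
                config = cfg, method = "BDM",
                info = list(family = "normal", hyper = hyper, m = m))
}

#' Baseline posterior for Gumbel data
#'
#' For a Gumbel baseline the block maxima are again exactly Gumbel, so the
#' Metropolis--Hastings machinery of [run_mhm()] applies unchanged to the
#' *whole* baseline sample `y` — that is the Baseline Distribution Method
#' in the Gumbel case. The returned chain carries the baseline parameters;
#' [transform_to_blockmax()] moves the draws to the block-maxima scale.
#'
#' @param y baseline sample (all `m = n * k` values).
#' @param priors,scales,cfg as in [run_mhm()].
#' @param ... passed on to [run_mhm()].
#' @return a `bmb_chain` with parameters `mu`, `sigma` (baseline scale).
#' @export
bdm_gumbel <- function(y, priors = NULL, scales = NULL,
                       cfg = chain_config(), ...) {
  chain <- run_mhm(y, priors = priors, scales = scales, cfg = cfg, ...)
  chain$method <- "BDM"
  chain$info$family <- "gumbel"
  chain
}

#' Map baseline draws to the block-maxima Gumbel scale
#'
#' Applies, draw by draw, the normalizing-constant relation of the family
#' at block size `k`:
#' * gumbel: \eqn{(\mu_b, \sigma_b) \to (\mu_b + \sigma_b \ln k, \sigma_b)}
#'   (exact)
#' * exponential: \eqn{\lambda_b \to (\ln k / \lambda_b, 1/\lambda_b)}
#' * normal: \eqn{(\mu_b, \sigma_b) \to (\mu_b + \sigma_b b_N,
#'   \sigma_b a_N)} with the standard-normal asymptotic constants
#'
#' Chain length and draw order are preserved.
#'
#' @param chain a `bmb_chain` from one of the baseline samplers.
#' @param family baseline family tag (taken from the chain's `info` when
#'   omitted).
#' @param k block size.
#' @return a `bmb_chain` with parameters `mu`, `sigma` on the block-maxima
#'   scale.
#' @export
transform_to_blockmax <- function(chain, family = NULL, k) {
  stopifnot(inherits(chain, "bmb_chain"))
  if (is.null(family)) family <- chain$info$family
  if (is.null(family)) abort("`family` not recorded in chain; supply it.")
  d <- chain$draws
  out <- switch(family,
    gumbel = list(mu = d$mu + d$sigma * log(k), sigma = d$sigma),
    exponential = list(mu = log(k) / d$lambda, sigma = 1 / d$lambda),
    normal = {
      std <- std_normal_constants(k)
      list(mu = d$mu + d$sigma * std[2], sigma = d$sigma * std[1])
    },
    abort(paste0("no closed-form block-maxima transform for family '",
                 family, "'."))
  )
  new_bmb_chain(out, acceptance = chain$acceptance, config = chain$config,
                method = chain$method,
                info = c(chain$info, list(k = k, transformed = TRUE)))
}

#' Point estimate of the baseline distribution from a chain
#'
#' Posterior means of the baseline parameters packaged as a
#' [baseline_spec()] — the estimator the error studies use.
#'
#' @param chain a baseline-scale `bmb_chain` (not yet transformed).
#' @param family baseline family tag (default: from the chain).
#' @return a [baseline_spec()].
#' @export
bdm_point_estimate <- function(chain, family = NULL) {
  if (is.null(family)) family <- chain$info$family
  est <- coef(chain)
  switch(family,
    gumbel = baseline_spec("gumbel", mu = est[["mu"]],
                           sigma = est[["sigma"]]),
    exponential = baseline_spec("exponential", rate = est[["lambda"]]),
    normal = baseline_spec("normal", mean = est[["mu"]], sd = est[["sigma"]]),
    abort(paste0("unsupported family '", family, "'."))
  )
}

#' Estimated block-maxima CDF under the Baseline Distribution Method
#'
#' The BDM estimate of the block-maxima distribution function is the k-th
#' power of the estimated baseline CDF, \eqn{H(x) = F(x; \hat\theta_b)^k},
#' with \eqn{\hat\theta_b} the posterior mean of the baseline parameters.
#' For a Gumbel baseline this is exactly the Gumbel CDF at the transformed
#' parameters.
#'
#' @param estimate a [baseline_spec()] holding the baseline point estimate
#'   (see [bdm_point_estimate()]).
#' @param k block size.
#' @return a function of one argument, the estimated CDF.
#' @export
bdm_estimate_cdf <- function(estimate, k) {
  force(estimate); force(k)
  function(x) kth_power_cdf(x, estimate, k)
}
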