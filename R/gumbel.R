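#' The Gumbel distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the Gumbel (type-I extreme value) distribution with location `mu` and
#' scale `sigma`,
#' \deqn{G(x; \mu, \sigma) = \exp\{-\exp[-(x - \mu)/\sigma]\}.}
#'
#' The Gumbel law is the limiting distribution of normalized block maxima for
#' baseline distributions with exponentially decaying tails (normal,
#' exponential, gamma, log-normal, Rayleigh, Gumbel itself).
#'
#' @param x,q numeric vector of quantiles.
#' @param p numeric vector of probabilities.
#' @param n number of draws.
#' @param mu location parameter.
#' @param sigma scale parameter, `> 0`.
#' @param log,log.p logical; if `TRUE`, densities/probabilities are returned
#'   on the log scale.
#' @param lower.tail logical; if `TRUE` (default), probabilities are
#'   \eqn{P(X \le x)}.
#' @return `dgumbel` gives the density, `pgumbel` the distribution function,
#'   `qgumbel` the quantile function and `rgumbel` random draws.
#' @examples
#' pgumbel(0, 0, 1)        # exp(-1)
#' qgumbel(pgumbel(1.3, 2, 0.5), 2, 0.5)
#' @name gumbel
NULL

check_sigma <- function(sigma) {
  if (any(!is.finite(sigma)) || any(sigma <= 0)) {
    abort("`sigma` must be finite and > 0.")
  }
  invisible(sigma)
}

#' @rdname gumbel
#' @export
dgumbel <- function(x, mu = 0, sigma = 1, log = FALSE) {
  check_sigma(sigma)
  z <- (x - mu) / sigma
  out <- -z - exp(-z) - base::log(sigma)
  if (log) out else exp(out)
}

#' @rdname gumbel
#' @export
pgumbel <- function(q, mu = 0, sigma = 1, lower.tail = TRUE, log.p = FALSE) {
  check_sigma(sigma)
  if (any(is.nan(q))) abort("non-finite quantile `q`.")
  z <- (q - mu) / sigma
  logF <- -exp(-z)                       # log G(q)
  if (lower.tail) {
    if (log.p) logF else exp(logF)
  } else {
    # log(1 - exp(logF)), stable for both tails
    logS <- ifelse(logF > -log(2), base::log(-expm1(logF)), log1p(-exp(logF)))
    if (log.p) logS else exp(logS)
  }
}

#' @rdname gumbel
#' @export
qgumbel <- function(p, mu = 0, sigma = 1) {
  check_sigma(sigma)
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("`p` must lie in [0, 1].")
  mu - sigma * base::log(-base::log(p))
}

#' @rdname gumbel
#' @export
rgumbel <- function(n, mu = 0, sigma = 1) {
  qgumbel(runif(n), mu, sigma)
}

#' Gumbel log-likelihood
#'
#' Log-likelihood of a Gumbel(`mu`, `sigma`) sample. With standardized
#' residuals \eqn{z_i = (x_i - \mu)/\sigma} it equals
#' \deqn{\ell(\mu, \sigma \mid x) = -n \log\sigma
#'       - \sum_i e^{-z_i} - \sum_i z_i,}
#' i.e. \eqn{-n\log\sigma + \Delta} where \eqn{\Delta} collects the two sums.
#' This is the likelihood driving every Metropolis--Hastings acceptance
#' ratio in the package.
#'
#' @param x numeric vector of observations (block maxima).
#' @param mu,sigma Gumbel location and scale; `sigma > 0`.
#' @return a single numeric, the log-likelihood.
#' @examples
#' x <- rgumbel(50, 1, 2)
#' gumbel_loglik(x, 1, 2)
#' @export
gumbel_loglik <- function(x, mu, sigma) {
  if (length(x) < 1L) abort("`x` must contain at least one observation.")
  if (any(!is.finite(x))) abort("`x` must be finite.")
  check_sigma(sigma)
  z <- (x - mu) / sigma
  -length(x) * base::log(sigma) - sum(exp(-z)) - sum(z)
}

#' Method-of-moments Gumbel parameter estimates
#'
#' Moment-matching starting values: \eqn{\hat\sigma = s\sqrt{6}/\pi} and
#' \eqn{\hat\mu = \bar{x} - \gamma\hat\sigma} with \eqn{\gamma} the
#' Euler--Mascheroni constant. Used to initialize the samplers and to elicit
#' weakly informative prior centres.
#'
#' @param x numeric sample.
#' @return named numeric vector `c(mu, sigma)`.
#' @export
gumbel_moments <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) s <- max(abs(x[1]), 1) * 1e-3 # degenerate guard
  sigma <- s * sqrt(6) / pi
  c(mu = mean(x) - EULER_GAMMA * sigma, sigma = sigma)
}
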