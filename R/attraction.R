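#' Normalizing constants of the Gumbel domain of attraction
#'
#' For a baseline distribution F attracted to the Gumbel law there are
#' sequences \eqn{a_k > 0}, \eqn{b_k} with
#' \eqn{F^k(a_k x + b_k) \to \exp(-e^{-x})}. The pair \eqn{(a_k, b_k)}
#' doubles as the (approximate) scale and location of the block-maxima
#' Gumbel distribution at block size `k`; it is the bridge the baseline
#' methods use to move estimates from the baseline scale to the
#' block-maxima scale.
#'
#' Closed forms per family (standard constants \eqn{a_N, b_N} for the
#' standard normal):
#' * exponential(rate \eqn{\lambda}): \eqn{a_k = 1/\lambda},
#'   \eqn{b_k = \ln k / \lambda} (exact: \eqn{b_k = F^{-1}(1 - 1/k)})
#' * gumbel(\eqn{\mu,\sigma}): \eqn{a_k = \sigma},
#'   \eqn{b_k = \mu + \sigma \ln k} (exact closure: \eqn{F^k} is again
#'   Gumbel)
#' * normal(\eqn{\mu,\sigma}): \eqn{a_k = \sigma (2\ln k)^{-1/2}},
#'   \eqn{b_k = \mu + \sigma b_N} with
#'   \eqn{b_N = (2\ln k)^{1/2} - \tfrac12 (2\ln k)^{-1/2}
#'   (\ln\ln k + \ln 4\pi)} (asymptotic)
#' * lognormal(\eqn{\mu,\sigma}): \eqn{a_k = a_N \sigma e^{\mu + \sigma b_N}},
#'   \eqn{b_k = e^{\mu + \sigma b_N}}
#' * rayleigh(\eqn{\sigma}): \eqn{a_k = \sigma (2\ln k)^{-1/2}},
#'   \eqn{b_k = \sigma (2\ln k)^{1/2}}
#' * gamma(shape \eqn{\alpha}, scale \eqn{\beta}):
#'   \eqn{a_k = \beta},
#'   \eqn{b_k = \beta[\ln k + (\alpha - 1)\ln\ln k - \ln\Gamma(\alpha)]}.
#'   The gamma row should be treated as experimental: the constants assume
#'   \eqn{\beta} is a *scale* parameter and are asymptotic only.
#'
#' The mixture family has no closed-form constants and errors.
#'
#' @param spec a [baseline_spec()].
#' @param k block size, `>= 2` for the asymptotic families.
#' @return an object of class `norm_constants`: list with `a`, `b`, `k`,
#'   `family`.
#' @examples
#' norm_constants(baseline_spec("gumbel", mu = 0, sigma = 4), 1000)
#' @export
norm_constants <- function(spec, k) {
  if (!inherits(spec, "baseline_spec")) abort("`spec` must be a baseline_spec.")
  if (k < 2) abort("`k` must be >= 2.")
  pp <- spec$params
  lk <- log(k)
  ab <- switch(spec$family,
    exponential = c(1 / pp$rate, lk / pp$rate),
    gumbel = c(pp$sigma, pp$mu + pp$sigma * lk),
    normal = {
      std <- std_normal_constants(k)
      c(pp$sd * std[1], pp$mean + pp$sd * std[2])
    },
    lognormal = {
      std <- std_normal_constants(k)
      b <- exp(pp$meanlog + pp$sdlog * std[2])
      c(std[1] * pp$sdlog * b, b)
    },
    rayleigh = c(pp$sigma / sqrt(2 * lk), pp$sigma * sqrt(2 * lk)),
    gamma = c(pp$scale,
              pp$scale * (lk + (pp$shape - 1) * log(lk) - lgamma(pp$shape))),
    normal_mixture = abort(
      "no closed-form normalizing constants for the mixture family.")
  )
  structure(list(a = ab[1], b = ab[2], k = k, family = spec$family),
            class = "norm_constants")
}

# (a_N, b_N) for the standard normal baseline
std_normal_constants <- function(k) {
  t2 <- 2 * log(k)
  b <- sqrt(t2) - (log(log(k)) + log(4 * pi)) / (2 * sqrt(t2))
  c(1 / sqrt(t2), b)
}

#' @export
print.norm_constants <- function(x, ...) {
  cat("<norm_constants> family ", x$family, ", k = ", x$k,
      ": a_k = ", signif(x$a, 6), ", b_k = ", signif(x$b, 6), "\n", sep = "")
  invisible(x)
}

#' Affine transfer of normalizing constants
#'
#' If X has constants \eqn{(a_k, b_k)} then the affine transform
#' \eqn{Y = \mu + \sigma X} has constants
#' \eqn{(\tilde a_k, \tilde b_k) = (\sigma a_k, \mu + \sigma b_k)}.
#'
#' @param const a `norm_constants` object.
#' @param mu location shift.
#' @param sigma scale factor, `> 0`.
#' @return a `norm_constants` object.
#' @export
affine_transfer <- function(const, mu, sigma) {
  if (!inherits(const, "norm_constants")) {
    abort("`const` must be a norm_constants object.")
  }
  if (sigma <= 0) abort("`sigma` must be > 0.")
  structure(list(a = sigma * const$a, b = mu + sigma * const$b, k = const$k,
                 family = const$family),
            class = "norm_constants")
}

#' Von Mises auxiliary function
#'
#' The function \eqn{h(t) = (1 - F(t)) / F'(t)} of the von Mises sufficient
#' condition for Gumbel attraction. Evaluated in log space
#' (\eqn{\exp[\log S(t) - \log f(t)]}) so it stays finite deep in the tail,
#' where both survival and density underflow.
#'
#' @param spec a [baseline_spec()].
#' @param t evaluation points; the density must be positive there.
#' @return positive numeric vector, \eqn{h(t)}.
#' @examples
#' von_mises_h(baseline_spec("exponential", rate = 2), 3)  # 1/2
#' @export
von_mises_h <- function(spec, t) {
  if (any(!is.finite(t))) abort("`t` must be finite.")
  logf <- dbaseline(t, spec, log = TRUE)
  if (any(!is.finite(logf))) {
    abort("density is zero at some `t` (outside the support of F).")
  }
  logS <- pbaseline(t, spec, lower.tail = FALSE, log.p = TRUE)
  if (any(!is.finite(logS))) {
    abort("`t` is at or above the right endpoint of F.")
  }
  exp(logS - logf)
}

#' Uniform gap between normalized maxima and the Gumbel limit
#'
#' Measures how far the distribution of normalized block maxima is from its
#' Gumbel limit: the maximum over a grid of
#' \eqn{|F(a_k x + b_k)^k - \exp(-e^{-x})|}. Zero (exactly) for a Gumbel
#' baseline; decreasing in `k` for the other families, very slowly so for
#' the normal.
#'
#' @param spec a [baseline_spec()].
#' @param k block size.
#' @param grid evaluation grid on the standardized scale; the default, 201
#'   equispaced points on `[-2, 6]`, covers the bulk of the standard Gumbel.
#' @return non-negative scalar.
#' @export
convergence_gap <- function(spec, k, grid = seq(-2, 6, length.out = 201)) {
  const <- norm_constants(spec, k)
  fk <- exp(k * pbaseline(const$a * grid + const$b, spec, log.p = TRUE))
  max(abs(fk - pgumbel(grid)))
}
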