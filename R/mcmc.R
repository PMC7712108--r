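#' MCMC protocol configuration
#'
#' Bundles the chain protocol: burn-in length, thinning interval, number of
#' kept draws, and the seed. The default protocol (burn-in 3000, thinning
#' 50, 10,000 kept draws) follows the single-chain study protocol; the total
#' raw iterations consumed are always `burn_in + thin * n_keep` and are
#' computed, never assumed ([raw_iterations()]).
#'
#' @param burn_in number of initial iterations discarded, `>= 0`.
#' @param thin keep every `thin`-th draw after burn-in, `>= 1`.
#' @param n_keep number of retained draws, `>= 1`.
#' @param seed optional integer seed applied at the start of a run.
#' @return object of class `chain_config`.
#' @seealso [chain_config_reduced()] for a desk-scale protocol.
#' @export
chain_config <- function(burn_in = 3000, thin = 50, n_keep = 10000,
                         seed = NULL) {
  if (burn_in < 0) abort("`burn_in` must be >= 0.")
  if (thin < 1) abort("`thin` must be >= 1.")
  if (n_keep < 1) abort("`n_keep` must be >= 1.")
  structure(list(burn_in = as.integer(burn_in), thin = as.integer(thin),
                 n_keep = as.integer(n_keep),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "chain_config")
}

#' Reduced chain protocol
#'
#' Burn-in 3000, thinning 10, 2000 kept draws: a 23,000-iteration protocol
#' sized for error-table reproduction on a single CPU. Posterior means under
#' this protocol agree with the full protocol well within replicate
#' Monte-Carlo error.
#'
#' @inheritParams chain_config
#' @return object of class `chain_config`.
#' @export
chain_config_reduced <- function(seed = NULL) {
  chain_config(burn_in = 3000, thin = 10, n_keep = 2000, seed = seed)
}

#' Total raw iterations a protocol consumes
#'
#' @param cfg a [chain_config()].
#' @return integer, `burn_in + thin * n_keep`.
#' @export
raw_iterations <- function(cfg) {
  cfg$burn_in + cfg$thin * cfg$n_keep
}

#' @export
print.chain_config <- function(x, ...) {
  cat("<chain_config> burn-in ", x$burn_in, ", thin ", x$thin,
      ", keep ", x$n_keep, " (", raw_iterations(x), " raw iterations)",
      if (!is.null(x$seed)) paste0(", seed ", x$seed), "\n", sep = "")
  invisible(x)
}

# internal chain constructor -------------------------------------------------
new_bmb_chain <- function(draws, acceptance, config, method, info = list()) {
  draws <- tibble::as_tibble(draws)
  draws <- dplyr::mutate(draws, iteration = dplyr::row_number(),
                         .before = 1L)
  structure(list(draws = draws, acceptance = acceptance, config = config,
                 method = method, info = info),
            class = "bmb_chain")
}

#' Apply burn-in and thinning to raw draws
#'
#' Drops the first `burn_in` raw draws and keeps every `thin`-th draw
#' thereafter, yielding exactly `n_keep` values; errors when the raw chain
#' is too short, naming the required total.
#'
#' @param raw numeric vector, matrix or data frame of raw draws (one row per
#'   iteration).
#' @param cfg a [chain_config()].
#' @return object of the same kind as `raw`, with `n_keep` rows/values.
#' @examples
#' apply_protocol(1:100, chain_config(burn_in = 20, thin = 4, n_keep = 20))
#' @export
apply_protocol <- function(raw, cfg) {
  n_raw <- if (is.null(dim(raw))) length(raw) else nrow(raw)
  need <- raw_iterations(cfg)
  if (n_raw < need) {
    abort(paste0("raw chain has ", n_raw, " iterations but the protocol ",
                 "(burn-in ", cfg$burn_in, ", thin ", cfg$thin, ", keep ",
                 cfg$n_keep, ") requires ", need, "."))
  }
  idx <- cfg$burn_in + cfg$thin * seq_len(cfg$n_keep)
  if (is.null(dim(raw))) raw[idx] else raw[idx, , drop = FALSE]
}

#' Chain draws as a tibble
#'
#' @param chain a `bmb_chain`.
#' @return tibble with an `iteration` column and one column per parameter.
#' @export
chain_draws <- function(chain) {
  stopifnot(inherits(chain, "bmb_chain"))
  chain$draws
}

chain_params <- function(chain) setdiff(names(chain$draws), "iteration")

#' Posterior point estimates
#'
#' Posterior means of the retained draws — the point estimator used
#' throughout the error studies (posterior means and medians are close for
#' these near-symmetric posteriors; the mean is the reported one).
#'
#' @param object a `bmb_chain`.
#' @param ... unused.
#' @return named numeric vector of posterior means.
#' @export
coef.bmb_chain <- function(object, ...) {
  vapply(chain_params(object), function(p) mean(object$draws[[p]]),
         numeric(1))
}

#' @export
print.bmb_chain <- function(x, ...) {
  cat("<bmb_chain> ", x$method, ": ", x$config$n_keep, " draws of (",
      paste(chain_params(x), collapse = ", "), ")\n", sep = "")
  est <- coef(x)
  cat("  posterior means: ",
      paste(names(est), signif(est, 5), sep = " = ", collapse = ", "),
      "\n", sep = "")
  acc <- x$acceptance[!is.na(x$acceptance)]
  if (length(acc)) {
    cat("  acceptance: ",
        paste(names(acc), signif(acc, 3), sep = " = ", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Tidy posterior summary of a chain
#'
#' One row per parameter: posterior mean, median, standard deviation and
#' central 95% interval.
#'
#' @param x a `bmb_chain`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.bmb_chain <- function(x, ...) {
  purrr::map_dfr(chain_params(x), function(p) {
    d <- x$draws[[p]]
    tibble::tibble(term = p, estimate = mean(d), median = median(d),
                   std.error = sd(d),
                   conf.low = unname(quantile(d, 0.025)),
                   conf.high = unname(quantile(d, 0.975)))
  })
}

#' One-line chain summary
#'
#' @param x a `bmb_chain`.
#' @param ... unused.
#' @return a one-row tibble with the protocol, minimum effective sample size
#'   across parameters, and acceptance rates.
#' @export
glance.bmb_chain <- function(x, ...) {
  ess <- vapply(chain_params(x), function(p) {
    d <- x$draws[[p]]
    if (sd(d) == 0) 0 else unname(coda::effectiveSize(d))
  }, numeric(1))
  acc <- x$acceptance[!is.na(x$acceptance)]
  tibble::tibble(method = x$method, n_keep = x$config$n_keep,
                 burn_in = x$config$burn_in, thin = x$config$thin,
                 raw_iterations = raw_iterations(x$config),
                 min_ess = min(ess),
                 mean_acceptance = if (length(acc)) mean(acc) else NA_real_)
}

#' Convergence diagnostics for a chain
#'
#' Per-parameter lag-1 autocorrelation, effective sample size (via
#' \pkg{coda}), posterior mean/median/sd and central 95% quantiles. A
#' constant (degenerate) chain is flagged with `degenerate = TRUE` and zero
#' effective sample size.
#'
#' @param chain a `bmb_chain` with at least 100 retained draws.
#' @return a tibble, one row per parameter.
#' @export
diagnostics <- function(chain) {
  stopifnot(inherits(chain, "bmb_chain"))
  if (chain$config$n_keep < 100) abort("diagnostics need n_keep >= 100.")
  purrr::map_dfr(chain_params(chain), function(p) {
    d <- chain$draws[[p]]
    degen <- sd(d) == 0
    lag1 <- if (degen) NA_real_ else {
      unname(acf(d, lag.max = 1, plot = FALSE)$acf[2])
    }
    tibble::tibble(
      term = p,
      mean = mean(d), median = median(d), sd = sd(d),
      q2.5 = unname(quantile(d, 0.025)), q97.5 = unname(quantile(d, 0.975)),
      lag1_acf = lag1,
      ess = if (degen) 0 else unname(coda::effectiveSize(d)),
      degenerate = degen)
  })
}

#' Trace and density plot of a chain
#'
#' @param object a `bmb_chain`.
#' @param ... unused.
#' @return a ggplot object, faceted by parameter, with the trace on the left
#'   and the marginal posterior density on the right.
#' @export
autoplot.bmb_chain <- function(object, ...) {
  long <- tidyr::pivot_longer(object$draws, -"iteration",
                              names_to = "parameter", values_to = "value")
  trace <- ggplot2::ggplot(long,
      ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.2, colour = "steelblue") +
    ggplot2::facet_wrap(~parameter, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "kept iteration", y = NULL,
                  title = paste0(object$method, " trace"))
  dens <- ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
    ggplot2::facet_wrap(~parameter, scales = "free", ncol = 1) +
    ggplot2::labs(x = NULL, y = "posterior density")
  if (requireNamespace("patchwork", quietly = TRUE)) {
    trace + dens
  } else {
    trace
  }
}

# derive independent per-replicate seeds from one master seed
derive_seeds <- function(master_seed, n) {
  withr::with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}
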