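# blockmaxbayes

Bayesian estimation of the Gumbel distribution of block maxima that uses
*all* of the data, not just the maxima.

## The problem

In block-maxima extreme value analysis a series of `m = n * k` raw
("baseline") observations is cut into `n` blocks of size `k` and only the
`n` block maxima are kept for inference. When the baseline distribution F
has an exponentially decaying tail (Gumbel, exponential, normal, gamma,
log-normal, Rayleigh, ...), the normalized maxima converge to the Gumbel
law

    G(x; mu, sigma) = exp{ -exp[ -(x - mu) / sigma ] },

and the normalizing constants `(a_k, b_k)` — with
`F^k(a_k x + b_k) -> G(x; 0, 1)` — are precisely the scale and location of
the limiting block-maxima Gumbel. Discarding the `(k - 1)/k` fraction of
non-maximal observations throws away most of the information; with short
records the posterior on `(mu, sigma)` is then wide and skewed. This
package implements three estimators that differ in how much of the sample
they use:

* **MHM** — classical component-wise Metropolis–Hastings on the `n` block
  maxima only, with independent Gumbel (location) × Rayleigh (scale)
  priors.
* **BDM** (Baseline Distribution Method) — fit the baseline family to all
  `m` observations (conjugate Gamma posterior for an exponential baseline,
  normal–inverse-gamma Gibbs for a normal baseline, the same MH kernel for
  a Gumbel baseline), then push the posterior through the
  normalizing-constant map, e.g. `(mu_b, sigma_b) -> (mu_b + sigma_b ln k,
  sigma_b)` for a Gumbel baseline, or take the k-th power of the estimated
  baseline CDF.
* **IBDM** (Improved BDM) — per MCMC iteration, one draw `theta_b` of the
  baseline posterior is mapped to the block-maxima scale and centres a
  normal proposal `theta* ~ N(f(theta_b), nu_theta)`; acceptance uses only
  the block-maxima Gumbel likelihood ratio. The baseline sample shapes the
  proposal, the extremes decide acceptance.

The package also provides the normalizing constants for the standard
families attracted to the Gumbel law, the von Mises tail function
`h = (1 - F)/F'`, convergence diagnostics for `F^k(a_k x + b_k) -> G`,
and a fully seeded simulation-study harness with both parameter-scale
error measures (ME / RMSE / MAE) and Monte-Carlo CDF-distance measures for
baselines whose maxima law is not exactly Gumbel.

## Worked example

Sixteen blocks of a thousand observations from a G(0, 4) baseline. The
exact block-maxima law is G(27.63, 4):

```r
library(blockmaxbayes)

norm_constants(baseline_spec("gumbel", mu = 0, sigma = 4), k = 1000)
#> <norm_constants> family gumbel, k = 1000: a_k = 4, b_k = 27.631

y <- sample_baseline(baseline_spec("gumbel", mu = 0, sigma = 4),
                     16000, seed = 1)
x <- block_maxima(y, 1000)

cfg <- chain_config_reduced(seed = 1)          # burn-in 3000, thin 10, keep 2000
bdm <- transform_to_blockmax(bdm_gumbel(y, cfg = cfg), k = 1000)
tidy(bdm)
#> # A tibble: 2 × 6
#>   term  estimate median std.error conf.low conf.high
#>   <chr>    <dbl>  <dbl>     <dbl>    <dbl>     <dbl>
#> 1 mu       27.8   27.8     0.189     27.4      28.2
#> 2 sigma     4.03   4.02    0.0255     3.98      4.08

mhm  <- run_mhm(x, cfg = cfg)
ibdm <- run_ibdm(x, y, "gumbel", k = 1000, cfg = cfg)
round(rbind(MHM = coef(mhm), BDM = coef(bdm), IBDM = coef(ibdm)), 3)
#>          mu sigma
#> MHM  25.833 4.581
#> BDM  27.802 4.025
#> IBDM 27.493 4.026
```

With only 16 maxima the maxima-only fit misses the location by almost two
units and overstates the scale by 15%; both baseline methods land on the
true `G(27.63, 4)` within their posterior uncertainty because they also
see the 15,984 discarded observations.

A command-line front end wrapping the same functions lives in
`inst/cli/blockmax-bayes` (`simulate`, `fit`, `study` subcommands), and
`run_study()` / `mixture_scenario()` reproduce the full error-table
grids; see the methods vignette (`vignettes/blockmaxbayes-methods.Rmd`)
for the model details and design choices.

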