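# demclim

Inferring demography–climate relationships (DCRs) from abundance time
series by Bayesian calibration of a spatially explicit, two-stage
individual-based model (IBM), with counterfactual attribution of
population trends to climate change.

## The problem

Long-term survey counts show that bird populations shift and change, but
correlative distribution models cannot say *which demographic process*
climate acts on. `demclim` takes the process-based route: a female-only,
two-stage (juvenile / breeding adult) IBM runs on a gridded landscape,
and each demographic rate is an explicit GLM-style function of
standardized seasonal climate predictors:

- fecundity (log link): `rho_max = exp(b0 + b1 T_br + b2 T_br^2 + b3 P_br + b4 P_br^2)`,
  with density dependence `rho = rho_max exp(-n_i b_i)`, `b_i = b * 100 / h_i`
  (`h_i` in [0,100] is the habitat-suitability index of the cell);
- juvenile survival (logit link) on autumn temperature and winter
  precipitation (quadratic);
- adult survival (logit link) on winter minimum temperature (linear) and
  winter precipitation (quadratic).

Natal dispersal is explicit (emigration probability `p_e`, exponential
kernel with mean distance `dbar`, neighbour-fallback settlement,
additive dispersal mortality). The 18 parameters (14 DCR coefficients,
`b`, `p_e`, `dbar`, and a negative-binomial dispersion `sigma`) are
estimated inversely from site-by-year counts: the likelihood compares
block-aggregated observed counts with replicate-averaged simulated adult
females through a negative binomial, sampled with an in-package
differential-evolution MCMC (DEzs, with z-archive and snooker updates).

Fitted models are evaluated with RMSE, Harrell's c-index, a mean yearly
spatial AUC and a temporal c-index, and interrogated for climate-change
impact in two ways: the partial response of the low-density growth rate
`r = s_a/2 + sqrt(s_a^2/4 + s_j rho)` to each predictor's accumulated
trend, and the ratio of simulated abundance under factual versus
detrended ("stationary") climate with common random numbers.

A first-class synthetic-data module generates the whole study system —
spatially autocorrelated climate fields with trends, clustered habitat
maps, spun-up initial populations and negative-binomial surveys from
known parameters — so every stage is testable against stored truths
without any external data.

## Worked example

```r
library(demclim)

# a 30 x 30 km landscape, 15 survey years, 60 sites, known parameters
sc <- synthetic_scenario(nr = 30, nc = 30, first_year = 1999,
                         last_year = 2013, n_sites = 60,
                         theta_true = preset_params("mountain"), seed = 42)
bundle <- gen_scenario_bundle(sc)
mean(bundle$survey$survey$count)
#> [1] 2.232222

# calibrate: priors, seed-pinned likelihood, mode ascent + 3 DEzs chains
priors  <- default_priors(sc$theta_true)
log_post <- make_log_posterior(bundle$survey$survey, bundle$climate$std,
                               bundle$habitat, bundle$initial, priors,
                               n_reps = 5, block_size = 10,
                               seed_policy = "pinned", pin_seed = 99)
map   <- map_ascent(log_post, priors, maxit = 2000)
run   <- dezs_sample(log_post, priors, n_chains = 3, iterations = 20000,
                     seed = 11, init = "start", start_state = map$par,
                     z_init_scale = 0.1, gamma_base = 0.25)
draws <- posterior_draws(run, 400, seed = 5)

# attribution: partial growth-rate response to each predictor's trend
trend <- fit_trend(bundle$climate$raw)
print(trend[, c("predictor", "slope", "accumulated")])
#>   predictor  slope accumulated
#> 1      T_br  0.050        0.70
#> 2      P_br -0.580       -8.12
#> 3      T_at  0.055        0.77
#> 4      T_wn  0.075        1.05
#> 5      P_wn  1.450       20.30
```

The trend table reads: breeding-season temperature rose 0.70 K and
winter precipitation 20.3 mm over the 14-year span of this synthetic
landscape (the generator's defaults emulate observed two-decade alpine
trends). `partial_response()` then converts each accumulated change to
standardized units and reports the growth-rate ratio per posterior draw,
classified as none / small / strong (5% and 10% thresholds), and
`scenario_ratio()` gives the overall factual-vs-stationary abundance
ratio.

The `analysis/` directory runs the same pipeline as a numbered workflow
(`01_simulate.R` → `04_attribute.R`) writing plain-text tables under
`results/run1/`.

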