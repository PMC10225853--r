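# Bayesian calibration: truncated-normal priors, negative-binomial
# likelihood on block-aggregated replicate-averaged simulations, and the
# log-posterior closure evaluated by the DEzs sampler (dezs.R).

#' Default prior specification
#'
#' Mildly regularizing truncated normal priors: every DCR slope
#' coefficient has mean 0, sd 1 and truncation \[-5, 5\]; the
#' negative-binomial dispersion has mean 50, sd 50 on (0, 500\].
#' Intercepts and the process parameters (`b`, `p_e`, `dbar`) get
#' user-configurable normals — in a real application their means and sds
#' come from independently measured demographic and dispersal traits; by
#' default they centre on a reference parameter vector with moderate
#' spread.
#'
#' @param theta_ref Reference [param_vector()] supplying intercept and
#'   process-parameter prior means.
#' @param intercept_sd,b_sd,p_e_sd,dbar_sd Prior sds for the
#'   trait-informed parameters.
#' @return Data frame (class `"prior_spec"`) with columns `name`, `mean`,
#'   `sd`, `lower`, `upper`, one row per parameter in canonical order.
#' @export
default_priors <- function(theta_ref = preset_params("mountain"),
                           intercept_sd = 0.5, b_sd = 0.05, p_e_sd = 0.15,
                           dbar_sd = 1) {
  nm <- param_names()
  mean <- stats::setNames(rep(0, 18), nm)
  sd <- stats::setNames(rep(1, 18), nm)
  lower <- stats::setNames(rep(-5, 18), nm)
  upper <- stats::setNames(rep(5, 18), nm)
  for (ic in c("fec_icpt", "sj_icpt", "sa_icpt")) {
    mean[ic] <- theta_ref[[ic]]
    sd[ic] <- intercept_sd
  }
  mean["b"] <- theta_ref[["b"]]; sd["b"] <- b_sd
  lower["b"] <- 1e-4; upper["b"] <- 1
  mean["p_e"] <- theta_ref[["p_e"]]; sd["p_e"] <- p_e_sd
  lower["p_e"] <- 0; upper["p_e"] <- 1
  mean["dbar"] <- theta_ref[["dbar"]]; sd["dbar"] <- dbar_sd
  lower["dbar"] <- 0.1; upper["dbar"] <- 20
  mean["sigma"] <- 50; sd["sigma"] <- 50
  lower["sigma"] <- 0; upper["sigma"] <- 500
  out <- data.frame(name = nm, mean = mean, sd = sd, lower = lower,
                    upper = upper, row.names = NULL)
  class(out) <- c("prior_spec", "data.frame")
  out
}

#' Log prior density
#'
#' Sum of independent truncated-normal log densities, each correctly
#' renormalized by its truncation mass; `-Inf` outside any bound.
#'
#' @param theta Named numeric vector over the prior's parameters.
#' @param priors A `prior_spec` from [default_priors()].
#' @return Scalar log density.
#' @export
log_prior <- function(theta, priors) {
  x <- as.numeric(theta[priors$name])
  if (any(!is.finite(x))) return(-Inf)
  if (any(x < priors$lower | x > priors$upper)) return(-Inf)
  z <- stats::pnorm(priors$upper, priors$mean, priors$sd) -
    stats::pnorm(priors$lower, priors$mean, priors$sd)
  sum(stats::dnorm(x, priors$mean, priors$sd, log = TRUE) - log(z))
}

#' Sample from the prior
#'
#' Truncated-normal sampling by inverse-CDF.
#'
#' @param priors A `prior_spec`.
#' @param n Number of draws.
#' @return `n x d` matrix with parameter-name columns.
#' @export
sample_prior <- function(priors, n) {
  d <- nrow(priors)
  plo <- stats::pnorm(priors$lower, priors$mean, priors$sd)
  phi <- stats::pnorm(priors$upper, priors$mean, priors$sd)
  u <- matrix(stats::runif(n * d), n, d, byrow = TRUE)
  q <- t(stats::qnorm(plo + t(u) * (phi - plo), priors$mean, priors$sd))
  # guard against u landing exactly on a truncation boundary
  q <- pmin(pmax(q, matrix(priors$lower, n, d, byrow = TRUE)),
            matrix(priors$upper, n, d, byrow = TRUE))
  colnames(q) <- priors$name
  q
}

#' Negative-binomial log likelihood
#'
#' `sum log NB(y | mu, size = sigma)` with variance `mu + mu^2/sigma`. A
#' mean floor of `1e-6` keeps zero-mean predictions with positive
#' observed counts finite (and very improbable) instead of `-Inf`.
#'
#' @param y Non-negative integer observations.
#' @param mu Predicted means (`>= 0`).
#' @param sigma Dispersion (`> 0`); the Poisson limit is approached as
#'   `sigma` grows.
#' @param mu_floor Mean floor.
#' @return Scalar log likelihood.
#' @export
nb_loglik <- function(y, mu, sigma, mu_floor = 1e-6) {
  if (sigma <= 0) stop("sigma must be > 0")
  if (any(y < 0) || any(y != round(y))) stop("y must be non-negative integers")
  if (any(mu < 0)) stop("mu must be >= 0")
  sum(stats::dnbinom(y, size = sigma, mu = pmax(mu, mu_floor), log = TRUE))
}

# block id per site from its cell coordinates
site_blocks <- function(sites, block_size) {
  bx <- (sites$x_cell - 1L) %/% block_size
  by <- (sites$y_cell - 1L) %/% block_size
  paste0(bx, "_", by)
}

#' Aggregate observations and simulations for the likelihood
#'
#' Survey sites are grouped into square blocks of `block_size` cells a
#' side (25 km blocks of 1 km cells in the original design). Per block
#' and year, `y` is the summed observed count and `mu` the mean over
#' replicates of the summed simulated adults at the same sites — the
#' aggregation that, together with replicate averaging, tempers the
#' stochasticity of the simulated likelihood.
#'
#' @param abundance Integer array `[rows, cols, years, reps]` from
#'   [simulate_ibm()].
#' @param survey Survey data frame (`site_id, x_cell, y_cell, year,
#'   count`).
#' @param years Year labels of the abundance array's third dimension.
#' @param block_size Block edge in cells (default 25).
#' @return Data frame with columns `block`, `year`, `y`, `mu`.
#' @export
aggregate_for_likelihood <- function(abundance, survey, years,
                                     block_size = 25L) {
  sites <- unique(survey[, c("site_id", "x_cell", "y_cell")])
  sites <- sites[order(sites$site_id), ]
  blocks <- site_blocks(sites, block_size)
  dm <- dim(abundance)
  cell_idx <- (sites$x_cell - 1L) * dm[1] + sites$y_cell
  ns <- nrow(sites)
  ny <- dm[3]
  reps <- dm[4]
  idx <- rep(cell_idx, times = ny * reps) +
    rep(rep((seq_len(ny) - 1L) * dm[1] * dm[2], each = ns), times = reps) +
    rep((seq_len(reps) - 1L) * dm[1] * dm[2] * ny, each = ns * ny)
  vals <- array(as.numeric(abundance)[idx], c(ns, ny, reps))
  site_year_mean <- apply(vals, c(1, 2), mean)
  mu <- rowsum(site_year_mean, blocks)
  obs <- matrix(NA_real_, ns, ny)
  yr_idx <- match(survey$year, years)
  st_idx <- match(survey$site_id, sites$site_id)
  obs[cbind(st_idx, yr_idx)] <- survey$count
  if (any(is.na(obs))) stop("survey must have one count per site and year")
  yb <- rowsum(obs, blocks)
  data.frame(block = rep(rownames(mu), times = ny),
             year = rep(years, each = nrow(mu)),
             y = as.vector(yb), mu = as.vector(mu))
}

#' Build the log-posterior closure
#'
#' Returns a function `theta -> log posterior` that (1) short-circuits to
#' `-Inf` outside the prior support without touching the simulator, and
#' (2) otherwise runs a fresh `n_reps`-replicate IBM simulation, block-
#' aggregates it against the survey and adds the negative-binomial log
#' likelihood to the log prior. With `seed_policy = "fresh"` the
#' simulation seed is drawn from the ambient RNG at each call (a
#' stochastic, pseudo-marginal-style likelihood); `"pinned"` fixes it so
#' repeated evaluation is identical.
#'
#' @param survey Survey data frame.
#' @param climate Standardized [climate_stack()].
#' @param habitat Suitability matrix.
#' @param initial Initial state or initializer (see [simulate_ibm()]).
#' @param priors A `prior_spec`.
#' @param n_reps IBM replicates averaged per evaluation (default 20).
#' @param block_size Likelihood aggregation block (cells).
#' @param seed_policy `"fresh"` or `"pinned"`.
#' @param pin_seed Seed used when pinned.
#' @param antithetic Pair simulation replicates antithetically (see
#'   [simulate_ibm()]); on by default — it reduces the variance of the
#'   replicate-averaged predicted means at no cost in bias.
#' @return Function of a named parameter vector; it carries an
#'   environment counting simulator calls (`attr(f, "n_sim_calls")()`).
#' @export
make_log_posterior <- function(survey, climate, habitat, initial, priors,
                               n_reps = 20, block_size = 25L,
                               seed_policy = c("fresh", "pinned"),
                               pin_seed = 1L, antithetic = TRUE) {
  seed_policy <- match.arg(seed_policy)
  years <- sort(unique(survey$year))
  sites <- unique(survey[, c("site_id", "x_cell", "y_cell")])
  sites <- sites[order(sites$site_id), ]
  blocks <- site_blocks(sites, block_size)
  dm <- dim(habitat)
  cell_idx <- (sites$x_cell - 1L) * dm[1] + sites$y_cell
  ns <- nrow(sites)
  ny <- length(years)
  obs <- matrix(NA_real_, ns, ny)
  obs[cbind(match(survey$site_id, sites$site_id),
            match(survey$year, years))] <- survey$count
  if (any(is.na(obs))) stop("survey must have one count per site and year")
  y_block <- rowsum(obs, blocks)
  plane <- dm[1] * dm[2]
  idx <- rep(cell_idx, times = ny) +
    rep((seq_len(ny) - 1L) * plane, each = ns)
  n_sim <- 0L
  env <- environment()
  f <- function(theta) {
    theta <- stats::setNames(as.numeric(theta[priors$name]), priors$name)
    lp <- log_prior(theta, priors)
    if (!is.finite(lp)) return(-Inf)
    sim_seed <- if (seed_policy == "pinned") pin_seed else
      sample.int(2147483646L, 1)
    env$n_sim <- env$n_sim + 1L
    sim <- simulate_ibm(theta, climate, habitat, initial, years = years,
                        n_reps = n_reps, seed = sim_seed,
                        antithetic = antithetic)
    flat <- as.numeric(sim$abundance)
    acc <- numeric(ns * ny)
    for (r in seq_len(n_reps)) {
      acc <- acc + flat[idx + (r - 1L) * plane * ny]
    }
    site_year_mean <- matrix(acc / n_reps, ns, ny)
    mu <- rowsum(site_year_mean, blocks)
    lp + nb_loglik(as.vector(y_block), as.vector(mu), theta[["sigma"]])
  }
  attr(f, "n_sim_calls") <- function() env$n_sim
  attr(f, "priors") <- priors
  f
}

#' Posterior-mode ascent
#'
#' Short Nelder-Mead maximization of the log posterior, used to seed the
#' sampler near the mode when the posterior is much tighter than the
#' prior (the usual situation for simulator likelihoods with informative
#' surveys). With a seed-pinned likelihood the target is deterministic
#' and the ascent is well defined; with a fresh-seed likelihood it is a
#' noisy ascent and only a rough localization.
#'
#' @param log_post Function of a named parameter vector.
#' @param priors A `prior_spec` (names and bounds).
#' @param start Starting vector (default: prior means).
#' @param maxit Maximum function evaluations.
#' @return List: `par` (named vector), `value` (log posterior), `evals`.
#' @export
map_ascent <- function(log_post, priors, start = NULL, maxit = 1500) {
  if (is.null(start)) start <- stats::setNames(priors$mean, priors$name)
  f <- function(x) {
    names(x) <- priors$name
    v <- log_post(x)
    if (!is.finite(v)) return(1e10)
    -v
  }
  opt <- stats::optim(as.numeric(start), f, method = "Nelder-Mead",
                      control = list(maxit = maxit))
  list(par = stats::setNames(opt$par, priors$name), value = -opt$value,
       evals = opt$counts[["function"]])
}

#' Mode-seeded, pilot-adapted DEzs calibration
#'
#' The package's standard calibration procedure for simulator
#' posteriors that are much tighter than their priors: (1) a two-stage
#' Nelder-Mead ascent from the prior means locates the posterior mode;
#' (2) a short pilot DEzs run started there, with a small initial
#' archive, estimates the posterior scale per parameter; (3) the
#' production chains run with an initial archive drawn at the
#' pilot-estimated centre and spread, so proposals are posterior-sized
#' from the first generation. Only the production chains contribute
#' samples.
#'
#' @param log_post Log-posterior function (see [make_log_posterior()]).
#' @param priors A `prior_spec`.
#' @param iterations Log-posterior evaluations per production chain.
#' @param n_chains Production DEzs chains.
#' @param seed Master seed.
#' @param map_maxit Nelder-Mead evaluations per ascent stage.
#' @param pilot_iterations Evaluations per pilot chain (0 skips the
#'   pilot and seeds the archive at `z_init_scale` of the prior sd).
#' @param z_init_scale Archive spread for the pilot phase.
#' @param gamma_base Jump factor for both phases (see [dezs_sample()]).
#' @param spread_mult Archive spread as a multiple of the pilot sd.
#' @param ... Passed to the production [dezs_sample()] call.
#' @return List: `run` (the production `mcmc_run`), `map`, `pilot_sd`.
#' @export
calibrate_pipeline <- function(log_post, priors, iterations = 20000,
                               n_chains = 3, seed = 1, map_maxit = 2000,
                               pilot_iterations = 4000, z_init_scale = 0.1,
                               gamma_base = 0.25, spread_mult = 1.5, ...) {
  lp_map <- if (is.function(log_post)) log_post else log_post[[1]]
  map1 <- map_ascent(lp_map, priors, maxit = map_maxit)
  map <- map_ascent(lp_map, priors, start = map1$par,
                    maxit = ceiling(map_maxit / 2))
  pilot_sd <- NULL
  z_init <- NULL
  centre <- map$par
  if (pilot_iterations > 0) {
    pilot <- dezs_sample(log_post, priors, n_chains = n_chains,
                         iterations = pilot_iterations,
                         seed = derive_seed(seed, "pilot"),
                         init = "start", start_state = map$par,
                         z_init_scale = z_init_scale,
                         gamma_base = gamma_base)
    pool <- do.call(rbind, mcmc_chain_list(pilot))
    pilot_sd <- apply(pool, 2, stats::sd)
    pilot_sd <- pmax(pilot_sd, 1e-3 * priors$sd)
    centre <- apply(pool, 2, stats::median)
    set.seed(derive_seed(seed, "zinit"))
    d <- nrow(priors)
    z0 <- max(10 * d, 2 * d + 2)
    # resample pilot states inflated about their centre: the archive
    # then carries the pilot-estimated posterior correlations, which is
    # what makes difference-vector proposals efficient
    rows <- pool[sample.int(nrow(pool), z0, replace = TRUE), , drop = FALSE]
    z_init <- sweep(sweep(rows, 2, centre, "-") * spread_mult, 2,
                    centre, "+")
    # a pinch of independent jitter so early archive points are distinct
    z_init <- z_init + matrix(stats::rnorm(z0 * d, 0, 0.05 * pilot_sd),
                              z0, d, byrow = TRUE)
  }
  run <- dezs_sample(log_post, priors, n_chains = n_chains,
                     iterations = iterations, seed = seed,
                     init = "start", start_state = centre,
                     z_init = z_init, z_init_scale = z_init_scale,
                     gamma_base = gamma_base, ...)
  list(run = run, map = map, pilot_sd = pilot_sd)
}

#' Gelman-Rubin potential scale reduction
#'
#' Standard split-free PSRF over the run's post-burn-in sub-chains (each
#' internal chain of each DEzs chain counts as one chain), plus the
#' Brooks-Gelman multivariate PSRF. Convergence is declared at
#' `PSRF < 1.1` for all parameters.
#'
#' @param run An `mcmc_run` from [dezs_sample()], or a list of numeric
#'   matrices (one chain each, iterations x parameters).
#' @return List: `psrf` (named vector), `mpsrf` (scalar), `converged`
#'   (logical).
#' @export
gelman_rubin <- function(run) {
  chains <- if (inherits(run, "mcmc_run")) mcmc_chain_list(run) else run
  m <- length(chains)
  if (m < 2) stop("need at least 2 chains")
  n <- nrow(chains[[1]])
  if (n < 10) stop("chains too short for a PSRF")
  d <- ncol(chains[[1]])
  means <- sapply(chains, colMeans)                    # d x m
  vars <- sapply(chains, function(ch) apply(ch, 2, stats::var))
  means <- matrix(means, d, m)
  vars <- matrix(vars, d, m)
  W <- rowMeans(vars)
  B_over_n <- apply(means, 1, stats::var)              # B/n
  var_hat <- (n - 1) / n * W + B_over_n
  psrf <- sqrt(var_hat / W)
  names(psrf) <- colnames(chains[[1]])
  Wm <- matrix(0, d, d)
  for (ch in chains) Wm <- Wm + stats::cov(ch)
  Wm <- Wm / m
  Bm <- stats::cov(t(means)) # covariance of chain means = B/n (matrix)
  mpsrf <- tryCatch({
    ev <- Re(eigen(solve(Wm, Bm), only.values = TRUE)$values[1])
    sqrt((n - 1) / n + (m + 1) / m * ev)
  }, error = function(e) NA_real_)
  list(psrf = psrf, mpsrf = mpsrf,
       converged = all(psrf < 1.1, na.rm = FALSE))
}

#' Joint posterior draws
#'
#' Uniform draws of whole parameter vectors from the pooled post-burn-in
#' samples (without replacement when the pool allows, with replacement
#' otherwise), preserving posterior correlations.
#'
#' @param run An `mcmc_run`.
#' @param n Number of draws (default 400).
#' @param seed RNG seed.
#' @return `n x d` matrix with parameter-name columns.
#' @export
posterior_draws <- function(run, n = 400, seed = 1) {
  pool <- do.call(rbind, mcmc_chain_list(run))
  if (nrow(pool) == 0) stop("empty posterior")
  set.seed(seed)
  ii <- sample.int(nrow(pool), n, replace = nrow(pool) < n)
  pool[ii, , drop = FALSE]
}
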