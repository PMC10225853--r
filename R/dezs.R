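# Differential-evolution MCMC with sampling from the past (DEzs):
# proposals are scaled differences of states drawn from a thinned
# archive (the z-matrix), with occasional snooker updates for
# mode-jumping along projected directions. Suited to the stochastic
# (pseudo-marginal-style) log posterior: only proposals are re-evaluated
# and the current state's value is cached.

propose_de <- function(x, Z, gamma, eps_sd) {
  ii <- sample.int(nrow(Z), 2)
  x + gamma * (Z[ii[1], ] - Z[ii[2], ]) + stats::rnorm(length(x), 0, eps_sd)
}

propose_snooker <- function(x, Z) {
  ii <- sample.int(nrow(Z), 3)
  z <- Z[ii[1], ]
  dvec <- x - z
  d2 <- sum(dvec^2)
  if (d2 == 0) return(NULL)
  gs <- stats::runif(1, 1.2, 2.2)
  proj <- function(v) sum(v * dvec) / d2 * dvec
  xp <- x + gs * (proj(Z[ii[2], ]) - proj(Z[ii[3], ]))
  # Metropolis correction for the move's non-symmetry: (|x*-z|/|x-z|)^(d-1)
  log_corr <- (length(x) - 1) / 2 * (log(sum((xp - z)^2)) - log(d2))
  list(x = xp, log_corr = log_corr)
}

#' DEzs MCMC sampling
#'
#' Runs `n_chains` independent DEzs chains, each consisting of
#' `n_internal` interacting internal chains and a z-archive initialized
#' from the prior. Per generation and internal chain, the proposal is
#' `x* = x + gamma (z1 - z2) + eps` with `gamma = 2.38/sqrt(2d)`
#' (`gamma = 1` every `gamma_jump_every`-th generation for mode jumps)
#' and `z1, z2` drawn from the archive, or — with probability
#' `snooker_prob` — a snooker update along `x - z`. Acceptance is
#' Metropolis on the (possibly stochastic) log posterior; the archive is
#' extended with the current states every `archive_thin`-th generation.
#' `iterations` counts log-posterior evaluations per DEzs chain; the
#' first half of each chain is flagged as burn-in.
#'
#' @param log_post Function of a named parameter vector (e.g. from
#'   [make_log_posterior()], or any log density for testing); or a list
#'   of such functions, one per DEzs chain — e.g. likelihoods pinned to
#'   different simulation-noise realizations, whose pooled draws then
#'   marginalize over those realizations.
#' @param priors A `prior_spec` (defines dimension, names, initial
#'   population and the jitter scale `1e-4 * prior sd`).
#' @param n_chains Independent DEzs chains (default 3).
#' @param iterations Log-posterior evaluations per chain.
#' @param seed Master seed.
#' @param n_internal Internal chains per DEzs chain (default 3).
#' @param snooker_prob Snooker-update probability (default 0.1).
#' @param archive_thin Generations between archive extensions.
#' @param gamma_jump_every Period of `gamma = 1` generations.
#' @param gamma_base Base jump factor; `NULL` uses the ter Braak-Vrugt
#'   default `2.38/sqrt(2d)`. Reduce when acceptance is far below ~0.2
#'   (the usual adaptive-scaling practice).
#' @param z_start_factor Initial archive size as a multiple of the
#'   dimension (default 10; at least `2 * d + 2` points are required).
#' @param burn_frac Fraction of each chain flagged as burn-in.
#' @param refresh_every With a stochastic log posterior, re-evaluate the
#'   current states every this many generations (0 = never, the default:
#'   only proposals are evaluated and the current value is cached).
#'   Periodic refreshing counters the "lucky evaluation" stickiness of a
#'   noisy likelihood at the price of extra evaluations.
#' @param init Starting states: `"prior"` (random prior draws),
#'   `"prior_mean"` (all chains at the prior means), or `"start"` (all
#'   chains at `start_state` — e.g. a posterior-mode estimate from
#'   [map_ascent()], the usual choice when the posterior is far tighter
#'   than the prior and burn-in is expensive).
#' @param start_state Named parameter vector used when `init = "start"`;
#'   also the shrink centre of the initial archive in that case.
#' @param z_init Optional explicit initial archive (matrix, columns in
#'   prior order) — e.g. posterior-scaled points from a pilot run;
#'   overrides `z_init_scale`. Rows outside the prior bounds are
#'   clipped.
#' @param z_init_scale Spread of the initial z-archive as a fraction of
#'   the prior sd (archive points are drawn from the prior shrunk toward
#'   the initialization centre by this factor). With a posterior much
#'   tighter than the prior, a value well below 1 gives early proposals
#'   of a useful size; the archive then adapts to the true posterior
#'   scale as states are appended. 1 reproduces plain prior
#'   initialization.
#' @return Object of class `"mcmc_run"`: per-chain sample arrays
#'   `[generations, n_internal, d]`, log posteriors, acceptance rates,
#'   per-chain seeds and settings.
#' @export
dezs_sample <- function(log_post, priors, n_chains = 3, iterations = 10000,
                        seed = 1, n_internal = 3, snooker_prob = 0.1,
                        archive_thin = 1, gamma_jump_every = 10,
                        gamma_base = NULL, z_start_factor = 10,
                        burn_frac = 0.5,
                        refresh_every = 0,
                        init = c("prior", "prior_mean", "start"),
                        start_state = NULL, z_init_scale = 1,
                        z_init = NULL) {
  init <- match.arg(init)
  lp_funs <- if (is.function(log_post)) {
    rep(list(log_post), n_chains)
  } else {
    stopifnot(length(log_post) == n_chains)
    log_post
  }
  if (init == "start") {
    if (is.null(start_state)) stop("init = 'start' needs start_state")
    start_state <- as.numeric(start_state[priors$name])
  }
  d <- nrow(priors)
  z0 <- if (is.null(z_init)) max(ceiling(z_start_factor * d), 2 * d + 2)
        else nrow(z_init)
  n_gen <- max(2L, as.integer(ceiling(iterations / n_internal)))
  set.seed(seed)
  chain_seeds <- sample.int(2147483646L, n_chains)
  eps_sd <- 1e-4 * priors$sd
  gamma0 <- if (is.null(gamma_base)) 2.38 / sqrt(2 * d) else gamma_base
  chains <- vector("list", n_chains)
  lps <- vector("list", n_chains)
  acc_rates <- numeric(n_chains)
  for (c in seq_len(n_chains)) {
    log_post <- lp_funs[[c]]
    set.seed(chain_seeds[c])
    z_cap <- z0 + (n_gen %/% archive_thin + 1L) * n_internal
    Z <- matrix(NA_real_, z_cap, d)
    Zi <- if (is.null(z_init)) sample_prior(priors, z0) else {
      pmin(pmax(z_init, matrix(priors$lower, z0, d, byrow = TRUE)),
           matrix(priors$upper, z0, d, byrow = TRUE))
    }
    if (is.null(z_init) && z_init_scale != 1) {
      centre <- if (init == "start") start_state else priors$mean
      Zi <- sweep(sweep(Zi, 2, priors$mean, "-") * z_init_scale, 2,
                  centre, "+")
      Zi <- pmin(pmax(Zi, matrix(priors$lower, z0, d, byrow = TRUE)),
                 matrix(priors$upper, z0, d, byrow = TRUE))
    }
    Z[seq_len(z0), ] <- Zi
    z_n <- z0
    if (z0 < 2 * d + 2) stop("initial archive too small")
    X <- switch(init,
      prior = sample_prior(priors, n_internal),
      prior_mean = matrix(priors$mean, n_internal, d, byrow = TRUE,
                          dimnames = list(NULL, priors$name)),
      start = matrix(start_state, n_internal, d, byrow = TRUE,
                     dimnames = list(NULL, priors$name)))
    lp_cur <- apply(X, 1, log_post)
    # a finite starting value helps chains leave flat -Inf regions fast
    tries <- 0
    while (any(!is.finite(lp_cur)) && tries < 50) {
      bad <- !is.finite(lp_cur)
      X[bad, ] <- sample_prior(priors, sum(bad))
      lp_cur[bad] <- apply(X[bad, , drop = FALSE], 1, log_post)
      tries <- tries + 1
    }
    samples <- array(NA_real_, c(n_gen, n_internal, d))
    lp_hist <- matrix(NA_real_, n_gen, n_internal)
    n_acc <- 0L
    for (g in seq_len(n_gen)) {
      gamma <- if (g %% gamma_jump_every == 0) 1 else gamma0
      if (refresh_every > 0 && g %% refresh_every == 0) {
        lp_cur <- apply(X, 1, function(x) {
          names(x) <- priors$name
          log_post(x)
        })
      }
      Zv <- Z[seq_len(z_n), , drop = FALSE]
      for (i in seq_len(n_internal)) {
        x <- X[i, ]
        log_corr <- 0
        if (stats::runif(1) < snooker_prob) {
          sn <- propose_snooker(x, Zv)
          if (is.null(sn)) {
            xp <- propose_de(x, Zv, gamma, eps_sd)
          } else {
            xp <- sn$x
            log_corr <- sn$log_corr
          }
        } else {
          xp <- propose_de(x, Zv, gamma, eps_sd)
        }
        names(xp) <- priors$name
        lp_new <- log_post(xp)
        if (is.finite(lp_new) &&
            log(stats::runif(1)) < lp_new - lp_cur[i] + log_corr) {
          X[i, ] <- xp
          lp_cur[i] <- lp_new
          n_acc <- n_acc + 1L
        }
      }
      samples[g, , ] <- X
      lp_hist[g, ] <- lp_cur
      if (g %% archive_thin == 0) {
        Z[z_n + seq_len(n_internal), ] <- X
        z_n <- z_n + n_internal
      }
    }
    chains[[c]] <- samples
    lps[[c]] <- lp_hist
    acc_rates[c] <- n_acc / (n_gen * n_internal)
  }
  structure(list(chains = chains, log_posteriors = lps,
                 acceptance = acc_rates, chain_seeds = chain_seeds,
                 param_names = priors$name, n_internal = n_internal,
                 n_gen = n_gen, burn_frac = burn_frac,
                 settings = list(iterations = iterations,
                                 snooker_prob = snooker_prob,
                                 archive_thin = archive_thin,
                                 gamma_jump_every = gamma_jump_every,
                                 z_start_factor = z_start_factor)),
            class = "mcmc_run")
}

#' Post-burn-in sub-chains of a run
#'
#' @param run An `mcmc_run`.
#' @param burn_frac Burn-in fraction (default: the run's own).
#' @return List of numeric matrices (one per internal chain of each DEzs
#'   chain), rows = post-burn-in generations, named columns.
#' @export
mcmc_chain_list <- function(run, burn_frac = run$burn_frac) {
  stopifnot(inherits(run, "mcmc_run"))
  keep <- seq(floor(run$n_gen * burn_frac) + 1, run$n_gen)
  out <- list()
  for (c in seq_along(run$chains)) {
    for (i in seq_len(run$n_internal)) {
      m <- run$chains[[c]][keep, i, , drop = FALSE]
      m <- matrix(m, length(keep), length(run$param_names))
      colnames(m) <- run$param_names
      out[[length(out) + 1]] <- m
    }
  }
  out
}

#' @export
print.mcmc_run <- function(x, ...) {
  cat(sprintf(
    "mcmc_run: %d DEzs chains x %d internal chains x %d generations\n",
    length(x$chains), x$n_internal, x$n_gen))
  cat(sprintf("acceptance rates: %s\n",
              paste(sprintf("%.3f", x$acceptance), collapse = ", ")))
  invisible(x)
}

#' Summarize posterior marginals
#'
#' @param object An `mcmc_run`.
#' @param probs Quantiles to report.
#' @param ... Unused.
#' @return Data frame: mean, sd and quantiles per parameter (post
#'   burn-in, pooled over chains).
#' @export
summary.mcmc_run <- function(object, probs = c(0.1, 0.5, 0.9), ...) {
  pool <- do.call(rbind, mcmc_chain_list(object))
  qs <- t(apply(pool, 2, stats::quantile, probs = probs))
  colnames(qs) <- paste0("q", probs * 100)
  data.frame(parameter = colnames(pool), mean = colMeans(pool),
             sd = apply(pool, 2, stats::sd), qs, row.names = NULL)
}
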