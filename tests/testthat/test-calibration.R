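test_that("the prior is a renormalized truncated-normal product", {
  pr <- default_priors()
  theta <- param_vector(base = preset_params("mountain"))
  expect_true(is.finite(log_prior(theta, pr)))
  # outside the slope truncation
  bad <- param_vector(base = theta); bad["fec_Tbr"] <- 6
  expect_identical(log_prior(bad, pr), -Inf)
  bad2 <- param_vector(base = theta); bad2["sigma"] <- 501
  expect_identical(log_prior(bad2, pr), -Inf)
  # closed-form truncated-normal oracle, parameter by parameter
  set.seed(1)
  draw <- sample_prior(pr, 1)[1, ]
  oracle <- sum(vapply(seq_len(nrow(pr)), function(i) {
    z <- pnorm(pr$upper[i], pr$mean[i], pr$sd[i]) -
      pnorm(pr$lower[i], pr$mean[i], pr$sd[i])
    dnorm(draw[i], pr$mean[i], pr$sd[i], log = TRUE) - log(z)
  }, numeric(1)))
  expect_equal(log_prior(draw, pr), oracle, tolerance = 1e-12)
  # a standard-normal slope at 0 contributes dnorm(0) minus its
  # truncation mass on [-5, 5]
  one <- pr[pr$name == "fec_Tbr", ]
  expect_equal(dnorm(0, log = TRUE) - log(pnorm(5) - pnorm(-5)),
               log(dnorm(0) / (pnorm(5) - pnorm(-5))))
  # prior samples live inside their bounds
  set.seed(2)
  S <- sample_prior(pr, 500)
  expect_true(all(t(S) >= pr$lower & t(S) <= pr$upper))
})

test_that("negative-binomial likelihood matches the log-gamma closed form", {
  set.seed(3)
  for (i in 1:50) {
    y <- sample(0:40, 1)
    mu <- runif(1, 0.01, 25)
    sigma <- runif(1, 0.5, 80)
    closed <- lgamma(y + sigma) - lgamma(sigma) - lgamma(y + 1) +
      sigma * log(sigma / (sigma + mu)) + y * log(mu / (sigma + mu))
    expect_equal(nb_loglik(y, mu, sigma), closed, tolerance = 1e-10)
  }
  # zero count at zero mean contributes (essentially) log 1
  expect_equal(nb_loglik(0L, 0, 5), 0, tolerance = 1e-5)
  # positive count at zero mean is finite but heavily penalized
  expect_true(is.finite(nb_loglik(3L, 0, 5)))
  expect_lt(nb_loglik(3L, 0, 5), -30)
  # Poisson limit
  expect_lt(abs(nb_loglik(3L, 2, 1e6) - dpois(3, 2, log = TRUE)), 1e-3)
  expect_error(nb_loglik(3L, 2, 0), "sigma must be > 0")
  expect_error(nb_loglik(-1L, 2, 5), "non-negative integers")
})

test_that("likelihood aggregation sums sites into blocks and averages reps", {
  # 2 blocks of one site each: aggregation is the identity on counts
  ab <- array(0L, c(10, 10, 2, 2))
  ab[3, 3, , ] <- 4L
  ab[8, 8, , ] <- 6L
  sv <- data.frame(site_id = rep(1:2, each = 2),
                   x_cell = rep(c(3L, 8L), each = 2),
                   y_cell = rep(c(3L, 8L), each = 2),
                   year = rep(2000:2001, 2), count = c(5L, 7L, 2L, 9L))
  agg <- aggregate_for_likelihood(ab, sv, 2000:2001, block_size = 5)
  expect_equal(nrow(agg), 4)
  expect_equal(sort(unique(agg$y[agg$block == agg$block[1]])),
               sort(sv$count[sv$site_id == 1]))
  expect_equal(agg$mu[agg$block == "0_0"], c(4, 4))
  # 4 sites in one block: y = 1+2+3+4 = 10; two replicates with block
  # sums 6 and 8 average to mu = 7
  ab2 <- array(0L, c(10, 10, 1, 2))
  xs <- c(1L, 2L, 1L, 2L); ys <- c(1L, 1L, 2L, 2L)
  ab2[cbind(ys, xs, 1L, 1L)] <- c(1L, 2L, 1L, 2L)   # sums to 6
  ab2[cbind(ys, xs, 1L, 2L)] <- c(2L, 2L, 2L, 2L)   # sums to 8
  sv2 <- data.frame(site_id = 1:4, x_cell = xs, y_cell = ys, year = 2000L,
                    count = 1:4)
  agg2 <- aggregate_for_likelihood(ab2, sv2, 2000L, block_size = 5)
  expect_equal(agg2$y, 10)
  expect_equal(agg2$mu, 7)
})

test_that("the log posterior short-circuits, pins and concentrates", {
  b <- small_bundle()
  pr <- default_priors(b$scenario$theta_true)
  lp_pin <- make_log_posterior(b$survey$survey, b$climate$std, b$habitat,
                               b$initial, pr, n_reps = 2, block_size = 4,
                               seed_policy = "pinned", pin_seed = 7)
  theta <- param_vector(base = b$scenario$theta_true)
  # outside support: -Inf without calling the simulator
  before <- attr(lp_pin, "n_sim_calls")()
  bad <- param_vector(base = theta); bad["sj_Tat"] <- 9
  expect_identical(lp_pin(bad), -Inf)
  expect_equal(attr(lp_pin, "n_sim_calls")(), before)
  # pinned seed: repeated evaluation identical
  v1 <- lp_pin(theta)
  v2 <- lp_pin(theta)
  expect_identical(v1, v2)
  expect_true(is.finite(v1))
  # replicate averaging tempers the stochastic likelihood: variance
  # shrinks roughly like 1/n_reps
  var_of <- function(n_reps) {
    lp <- make_log_posterior(b$survey$survey, b$climate$std, b$habitat,
                             b$initial, pr, n_reps = n_reps, block_size = 4)
    set.seed(11)
    var(replicate(25, lp(theta)))
  }
  v_small <- var_of(1)
  v_big <- var_of(8)
  expect_lt(v_big, v_small / 2)
})

test_that("PSRF separates mixed from unmixed chains and matches coda", {
  set.seed(5)
  mk <- function(mu) matrix(rnorm(5000 * 2, mu), 5000, 2,
                            dimnames = list(NULL, c("a", "b")))
  same <- list(mk(0), mk(0), mk(0))
  gr_same <- gelman_rubin(same)
  expect_true(all(gr_same$psrf < 1.05))
  expect_true(gr_same$converged)
  ident <- list(same[[1]], same[[1]] + 1e-12)
  expect_true(all(gelman_rubin(ident)$psrf < 1.01))
  shifted <- list(mk(0), mk(5), mk(0))
  gr_shift <- gelman_rubin(shifted)
  expect_true(all(gr_shift$psrf > 1.1))
  expect_false(gr_shift$converged)
  skip_if_not_installed("coda")
  # independent cross-check near convergence, where the estimator
  # conventions (degrees-of-freedom correction) agree closely
  cl <- coda::mcmc.list(lapply(same, coda::mcmc))
  cg <- coda::gelman.diag(cl, autoburnin = FALSE, transform = FALSE)
  expect_equal(unname(gr_same$psrf), unname(cg$psrf[, 1]), tolerance = 0.01)
  cl2 <- coda::mcmc.list(lapply(shifted, coda::mcmc))
  cg2 <- coda::gelman.diag(cl2, autoburnin = FALSE, transform = FALSE)
  expect_true(all(cg2$psrf[, 1] > 1.1) && all(gr_shift$psrf > 1.1))
  expect_error(gelman_rubin(list(mk(0))), "at least 2 chains")
  expect_error(gelman_rubin(list(mk(0)[1:5, ], mk(0)[1:5, ])), "too short")
})

test_that("posterior draws resample the pooled chains faithfully", {
  pr <- default_priors()[15:18, ]  # small dimension for speed
  pr$name <- c("a", "b", "c", "d")
  target_mu <- c(0.3, 0.5, 3, 40)
  lp <- function(th) sum(dnorm(th, target_mu, c(0.05, 0.1, 0.5, 5),
                               log = TRUE))
  run <- dezs_sample(lp, pr, n_chains = 2, iterations = 3000, seed = 9)
  pool <- do.call(rbind, mcmc_chain_list(run))
  d1 <- posterior_draws(run, n = 200, seed = 4)
  d2 <- posterior_draws(run, n = 200, seed = 4)
  expect_identical(d1, d2)
  # more draws than the pool: sampling with replacement, members only
  dbig <- posterior_draws(run, n = nrow(pool) + 500, seed = 1)
  expect_true(all(dbig[, "a"] %in% pool[, "a"]))
  # marginal means within Monte-Carlo error of pooled-chain means
  d3 <- posterior_draws(run, n = 400, seed = 2)
  for (j in 1:4) {
    expect_lt(abs(mean(d3[, j]) - mean(pool[, j])),
              4 * sd(pool[, j]) / sqrt(400))
  }
})

test_that("a stochastic likelihood with known truth is covered at
           roughly the nominal rate (pseudo-marginal sanity)", {
  # sigma of an NB observation model with known means, 20 repeats:
  # the 80% credible interval should cover the truth ~16/20 times
  sigma_true <- 25
  mu <- rep(c(2, 5, 9, 14), each = 50)
  pr <- data.frame(name = "sigma", mean = 50, sd = 50, lower = 0.01,
                   upper = 500)
  class(pr) <- c("prior_spec", "data.frame")
  covered <- 0
  set.seed(77)
  rep_seeds <- sample.int(1e6, 20)
  for (r in 1:20) {
    set.seed(rep_seeds[r])
    y <- rnbinom(length(mu), size = sigma_true, mu = mu)
    lp <- function(th) {
      if (th[1] < pr$lower || th[1] > pr$upper) return(-Inf)
      log_prior(c(sigma = th[1]), pr) + nb_loglik(y, mu, th[1])
    }
    run <- dezs_sample(lp, pr, n_chains = 2, iterations = 1200,
                       seed = rep_seeds[r])
    pool <- do.call(rbind, mcmc_chain_list(run))
    ci <- quantile(pool[, 1], c(0.1, 0.9))
    if (sigma_true >= ci[1] && sigma_true <= ci[2]) covered <- covered + 1
  }
  # binomial(20, 0.8): 11 is ~3 sd below the mean
  expect_gte(covered, 11)
})
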