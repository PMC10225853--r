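test_that("synthetic climate has the requested trend, noise and determinism", {
  sc0 <- synthetic_scenario(nr = 8, nc = 8, first_year = 2000,
                            last_year = 2009, n_sites = 10,
                            clim_noise_sd = c(T_br = 0, P_br = 0, T_at = 0,
                                              T_wn = 0, P_wn = 0),
                            clim_slope = c(T_br = 0, P_br = 0, T_at = 0,
                                           T_wn = 0, P_wn = 0), seed = 2)
  cl0 <- gen_climate(sc0)
  # zero slope, zero noise: every year's grid identical
  for (k in 2:10) {
    expect_identical(cl0$raw$layers$T_br[, , k], cl0$raw$layers$T_br[, , 1])
  }
  # same seed twice: bit-identical stacks
  expect_identical(gen_climate(sc0), cl0)
  # requested slope recovered within 2 SE by OLS on landscape means
  sc1 <- synthetic_scenario(nr = 10, nc = 10, first_year = 1999,
                            last_year = 2019, n_sites = 10, seed = 31)
  cl1 <- gen_climate(sc1)
  tr <- fit_trend(cl1$raw)
  for (p in predictor_ids()) {
    row <- tr[tr$predictor == p, ]
    expect_lt(abs(row$slope - sc1$clim_slope[[p]]), 2 * row$se_slope)
  }
  # raw and standardized members agree through the recorded transform
  expect_equal(unstandardize(cl1$std)$layers, cl1$raw$layers,
               tolerance = 1e-12)
  expect_error(synthetic_scenario(corr_length = 0), "must be > 0")
})

test_that("synthetic habitat honours cover and clusters when asked", {
  base <- list(nr = 12, nc = 12, first_year = 2000, last_year = 2004,
               n_sites = 10)
  h0 <- gen_habitat(do.call(synthetic_scenario, c(base, cover = 0, seed = 1)))
  expect_true(all(h0 == 0L))
  h1 <- gen_habitat(do.call(synthetic_scenario, c(base, cover = 1, seed = 1)))
  expect_true(all(h1 == 100L))
  sc <- do.call(synthetic_scenario, c(base, cover = 0.4, seed = 8))
  h <- gen_habitat(sc)
  expect_true(all(h >= 0 & h <= 100) && is.integer(h))
  # realized cover within 5 percentage points of the request
  expect_lt(abs(mean(h) / 100 - 0.4), 0.05)
  # clustering raises Moran's I relative to independent habitat
  sc_iid <- do.call(synthetic_scenario,
                    c(base, cover = 0.4, clustering = 0, seed = 8))
  expect_gt(morans_i(h + 0), morans_i(gen_habitat(sc_iid) + 0))
  expect_identical(gen_habitat(sc), h)
})

test_that("Moran's I matches the explicit double-sum oracle", {
  set.seed(9)
  for (i in 1:3) {
    m <- matrix(rnorm(30), 5, 6)
    expect_equal(morans_i(m), morans_i_oracle(m), tolerance = 1e-12)
  }
})

test_that("spin-up initial abundance behaves at its degenerate limits", {
  clim <- flat_climate(8, 8, 2000:2003)
  hab <- flat_habitat(8, 8, 50L)
  hab[1:2, ] <- 0L
  theta <- preset_params("mountain")
  st0 <- gen_initial_abundance(hab, clim, theta, spinup_years = 0,
                               seed_density = 2)
  expect_true(all(st0$A[hab > 0] == 2L))
  expect_true(all(st0$A[hab == 0] == 0L))
  # lethal rates: survival -> 0 and no reproduction drives extinction
  lethal <- param_vector(sj_icpt = -50, sa_icpt = -50, fec_icpt = -50)
  stl <- gen_initial_abundance(hab, clim, lethal, spinup_years = 10, seed = 3)
  expect_equal(sum(stl$A), 0)
  expect_error(gen_initial_abundance(matrix(0L, 4, 4), clim, theta),
               "no suitable cells")
})

test_that("spin-up settles into the replicate equilibrium band", {
  clim <- flat_climate(10, 10, 2000:2002)
  hab <- flat_habitat(10, 10)
  theta <- preset_params("mountain")
  totals <- vapply(1:100, function(s) {
    sum(gen_initial_abundance(hab, clim, theta, spinup_years = 25,
                              seed = 1000 + s)$A)
  }, numeric(1))
  one <- sum(gen_initial_abundance(hab, clim, theta, spinup_years = 25,
                                   seed = 7)$A)
  expect_lt(abs(one - mean(totals)), 3 * sd(totals))
  # band itself is sane: a persistent population, not extinction
  expect_gt(mean(totals), 100)
})

test_that("surveys are valid count tables wired to the simulated truth", {
  b <- small_bundle()
  sv <- b$survey$survey
  expect_true(all(sv$count >= 0 & sv$count == round(sv$count)))
  expect_true(all(sv$x_cell >= 1 & sv$x_cell <= 12 &
                    sv$y_cell >= 1 & sv$y_cell <= 12))
  expect_equal(anyDuplicated(sv[, c("site_id", "year")]), 0)
  expect_equal(nrow(sv), 20 * 8)
  # noise-free reference index is 1 at the first year by construction
  expect_equal(b$survey$reference_index$index[1], 1)
  expect_equal(b$survey$reference_index$index,
               b$survey$truth$total / b$survey$truth$total[1])
  # observed counts are NB draws around the simulated truth: the mean
  # over all site-years sits within 3 SE of the mean simulated abundance
  truth_at_sites <- t(apply(b$survey$truth$abundance, 3, function(m)
    m[cbind(b$survey$truth$sites$y_cell, b$survey$truth$sites$x_cell)]))
  mu <- as.numeric(truth_at_sites)  # site-major per year
  sv_o <- sv[order(sv$year, sv$site_id), ]
  se <- sqrt(sum(mu + mu^2 / b$scenario$sigma_true)) / length(mu)
  expect_lt(abs(mean(sv_o$count) - mean(mu)), 3 * se)
  expect_error(gen_survey(b$scenario$theta_true, b$climate$std, b$habitat,
                          5, sigma_true = 0), "sigma_true must be > 0")
})

test_that("whole bundles regenerate identically from the master seed", {
  sc <- synthetic_scenario(nr = 8, nc = 8, first_year = 2001,
                           last_year = 2005, n_sites = 6, seed = 123,
                           spinup_years = 5)
  b1 <- gen_scenario_bundle(sc)
  b2 <- gen_scenario_bundle(sc)
  expect_identical(b1$climate$raw$layers, b2$climate$raw$layers)
  expect_identical(b1$habitat, b2$habitat)
  expect_identical(b1$initial$A, b2$initial$A)
  expect_identical(b1$survey$survey, b2$survey$survey)
})
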