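test_that("growth rate is the dominant eigenvalue of the stage matrix", {
  # reducible cases collapse to adult survival
  expect_equal(growth_rate(0.5, 0, 3), 0.5)
  expect_equal(growth_rate(0.5, 0.4, 0), 0.5)
  # perfect square: sa = 0, sj * rho = 1
  expect_equal(growth_rate(0, 0.25, 4), 1)
  expect_equal(growth_rate(0.6, 0.3, 2.5), 0.3 + sqrt(0.84))
  # numeric eigen-decomposition oracle on random triples
  set.seed(1)
  for (i in 1:1000) {
    sa <- runif(1); sj <- runif(1); rho <- runif(1, 0, 6)
    ev <- max(abs(eigen(matrix(c(0, sj, rho, sa), 2, 2),
                        only.values = TRUE)$values))
    expect_equal(growth_rate(sa, sj, rho), ev, tolerance = 1e-12)
  }
})

test_that("growth rate is nondecreasing in each demographic rate", {
  grid <- seq(0.05, 0.95, by = 0.15)
  for (sj in grid) for (rho in c(0.5, 1.5, 3)) {
    expect_true(all(diff(growth_rate(grid, sj, rho)) >= 0))
  }
  for (sa in grid) for (rho in c(0.5, 1.5, 3)) {
    expect_true(all(diff(growth_rate(sa, grid, rho)) >= 0))
  }
  for (sa in grid) for (sj in grid) {
    expect_true(all(diff(growth_rate(sa, sj, seq(0, 5, by = 0.5))) >= 0))
  }
})

test_that("growth-rate maps compose the DCRs with the eigenvalue formula", {
  clim <- flat_climate(6, 6, 2000:2003)
  hab <- flat_habitat(6, 6)
  hab[1, ] <- 0L
  theta0 <- param_vector(b = 0.01)
  gm <- growth_rate_map(theta0, clim, 2001, hab)
  # zero coefficients, b = 0.01, h = 100: closed-form value
  expect_equal(unique(gm$r[hab > 0]),
               0.25 + sqrt(0.0625 + 0.5 * exp(-0.01)))
  expect_true(all(is.na(gm$r[hab == 0])))
  # equals the scalar chain cell by cell for heterogeneous habitat
  hab2 <- flat_habitat(6, 6, 30L)
  hab2[3, 3] <- 90L
  theta <- preset_params("lowland")
  gm2 <- growth_rate_map(theta, clim, 2000, hab2)
  bl <- param_blocks(theta)
  for (ij in list(c(3, 3), c(2, 5))) {
    rho1 <- fecundity_realized(fecundity_max(0, 0, bl$fec), 1,
                               hab2[ij[1], ij[2]], bl$b)
    expect_equal(gm2$r[ij[1], ij[2]],
                 growth_rate(survival_rate(0, 0, bl$sa, "sa"),
                             survival_rate(0, 0, bl$sj, "sj"), rho1))
  }
  expect_identical(gm2$growing, gm2$r > 1)
})

test_that("effect classes follow the 5% and 10% thresholds", {
  expect_equal(classify_effect(c(0.96, 0.93, 0.88, 1.04, 1.07, 1.12)),
               c("none", "small decrease", "strong decrease", "none",
                 "small increase", "strong increase"))
  expect_equal(classify_effect(1), "none")
})

test_that("partial responses isolate one predictor's accumulated trend", {
  clim_sample <- data.frame(T_br = rnorm(200), P_br = rnorm(200),
                            T_at = rnorm(200), T_wn = rnorm(200),
                            P_wn = rnorm(200))
  trend <- fit_trend(trended_climate(4, 4, 2000:2019, slope = 0.05))
  std1 <- lapply(stats::setNames(predictor_ids(), predictor_ids()),
                 function(p) list(mean = 0, sd = 1))
  # a draw with no climate effect anywhere: every ratio exactly 1
  theta0 <- param_vector(b = 0.01)
  pr0 <- partial_response(theta0, clim_sample, trend, std = std1)
  expect_equal(pr0$ratio, rep(1, 5))
  expect_equal(pr0$class, rep("none", 5))
  # zero trends: ratio 1 for every predictor even with strong DCRs
  trend0 <- fit_trend(trended_climate(4, 4, 2000:2019, slope = 0))
  pr1 <- partial_response(preset_params("mountain"), clim_sample, trend0,
                          std = std1)
  expect_equal(pr1$ratio, rep(1, 5))
  # closed-form chain oracle: only a linear winter-temperature effect on
  # adult survival; shift T_wn by +1 standardized unit
  theta <- param_vector(sa_Twn = 0.2, b = 0.01)
  med <- vapply(clim_sample, median, numeric(1))
  trend1 <- trend
  trend1$slope <- ifelse(trend1$predictor == "T_wn", 0.05, 0)
  trend1$accumulated <- ifelse(trend1$predictor == "T_wn", 1, 0)
  pr2 <- partial_response(theta, clim_sample, trend1, std = std1,
                          h_ref = 100)
  rho1 <- exp(-0.01)
  r_base <- growth_rate(plogis(0.2 * med[["T_wn"]]), 0.5, rho1)
  r_shift <- growth_rate(plogis(0.2 * (med[["T_wn"]] + 1)), 0.5, rho1)
  row <- pr2[pr2$predictor == "T_wn", ]
  expect_equal(row$base_r, unname(r_base))
  expect_equal(row$ratio, unname(r_shift / r_base))
  expect_equal(pr2$ratio[pr2$predictor != "T_wn"], rep(1, 4))
  # standardization record rescales raw trends into z-units
  std2 <- std1
  std2$T_wn$sd <- 2
  pr3 <- partial_response(theta, clim_sample, trend1, std = std2)
  r_half <- growth_rate(plogis(0.2 * (med[["T_wn"]] + 0.5)), 0.5, rho1)
  expect_equal(pr3$ratio[pr3$predictor == "T_wn"],
               unname(r_half / r_base))
})

test_that("scenario ratios are exactly 1 when climate cannot matter", {
  b <- small_bundle()
  theta <- param_vector(base = b$scenario$theta_true)
  # identical climates, common random numbers
  sr <- scenario_ratio(theta, b$climate$std, b$climate$std, b$habitat,
                       b$initial, n_reps = 2, seed = 3)
  expect_equal(sr$ratios, 1)
  expect_equal(sr$median, 1)
  # climate-insensitive parameters: detrended scenario changes nothing
  theta0 <- param_vector(fec_icpt = log(1.8), sj_icpt = 0.3, b = 0.05,
                         p_e = 0.2)
  cf <- detrend(b$climate$std, fit_trend(b$climate$std))
  sr0 <- scenario_ratio(theta0, b$climate$std, cf, b$habitat, b$initial,
                        n_reps = 2, seed = 4)
  expect_equal(sr0$ratios, 1)
  # counterfactual extinction is excluded and reported
  lethal <- param_vector(fec_icpt = -50, sj_icpt = -50, sa_icpt = -50)
  expect_error(scenario_ratio(lethal, b$climate$std, cf, b$habitat,
                              b$initial, n_reps = 1, seed = 5),
               "extinct for every draw")
})
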