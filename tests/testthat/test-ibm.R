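theta_flat <- param_vector(b = 0.001, p_e = 0.3, dbar = 2)

flat_rates <- function(nr, nc, hab, rho = 1, sj = 0.5, sa = 0.5) {
  mk <- function(v) {
    m <- matrix(v, nr, nc)
    m[hab <= 0] <- NA_real_
    m
  }
  structure(list(rho_max = mk(rho), sj = mk(sj), sa = mk(sa),
                 year = 2000, habitat = hab), class = "rate_maps")
}

test_that("reproduction is Poisson with the density-dependent mean", {
  nr <- 100; nc <- 100
  hab <- flat_habitat(nr, nc, 80L)
  theta <- param_vector(b = 0.01)
  rates <- flat_rates(nr, nc, hab, rho = 1.6)
  n <- 12L
  st <- population_state(matrix(n, nr, nc))
  set.seed(1)
  J <- reproduce(st, rates, theta)
  # 10^4 cells = 10^4 replicate draws of one mean
  mu <- n * fecundity_realized(1.6, n, 80, 0.01)
  se <- sqrt(mu / (nr * nc))
  expect_lt(abs(mean(J) - mu), 3 * se)
  # empty cells and unsuitable cells produce nothing
  st0 <- population_state(matrix(0L, 4, 4))
  expect_true(all(reproduce(st0, flat_rates(4, 4, flat_habitat(4, 4)),
                            theta) == 0L))
  hab0 <- matrix(0L, 4, 4)
  stbad <- population_state(matrix(5L, 4, 4))
  expect_true(all(reproduce(stbad, flat_rates(4, 4, hab0), theta) == 0L))
})

test_that("dispersal conserves individuals and respects suitability", {
  nr <- 15; nc <- 15
  hab <- flat_habitat(nr, nc, 70L)
  cohort <- matrix(0L, nr, nc)
  cohort[8, 8] <- 500L
  # p_e = 0: everyone stays home
  d0 <- disperse(cohort, hab, param_vector(p_e = 0), record = FALSE)
  expect_identical(d0$settled, cohort)
  expect_equal(d0$deaths, 0)
  # general case: settled + deaths = cohort
  set.seed(2)
  d1 <- disperse(cohort, hab, param_vector(p_e = 0.8, dbar = 3))
  expect_equal(sum(d1$settled) + d1$deaths, sum(cohort))
  # no settlement on unsuitable cells
  hab2 <- hab
  hab2[, 1:7] <- 0L
  d2 <- disperse(cohort, hab2, param_vector(p_e = 1, dbar = 4))
  expect_true(all(d2$settled[hab2 == 0] == 0L))
  expect_equal(sum(d2$settled) + d2$deaths, sum(cohort))
  # an isolated natal cell in a hostile landscape: emigrants nearly all die
  hab3 <- matrix(0L, nr, nc)
  hab3[8, 8] <- 50L
  set.seed(3)
  d3 <- disperse(cohort, hab3, param_vector(p_e = 1, dbar = 50))
  expect_gt(d3$deaths / sum(cohort), 0.95)
})

test_that("survival and transition follow the two-stage bookkeeping", {
  nr <- 50; nc <- 50
  hab <- flat_habitat(nr, nc)
  A <- matrix(20L, nr, nc)
  J <- matrix(10L, nr, nc)
  st <- population_state(A, J)
  # certain survival: adults' = adults + juveniles exactly
  r1 <- survive_and_transition(st, flat_rates(nr, nc, hab, sj = plogis(50),
                                              sa = plogis(50)))
  expect_true(all(r1$A == 30L))
  expect_true(all(r1$J == 0L))
  # certain death: extinction
  r0 <- survive_and_transition(st, flat_rates(nr, nc, hab, sj = 1e-300,
                                              sa = 1e-300))
  expect_equal(sum(r0$A), 0)
  # binomial means within 3 SE over 2500 cells
  set.seed(4)
  r <- survive_and_transition(st, flat_rates(nr, nc, hab, sj = 0.3, sa = 0.7))
  mu <- 20 * 0.7 + 10 * 0.3
  se <- sqrt((20 * 0.7 * 0.3 + 10 * 0.3 * 0.7) / (nr * nc))
  expect_lt(abs(mean(r$A) - mu), 3 * se)
})

test_that("the annual cycle composes reproduction, dispersal, survival", {
  hab <- flat_habitat(6, 6)
  theta <- param_vector(b = 0.001, p_e = 0)
  # empty state is absorbing
  empty <- population_state(matrix(0L, 6, 6))
  out <- step_year(empty, flat_rates(6, 6, hab, rho = 2), theta)
  expect_equal(sum(out$A), 0)
  # accounting detail: settled + dispersal deaths = produced cohort,
  # survivors bounded by their pre-survival counts
  set.seed(5)
  st <- population_state(matrix(8L, 6, 6))
  det <- step_year(st, flat_rates(6, 6, hab, rho = 1.5), theta,
                   detail = TRUE)
  expect_equal(sum(det$settled) + det$dispersal_deaths, sum(det$produced))
  expect_true(all(det$J_surv <= det$settled))
  expect_true(all(det$A_surv <= st$A))
  expect_equal(det$state$A, det$J_surv + det$A_surv)
  # order contract: with certain survival and no dispersal, next adults
  # equal pre-reproduction adults plus the produced cohort -- fecundity
  # must have used pre-reproduction adults, not post-transition ones
  det2 <- step_year(st, flat_rates(6, 6, hab, rho = 1.5, sj = plogis(50),
                                   sa = plogis(50)), theta, detail = TRUE)
  expect_equal(det2$state$A, st$A + det2$produced)
})

test_that("survival is evaluated at the settlement cell, not the natal cell", {
  # natal column is lethal for juveniles, destination column is safe;
  # with forced short-range emigration all surviving juveniles must have
  # been scored with the settlement cell's s_j
  hab <- matrix(0L, 3, 3)
  hab[2, 2] <- 100L  # natal
  hab[2, 3] <- 100L  # only other suitable cell
  sj <- matrix(0, 3, 3)
  sj[2, 2] <- 0      # lethal at natal cell
  sj[2, 3] <- 1      # certain survival at destination
  rates <- structure(list(rho_max = matrix(2, 3, 3), sj = sj,
                          sa = matrix(0, 3, 3), year = 2000,
                          habitat = hab), class = "rate_maps")
  theta <- param_vector(b = 0.0001, p_e = 1, dbar = 1)
  set.seed(6)
  st <- population_state({
    A <- matrix(0L, 3, 3); A[2, 2] <- 200L; A
  })
  det <- step_year(st, rates, theta, detail = TRUE)
  # juveniles that settled at (2,3) all survive; any left at (2,2) all die
  expect_equal(det$J_surv[2, 3], det$settled[2, 3])
  expect_equal(det$J_surv[2, 2], 0L)
  expect_gt(det$settled[2, 3], 0L)
})

test_that("one-step mean matches the density-feedback matrix expectation", {
  nr <- 40; nc <- 40
  hab <- flat_habitat(nr, nc)
  theta <- param_vector(b = 0.001, p_e = 0)
  n <- 10L
  rho_max <- 1.4; sj <- 0.45; sa <- 0.55
  rho_n <- fecundity_realized(rho_max, n, 100, 0.001)
  mu <- n * (sa + sj * rho_n)
  set.seed(7)
  st <- population_state(matrix(n, nr, nc))
  out <- step_year(st, flat_rates(nr, nc, hab, rho_max, sj, sa), theta)
  var1 <- n * sa * (1 - sa) + n * rho_n * sj # Poisson-thinned juveniles
  se <- sqrt(var1 / (nr * nc))
  expect_lt(abs(mean(out$A) - mu), 3 * se)
})

test_that("replicate simulations are seed-reproducible and independent", {
  b <- small_bundle()
  theta <- b$scenario$theta_true
  s1 <- simulate_ibm(theta, b$climate$std, b$habitat, b$initial, n_reps = 2,
                     seed = 5)
  s2 <- simulate_ibm(theta, b$climate$std, b$habitat, b$initial, n_reps = 2,
                     seed = 5)
  expect_identical(s1$abundance, s2$abundance)
  expect_false(identical(s1$abundance[, , , 1], s1$abundance[, , , 2]))
  # no individual ever occupies an unsuitable cell
  for (k in seq_along(s1$years)) {
    expect_true(all(s1$abundance[, , k, 1][b$habitat == 0] == 0L))
  }
  # deterministic limit: no reproduction, certain adult survival
  frozen <- param_vector(fec_icpt = -50, sj_icpt = 50, sa_icpt = 50,
                         p_e = 0)
  s3 <- simulate_ibm(frozen, b$climate$std, b$habitat, b$initial,
                     n_reps = 1, seed = 1)
  for (k in seq_along(s3$years)) {
    expect_identical(s3$abundance[, , k, 1], unclass(b$initial$A))
  }
  expect_error(simulate_ibm(theta, b$climate$std, b$habitat[1:5, 1:5],
                            b$initial), "does not match")
})

test_that("with no emigration the occupied range never grows", {
  b <- small_bundle()
  theta <- param_vector(base = b$scenario$theta_true)
  theta["p_e"] <- 0
  s <- simulate_ibm(theta, b$climate$std, b$habitat, b$initial, n_reps = 1,
                    seed = 9)
  occ_prev <- b$initial$A > 0
  for (k in seq_along(s$years)) {
    occ <- s$abundance[, , k, 1] > 0
    expect_true(all(!occ | occ_prev))
    occ_prev <- occ
  }
})

test_that("raising adult survival raises expected abundance", {
  hab <- flat_habitat(12, 12, 60L)
  clim <- flat_climate(12, 12, 2000:2005)
  lo <- param_vector(fec_icpt = log(1.4), sa_icpt = qlogis(0.4), b = 0.01)
  hi <- param_vector(base = lo); hi["sa_icpt"] <- qlogis(0.7)
  init <- population_state(matrix(10L, 12, 12))
  tot <- function(th, seed) {
    s <- simulate_ibm(th, clim, hab, init, n_reps = 30, seed = seed)
    mean(apply(s$abundance[, , 6, , drop = FALSE], 4, sum))
  }
  expect_gt(tot(hi, 21), tot(lo, 21))
})

test_that("per-cell draws match the per-individual reference distribution", {
  nr <- 5; nc <- 5
  hab <- flat_habitat(nr, nc, 60L)
  theta <- param_vector(b = 0.01, p_e = 0.5, dbar = 1.5)
  rates <- flat_rates(nr, nc, hab, rho = 1.8, sj = 0.6, sa = 0.5)
  st <- population_state(matrix(6L, nr, nc))
  n_rep <- 150
  stat <- function(stepper) {
    set.seed(33)
    out <- replicate(n_rep, {
      d <- stepper(st, rates, theta, hab, detail = TRUE)
      c(adults = sum(d$state$A), produced = sum(d$produced),
        deaths = d$dispersal_deaths)
    })
    rowMeans(out)
  }
  fast <- stat(function(...) step_year(...))
  ref <- stat(function(st, rates, theta, hab, detail)
    step_year_reference(st, rates, theta, hab))
  # means agree within 4 combined standard errors (same model, two
  # independent implementations)
  set.seed(34)
  sd_fast <- apply(replicate(60, {
    d <- step_year(st, rates, theta, hab, detail = TRUE)
    c(sum(d$state$A), sum(d$produced), d$dispersal_deaths)
  }), 1, sd)
  tol <- 4 * sd_fast * sqrt(2 / n_rep)
  expect_lt(abs(fast[["adults"]] - ref[["adults"]]), tol[1])
  expect_lt(abs(fast[["produced"]] - ref[["produced"]]), tol[2])
  expect_lt(abs(fast[["deaths"]] - ref[["deaths"]]), tol[3])
})

test_that("runaway trajectories saturate instead of stalling", {
  hab <- flat_habitat(8, 8)
  clim <- flat_climate(8, 8, 2000:2004)
  explosive <- param_vector(fec_icpt = 6, sj_icpt = 5, sa_icpt = 5,
                            b = 1e-4, p_e = 0)
  init <- population_state(matrix(50L, 8, 8))
  t0 <- Sys.time()
  s <- simulate_ibm(explosive, clim, hab, init, n_reps = 1, seed = 2,
                    pop_ceiling = 1e5)
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 30)
  expect_true(max(s$abundance) >= 1e5)
})
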