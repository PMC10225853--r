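# Synthetic study systems: spatially autocorrelated climate with linear
# trends, clustered habitat, and surveys generated from the IBM under
# known parameters. Everything downstream is testable against the stored
# truths with no external data.

#' Deterministic sub-seed from a master seed and a stream label
#'
#' Expands one master seed into independent, reproducible module
#' streams (climate, habitat, survey, calibration, ...). The result is
#' below 2^31, hence a valid seed everywhere seeds are accepted.
#'
#' @param master Integer master seed.
#' @param label Character stream label.
#' @return Integer seed.
#' @export
derive_seed <- function(master, label) {
  # polynomial rolling hash of the label (collision-free in practice,
  # unlike simple character sums), mixed with the master seed; all
  # arithmetic stays below 2^53 so doubles are exact
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 2147483647
  as.integer((as.double(master) * 48271 + h * 7919 + h + 1) %% 2147483647)
}

#' Stationary Gaussian random field on a grid
#'
#' White noise convolved (circularly, via FFT) with an isotropic Gaussian
#' kernel of the given correlation length, then rescaled to zero mean and
#' unit variance. `corr_length = 0` returns plain white noise.
#'
#' @param nr,nc Grid dimensions.
#' @param corr_length Kernel length scale in cells (`>= 0`).
#' @return `nr x nc` matrix with mean 0 and sd 1.
#' @export
gaussian_field <- function(nr, nc, corr_length) {
  if (corr_length < 0) stop("correlation length must be >= 0")
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (corr_length == 0) return((z - mean(z)) / stats::sd(as.numeric(z)))
  dx <- pmin(0:(nr - 1), nr - (0:(nr - 1)))
  dy <- pmin(0:(nc - 1), nc - (0:(nc - 1)))
  k <- exp(-outer(dx^2, dy^2, "+") / (2 * corr_length^2))
  f <- Re(stats::fft(stats::fft(z) * stats::fft(k), inverse = TRUE))
  (f - mean(f)) / stats::sd(as.numeric(f))
}

#' Define a synthetic scenario
#'
#' Bundles every knob of the synthetic study system: grid, years, climate
#' means/trends/noise, habitat cover and clustering, the true parameter
#' vector and the observation process. Defaults emulate a two-decade
#' alpine survey: per-year predictor trends equal the observed Swiss
#' accumulated 20-year changes (+1.0 K breeding temperature, -11.6 mm
#' breeding precipitation, +1.1 K autumn temperature, +1.5 K minimum
#' winter temperature, +29 mm winter precipitation) divided by the span.
#'
#' @param nr,nc Grid rows and columns (each `>= 5`).
#' @param cell_km Cell edge length, km.
#' @param first_year,last_year Survey years (span `>= 3`).
#' @param clim_mean,clim_base_sd,clim_noise_sd,clim_slope Named numeric
#'   vectors over [predictor_ids()]: landscape mean, spatial sd of the
#'   fixed base field, interannual noise sd, and temporal trend
#'   (units/yr).
#' @param corr_length Climate spatial correlation length (cells, `> 0`).
#' @param cover Habitat cover fraction in \[0, 1\].
#' @param clustering Habitat clustering length (coarse cells, `>= 0`).
#' @param theta_true True [param_vector()].
#' @param sigma_true Observation (negative-binomial) dispersion; defaults
#'   to `theta_true["sigma"]`.
#' @param n_sites Number of surveyed cells.
#' @param seed_density Adults seeded per suitable cell before spin-up.
#' @param spinup_years Spin-up length under first-year climate.
#' @param seed Master seed; every derived artifact records its sub-seed.
#' @return Object of class `"synthetic_scenario"`.
#' @export
synthetic_scenario <- function(nr = 30, nc = 30, cell_km = 1,
                               first_year = 1999, last_year = 2019,
                               clim_mean = c(T_br = 12, P_br = 150,
                                             T_at = 8, T_wn = -5, P_wn = 100),
                               clim_base_sd = c(T_br = 2, P_br = 30,
                                                T_at = 2, T_wn = 3, P_wn = 25),
                               clim_noise_sd = c(T_br = 0.6, P_br = 15,
                                                 T_at = 0.6, T_wn = 0.8,
                                                 P_wn = 12),
                               clim_slope = c(T_br = 0.05, P_br = -0.58,
                                              T_at = 0.055, T_wn = 0.075,
                                              P_wn = 1.45),
                               corr_length = 5, cover = 0.5, clustering = 3,
                               theta_true = preset_params("mountain"),
                               sigma_true = NULL, n_sites = 60,
                               seed_density = 4, spinup_years = 30,
                               seed = 1) {
  if (nr < 5 || nc < 5) stop("grid must be at least 5 x 5")
  if (last_year - first_year < 2) stop("years must span at least 3")
  if (cover < 0 || cover > 1) stop("cover fraction must be in [0, 1]")
  if (corr_length <= 0) stop("climate correlation length must be > 0")
  if (clustering < 0) stop("clustering strength must be >= 0")
  validate_params(theta_true)
  if (is.null(sigma_true)) sigma_true <- as.numeric(theta_true[["sigma"]])
  if (sigma_true <= 0) stop("sigma_true must be > 0")
  ids <- predictor_ids()
  for (v in list(clim_mean, clim_base_sd, clim_noise_sd, clim_slope)) {
    if (!all(ids %in% names(v))) stop("climate settings must name all predictors")
  }
  if (n_sites > nr * nc) stop("more sites than cells")
  structure(list(nr = nr, nc = nc, cell_km = cell_km,
                 first_year = first_year, last_year = last_year,
                 clim_mean = clim_mean[ids], clim_base_sd = clim_base_sd[ids],
                 clim_noise_sd = clim_noise_sd[ids],
                 clim_slope = clim_slope[ids],
                 corr_length = corr_length, cover = cover,
                 clustering = clustering, theta_true = theta_true,
                 sigma_true = sigma_true, n_sites = n_sites,
                 seed_density = seed_density, spinup_years = spinup_years,
                 seed = seed),
            class = "synthetic_scenario")
}

#' Generate the synthetic climate stack
#'
#' Each predictor's grid for year `t` is a fixed smooth spatial base
#' field plus `slope * (t - first_year)` plus spatially correlated
#' interannual noise drawn fresh each year.
#'
#' @param scenario A [synthetic_scenario()].
#' @return List with elements `raw` and `std` (the same stack,
#'   standardized over all years).
#' @export
gen_climate <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  years <- scenario$first_year:scenario$last_year
  ny <- length(years)
  set.seed(derive_seed(scenario$seed, "climate"))
  layers <- list()
  for (p in predictor_ids()) {
    base <- scenario$clim_mean[[p]] +
      scenario$clim_base_sd[[p]] *
        gaussian_field(scenario$nr, scenario$nc, scenario$corr_length)
    arr <- array(0, dim = c(scenario$nr, scenario$nc, ny))
    for (k in seq_len(ny)) {
      noise <- if (scenario$clim_noise_sd[[p]] > 0) {
        scenario$clim_noise_sd[[p]] *
          gaussian_field(scenario$nr, scenario$nc, scenario$corr_length)
      } else 0
      arr[, , k] <- base + scenario$clim_slope[[p]] * (years[k] - years[1]) +
        noise
    }
    layers[[p]] <- arr
  }
  raw <- climate_stack(layers, years, scenario$cell_km)
  list(raw = raw, std = standardize(raw))
}

#' Generate a clustered habitat-suitability map
#'
#' Builds a fine (10x-resolution) binary habitat grid by thresholding a
#' Gaussian random field at the requested cover fraction, then aggregates
#' it with [aggregate_suitability()], so the suitability index is the
#' count of fine habitat cells per landscape cell, exactly as for real
#' land-cover maps. `clustering` is the correlation length of the fine
#' field in coarse-cell units; 0 gives spatially independent habitat.
#'
#' @param scenario A [synthetic_scenario()].
#' @return Integer `nr x nc` matrix in \[0, 100\] (a `HabitatMap`).
#' @export
gen_habitat <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  set.seed(derive_seed(scenario$seed, "habitat"))
  f <- 10L
  nrf <- scenario$nr * f
  ncf <- scenario$nc * f
  if (scenario$cover == 0) return(matrix(0L, scenario$nr, scenario$nc))
  if (scenario$cover == 1) return(matrix(100L, scenario$nr, scenario$nc))
  g <- gaussian_field(nrf, ncf, scenario$clustering * f)
  thr <- stats::quantile(g, 1 - scenario$cover, names = FALSE)
  fine <- matrix(as.integer(g >= thr), nrf, ncf)
  aggregate_suitability(fine, factor = f)
}

#' Moran's I spatial autocorrelation (queen adjacency)
#'
#' @param x Numeric matrix.
#' @return Moran's I statistic.
#' @export
morans_i <- function(x) {
  nr <- nrow(x)
  nc <- ncol(x)
  z <- x - mean(x)
  num <- 0
  wsum <- 0
  shifts <- expand.grid(dr = -1:1, dc = -1:1)
  shifts <- shifts[!(shifts$dr == 0 & shifts$dc == 0), ]
  for (k in seq_len(nrow(shifts))) {
    dr <- shifts$dr[k]; dc <- shifts$dc[k]
    r1 <- max(1, 1 + dr):min(nr, nr + dr)
    c1 <- max(1, 1 + dc):min(nc, nc + dc)
    a <- z[r1, c1, drop = FALSE]
    b <- z[r1 - dr, c1 - dc, drop = FALSE]
    num <- num + sum(a * b)
    wsum <- wsum + length(a)
  }
  (length(z) / wsum) * num / sum(z^2)
}

#' Initial population state by demographic spin-up
#'
#' Seeds every suitable cell with a fixed number of adult females, then
#' runs the IBM forward under the first year's climate so the initial
#' state carries realistic spatial structure and stochasticity. Replaces
#' an abundance-atlas-fitted initial model with a self-contained,
#' pluggable initializer.
#'
#' @param habitat Suitability matrix.
#' @param climate_std Standardized [climate_stack()].
#' @param theta A [param_vector()].
#' @param spinup_years Years of spin-up (`>= 0`).
#' @param seed RNG seed.
#' @param seed_density Adults per suitable cell before spin-up.
#' @param year Climate year used throughout the spin-up (default first).
#' @return A `population_state`: list with integer matrices `A` (adults)
#'   and `J` (juveniles, zero).
#' @export
gen_initial_abundance <- function(habitat, climate_std, theta,
                                  spinup_years = 30, seed = 1,
                                  seed_density = 4,
                                  year = climate_std$years[1]) {
  if (spinup_years < 0) stop("spinup_years must be >= 0")
  if (!any(habitat > 0)) stop("no suitable cells")
  A <- matrix(0L, nrow(habitat), ncol(habitat))
  A[habitat > 0] <- as.integer(seed_density)
  state <- list(A = A, J = matrix(0L, nrow(habitat), ncol(habitat)))
  if (spinup_years == 0) return(state)
  rm0 <- rate_maps(theta, climate_std, year, habitat)
  set.seed(seed)
  for (i in seq_len(spinup_years)) {
    state <- step_year(state, rm0, theta, habitat)
  }
  state
}

#' Simulate a survey from known parameters
#'
#' Runs one IBM realization under the true parameters, samples survey
#' cells uniformly without replacement, and draws one observed count per
#' site and year from a negative binomial with mean equal to the
#' simulated adult females in the cell and dispersion `sigma_true`. Also
#' returns a reference total-abundance index (true total adults relative
#' to the first year, optionally with multiplicative lognormal noise),
#' and all truths for recovery tests.
#'
#' @param theta_true True [param_vector()].
#' @param climate_std Standardized [climate_stack()].
#' @param habitat Suitability matrix.
#' @param n_sites Number of surveyed cells (`<=` number of cells).
#' @param sigma_true NB dispersion (`> 0`).
#' @param seed RNG seed.
#' @param initial Initial `population_state` (default: spin-up with the
#'   same seed).
#' @param index_noise_sd Sd of lognormal noise on the reference index
#'   (0 = noise-free).
#' @return List: `survey` (data frame `site_id, x_cell, y_cell, year,
#'   count`), `reference_index` (data frame `year, index`), `truth`
#'   (list: `abundance` array `[rows, cols, years]`, `sites` data frame,
#'   `theta_true`, `total` yearly true totals).
#' @export
gen_survey <- function(theta_true, climate_std, habitat, n_sites,
                       sigma_true, seed = 1, initial = NULL,
                       index_noise_sd = 0) {
  if (sigma_true <= 0) stop("sigma_true must be > 0")
  ncell <- length(habitat)
  if (n_sites > ncell) stop("more sites than cells")
  if (is.null(initial)) {
    initial <- gen_initial_abundance(habitat, climate_std, theta_true,
                                     seed = derive_seed(seed, "spinup"))
  }
  sim <- simulate_ibm(theta_true, climate_std, habitat, initial,
                      years = climate_std$years, n_reps = 1,
                      seed = derive_seed(seed, "truth"))
  abund <- sim$abundance[, , , 1]  # rows x cols x years
  set.seed(derive_seed(seed, "observe"))
  idx <- sample.int(ncell, n_sites)
  rc <- arrayInd(idx, dim(habitat))
  sites <- data.frame(site_id = seq_len(n_sites), x_cell = rc[, 2],
                      y_cell = rc[, 1])
  years <- climate_std$years
  recs <- lapply(seq_along(years), function(k) {
    mu <- abund[, , k][idx]
    data.frame(site_id = sites$site_id, x_cell = sites$x_cell,
               y_cell = sites$y_cell, year = years[k],
               count = stats::rnbinom(n_sites, size = sigma_true, mu = mu))
  })
  survey <- do.call(rbind, recs)
  total <- apply(abund, 3, sum)
  index <- total / total[1]
  if (index_noise_sd > 0) {
    index <- index * exp(stats::rnorm(length(index), 0, index_noise_sd))
    index <- index / index[1]
  }
  list(survey = survey,
       reference_index = data.frame(year = years, index = index),
       truth = list(abundance = abund, sites = sites,
                    theta_true = theta_true, total = total))
}

#' Generate a full scenario bundle
#'
#' Climate, habitat, initial state and survey for one scenario, all
#' derived deterministically from the scenario's master seed.
#'
#' @param scenario A [synthetic_scenario()].
#' @return List with `scenario`, `climate` (list `raw`, `std`),
#'   `habitat`, `initial`, `survey` (the [gen_survey()] result).
#' @export
gen_scenario_bundle <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  climate <- gen_climate(scenario)
  habitat <- gen_habitat(scenario)
  initial <- gen_initial_abundance(habitat, climate$std, scenario$theta_true,
                                   spinup_years = scenario$spinup_years,
                                   seed = derive_seed(scenario$seed, "spinup"),
                                   seed_density = scenario$seed_density)
  survey <- gen_survey(scenario$theta_true, climate$std, habitat,
                       n_sites = scenario$n_sites,
                       sigma_true = scenario$sigma_true,
                       seed = derive_seed(scenario$seed, "survey"),
                       initial = initial)
  list(scenario = scenario, climate = climate, habitat = habitat,
       initial = initial, survey = survey)
}
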