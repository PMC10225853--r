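# R interface to the individual-based model: yearly process steps,
# multi-year / multi-replicate simulation, and a per-individual reference
# implementation used to verify the per-cell draws.

as_int_matrix <- function(x) {
  storage.mode(x) <- "integer"
  x
}

# rate matrices with NA on masked cells are passed to C++ with zeros
# there; the C++ side never evaluates rates where habitat <= 0
unmask <- function(m) {
  m[!is.finite(m)] <- 0
  m
}

# a fresh stream seed for the counter-based simulation RNG, drawn from
# R's global RNG so set.seed() governs everything downstream
rand_seed <- function() floor(stats::runif(1) * 9007199254740992)

#' Construct a population state
#'
#' @param A Integer matrix of adult females per cell.
#' @param J Integer matrix of juvenile females per cell (default zero).
#' @return List with elements `A` and `J` (class `"population_state"`).
#' @export
population_state <- function(A, J = NULL) {
  A <- as_int_matrix(A)
  if (is.null(J)) J <- matrix(0L, nrow(A), ncol(A))
  J <- as_int_matrix(J)
  stopifnot(all(dim(A) == dim(J)), all(A >= 0), all(J >= 0))
  structure(list(A = A, J = J), class = "population_state")
}

#' Reproduction: density-dependent Poisson offspring per cell
#'
#' Each cell produces `Poisson(n_i * rho(n_i))` juvenile females, where
#' `rho` is the realized fecundity at the cell's pre-breeding adult
#' density. Adults are unchanged; unsuitable cells produce nothing.
#'
#' @param state A [population_state()].
#' @param rates A `rate_maps` object for the current year.
#' @param theta A [param_vector()] (supplies `b`).
#' @param seed Stream seed for the counter-based draws (default: drawn
#'   from R's RNG, so `set.seed()` gives reproducibility).
#' @return Integer matrix of the juvenile cohort.
#' @export
reproduce <- function(state, rates, theta, seed = NULL) {
  if (is.null(seed)) seed <- rand_seed()
  cpp_reproduce(as_int_matrix(state$A), unmask(rates$rho_max),
                as_int_matrix(rates$habitat), theta[["b"]], seed)
}

#' Natal dispersal of a juvenile cohort
#'
#' Emigration with probability `p_e`; transfer by an exponential distance
#' kernel (mean `dbar`) with uniform direction from the natal cell
#' centre; settlement in the destination cell if suitable, else in a
#' uniformly chosen suitable cell among its eight neighbours, else
#' death. Endpoints beyond the grid are deaths, so dispersal mortality is
#' additive to annual survival.
#'
#' @param cohort Integer matrix of juveniles to disperse.
#' @param habitat Suitability matrix.
#' @param theta A [param_vector()] (supplies `p_e`, `dbar`).
#' @param cell_km Cell edge length (km).
#' @param record If `TRUE`, return the drawn distances and angles of all
#'   emigrants (for kernel diagnostics).
#' @param seed Stream seed (default: drawn from R's RNG).
#' @return List: `settled` (integer matrix), `deaths` (count), and with
#'   `record` also `distances`, `angles`.
#' @export
disperse <- function(cohort, habitat, theta, cell_km = 1, record = FALSE,
                     seed = NULL) {
  if (is.null(seed)) seed <- rand_seed()
  cpp_disperse(as_int_matrix(cohort), as_int_matrix(habitat),
               theta[["p_e"]], theta[["dbar"]], cell_km, seed, record)
}

#' Survival and stage transition
#'
#' Post-dispersal juveniles survive with their settlement cell's `s_j`,
#' adults with `s_a` (independent binomial draws per cell); surviving
#' juveniles mature, so next year's adults are the surviving adults plus
#' surviving juveniles and next year's juvenile count is zero.
#'
#' @param state A [population_state()] whose `J` is post-dispersal.
#' @param rates A `rate_maps` object.
#' @param seed Stream seed (default: drawn from R's RNG).
#' @return Next year's [population_state()].
#' @export
survive_and_transition <- function(state, rates, seed = NULL) {
  if (is.null(seed)) seed <- rand_seed()
  res <- cpp_survive(as_int_matrix(state$J), as_int_matrix(state$A),
                     unmask(rates$sj), unmask(rates$sa),
                     as_int_matrix(rates$habitat), seed)
  population_state(res$A)
}

#' One full simulation year
#'
#' Composition, in order: reproduction, dispersal, then survival and
#' transition.
#'
#' @param state A [population_state()].
#' @param rates A `rate_maps` object for this year.
#' @param theta A [param_vector()].
#' @param habitat Suitability matrix (must match `rates$habitat`).
#' @param cell_km Cell edge length (km).
#' @param detail If `TRUE`, also return the produced cohort, settled
#'   cohort, dispersal deaths and stage-wise survivor counts (for
#'   individual-conservation checks).
#' @param seed Stream seed for the year's draws (default: drawn from
#'   R's RNG).
#' @return Next year's [population_state()]; with `detail`, a list with
#'   `state` and the accounting fields.
#' @export
step_year <- function(state, rates, theta, habitat = rates$habitat,
                      cell_km = 1, detail = FALSE, pop_ceiling = 1e6,
                      seed = NULL) {
  if (is.null(seed)) seed <- rand_seed()
  res <- cpp_step(as_int_matrix(state$A), unmask(rates$rho_max),
                  unmask(rates$sj), unmask(rates$sa),
                  as_int_matrix(habitat), theta[["b"]], theta[["p_e"]],
                  theta[["dbar"]], cell_km, seed, detail, pop_ceiling)
  nxt <- population_state(res$A, res$J)
  if (!detail) return(nxt)
  list(state = nxt, produced = res$produced, settled = res$settled,
       dispersal_deaths = res$dispersal_deaths, J_surv = res$J_surv,
       A_surv = res$A_surv)
}

#' Demographic-rate arrays for all years
#'
#' Vectorized evaluation of the three DCRs over every cell and year of a
#' standardized climate stack (the per-year analogue is [rate_maps()]).
#'
#' @param theta A [param_vector()].
#' @param climate Standardized [climate_stack()].
#' @param habitat Suitability matrix.
#' @return List of `[rows, cols, years]` arrays `rho_max`, `sj`, `sa`
#'   (zero/0.5-link values overwritten with `NA` on unsuitable cells).
#' @export
rate_arrays <- function(theta, climate, habitat) {
  stopifnot(isTRUE(climate$standardized))
  bl <- param_blocks(theta)
  rho_max <- fecundity_max(climate$layers$T_br, climate$layers$P_br, bl$fec)
  sj <- survival_rate(climate$layers$T_at, climate$layers$P_wn, bl$sj, "sj")
  sa <- survival_rate(climate$layers$T_wn, climate$layers$P_wn, bl$sa, "sa")
  mask <- array(rep(habitat <= 0, dim(rho_max)[3]), dim = dim(rho_max))
  rho_max[mask] <- NA_real_
  sj[mask] <- NA_real_
  sa[mask] <- NA_real_
  list(rho_max = rho_max, sj = sj, sa = sa)
}

#' Simulate replicate abundance trajectories
#'
#' Runs `n_reps` independent IBM realizations over the given years.
#' Per-replicate seeds are derived deterministically from the master
#' seed, so any replicate is exactly regenerable. The initial state may
#' be a fixed [population_state()] (used for every replicate) or a
#' function `(seed) -> population_state` sampling stochastic initial
#' conditions per replicate.
#'
#' @param theta A [param_vector()].
#' @param climate Standardized [climate_stack()].
#' @param habitat Suitability matrix.
#' @param initial A [population_state()] or an initializer function.
#' @param years Years to simulate (must be in the stack; default all).
#' @param n_reps Number of replicates.
#' @param seed Master seed.
#' @param pop_ceiling Total-population guard: trajectories exceeding it
#'   saturate (see the methods vignette); irrelevant for plausible
#'   parameters, it bounds the cost of degenerate proposals during
#'   calibration.
#' @param antithetic If `TRUE`, consecutive replicates form antithetic
#'   pairs: the even member of each pair reuses its partner's uniform
#'   streams flipped to `1 - u`. Every replicate remains an exact draw
#'   from the IBM (inverse-CDF marginals are unchanged); the pairing
#'   only induces negative correlation, a classical variance reduction
#'   for replicate-averaged predictions. Used by the calibration
#'   likelihood; off by default.
#' @return List: `abundance` — integer array `[rows, cols, years, reps]`
#'   of adult females after each annual cycle; `years`; `rep_seeds`.
#' @export
simulate_ibm <- function(theta, climate, habitat, initial,
                         years = climate$years, n_reps = 1, seed = 1,
                         pop_ceiling = 1e6, antithetic = FALSE) {
  validate_params(theta)
  if (!all(years %in% climate$years)) stop("climate does not cover all years")
  dm <- dim(climate$layers[[1]])[1:2]
  if (!all(dim(habitat) == dm)) stop("habitat grid does not match climate")
  iy <- match(years, climate$years)
  ra <- rate_arrays(theta, climate, habitat)
  rho <- unmask(ra$rho_max[, , iy, drop = FALSE])
  sj <- unmask(ra$sj[, , iy, drop = FALSE])
  sa <- unmask(ra$sa[, , iy, drop = FALSE])
  # replicate seeds derive deterministically from the master seed without
  # touching the caller's RNG state (the sampler owns the global stream);
  # antithetic mode pairs replicates (2r-1, 2r) on one seed with flipped
  # uniforms
  rep_seeds <- vapply(seq_len(n_reps), function(r) {
    k <- if (antithetic) (r + 1L) %/% 2L else r
    derive_seed(seed, paste0("rep", k))
  }, integer(1))
  anti <- if (antithetic) seq_len(n_reps) %% 2L == 0L else rep(FALSE, n_reps)
  out <- array(0L, dim = c(dm[1], dm[2], length(years), n_reps))
  hab <- as_int_matrix(habitat)
  for (r in seq_len(n_reps)) {
    st <- if (is.function(initial)) initial(rep_seeds[r]) else initial
    out[, , , r] <- cpp_run_years(as_int_matrix(st$A), rho, sj, sa, hab,
                                  theta[["b"]], theta[["p_e"]],
                                  theta[["dbar"]], climate$cell_km,
                                  rep_seeds[r], pop_ceiling, anti[r])
  }
  list(abundance = out, years = years, rep_seeds = rep_seeds)
}

#' Per-individual reference year step
#'
#' Slow, loop-over-individuals implementation of the annual cycle, used
#' to verify that the per-cell draws of [step_year()] are
#' distributionally equivalent. Each female's offspring count is an
#' independent Poisson draw, each juvenile's emigration and each
#' individual's survival an independent Bernoulli draw.
#'
#' @inheritParams step_year
#' @return As [step_year()] with `detail = TRUE`.
#' @export
step_year_reference <- function(state, rates, theta, habitat = rates$habitat,
                                cell_km = 1) {
  bl <- param_blocks(theta)
  nr <- nrow(habitat)
  nc <- ncol(habitat)
  produced <- matrix(0L, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    n <- state$A[i, j]
    if (n <= 0 || habitat[i, j] <= 0) next
    rho <- fecundity_realized(rates$rho_max[i, j], n, habitat[i, j], bl$b)
    produced[i, j] <- sum(stats::rpois(n, rho))
  }
  settled <- matrix(0L, nr, nc)
  deaths <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    for (k in seq_len(produced[i, j])) {
      if (stats::runif(1) >= bl$p_e) {
        settled[i, j] <- settled[i, j] + 1L
        next
      }
      d <- stats::rexp(1, rate = 1 / bl$dbar)
      a <- stats::runif(1, 0, 2 * pi)
      x <- (j - 0.5) * cell_km + d * cos(a)
      y <- (i - 0.5) * cell_km + d * sin(a)
      di <- floor(y / cell_km) + 1
      dj <- floor(x / cell_km) + 1
      if (di < 1 || di > nr || dj < 1 || dj > nc) {
        deaths <- deaths + 1L
        next
      }
      if (habitat[di, dj] > 0) {
        settled[di, dj] <- settled[di, dj] + 1L
        next
      }
      nb <- expand.grid(r = di + (-1:1), c = dj + (-1:1))
      nb <- nb[!(nb$r == di & nb$c == dj), ]
      nb <- nb[nb$r >= 1 & nb$r <= nr & nb$c >= 1 & nb$c <= nc, ]
      nb <- nb[habitat[cbind(nb$r, nb$c)] > 0, ]
      if (nrow(nb) == 0) {
        deaths <- deaths + 1L
        next
      }
      pick <- nb[sample.int(nrow(nb), 1), ]
      settled[pick$r, pick$c] <- settled[pick$r, pick$c] + 1L
    }
  }
  J_surv <- matrix(0L, nr, nc)
  A_surv <- matrix(0L, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (habitat[i, j] <= 0) next
    if (settled[i, j] > 0)
      J_surv[i, j] <- sum(stats::runif(settled[i, j]) < rates$sj[i, j])
    if (state$A[i, j] > 0)
      A_surv[i, j] <- sum(stats::runif(state$A[i, j]) < rates$sa[i, j])
  }
  list(state = population_state(J_surv + A_surv), produced = produced,
       settled = settled, dispersal_deaths = deaths, J_surv = J_surv,
       A_surv = A_surv)
}
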