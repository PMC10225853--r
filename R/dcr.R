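# Demography-climate relationships (DCRs): GLM-structured links from
# standardized seasonal climate predictors to the three demographic rates.

# linear predictors are clipped to +-50 before exp()/plogis() purely to
# avoid floating overflow; at |eta| = 50 both links are saturated far
# beyond any representable difference.
ETA_CLIP <- 50

clip_eta <- function(eta) pmin(pmax(eta, -ETA_CLIP), ETA_CLIP)

#' Maximum (density-independent) fecundity
#'
#' Expected female offspring per adult female at vanishing density, from
#' the breeding-season DCR with a log link:
#' `rho_max = exp(b0 + b1*T + b2*T^2 + b3*P + b4*P^2)`.
#'
#' @param T_br,P_br Standardized breeding-season mean temperature and
#'   total precipitation (scalars, vectors or matrices of equal shape).
#' @param beta Numeric length-5 coefficient vector
#'   `(intercept, T, T^2, P, P^2)`.
#' @return `rho_max`, same shape as the inputs, strictly positive.
#' @export
fecundity_max <- function(T_br, P_br, beta) {
  stopifnot(length(beta) == 5)
  eta <- beta[1] + beta[2] * T_br + beta[3] * T_br^2 +
    beta[4] * P_br + beta[5] * P_br^2
  exp(clip_eta(eta))
}

#' Density-dependent realized fecundity
#'
#' Fecundity decreases exponentially with the product of local density
#' `n_i` and the local density-dependence rate `b_i = b * 100 / h_i`,
#' where `1/b` is overall resource availability and `h_i` in \[0, 100\] is
#' the local habitat-suitability index: `rho = rho_max * exp(-n_i * b_i)`.
#' Unsuitable cells (`h_i = 0`) have zero fecundity.
#'
#' @param rho_max Maximum fecundity (from [fecundity_max()]).
#' @param n Local density (adult females per cell), `>= 0`.
#' @param h Suitability index in \[0, 100\].
#' @param b Density-dependence strength, `> 0`.
#' @return Realized fecundity, same shape as inputs.
#' @export
fecundity_realized <- function(rho_max, n, h, b) {
  if (b <= 0) stop("b must be > 0")
  if (any(n < 0)) stop("n must be >= 0")
  out <- rho_max * exp(-n * b * 100 / pmax(h, .Machine$double.eps))
  out[h <= 0] <- 0
  out
}

#' Climate-dependent survival probability
#'
#' Logistic-link DCR. For juvenile survival the design is
#' `(1, T_at, T_at^2, P_wn, P_wn^2)` (5 coefficients); for adult survival
#' `(1, T_wn, P_wn, P_wn^2)` (4 coefficients; minimum winter temperature
#' enters linearly only).
#'
#' @param T,P Standardized temperature and precipitation predictors.
#' @param coef Coefficient vector of length 4 or 5 (see above).
#' @param rate `"sj"` (expects 5 coefficients) or `"sa"` (expects 4).
#' @return Survival probability strictly in (0, 1), same shape as inputs.
#' @export
survival_rate <- function(T, P, coef, rate = c("sj", "sa")) {
  rate <- match.arg(rate)
  need <- if (rate == "sj") 5L else 4L
  if (length(coef) != need)
    stop(sprintf("rate '%s' needs %d coefficients, got %d", rate, need,
                 length(coef)))
  eta <- if (rate == "sj") {
    coef[1] + coef[2] * T + coef[3] * T^2 + coef[4] * P + coef[5] * P^2
  } else {
    coef[1] + coef[2] * T + coef[3] * P + coef[4] * P^2
  }
  stats::plogis(clip_eta(eta))
}

#' Cellwise demographic-rate maps for one year
#'
#' Applies the three DCRs to a year's standardized climate layers.
#' `rho_max` is stored before density dependence (density acts inside the
#' IBM each year with the then-current adult counts). Cells with `h = 0`
#' are masked to `NA`.
#'
#' @param theta A [param_vector()].
#' @param climate A standardized [climate_stack()].
#' @param year Calendar year to evaluate.
#' @param habitat Integer suitability matrix in \[0, 100\], same grid.
#' @return List of matrices `rho_max`, `sj`, `sa` plus `year` and the
#'   habitat used; class `"rate_maps"`.
#' @export
rate_maps <- function(theta, climate, year, habitat) {
  validate_params(theta)
  stopifnot(inherits(climate, "climate_stack"))
  if (!isTRUE(climate$standardized))
    stop("rate_maps requires a standardized climate stack")
  iy <- match(year, climate$years)
  if (is.na(iy)) stop("year ", year, " not in climate stack")
  dm <- dim(climate$layers[[1]])[1:2]
  if (!all(dim(habitat) == dm)) stop("habitat grid does not match climate grid")
  bl <- param_blocks(theta)
  g <- function(p) climate$layers[[p]][, , iy]
  rho_max <- fecundity_max(g("T_br"), g("P_br"), bl$fec)
  sj <- survival_rate(g("T_at"), g("P_wn"), bl$sj, "sj")
  sa <- survival_rate(g("T_wn"), g("P_wn"), bl$sa, "sa")
  mask <- habitat <= 0
  rho_max[mask] <- NA_real_
  sj[mask] <- NA_real_
  sa[mask] <- NA_real_
  structure(list(rho_max = rho_max, sj = sj, sa = sa, year = year,
                 habitat = habitat), class = "rate_maps")
}

#' Conditional DCR response curve across posterior draws
#'
#' Varies one focal predictor over the central span of climate values in
#' occupied cells (by default the 10th-90th percentile) while holding the
#' rate's co-predictor at its median. For fecundity, density is fixed at
#' one breeding pair per cell (`n = 1`) and suitability at `h_ref`
#' (default: median of the supplied suitability values), so the curve is
#' the fecundity realized at low density.
#'
#' @param draws Matrix of posterior draws (rows = draws, columns named as
#'   [param_names()]), or a single [param_vector()].
#' @param rate `"fecundity"`, `"sj"` or `"sa"`.
#' @param predictor Focal predictor id (e.g. `"T_br"`).
#' @param climate_sample Data frame or matrix of standardized predictor
#'   values in occupied cells (columns named by predictor id).
#' @param h_ref Suitability values (vector) or a single reference value
#'   used for fecundity's density term.
#' @param quantile_lo,quantile_hi Span of the focal predictor.
#' @param n_grid Number of grid points.
#' @return Data frame with columns `predictor_value`, `median`, `lo80`,
#'   `hi80`, `lo95`, `hi95`.
#' @export
response_curve <- function(draws, rate = c("fecundity", "sj", "sa"),
                           predictor, climate_sample, h_ref = 100,
                           quantile_lo = 0.10, quantile_hi = 0.90,
                           n_grid = 51) {
  rate <- match.arg(rate)
  if (is.null(dim(draws))) draws <- matrix(draws, nrow = 1,
                                           dimnames = list(NULL, names(draws)))
  climate_sample <- as.data.frame(climate_sample)
  if (nrow(climate_sample) == 0) stop("empty climate sample")
  pair <- switch(rate,
    fecundity = c("T_br", "P_br"),
    sj = c("T_at", "P_wn"),
    sa = c("T_wn", "P_wn"))
  if (!predictor %in% pair)
    stop("predictor '", predictor, "' does not enter rate '", rate, "'")
  other <- setdiff(pair, predictor)
  xs <- stats::quantile(climate_sample[[predictor]],
                        c(quantile_lo, quantile_hi), names = FALSE)
  grid <- seq(xs[1], xs[2], length.out = n_grid)
  x_other <- stats::median(climate_sample[[other]])
  h_med <- stats::median(h_ref)

  eval_one <- function(theta, x) {
    bl <- param_blocks(param_vector(base = theta))
    vals <- stats::setNames(c(x, x_other), c(predictor, other))
    switch(rate,
      fecundity = fecundity_realized(
        fecundity_max(vals[["T_br"]], vals[["P_br"]], bl$fec),
        n = 1, h = h_med, b = bl$b),
      sj = survival_rate(vals[["T_at"]], vals[["P_wn"]], bl$sj, "sj"),
      sa = survival_rate(vals[["T_wn"]], vals[["P_wn"]], bl$sa, "sa"))
  }
  curves <- apply(draws, 1, function(th) vapply(grid, function(x)
    eval_one(th, x), numeric(1)))
  curves <- matrix(curves, nrow = n_grid)  # n_grid x n_draws
  qs <- t(apply(curves, 1, stats::quantile,
                probs = c(0.5, 0.10, 0.90, 0.025, 0.975), names = FALSE))
  data.frame(predictor_value = grid, median = qs[, 1], lo80 = qs[, 2],
             hi80 = qs[, 3], lo95 = qs[, 4], hi95 = qs[, 5])
}
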