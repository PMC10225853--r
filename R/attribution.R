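# Attribution of population trends to climate change: low-density
# growth rates, partial responses of growth to per-predictor climate
# trends, and the factual vs counterfactual abundance ratio.

#' Low-density growth rate from the three demographic rates
#'
#' Dominant eigenvalue of the two-stage transition matrix
#' `[[0, rho], [s_j, s_a]]`:
#' `r = s_a/2 + sqrt(s_a^2/4 + s_j * rho)`. `r > 1` marks locally
#' growing populations; where `s_j * rho = 0` the matrix is reducible
#' and `r = s_a`.
#'
#' @param s_a,s_j Survival probabilities in \[0, 1\].
#' @param rho Fecundity (`>= 0`), typically realized at low density.
#' @return Growth rate(s), same shape as inputs.
#' @export
growth_rate <- function(s_a, s_j, rho) {
  s_a / 2 + sqrt(s_a^2 / 4 + s_j * rho)
}

#' Map of low-density growth rates
#'
#' Cellwise `r` for one year's climate, with fecundity realized at one
#' breeding pair per cell (`n = 1`) and the cell's own suitability;
#' unsuitable cells are `NA`.
#'
#' @param theta A [param_vector()].
#' @param climate Standardized [climate_stack()].
#' @param year Calendar year.
#' @param habitat Suitability matrix.
#' @return List: `r` (matrix), `growing` (logical matrix, `r > 1`),
#'   `year`.
#' @export
growth_rate_map <- function(theta, climate, year, habitat) {
  rm <- rate_maps(theta, climate, year, habitat)
  bl <- param_blocks(theta)
  rho1 <- fecundity_realized(rm$rho_max, 1, habitat, bl$b)
  rho1[habitat <= 0] <- NA_real_
  r <- growth_rate(rm$sa, rm$sj, rho1)
  list(r = r, growing = r > 1, year = year)
}

#' Classify a growth-rate ratio by effect strength
#'
#' Thresholds: less than 5% change is "none"; more than 5% a small
#' change; more than 10% a strong change, signed by direction.
#'
#' @param ratio Positive ratio(s) of perturbed to base growth rate.
#' @return Character vector over `"none"`, `"small increase"`,
#'   `"small decrease"`, `"strong increase"`, `"strong decrease"`.
#' @export
classify_effect <- function(ratio) {
  delta <- ratio - 1
  out <- rep("none", length(ratio))
  out[delta >= 0.05 & delta <= 0.10] <- "small increase"
  out[delta > 0.10] <- "strong increase"
  out[delta <= -0.05 & delta >= -0.10] <- "small decrease"
  out[delta < -0.10] <- "strong decrease"
  out
}

#' Partial response of growth rate to per-predictor climate trends
#'
#' For each posterior draw, a base growth rate is evaluated at the
#' median of every predictor over occupied cells (fecundity at `n = 1`
#' and the reference suitability). Then, one predictor at a time is
#' shifted by its trend accumulated over the survey span (converted to
#' standardized units by the standardization record) and the growth rate
#' recomputed; the ratio to base quantifies that predictor's isolated
#' contribution, classified by [classify_effect()].
#'
#' @param draws Posterior draw matrix (rows = draws, named columns) or a
#'   single [param_vector()].
#' @param climate_sample Data frame/matrix of standardized predictor
#'   values in occupied cells (columns = [predictor_ids()]).
#' @param trend A `trend_record` from [fit_trend()] (on the raw stack).
#' @param std Standardization record (`stack$std`) used to express the
#'   accumulated raw change in z-units; `NULL` if the trend was fitted
#'   on standardized layers.
#' @param h_ref Suitability value(s) for the fecundity density term
#'   (median taken).
#' @return Data frame (one row per draw x predictor): `draw`,
#'   `predictor`, `base_r`, `perturbed_r`, `ratio`, `class`.
#' @export
partial_response <- function(draws, climate_sample, trend, std = NULL,
                             h_ref = 100) {
  if (is.null(dim(draws))) draws <- matrix(draws, nrow = 1,
                                           dimnames = list(NULL, names(draws)))
  climate_sample <- as.data.frame(climate_sample)
  ids <- predictor_ids()
  if (!all(ids %in% names(climate_sample)))
    stop("climate sample must contain all predictors")
  med <- vapply(climate_sample[ids], stats::median, numeric(1))
  shift_z <- stats::setNames(numeric(5), ids)
  for (p in ids) {
    acc <- trend$accumulated[trend$predictor == p]
    s <- if (is.null(std)) 1 else std[[p]]$sd
    if (is.null(s)) stop("missing standardization record for ", p)
    shift_z[p] <- acc / s
  }
  h_med <- stats::median(h_ref)
  r_at <- function(bl, v) {
    rho <- fecundity_realized(
      fecundity_max(v[["T_br"]], v[["P_br"]], bl$fec), 1, h_med, bl$b)
    growth_rate(survival_rate(v[["T_wn"]], v[["P_wn"]], bl$sa, "sa"),
                survival_rate(v[["T_at"]], v[["P_wn"]], bl$sj, "sj"), rho)
  }
  rows <- list()
  for (k in seq_len(nrow(draws))) {
    bl <- param_blocks(param_vector(base = draws[k, ]))
    base_r <- r_at(bl, med)
    for (p in ids) {
      v <- med
      v[p] <- v[p] + shift_z[p]
      pr <- r_at(bl, v)
      rows[[length(rows) + 1]] <- data.frame(
        draw = k, predictor = p, base_r = base_r, perturbed_r = pr,
        ratio = pr / base_r)
    }
  }
  out <- do.call(rbind, rows)
  out$class <- classify_effect(out$ratio)
  out
}

#' Factual vs counterfactual abundance ratio
#'
#' For each posterior draw, simulates the IBM under the factual climate
#' and under the counterfactual (detrended, stationary) climate with
#' common random numbers (the same seed for both members of a pair, so
#' the ratio isolates the climate signal), and computes the ratio of
#' mean total adult abundance over the final `window_years` years.
#' Draws whose counterfactual goes extinct in the window are excluded
#' and counted.
#'
#' @param draws Posterior draw matrix or single [param_vector()].
#' @param climate_fact,climate_cf Standardized factual and counterfactual
#'   [climate_stack()]s (same grid, years and standardization record).
#' @param habitat Suitability matrix.
#' @param initial Initial state or initializer (see [simulate_ibm()]).
#' @param n_reps IBM replicates per scenario member.
#' @param window_years Averaging window at the end of the series.
#' @param seed Master seed.
#' @param common_rng Use common random numbers across the pair (default
#'   `TRUE`); `FALSE` gives independent streams.
#' @return List: `ratios` (per usable draw), `median`, `ci80`
#'   (10-90% interval), `n_excluded`.
#' @export
scenario_ratio <- function(draws, climate_fact, climate_cf, habitat,
                           initial, n_reps = 5, window_years = 3,
                           seed = 1, common_rng = TRUE) {
  if (is.null(dim(draws))) draws <- matrix(draws, nrow = 1,
                                           dimnames = list(NULL, names(draws)))
  stopifnot(identical(climate_fact$years, climate_cf$years))
  years <- climate_fact$years
  window <- years[(length(years) - window_years + 1):length(years)]
  set.seed(seed)
  draw_seeds <- sample.int(2147483646L, nrow(draws))
  ratios <- rep(NA_real_, nrow(draws))
  for (k in seq_len(nrow(draws))) {
    theta <- param_vector(base = draws[k, ])
    s1 <- draw_seeds[k]
    s2 <- if (common_rng) s1 else derive_seed(s1, "counterfactual")
    fact <- simulate_ibm(theta, climate_fact, habitat, initial,
                         n_reps = n_reps, seed = s1)
    cf <- simulate_ibm(theta, climate_cf, habitat, initial,
                       n_reps = n_reps, seed = s2)
    kw <- match(window, years)
    m_fact <- mean(apply(fact$abundance[, , kw, , drop = FALSE], c(3, 4), sum))
    m_cf <- mean(apply(cf$abundance[, , kw, , drop = FALSE], c(3, 4), sum))
    ratios[k] <- if (m_cf > 0) m_fact / m_cf else NA_real_
  }
  excluded <- sum(is.na(ratios))
  usable <- ratios[!is.na(ratios)]
  if (!length(usable)) stop("counterfactual extinct for every draw")
  list(ratios = usable, median = stats::median(usable),
       ci80 = stats::quantile(usable, c(0.1, 0.9), names = FALSE),
       n_excluded = excluded)
}
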