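#' Canonical parameter names
#'
#' The 18 calibrated quantities in their fixed canonical order: 14 DCR
#' coefficients (5 fecundity, 5 juvenile survival, 4 adult survival), the
#' density-dependence strength `b`, the emigration probability `p_e`, the
#' mean dispersal distance `dbar` (km), and the negative-binomial
#' dispersion `sigma`.
#'
#' Design matrices per rate (predictors standardized):
#' fecundity: (1, T_br, T_br^2, P_br, P_br^2), log link;
#' juvenile survival: (1, T_at, T_at^2, P_wn, P_wn^2), logit link;
#' adult survival: (1, T_wn, P_wn, P_wn^2), logit link. Minimum winter
#' temperature enters adult survival only (linear), having been excluded
#' from juvenile survival for collinearity with autumn temperature.
#'
#' @return Character vector of length 18.
#' @export
param_names <- function() {
  c("fec_icpt", "fec_Tbr", "fec_Tbr2", "fec_Pbr", "fec_Pbr2",
    "sj_icpt",  "sj_Tat",  "sj_Tat2",  "sj_Pwn",  "sj_Pwn2",
    "sa_icpt",  "sa_Twn",  "sa_Pwn",   "sa_Pwn2",
    "b", "p_e", "dbar", "sigma")
}

#' Build a named parameter vector
#'
#' @param ... Named values for any subset of [param_names()]; unnamed
#'   defaults are zero coefficients, `b = 0.1`, `p_e = 0.3`, `dbar = 2`,
#'   `sigma = 20`.
#' @param base Optional base vector to modify.
#' @return Named numeric vector of length 18, class `"param_vector"`.
#' @export
param_vector <- function(..., base = NULL) {
  nm <- param_names()
  theta <- if (is.null(base)) {
    stats::setNames(c(rep(0, 14), 0.1, 0.3, 2, 20), nm)
  } else {
    validate_params(base)
    stats::setNames(as.numeric(base[nm]), nm)
  }
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("all arguments must be named")
    bad <- setdiff(names(dots), nm)
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    theta[names(dots)] <- unlist(dots)
  }
  class(theta) <- c("param_vector", "numeric")
  theta
}

#' Validate a parameter vector
#'
#' Checks names, length and hard constraints (`b > 0`, `p_e` in \[0,1\],
#' `dbar > 0`, `sigma > 0`).
#'
#' @param theta Named numeric vector.
#' @return `theta`, invisibly; errors otherwise.
#' @export
validate_params <- function(theta) {
  nm <- param_names()
  if (!all(nm %in% names(theta)))
    stop("parameter vector must contain all of: ", paste(nm, collapse = ", "))
  if (any(!is.finite(as.numeric(theta[nm])))) stop("non-finite parameter value")
  if (theta[["b"]] <= 0) stop("b must be > 0")
  if (theta[["p_e"]] < 0 || theta[["p_e"]] > 1) stop("p_e must be in [0, 1]")
  if (theta[["dbar"]] <= 0) stop("dbar must be > 0")
  if (theta[["sigma"]] <= 0) stop("sigma must be > 0")
  invisible(theta)
}

#' Archetype parameter presets
#'
#' Two contrasting demographic archetypes shipped as package fixtures for
#' synthetic scenarios (they are illustrative, not empirical estimates).
#' The "mountain" archetype gains from wetter winters and loses from
#' warmer breeding seasons; the "lowland" archetype shows the opposite
#' winter-precipitation response.
#'
#' @param name `"mountain"` or `"lowland"`.
#' @return A [param_vector()].
#' @export
preset_params <- function(name = c("mountain", "lowland")) {
  name <- match.arg(name)
  common <- param_vector(
    fec_icpt = log(2), fec_Tbr2 = -0.10, fec_Pbr = 0.10, fec_Pbr2 = -0.05,
    sj_icpt = 0.2, sj_Tat = -0.20, sj_Tat2 = -0.05, sj_Pwn2 = -0.05,
    sa_icpt = 0.0, sa_Twn = 0.15, sa_Pwn = 0.10, sa_Pwn2 = -0.05,
    b = 0.1, p_e = 0.3, dbar = 2, sigma = 20)
  switch(name,
    mountain = param_vector(fec_Tbr = -0.30, sj_Pwn = 0.30, base = common),
    lowland  = param_vector(fec_Tbr = -0.15, sj_Pwn = -0.25, base = common))
}

#' Split a parameter vector into DCR coefficient blocks
#'
#' @param theta A [param_vector()].
#' @return List with elements `fec` (length 5), `sj` (length 5), `sa`
#'   (length 4), `b`, `p_e`, `dbar`, `sigma`.
#' @export
param_blocks <- function(theta) {
  validate_params(theta)
  list(fec  = as.numeric(theta[1:5]),
       sj   = as.numeric(theta[6:10]),
       sa   = as.numeric(theta[11:14]),
       b    = as.numeric(theta[["b"]]),
       p_e  = as.numeric(theta[["p_e"]]),
       dbar = as.numeric(theta[["dbar"]]),
       sigma = as.numeric(theta[["sigma"]]))
}
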