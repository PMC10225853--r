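# Goodness-of-fit and discriminatory power of posterior predictions:
# RMSE, Harrell's c-index (spatio-temporal and temporal), mean yearly
# spatial AUC, and relative-abundance envelopes.

#' Root mean squared error
#'
#' @param pred,obs Paired finite numeric vectors.
#' @return `sqrt(mean((pred - obs)^2))`.
#' @export
rmse <- function(pred, obs) {
  if (length(pred) == 0 || length(pred) != length(obs))
    stop("pred and obs must be non-empty and of equal length")
  if (any(!is.finite(pred)) || any(!is.finite(obs)))
    stop("pred and obs must be finite")
  sqrt(mean((pred - obs)^2))
}

#' Harrell's concordance index
#'
#' Probability that a randomly chosen pair with different observed
#' values is ranked in the same order by the predictions: over all pairs
#' with `obs_i != obs_j`, concordant pairs score 1, prediction ties 0.5,
#' discordant 0; the index is the score divided by the number of usable
#' pairs. Generalizes the AUC to non-binary responses and is invariant
#' under strictly monotone transforms of the predictions.
#'
#' @param pred Numeric predictions.
#' @param obs Numeric observations.
#' @return Scalar in \[0, 1\].
#' @export
c_index <- function(pred, obs) {
  stopifnot(length(pred) == length(obs), length(pred) >= 2)
  o <- outer(obs, obs, "-")
  use <- upper.tri(o) & o != 0
  if (!any(use)) stop("all observations tied: no usable pairs")
  p <- outer(pred, pred, "-")
  agree <- sign(p[use]) == sign(o[use])
  tie <- p[use] == 0
  (sum(agree & !tie) + 0.5 * sum(tie)) / sum(use)
}

#' Mean yearly spatial AUC of occupancy predictions
#'
#' Abundance predictions are compressed to presence-absence per
#' replicate (`abundance > 0`), averaged over replicates into per-cell
#' occupancy probabilities, and scored per year against observed
#' presence with the rank-statistic AUC (ties counted 0.5, i.e. the
#' c-index on a binary response). Years without both a presence and an
#' absence are skipped with a warning; the mean over the remaining years
#' is returned.
#'
#' @param occ_prob Matrix `[units, years]` of occupancy probabilities
#'   (or an abundance array `[units, years, reps]` to be compressed).
#' @param presence Matrix `[units, years]` of observed 0/1 presence.
#' @return List: `mean_auc`, `yearly` (per-year AUC, `NA` where skipped).
#' @export
spatial_auc <- function(occ_prob, presence) {
  if (length(dim(occ_prob)) == 3) {
    occ_prob <- apply(occ_prob > 0, c(1, 2), mean)
  }
  stopifnot(all(dim(occ_prob) == dim(presence)))
  ny <- ncol(presence)
  yearly <- rep(NA_real_, ny)
  for (k in seq_len(ny)) {
    y <- presence[, k]
    if (length(unique(y)) < 2) next
    yearly[k] <- c_index(occ_prob[, k], y)
  }
  if (all(is.na(yearly))) stop("no year with both presences and absences")
  if (any(is.na(yearly)))
    warning(sum(is.na(yearly)), " year(s) without both classes skipped")
  list(mean_auc = mean(yearly, na.rm = TRUE), yearly = yearly)
}

#' Temporal c-index against a reference abundance index
#'
#' The c-index applied to yearly relative-abundance predictions, with
#' the reference index series as the observations.
#'
#' @param pred_series Named or year-aligned numeric vector of predicted
#'   relative abundances.
#' @param reference Data frame `year, index` or a numeric vector of the
#'   same length/order.
#' @param years Years of `pred_series` (required when `reference` is a
#'   data frame).
#' @return Scalar c-index.
#' @export
temporal_c_index <- function(pred_series, reference, years = NULL) {
  if (is.data.frame(reference)) {
    if (is.null(years)) stop("supply years to align against the reference")
    m <- match(years, reference$year)
    if (any(is.na(m))) stop("years missing from the reference index")
    reference <- reference$index[m]
  }
  if (length(pred_series) != length(reference))
    stop("series are not aligned")
  c_index(pred_series, reference)
}

#' Relative-abundance envelopes across posterior predictions
#'
#' Per draw and replicate, the yearly total adult abundance divided by
#' the total in the reference year; the median and the 80% and 95%
#' credible envelopes are taken across draws and replicates. Trajectories
#' extinct at the reference year are excluded with a warning and their
#' count reported.
#'
#' @param totals Matrix `[years, trajectories]` of total adults (one
#'   column per draw x replicate), or a list of [simulate_ibm()] results
#'   whose totals are extracted.
#' @param years Year labels.
#' @param reference_year Normalizing year (default: first).
#' @return List: `series` (data frame `year, median, lo80, hi80, lo95,
#'   hi95`), `n_excluded`.
#' @export
relative_abundance <- function(totals, years, reference_year = years[1]) {
  if (is.list(totals) && !is.matrix(totals)) {
    totals <- do.call(cbind, lapply(totals, function(sim)
      apply(sim$abundance, c(3, 4), sum)))
  }
  stopifnot(nrow(totals) == length(years))
  k0 <- match(reference_year, years)
  if (is.na(k0)) stop("reference year not in years")
  ref <- totals[k0, ]
  bad <- ref <= 0
  if (all(bad)) stop("every trajectory extinct at the reference year")
  if (any(bad))
    warning(sum(bad), " trajectory(ies) extinct at reference year excluded")
  rel <- sweep(totals[, !bad, drop = FALSE], 2, ref[!bad], "/")
  qs <- t(apply(rel, 1, stats::quantile,
                probs = c(0.5, 0.10, 0.90, 0.025, 0.975), names = FALSE))
  list(series = data.frame(year = years, median = qs[, 1], lo80 = qs[, 2],
                           hi80 = qs[, 3], lo95 = qs[, 4], hi95 = qs[, 5]),
       n_excluded = sum(bad))
}

#' Site-level posterior predictions for fit metrics
#'
#' Mean over replicates of simulated adults at each surveyed cell and
#' year — the finest unit comparable to the observed counts (block-level
#' aggregation for these metrics is available via
#' [aggregate_for_likelihood()]).
#'
#' @param abundance Array `[rows, cols, years, reps]`.
#' @param sites Data frame with `site_id, x_cell, y_cell`.
#' @return Matrix `[sites, years]` of predicted means.
#' @export
predict_sites <- function(abundance, sites) {
  dm <- dim(abundance)
  idx <- (sites$x_cell - 1L) * dm[1] + sites$y_cell
  out <- matrix(0, nrow(sites), dm[3])
  for (r in seq_len(dm[4])) {
    for (k in seq_len(dm[3])) {
      plane <- abundance[, , k, r]
      out[, k] <- out[, k] + plane[idx]
    }
  }
  out / dm[4]
}
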