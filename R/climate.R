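# Seasonal climate predictors: construction, standardization, temporal
# trends and counterfactual (detrended) stacks.

#' The five seasonal climate predictors
#'
#' `T_br`/`P_br`: mean temperature / total precipitation, breeding season
#' (Apr-Jul); `T_at`: mean autumn temperature (Sep-Nov); `T_wn`: minimum
#' winter temperature (Dec-Feb); `P_wn`: total winter precipitation
#' (Dec-Feb). Winter seasons span the calendar boundary: the winter of
#' year `y` uses December of `y - 1`.
#'
#' @return Character vector of predictor ids.
#' @export
predictor_ids <- function() c("T_br", "P_br", "T_at", "T_wn", "P_wn")

#' Construct a climate stack
#'
#' @param layers Named list (all of [predictor_ids()]) of 3-d arrays
#'   `[rows, cols, years]`.
#' @param years Integer vector of calendar years (third dimension).
#' @param cell_km Cell edge length in km (default 1).
#' @param standardized Logical; are layers in z-units?
#' @param std Standardization record (see [standardize()]), or `NULL`.
#' @return Object of class `"climate_stack"`.
#' @export
climate_stack <- function(layers, years, cell_km = 1, standardized = FALSE,
                          std = NULL) {
  ids <- predictor_ids()
  if (!all(ids %in% names(layers)))
    stop("layers must contain all of: ", paste(ids, collapse = ", "))
  layers <- layers[ids]
  dm <- dim(layers[[1]])
  if (length(dm) != 3) stop("each layer must be a [rows, cols, years] array")
  for (p in ids) {
    if (!all(dim(layers[[p]]) == dm)) stop("layer shapes differ")
    if (any(!is.finite(layers[[p]]))) stop("non-finite values in layer ", p)
  }
  if (dm[3] != length(years)) stop("third dimension must match length(years)")
  structure(list(layers = layers, years = as.integer(years),
                 cell_km = cell_km, standardized = standardized, std = std),
            class = "climate_stack")
}

#' @export
print.climate_stack <- function(x, ...) {
  dm <- dim(x$layers[[1]])
  cat(sprintf("climate_stack: %d x %d grid (%g km cells), years %d-%d, %s\n",
              dm[1], dm[2], x$cell_km, min(x$years), max(x$years),
              if (isTRUE(x$standardized)) "standardized" else "raw"))
  invisible(x)
}

#' Bundle monthly layers for seasonal aggregation
#'
#' @param data 3-d array `[rows, cols, n_layers]` of monthly grids.
#' @param year,month Integer vectors (length `n_layers`) labelling each
#'   layer.
#' @return Object of class `"monthly_stack"`.
#' @export
monthly_stack <- function(data, year, month) {
  stopifnot(length(dim(data)) == 3, dim(data)[3] == length(year),
            length(year) == length(month), all(month %in% 1:12))
  structure(list(data = data, year = as.integer(year),
                 month = as.integer(month)), class = "monthly_stack")
}

# Year offsets for a season's month list: the last listed month belongs to
# the labelled year; walking backwards, a month greater than its successor
# falls in the previous calendar year (winter Dec-Feb -> Dec of y - 1).
season_offsets <- function(months) {
  k <- length(months)
  off <- integer(k)
  for (i in seq(k - 1, 1, length.out = max(k - 1, 0))) {
    off[i] <- off[i + 1] - as.integer(months[i] > months[i + 1])
  }
  off
}

#' Aggregate monthly layers into a seasonal grid
#'
#' Cellwise aggregate of the listed months for one labelled year. The
#' season may span the calendar boundary: for `months = c(12, 1, 2)` and
#' `year = y`, December of `y - 1` is combined with January and February
#' of `y`. Statistics: `"mean"` (seasonal mean of monthly values — also
#' the convention for total precipitation, whose monthly totals are
#' averaged over the season, and for minimum temperature, whose monthly
#' minima are averaged), `"min"` (min of monthly values) or `"sum"`.
#'
#' @param monthly A [monthly_stack()].
#' @param year Labelled calendar year of the season.
#' @param months Integer months in season order (e.g. `4:7`, `c(12, 1, 2)`).
#' @param statistic `"mean"`, `"min"` or `"sum"`.
#' @return A matrix (one seasonal grid).
#' @export
aggregate_season <- function(monthly, year, months,
                             statistic = c("mean", "min", "sum")) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(monthly, "monthly_stack"))
  off <- season_offsets(months)
  idx <- integer(length(months))
  for (i in seq_along(months)) {
    j <- which(monthly$year == year + off[i] & monthly$month == months[i])
    if (length(j) != 1)
      stop(sprintf("missing month layer: year %d month %d",
                   year + off[i], months[i]))
    idx[i] <- j
  }
  sub <- monthly$data[, , idx, drop = FALSE]
  apply(sub, c(1, 2), switch(statistic, mean = mean, min = min, sum = sum))
}

#' Standardize a climate stack over a reference period
#'
#' Each predictor is centred and scaled by its mean and standard
#' deviation pooled over all cells and all reference years (a single
#' global record per predictor, preserving spatial gradients in
#' z-units).
#'
#' @param stack A raw [climate_stack()].
#' @param reference_years Years to pool over (default: all years).
#' @return Standardized `climate_stack` with a `std` record
#'   (`mean`, `sd`, `reference_years` per predictor).
#' @export
standardize <- function(stack, reference_years = stack$years) {
  stopifnot(inherits(stack, "climate_stack"))
  if (isTRUE(stack$standardized)) stop("stack is already standardized")
  if (!all(reference_years %in% stack$years))
    stop("reference years outside available years")
  iy <- match(reference_years, stack$years)
  std <- list()
  layers <- stack$layers
  for (p in predictor_ids()) {
    v <- stack$layers[[p]][, , iy]
    m <- mean(v)
    s <- stats::sd(as.numeric(v))
    if (!is.finite(s) || s <= 0)
      stop("zero pooled standard deviation for predictor ", p)
    std[[p]] <- list(mean = m, sd = s,
                     reference_years = as.integer(reference_years))
    layers[[p]] <- (stack$layers[[p]] - m) / s
  }
  climate_stack(layers, stack$years, stack$cell_km, standardized = TRUE,
                std = std)
}

#' Invert standardization
#'
#' @param stack A standardized [climate_stack()] carrying its `std` record.
#' @return Raw-scale `climate_stack`.
#' @export
unstandardize <- function(stack) {
  stopifnot(inherits(stack, "climate_stack"))
  if (!isTRUE(stack$standardized) || is.null(stack$std))
    stop("stack is not standardized or lacks its record")
  layers <- stack$layers
  for (p in predictor_ids()) {
    layers[[p]] <- stack$layers[[p]] * stack$std[[p]]$sd + stack$std[[p]]$mean
  }
  climate_stack(layers, stack$years, stack$cell_km, standardized = FALSE)
}

#' Landscape-mean yearly series of one predictor
#'
#' @param stack A [climate_stack()].
#' @param predictor Predictor id.
#' @return Numeric vector (one value per year).
#' @export
landscape_mean_series <- function(stack, predictor) {
  apply(stack$layers[[predictor]], 3, mean)
}

#' Fit linear temporal trends per predictor
#'
#' Ordinary least squares of the landscape-mean series against calendar
#' year, one slope per predictor, with the accumulated change over the
#' span (`slope * (last - first year)`).
#'
#' @param stack A [climate_stack()].
#' @param years Years to fit over (default all).
#' @return Data frame (class `"trend_record"`) with columns `predictor`,
#'   `slope`, `intercept`, `se_slope`, `accumulated` and attributes
#'   `first_year`, `last_year`.
#' @export
fit_trend <- function(stack, years = stack$years) {
  stopifnot(inherits(stack, "climate_stack"))
  if (length(years) < 3) stop("need at least 3 years to fit a trend")
  if (!all(years %in% stack$years)) stop("years outside stack")
  iy <- match(years, stack$years)
  span <- max(years) - min(years)
  rows <- lapply(predictor_ids(), function(p) {
    y <- apply(stack$layers[[p]][, , iy, drop = FALSE], 3, mean)
    xc <- years - mean(years)
    sxx <- sum(xc^2)
    slope <- sum(xc * y) / sxx
    intercept <- mean(y) - slope * mean(years)
    rss <- sum((y - intercept - slope * years)^2)
    se <- sqrt(max(rss, 0) / (length(years) - 2) / sxx)
    data.frame(predictor = p, slope = slope, intercept = intercept,
               se_slope = se, accumulated = slope * span)
  })
  out <- do.call(rbind, rows)
  attr(out, "first_year") <- min(years)
  attr(out, "last_year") <- max(years)
  class(out) <- c("trend_record", "data.frame")
  out
}

#' Remove fitted linear trends (counterfactual stationary climate)
#'
#' Subtracts `slope * (year - anchor_year)` from each year's grid of each
#' predictor, yielding a no-climate-change scenario in which conditions
#' are held at the anchor year's level; the anchor-year layer itself is
#' unchanged.
#'
#' @param stack A [climate_stack()].
#' @param trend A `trend_record` from [fit_trend()] on the same stack.
#' @param anchor_year Year whose level is preserved (default: first year
#'   of the trend fit).
#' @return Detrended `climate_stack` (same standardization state).
#' @export
detrend <- function(stack, trend, anchor_year = attr(trend, "first_year")) {
  stopifnot(inherits(stack, "climate_stack"), inherits(trend, "trend_record"))
  if (anchor_year < min(stack$years) || anchor_year > max(stack$years))
    stop("anchor year outside stack year range")
  layers <- stack$layers
  for (p in predictor_ids()) {
    sl <- trend$slope[trend$predictor == p]
    shift <- sl * (stack$years - anchor_year)
    for (k in seq_along(stack$years)) {
      layers[[p]][, , k] <- layers[[p]][, , k] - shift[k]
    }
  }
  climate_stack(layers, stack$years, stack$cell_km,
                standardized = stack$standardized, std = stack$std)
}

#' Pairwise predictor correlations and collinearity flags
#'
#' Pearson correlation over all cell-years for each predictor pair;
#' pairs at or above the threshold in absolute value are flagged for
#' exclusion (the design here already excludes minimum winter
#' temperature from juvenile survival on these grounds).
#'
#' @param stack A [climate_stack()].
#' @param threshold Absolute correlation to flag at (default 0.7).
#' @return List with `correlation` (5 x 5 matrix) and `flagged` (data
#'   frame of offending pairs with their r).
#' @export
check_collinearity <- function(stack, threshold = 0.7) {
  stopifnot(inherits(stack, "climate_stack"))
  ids <- predictor_ids()
  X <- sapply(ids, function(p) as.numeric(stack$layers[[p]]))
  R <- stats::cor(X)
  flagged <- data.frame(predictor_a = character(), predictor_b = character(),
                        r = numeric())
  for (i in seq_len(length(ids) - 1)) {
    for (j in seq(i + 1, length(ids))) {
      if (abs(R[i, j]) >= threshold) {
        flagged <- rbind(flagged, data.frame(predictor_a = ids[i],
                                             predictor_b = ids[j],
                                             r = R[i, j]))
      }
    }
  }
  list(correlation = R, flagged = flagged)
}
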