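# Shared fixtures, built in code.

# spatially uniform standardized climate: every predictor constant at the
# given z-value for every cell and year (std record: mean 0, sd 1)
flat_climate <- function(nr = 10, nc = 10, years = 2000:2004,
                         z = c(T_br = 0, P_br = 0, T_at = 0, T_wn = 0,
                               P_wn = 0), cell_km = 1) {
  layers <- lapply(z[predictor_ids()], function(v)
    array(v, c(nr, nc, length(years))))
  names(layers) <- predictor_ids()
  std <- lapply(stats::setNames(predictor_ids(), predictor_ids()),
                function(p) list(mean = 0, sd = 1,
                                 reference_years = as.integer(years)))
  climate_stack(layers, years, cell_km, standardized = TRUE, std = std)
}

# raw stack with a prescribed linear trend plus optional iid noise
trended_climate <- function(nr = 6, nc = 6, years = 2000:2019,
                            slope = 0.05, base = 10, noise_sd = 0) {
  layers <- lapply(stats::setNames(predictor_ids(), predictor_ids()),
                   function(p) {
    arr <- array(base, c(nr, nc, length(years)))
    for (k in seq_along(years)) {
      arr[, , k] <- base + slope * (years[k] - years[1]) +
        if (noise_sd > 0) matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc)
        else 0
    }
    arr
  })
  climate_stack(layers, years)
}

# uniform habitat map
flat_habitat <- function(nr = 10, nc = 10, h = 100L) {
  matrix(as.integer(h), nr, nc)
}

# a small calibration-ready scenario bundle (shared across tests; cheap)
small_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sc <- synthetic_scenario(nr = 12, nc = 12, first_year = 2000,
                               last_year = 2007, n_sites = 20, seed = 99,
                               spinup_years = 15)
      cache <<- gen_scenario_bundle(sc)
    }
    cache
  }
})

# Moran's I by explicit double sum over all cell pairs (oracle)
morans_i_oracle <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  z <- as.vector(x - mean(x))
  coords <- expand.grid(r = seq_len(nr), c = seq_len(nc))
  num <- 0; wsum <- 0
  for (a in seq_along(z)) {
    for (b in seq_along(z)) {
      if (a == b) next
      w <- as.numeric(abs(coords$r[a] - coords$r[b]) <= 1 &
                        abs(coords$c[a] - coords$c[b]) <= 1)
      num <- num + w * z[a] * z[b]
      wsum <- wsum + w
    }
  }
  (length(z) / wsum) * num / sum(z^2)
}

# Harrell's c by explicit pair loop (oracle)
c_index_oracle <- function(pred, obs) {
  n <- length(pred)
  score <- 0; usable <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (obs[i] == obs[j]) next
      usable <- usable + 1
      if (pred[i] == pred[j]) score <- score + 0.5
      else if (sign(pred[i] - pred[j]) == sign(obs[i] - obs[j]))
        score <- score + 1
    }
  }
  score / usable
}
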