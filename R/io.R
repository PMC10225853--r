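# Plain-text serialization: grids and stacks as CSV with JSON sidecars,
# scenarios as YAML. Everything written here reloads into an identical
# in-memory object, so any artifact is regenerable from its files.

#' Write / read a single grid as CSV
#'
#' Plain rectangular CSV of cell values (row = grid row), no headers.
#'
#' @param x Numeric/integer matrix.
#' @param path File path.
#' @return `read_grid_csv` returns a matrix.
#' @export
write_grid_csv <- function(x, path) {
  utils::write.table(x, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_grid_csv
#' @param integer Coerce to integer on read.
#' @export
read_grid_csv <- function(path, integer = FALSE) {
  m <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(m) <- NULL
  if (integer) storage.mode(m) <- "integer"
  m
}

#' Write / read a climate stack
#'
#' One long CSV (`predictor, year, row, col, value`) plus a JSON sidecar
#' holding years, cell size, standardization state and record.
#'
#' @param stack A [climate_stack()].
#' @param path CSV path; the sidecar is `paste0(path, ".json")`.
#' @return `read_climate_csv` returns a `climate_stack`.
#' @export
write_climate_csv <- function(stack, path) {
  stopifnot(inherits(stack, "climate_stack"))
  dm <- dim(stack$layers[[1]])
  rows <- lapply(predictor_ids(), function(p) {
    data.frame(predictor = p,
               year = rep(stack$years, each = dm[1] * dm[2]),
               row = rep(seq_len(dm[1]), times = dm[2] * dm[3]),
               col = rep(rep(seq_len(dm[2]), each = dm[1]), times = dm[3]),
               value = as.vector(stack$layers[[p]]))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  meta <- list(years = stack$years, cell_km = stack$cell_km,
               standardized = stack$standardized, std = stack$std,
               nrow = dm[1], ncol = dm[2])
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_climate_csv
#' @export
read_climate_csv <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(path)
  layers <- list()
  for (p in predictor_ids()) {
    sub <- df[df$predictor == p, ]
    sub <- sub[order(sub$year, sub$col, sub$row), ]
    layers[[p]] <- array(sub$value, c(meta$nrow, meta$ncol,
                                      length(meta$years)))
  }
  std <- NULL
  if (isTRUE(meta$standardized)) {
    std <- lapply(meta$std, function(s)
      list(mean = s$mean, sd = s$sd,
           reference_years = as.integer(s$reference_years)))
  }
  climate_stack(layers, meta$years, meta$cell_km,
                standardized = isTRUE(meta$standardized), std = std)
}

#' Write / read a survey table
#'
#' CSV with columns `site_id, x_cell, y_cell, year, count`.
#'
#' @param survey Survey data frame.
#' @param path File path.
#' @export
write_survey_csv <- function(survey, path) {
  stopifnot(all(c("site_id", "x_cell", "y_cell", "year", "count") %in%
                  names(survey)))
  utils::write.csv(survey, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_survey_csv
#' @export
read_survey_csv <- function(path) {
  utils::read.csv(path)
}

#' Write / read a scenario definition as YAML
#'
#' @param scenario A [synthetic_scenario()].
#' @param path File path.
#' @export
write_scenario_yaml <- function(scenario, path) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  lst <- unclass(scenario)
  lst$theta_true <- as.list(stats::setNames(as.numeric(scenario$theta_true),
                                            names(scenario$theta_true)))
  for (f in c("clim_mean", "clim_base_sd", "clim_noise_sd", "clim_slope")) {
    lst[[f]] <- as.list(lst[[f]])
  }
  yaml::write_yaml(lst, path, precision = 15)
  invisible(path)
}

#' @rdname write_scenario_yaml
#' @export
read_scenario_yaml <- function(path) {
  lst <- yaml::read_yaml(path)
  theta <- do.call(param_vector, lst$theta_true)
  do.call(synthetic_scenario, c(
    lst[c("nr", "nc", "cell_km", "first_year", "last_year", "corr_length",
          "cover", "clustering", "sigma_true", "n_sites", "seed_density",
          "spinup_years", "seed")],
    lapply(lst[c("clim_mean", "clim_base_sd", "clim_noise_sd",
                 "clim_slope")], unlist),
    list(theta_true = theta)))
}

#' Write a trend or standardization record as JSON
#'
#' @param x A `trend_record` or a `std` record list.
#' @param path File path.
#' @export
write_record_json <- function(x, path) {
  if (inherits(x, "trend_record")) {
    out <- list(type = "trend", first_year = attr(x, "first_year"),
                last_year = attr(x, "last_year"),
                table = as.data.frame(x))
  } else {
    out <- list(type = "standardization", record = x)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write MCMC chains to a columnar CSV
#'
#' Columns: `chain`, `internal`, `generation`, one column per parameter,
#' and `log_posterior`.
#'
#' @param run An `mcmc_run`.
#' @param path File path.
#' @export
write_chains_csv <- function(run, path) {
  stopifnot(inherits(run, "mcmc_run"))
  rows <- list()
  for (c in seq_along(run$chains)) {
    for (i in seq_len(run$n_internal)) {
      m <- matrix(run$chains[[c]][, i, ], run$n_gen,
                  length(run$param_names))
      colnames(m) <- run$param_names
      rows[[length(rows) + 1]] <- data.frame(
        chain = c, internal = i, generation = seq_len(run$n_gen), m,
        log_posterior = run$log_posteriors[[c]][, i])
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
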