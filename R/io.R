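## File I/O contracts: self-describing gridded array files (JSON with named
## lon/lat/time dimensions and units attributes — a text-based stand-in for
## NetCDF, which has no reader in this package's dependency set), CSV
## tables, and JSON config files. Every writer has a reader and
## write -> read -> write is byte-identical.

#' Write a gridded field to a self-describing array file
#'
#' JSON container with named dimensions (`lon`, `lat` and optionally
#' `time`), a units attribute and the flattened (column-major) data.
#'
#' @param x matrix (lon x lat) or 3-d array (lon x lat x time).
#' @param path output path.
#' @param name variable name stored in the file.
#' @param units units attribute string.
#' @export
write_grid_field <- function(x, path, name, units) {
  d <- dim(x)
  assert_that(length(d) %in% c(2, 3), "expected a 2-d or 3-d field")
  dims <- list(lon = d[1], lat = d[2])
  if (length(d) == 3) dims$time <- d[3]
  obj <- list(name = name, units = units, dims = dims,
              data = as.vector(x))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a gridded field written by [write_grid_field()]
#' @param path file path.
#' @return the array, with `name` and `units` attributes.
#' @export
read_grid_field <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  x <- array(obj$data, dim = unname(unlist(obj$dims)))
  attr(x, "name") <- obj$name
  attr(x, "units") <- obj$units
  x
}

#' Write / read a CSV table (UTF-8, header row mandatory)
#' @param x data.frame.
#' @param path file path.
#' @rdname table_io
#' @export
write_table <- function(x, path) {
  write.csv(x, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname table_io
#' @export
read_table <- function(path) {
  read.csv(path, fileEncoding = "UTF-8", stringsAsFactors = FALSE)
}

pipeline_defaults <- function() {
  list(seed = 1L,
       grid = list(n_lon = 6L, n_lat = 6L, cell_area_km2 = 2500,
                   n_days = 60L, steps_per_day = 24L),
       regions = list(n_districts_x = 3L, n_districts_y = 2L,
                      n_states = 3L, n_countries = 2L),
       urban_fraction = 0.08,
       kernel = list(peak_hour = 14.5, window = c(6.5, 19.5),
                     window_mass = 0.95),
       shifts = c(-6:-1, 1),
       thresholds = list(urban = 400, dense = 1000,
                         x_kt_per_mt = 1.3, y_deaths_per_kt = 1000),
       n_draws = 1000L,
       year = 2015L)
}

validate_config <- function(cfg) {
  chk <- function(ok, key, what) {
    if (!isTRUE(ok)) stop("config error at '", key, "': ", what,
                          call. = FALSE)
  }
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1, "seed",
      "must be a single integer")
  chk(cfg$grid$n_lon >= 2 && cfg$grid$n_lat >= 2, "grid",
      "grid must be at least 2x2")
  chk(24 %% cfg$grid$steps_per_day == 0, "grid.steps_per_day",
      "must divide 24")
  chk(cfg$regions$n_districts_x * cfg$regions$n_districts_y >= 1, "regions",
      "need at least one district")
  chk(cfg$n_draws >= 1, "n_draws", "must be >= 1")
  chk(all(cfg$shifts == round(cfg$shifts)), "shifts", "must be integers")
  k <- cfg$kernel
  chk(k$window[1] < k$peak_hour && k$peak_hour < k$window[2],
      "kernel", "peak must lie inside the window")
  invisible(cfg)
}

#' Read a pipeline configuration file
#'
#' JSON key-value file; missing keys fall back to the documented defaults
#' (6x6 grid, 60 days hourly, 3x2 districts in 3 states and 2 countries,
#' the 14:30-peak triangular kernel, 1000 draws, seed 1).
#'
#' @param path path to a JSON config file, or `NULL` for pure defaults.
#' @return validated config list.
#' @export
read_config <- function(path = NULL) {
  cfg <- pipeline_defaults()
  if (!is.null(path)) {
    assert_that(file.exists(path), paste0("config file not found: ", path))
    user <- jsonlite::read_json(path, simplifyVector = TRUE)
    for (key in names(user)) {
      if (is.list(cfg[[key]]) && is.list(user[[key]])) {
        for (sub in names(user[[key]])) cfg[[key]][[sub]] <- user[[key]][[sub]]
      } else {
        cfg[[key]] <- user[[key]]
      }
    }
  }
  validate_config(cfg)
}

log_msg <- function(...) message("[burnadjoint] ", ...)
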