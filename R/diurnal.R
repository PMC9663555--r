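## Triangular within-day emission profile: a symmetric triangle centred on
## the peak hour whose half-base is solved numerically so that a stated
## fraction of total mass (default 95%) falls inside a stated local-time
## window (default 06:30-19:30). Hour-bin weights are exact integrals of the
## continuous density, clipped to [0, 24) and renormalized.

# CDF of the symmetric triangular density with peak p and half-base b
tri_cdf <- function(x, p, b) {
  lo <- p - b
  hi <- p + b
  y <- numeric(length(x))
  y[x >= hi] <- 1
  mid <- x > lo & x <= p
  y[mid] <- 0.5 * ((x[mid] - lo) / b)^2
  up <- x > p & x < hi
  y[up] <- 1 - 0.5 * ((hi - x[up]) / b)^2
  y
}

tri_bin_weights <- function(peak, half_base) {
  # integrate over each hour bin of [0, 24); mass outside the day is clipped
  # and the remaining weights renormalized
  edges <- 0:24
  w <- diff(tri_cdf(edges, peak, half_base))
  w <- pmax(w, 0)
  s <- sum(w)
  assert_that(s > 0, "kernel support falls entirely outside [0, 24)")
  w / s
}

new_kernel <- function(weights, peak_hour, window, half_base, window_mass) {
  structure(list(weights = weights, peak_hour = peak_hour, window = window,
                 half_base = half_base, window_mass = window_mass),
            class = "diurnal_kernel")
}

#' Triangular diurnal emission kernel
#'
#' Builds the 24-bin within-day weight profile of burning emissions as a
#' symmetric triangle about `peak_hour`, with its half-base solved so that
#' the fraction `window_mass` of the continuous mass lies inside `window`.
#' The defaults place 95% of emissions between 06:30 and 19:30 local time
#' with the peak at 14:30, so the maximal hourly bin is hour 14
#' (14:00-15:00).
#'
#' @param peak_hour peak of burning activity, hours after midnight.
#' @param window `c(start, end)` local-time window in hours.
#' @param window_mass fraction of total mass required inside the window.
#' @return object of class `diurnal_kernel` with fields `weights` (24
#'   values summing to 1), `peak_hour`, `window`, `half_base`.
#' @examples
#' k <- build_triangular_kernel()
#' which.max(k$weights) - 1  # hour bin 14 contains 14:30
#' @export
build_triangular_kernel <- function(peak_hour = 14.5,
                                    window = c(6.5, 19.5),
                                    window_mass = 0.95) {
  s <- window[1]; e <- window[2]
  assert_that(s >= 0 && s < peak_hour && peak_hour < e && e <= 24,
              "need 0 <= start < peak < end <= 24")
  assert_that(window_mass > 0 && window_mass <= 1,
              "window_mass must be in (0, 1]")
  b_min <- min(peak_hour - s, e - peak_hour)
  mass_in <- function(b) tri_cdf(e, peak_hour, b) - tri_cdf(s, peak_hour, b)
  if (window_mass == 1) {
    b <- b_min
  } else {
    # mass_in(b) decreases from 1 (b = b_min) toward 0; bracket the root
    b_hi <- b_min
    while (mass_in(b_hi) > window_mass && b_hi < 1e3) b_hi <- b_hi * 2
    assert_that(mass_in(b_hi) <= window_mass,
                "window_mass condition is infeasible")
    b <- uniroot(function(b) mass_in(b) - window_mass,
                 lower = b_min, upper = b_hi, tol = 1e-13)$root
  }
  new_kernel(tri_bin_weights(peak_hour, b), peak_hour, window, b, window_mass)
}

#' Continuous kernel mass inside an interval
#'
#' Mass of the continuous (pre-discretization) triangular density between
#' hours `a` and `b`; e.g. the default kernel has mass 0.95 in
#' `c(6.5, 19.5)`.
#'
#' @param k `diurnal_kernel`.
#' @param a,b interval bounds in hours.
#' @return scalar in `[0, 1]`.
#' @export
kernel_mass_in <- function(k, a, b) {
  tri_cdf(b, k$peak_hour, k$half_base) - tri_cdf(a, k$peak_hour, k$half_base)
}

#' Shift a diurnal kernel within the day
#'
#' Translates the continuous triangle by an integer number of hours,
#' clipping at the day boundary (burning does not wrap past midnight) and
#' renormalizing the remaining hourly weights so daily totals are
#' conserved. The study range is -6 to +1 hours; values outside it are
#' accepted with a warning.
#'
#' @param k `diurnal_kernel`.
#' @param delta_hours integer shift; negative = earlier.
#' @return shifted `diurnal_kernel`.
#' @export
shift_kernel <- function(k, delta_hours) {
  assert_that(delta_hours == round(delta_hours),
              "delta_hours must be an integer")
  if (delta_hours < -6 || delta_hours > 1)
    warning("shift of ", delta_hours,
            " h is outside the evaluated range [-6, +1]", call. = FALSE)
  if (delta_hours == 0) return(k)
  peak <- k$peak_hour + delta_hours
  new_kernel(tri_bin_weights(peak, k$half_base), peak,
             k$window + delta_hours, k$half_base, k$window_mass)
}

#' Disaggregate daily emissions to hourly with a diurnal kernel
#'
#' Each day's per-cell total is distributed across the 24 hour bins in
#' proportion to the kernel weights, conserving per-cell daily totals.
#'
#' @param E_daily daily `emission_inventory`.
#' @param k `diurnal_kernel` (24 weights; must match the target
#'   steps-per-day).
#' @param steps_per_day steps per day of the target resolution (24).
#' @return hourly `emission_inventory`.
#' @export
apply_kernel <- function(E_daily, k, steps_per_day = 24L) {
  assert_that(inherits(E_daily, "emission_inventory") &&
                identical(E_daily$resolution, "daily"),
              "apply_kernel expects a daily emission inventory")
  if (length(k$weights) != steps_per_day)
    stop("kernel has ", length(k$weights), " bins but the grid has ",
         steps_per_day, " steps per day", call. = FALSE)
  d <- dim(E_daily$E)
  n_days <- d[3]
  Eh <- array(0, dim = c(d[1], d[2], n_days * steps_per_day))
  for (day in seq_len(n_days)) {
    base <- (day - 1L) * steps_per_day
    for (h in seq_len(steps_per_day)) {
      Eh[, , base + h] <- E_daily$E[, , day] * k$weights[h]
    }
  }
  emission_inventory(Eh, resolution = "hourly", species = E_daily$species,
                     season_of_day = E_daily$season_of_day)
}

#' @export
print.diurnal_kernel <- function(x, ...) {
  cat(sprintf(
    "<diurnal_kernel> peak %.1f h, half-base %.3f h, %.0f%% in [%.1f, %.1f]\n",
    x$peak_hour, x$half_base, 100 * x$window_mass, x$window[1], x$window[2]))
  invisible(x)
}
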