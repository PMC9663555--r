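## Counterfactual experiments: within-day timing shifts, district
## categorization, contribution ranking.

scope_filter <- function(E_daily, regions, scope) {
  # scope: NULL, or list(region_id=, level=, days=) — days restricts the
  # calendar (month analog); region restricts source cells
  E <- E_daily$E
  if (!is.null(scope$region_id)) {
    level <- scope$level %||% "state"
    ids <- regions[[paste0(level, "_id")]]
    keep <- ids == scope$region_id
    E <- E * array(rep(as.numeric(keep), dim(E)[3]), dim(E))
  }
  if (!is.null(scope$days)) {
    keep_d <- seq_len(dim(E)[3]) %in% scope$days
    E <- E * array(rep(keep_d, each = prod(dim(E)[1:2])), dim(E))
  }
  emission_inventory(E, resolution = "daily", species = E_daily$species,
                     season_of_day = E_daily$season_of_day)
}

#' Within-day burning timing-shift experiment
#'
#' For each shift delta (hours; negative = earlier), daily emissions in the
#' chosen scope are disaggregated with the shifted triangular kernel,
#' attributed through the hourly adjoint sensitivities, and compared with
#' the unshifted kernel: percent change = 100 (dP(delta) - dP(0)) / dP(0).
#' A negative value is an air quality benefit. With several worlds (seeds
#' standing in for meteorological years) the min/mean/max across worlds is
#' reported, the error-bar analog of a multi-year analysis.
#'
#' @param S hourly `sensitivity_field`, or a list of them (one per world).
#' @param E_daily daily `emission_inventory`, or a list parallel to `S`.
#' @param base_kernel unshifted `diurnal_kernel`.
#' @param shifts integer shifts; default -6..-1 and +1.
#' @param regions `region_map` (needed when `scope` restricts a region).
#' @param scope optional list(region_id, level, days) restricting the
#'   experiment to one source region and/or a day range.
#' @return data.frame with one row per shift: `shift_hours`,
#'   `pct_change_mean`, `pct_change_min`, `pct_change_max`.
#' @export
timing_shift_experiment <- function(S, E_daily, base_kernel,
                                    shifts = c(-6:-1, 1),
                                    regions = NULL, scope = NULL) {
  Ss <- if (inherits(S, "sensitivity_field")) list(S) else S
  Es <- if (inherits(E_daily, "emission_inventory")) list(E_daily) else E_daily
  assert_that(length(Ss) == length(Es), "need one emission set per world")
  pct <- matrix(NA_real_, length(Ss), length(shifts))
  for (w in seq_along(Ss)) {
    E_scoped <- if (is.null(scope)) Es[[w]] else
      scope_filter(Es[[w]], regions, scope)
    base <- attribute_exposure(Ss[[w]],
                               apply_kernel(E_scoped, base_kernel))$total
    if (base == 0)
      stop("scope has zero baseline attributable exposure", call. = FALSE)
    for (k in seq_along(shifts)) {
      dp <- attribute_exposure(
        Ss[[w]], apply_kernel(E_scoped,
                              shift_kernel(base_kernel, shifts[k])))$total
      pct[w, k] <- 100 * (dp - base) / base
    }
  }
  data.frame(shift_hours = shifts,
             pct_change_mean = colMeans(pct),
             pct_change_min = apply(pct, 2, min),
             pct_change_max = apply(pct, 2, max))
}

#' Two-axis district categorization
#'
#' Classifies districts by emission intensity (x, KT of PM2.5 per MT of
#' crop production) and mortality intensity (y, deaths per KT emitted):
#' C1 high/high, C2 low-x/high-y, C3 high-x/low-y, C4 low/low. Values
#' exactly at a threshold count as high.
#'
#' @param metrics table from [per_unit_metrics()].
#' @param x_threshold emission-intensity cut (default 1.3 KT/MT).
#' @param y_threshold mortality-intensity cut (default 1000 deaths/KT).
#' @return the metrics table with an added `category` column.
#' @export
categorize_districts <- function(metrics, x_threshold = 1.3,
                                 y_threshold = 1000) {
  hi_x <- metrics$x_kt_per_mt >= x_threshold
  hi_y <- metrics$y_deaths_per_kt >= y_threshold
  metrics$category <- ifelse(hi_x & hi_y, "C1",
                      ifelse(!hi_x & hi_y, "C2",
                      ifelse(hi_x & !hi_y, "C3", "C4")))
  metrics
}

#' Rank regions by contribution share
#'
#' Orders an aggregation table by descending share with a cumulative-share
#' column; ties are broken by key label for determinism.
#'
#' @param agg table from [aggregate_contribution()].
#' @param top_n optional number of rows to keep (after ranking).
#' @return ranked data.frame with `rank` and `cumulative_share_percent`.
#' @export
rank_contributions <- function(agg, top_n = NULL) {
  o <- order(-agg$share_percent, agg$key)
  r <- agg[o, , drop = FALSE]
  r$rank <- seq_len(nrow(r))
  r$cumulative_share_percent <- cumsum(r$share_percent)
  rownames(r) <- NULL
  if (!is.null(top_n)) r <- r[seq_len(min(top_n, nrow(r))), , drop = FALSE]
  r
}
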