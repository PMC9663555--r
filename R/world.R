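## Synthetic world: grid, population, regions, crops, transport config,
## demography, IER parameter draws, economic series. Everything is seeded and
## deterministic; magnitudes are order-of-magnitude plausible for northern
## India but arbitrary — no synthetic number reproduces a published value.

#' Default scenario configuration for the synthetic world
#'
#' The default is the desk-scale reference world used throughout the test
#' suite: a 6x6 grid of 50 km cells simulated hourly for 60 days (a
#' compressed "year" containing one pre-monsoon and one post-monsoon burning
#' season), six districts tiled 3x2 across the grid and nested into three
#' states and two countries. Winds blow toward the east-northeast so the
#' westernmost (agricultural) districts sit upwind of the urban cluster.
#'
#' @param n_lon,n_lat grid dimensions (cells); both must be >= 2.
#' @param cell_area_km2 area of one grid cell in km^2.
#' @param n_days number of simulated days; must cover both burning seasons.
#' @param steps_per_day time steps per day; must divide 24. Hourly (24) is
#'   required by the transport model.
#' @param n_districts_x,n_districts_y district tiling of the grid.
#' @param n_states,n_countries counts; districts are grouped west-to-east
#'   into states and states into countries, so nesting is automatic.
#' @param urban_fraction fraction of cells made "dense urban"
#'   (>1000 people km^-2); an equal number of suburban cells
#'   (400-1000 people km^-2) is also placed. Set 0 for a fully rural world.
#' @param seasons list with integer day ranges `pre_monsoon` and
#'   `post_monsoon` (inclusive `c(first, last)`); `NULL` scales the default
#'   ranges to `n_days`.
#' @param seed master integer seed; all stages derive named sub-streams.
#' @return a named list understood by [make_world()].
#' @export
world_config <- function(n_lon = 6L, n_lat = 6L, cell_area_km2 = 2500,
                         n_days = 60L, steps_per_day = 24L,
                         n_districts_x = 3L, n_districts_y = 2L,
                         n_states = 3L, n_countries = 2L,
                         urban_fraction = 0.08,
                         seasons = NULL, seed = 1L) {
  list(n_lon = as.integer(n_lon), n_lat = as.integer(n_lat),
       cell_area_km2 = cell_area_km2, n_days = as.integer(n_days),
       steps_per_day = as.integer(steps_per_day),
       n_districts_x = as.integer(n_districts_x),
       n_districts_y = as.integer(n_districts_y),
       n_states = as.integer(n_states), n_countries = as.integer(n_countries),
       urban_fraction = urban_fraction,
       seasons = seasons, seed = as.integer(seed))
}

default_seasons <- function(n_days) {
  list(pre_monsoon  = c(ceiling(n_days * 0.18), floor(n_days * 0.42)),
       post_monsoon = c(ceiling(n_days * 0.60), floor(n_days * 0.92)))
}

season_of_day <- function(n_days, seasons) {
  s <- rep("off_season", n_days)
  s[seq(seasons$pre_monsoon[1], seasons$pre_monsoon[2])] <- "pre_monsoon"
  s[seq(seasons$post_monsoon[1], seasons$post_monsoon[2])] <- "post_monsoon"
  factor(s, levels = c("pre_monsoon", "post_monsoon", "off_season"))
}

#' Grid specification
#' @param n_lon,n_lat,cell_area_km2,n_days,steps_per_day see [world_config()].
#' @param local_time_offset hours added per cell column (0 = single zone).
#' @return object of class `grid_spec`.
#' @export
grid_spec <- function(n_lon, n_lat, cell_area_km2, n_days, steps_per_day,
                      local_time_offset = 0) {
  assert_that(n_lon >= 2 && n_lat >= 2, "grid must be at least 2x2")
  assert_that(24L %% as.integer(steps_per_day) == 0L,
              "steps_per_day must divide 24")
  structure(list(n_lon = as.integer(n_lon), n_lat = as.integer(n_lat),
                 cell_area_km2 = cell_area_km2, n_days = as.integer(n_days),
                 steps_per_day = as.integer(steps_per_day),
                 local_time_offset = local_time_offset,
                 n_steps = as.integer(n_days) * as.integer(steps_per_day)),
            class = "grid_spec")
}

split_contiguous <- function(n, k) {
  # partition 1..n into k contiguous groups, sizes differing by at most 1
  sizes <- rep(n %/% k, k)
  if (n %% k > 0) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
  rep(seq_len(k), sizes)
}

make_regions <- function(grid, n_districts_x, n_districts_y,
                         n_states, n_countries) {
  assert_that(n_districts_x >= 1 && n_districts_y >= 1,
              "need at least one district")
  assert_that(n_districts_x <= grid$n_lon && n_districts_y <= grid$n_lat,
              "more district tiles than grid cells")
  n_districts <- n_districts_x * n_districts_y
  assert_that(n_states <= n_districts && n_countries <= n_states,
              "states must not outnumber districts, nor countries states")
  dx <- split_contiguous(grid$n_lon, n_districts_x)   # tile column per i
  dy <- split_contiguous(grid$n_lat, n_districts_y)   # tile row per j
  district_id <- outer(dx, dy, function(a, b) (a - 1L) * n_districts_y + b)
  # districts ordered west->east then south->north; states take contiguous
  # district runs, countries contiguous state runs => nesting holds by
  # construction
  state_of_district <- split_contiguous(n_districts, n_states)
  country_of_state <- split_contiguous(n_states, n_countries)
  state_id <- matrix(state_of_district[district_id],
                     grid$n_lon, grid$n_lat)
  country_id <- matrix(country_of_state[state_id], grid$n_lon, grid$n_lat)
  structure(list(
    district_id = district_id, state_id = state_id, country_id = country_id,
    n_districts = n_districts, n_states = n_states, n_countries = n_countries,
    state_of_district = state_of_district,
    country_of_state = country_of_state,
    names = list(
      district = sprintf("district_%02d", seq_len(n_districts)),
      state    = sprintf("state_%02d", seq_len(n_states)),
      country  = sprintf("country_%02d", seq_len(n_countries)))),
    class = "region_map")
}

make_population <- function(grid, regions, urban_fraction, seed) {
  set.seed(sub_seed(seed, "population"))
  n <- grid$n_lon * grid$n_lat
  density <- matrix(runif(n, 40, 300), grid$n_lon, grid$n_lat)
  n_urban <- round(urban_fraction * n)
  if (n_urban > 0) {
    # place dense cells downwind (eastern half of country 1), suburbs beside
    in_c1 <- which(regions$country_id == 1L)
    cols <- ((in_c1 - 1L) %/% grid$n_lon) + 1L  # not used; cells indexed by column-major
    i_of <- ((in_c1 - 1L) %% grid$n_lon) + 1L
    east <- in_c1[i_of > max(i_of) / 2]
    urban_cells <- sample(east, min(n_urban, length(east)))
    density[urban_cells] <- runif(length(urban_cells), 1200, 4000)
    rest <- setdiff(east, urban_cells)
    sub <- sample(rest, min(length(urban_cells), length(rest)))
    density[sub] <- runif(length(sub), 450, 900)
  }
  pop <- density * grid$cell_area_km2
  assert_that(all(pop >= 0) && sum(pop) > 0, "population must be non-negative")
  pop
}

make_crops <- function(regions, seed) {
  set.seed(sub_seed(seed, "crops"))
  n <- regions$n_districts
  # production in MT (million metric tonnes) per year; emission_factor in
  # kg PM2.5 (BC+OC) per MT of residue burned
  crops <- data.frame(
    district_id = seq_len(n),
    district = regions$names$district,
    production_mt = runif(n, 0.5, 3.0),
    residue_ratio = runif(n, 1.2, 1.8),
    burned_fraction = runif(n, 0.10, 0.35),
    emission_factor_kg_per_mt = runif(n, 4e6, 8e6))
  # westernmost (upwind) state is the residue-intensive breadbasket
  upwind <- which(regions$state_of_district == 1L)
  crops$production_mt[upwind] <- crops$production_mt[upwind] * 2.5
  crops$burned_fraction[upwind] <- pmin(0.9, crops$burned_fraction[upwind] * 1.8)
  crops
}

#' Transport configuration for the toy linear model
#'
#' First-order upwind advection, five-point diffusion and linear deposition,
#' with a 24-value diurnal mixing-depth cycle that dilutes fresh emissions;
#' the cycle peaks in the 13:00-14:00 bin, mimicking the early-afternoon
#' maximum of planetary-boundary-layer height.
#'
#' @param u,v advection, in cells per step (|u|+|v| plus 4*diffusion must
#'   keep the one-step operator non-negative; each |.| <= 1).
#' @param diffusion per-step weight given to each of the four neighbours.
#' @param deposition_rate fraction of mass removed per step, in (0, 1).
#' @param mixing_depth_cycle 24 positive diurnal dilution multipliers.
#' @return object of class `transport_config`.
#' @export
transport_config <- function(u = 0.4, v = 0.1, diffusion = 0.05,
                             deposition_rate = 0.02,
                             mixing_depth_cycle = NULL) {
  if (is.null(mixing_depth_cycle)) {
    h <- 0:23
    mixing_depth_cycle <- 0.6 + 2.4 * exp(-0.5 * ((h + 0.5 - 13.5) / 3)^2)
  }
  assert_that(length(mixing_depth_cycle) == 24 && all(mixing_depth_cycle > 0),
              "mixing_depth_cycle must be 24 positive values")
  assert_that(deposition_rate > 0 && deposition_rate < 1,
              "deposition_rate must be in (0, 1)")
  assert_that(abs(u) <= 1 && abs(v) <= 1 && diffusion >= 0 &&
                (1 - 4 * diffusion) >= 0,
              "advection/diffusion weights must keep the operator non-negative")
  structure(list(u = u, v = v, diffusion = diffusion,
                 deposition_rate = deposition_rate,
                 mixing_depth_cycle = mixing_depth_cycle),
            class = "transport_config")
}

#' Demography: age structure and cause-specific baseline mortality
#'
#' Five age groups and the five PM2.5-linked causes of death (COPD, IHD,
#' LRI, lung cancer, cerebrovascular disease). Baseline mortality rates are
#' deaths per person per year; `age_rr_multiplier` scales the *excess*
#' relative risk by age for the two cardiovascular causes.
#'
#' @param seed integer seed.
#' @return object of class `demography_table`.
#' @export
make_demography <- function(seed = 1L) {
  set.seed(sub_seed(seed, "demography"))
  ages <- c("0-4", "5-14", "15-49", "50-69", "70+")
  shares <- c(0.09, 0.18, 0.52, 0.16, 0.05)
  shares <- shares / sum(shares)
  causes <- c("COPD", "IHD", "LRI", "lung_cancer", "cerebrovascular")
  # per-cause all-age rates (deaths/person/yr), spread across ages with a
  # steep age gradient except LRI (children also at risk)
  base <- c(COPD = 6e-4, IHD = 1.5e-3, LRI = 4e-4,
            lung_cancer = 6e-5, cerebrovascular = 7e-4)
  grad <- rbind(
    COPD            = c(0.02, 0.02, 0.25, 2.5, 8.0),
    IHD             = c(0.01, 0.01, 0.30, 3.0, 9.0),
    LRI             = c(1.50, 0.30, 0.20, 1.5, 6.0),
    lung_cancer     = c(0.00, 0.00, 0.30, 3.5, 7.0),
    cerebrovascular = c(0.02, 0.02, 0.25, 3.0, 9.0))
  bmr <- matrix(0, length(causes), length(ages),
                dimnames = list(causes, ages))
  for (h in causes) {
    w <- grad[h, ] * shares
    bmr[h, ] <- base[[h]] * grad[h, ] / sum(w)  # so sum(share*bmr)=base
  }
  structure(list(
    ages = ages, age_shares = setNames(shares, ages),
    causes = causes, bmr = bmr,
    age_rr_multiplier = setNames(c(0.2, 0.2, 0.8, 1.2, 1.4), ages),
    age_weighted_causes = c("IHD", "cerebrovascular")),
    class = "demography_table")
}

#' Monte Carlo draws of IER relative-risk parameters
#'
#' One (alpha, beta, delta, chi0) quadruple per cause and draw. chi0, the
#' theoretical minimum-risk concentration, is drawn uniformly on
#' 2.4-5.9 ug/m3; the shape parameters are log-normal around cause-specific
#' central values.
#'
#' @param n_draws number of draws (default 1000).
#' @param seed integer seed.
#' @return object of class `ier_draws`: list of per-cause data frames with
#'   columns draw, alpha, beta, delta, chi0.
#' @export
draw_ier_params <- function(n_draws = 1000L, seed = 1L) {
  assert_that(n_draws >= 1, "n_draws must be >= 1")
  set.seed(sub_seed(seed, "ier"))
  causes <- c("COPD", "IHD", "LRI", "lung_cancer", "cerebrovascular")
  central <- list(
    COPD            = c(alpha = 1.00, beta = 0.020, delta = 0.80),
    IHD             = c(alpha = 1.40, beta = 0.045, delta = 0.65),
    LRI             = c(alpha = 2.00, beta = 0.030, delta = 0.70),
    lung_cancer     = c(alpha = 0.90, beta = 0.025, delta = 0.75),
    cerebrovascular = c(alpha = 1.10, beta = 0.035, delta = 0.70))
  draws <- lapply(causes, function(h) {
    ctr <- central[[h]]
    data.frame(
      draw = seq_len(n_draws),
      alpha = rlnorm(n_draws, log(ctr[["alpha"]]), 0.15),
      beta  = rlnorm(n_draws, log(ctr[["beta"]]), 0.20),
      delta = rlnorm(n_draws, log(ctr[["delta"]]), 0.10),
      chi0  = runif(n_draws, 2.4, 5.9))
  })
  names(draws) <- causes
  structure(list(draws = draws, n_draws = as.integer(n_draws),
                 causes = causes), class = "ier_draws")
}

#' Annual economic series for VSL benefit transfer
#'
#' US real GDP per capita, GDP implicit price deflator and the India/US
#' PPP GDP-per-capita ratio by year, plus the Weibull parameters of the
#' US 1990 VSL and the two income elasticities (0.7 within the US over
#' time, 1.5 US-to-India). The Weibull default has mean near 4.8 million
#' 1990 USD; it is a synthetic stand-in, not a published parameterization.
#'
#' @param years integer vector of target years (1990 is always included as
#'   the transfer base year).
#' @param seed integer seed.
#' @param epsilon1,epsilon2 income elasticities.
#' @return object of class `econ_series`.
#' @export
make_econ_series <- function(years = 2003:2019, seed = 1L,
                             epsilon1 = 0.7, epsilon2 = 1.5) {
  set.seed(sub_seed(seed, "econ"))
  years <- sort(unique(c(1990L, as.integer(years))))
  t <- years - 1990L
  series <- data.frame(
    year = years,
    gdp_per_capita_us = 36000 * (1.016)^t * exp(rnorm(length(t), 0, 0.005)),
    gdp_deflator = 100 * (1.021)^t,
    ppp_ratio = pmin(1, 0.055 * (1.045)^t))
  assert_that(all(series$gdp_per_capita_us > 0) &&
                all(series$gdp_deflator > 0) && all(series$ppp_ratio > 0),
              "economic series must be strictly positive")
  shape <- 1.51
  scale <- 4.8e6 / gamma(1 + 1 / shape)
  structure(list(series = series, vsl_us_1990_shape = shape,
                 vsl_us_1990_scale = scale,
                 epsilon1 = epsilon1, epsilon2 = epsilon2),
            class = "econ_series")
}

make_background <- function(grid, pop, seed) {
  set.seed(sub_seed(seed, "background"))
  dens <- pop / grid$cell_area_km2
  bg <- 25 + 45 * (dens / max(dens))^0.25 +
    matrix(rnorm(length(pop), 0, 3), nrow(pop), ncol(pop))
  pmax(bg, 5)
}

#' Build the complete synthetic world
#'
#' Generates, from one seeded configuration, every input the attribution
#' pipeline needs: grid, clustered population (with dense-urban cells
#' exceeding 1000 people km^-2 unless `urban_fraction = 0`), nested
#' country/state/district region map, per-district crop table, linear
#' transport configuration, demography, IER parameter draws, economic
#' series, a non-fire background PM2.5 field, and the season calendar.
#'
#' @param config list from [world_config()].
#' @return object of class `burn_world`.
#' @examples
#' w <- make_world(world_config(seed = 1))
#' sum(w$pop)
#' @export
make_world <- function(config = world_config()) {
  grid <- grid_spec(config$n_lon, config$n_lat, config$cell_area_km2,
                    config$n_days, config$steps_per_day)
  regions <- make_regions(grid, config$n_districts_x, config$n_districts_y,
                          config$n_states, config$n_countries)
  seasons <- config$seasons %||% default_seasons(grid$n_days)
  assert_that(seasons$pre_monsoon[1] >= 1 &&
                seasons$pre_monsoon[2] >= seasons$pre_monsoon[1] &&
                seasons$post_monsoon[2] >= seasons$post_monsoon[1] &&
                seasons$post_monsoon[2] <= grid$n_days &&
                seasons$pre_monsoon[2] < seasons$post_monsoon[1],
              "season day ranges must be ordered and inside the simulation")
  pop <- make_population(grid, regions, config$urban_fraction, config$seed)
  crops <- make_crops(regions, config$seed)
  tc <- transport_config()
  structure(list(
    grid = grid, regions = regions, pop = pop, crops = crops,
    transport = tc,
    demography = make_demography(config$seed),
    ier = draw_ier_params(1000L, config$seed),
    econ = make_econ_series(seed = config$seed),
    background_chi = make_background(grid, pop, config$seed),
    seasons = seasons,
    season_of_day = season_of_day(grid$n_days, seasons),
    config = config), class = "burn_world")
}

#' Gridded daily burning emissions from the crop table
#'
#' Each district's annual emission total is production x residue_ratio x
#' burned_fraction x emission_factor (kg). The total is spread over the
#' district's cells with seeded random weights and over days so that 97% of
#' mass falls in the two burning seasons (pre-monsoon and post-monsoon,
#' split 40/60) and the remainder is uniform off-season background burning.
#'
#' @param crops crop table (as in `world$crops`).
#' @param regions region map.
#' @param grid grid spec.
#' @param seed integer seed.
#' @param seasons season day ranges; defaults to the world defaults.
#' @param season_mass fraction of the annual total inside the two seasons.
#' @param season_split length-2 positive weights (pre, post).
#' @return object of class `emission_inventory` with daily resolution.
#' @export
make_emissions <- function(crops, regions, grid, seed = 1L,
                           seasons = default_seasons(grid$n_days),
                           season_mass = 0.97,
                           season_split = c(pre = 0.4, post = 0.6)) {
  missing <- setdiff(crops$district_id, seq_len(regions$n_districts))
  if (length(missing) > 0)
    stop("districts not present in region map: ",
         paste(missing, collapse = ", "), call. = FALSE)
  set.seed(sub_seed(seed, "emissions"))
  season_split <- season_split / sum(season_split)
  sod <- season_of_day(grid$n_days, seasons)
  E <- array(0, dim = c(grid$n_lon, grid$n_lat, grid$n_days))
  for (r in seq_len(nrow(crops))) {
    d <- crops$district_id[r]
    total <- crops$production_mt[r] * crops$residue_ratio[r] *
      crops$burned_fraction[r] * crops$emission_factor_kg_per_mt[r]
    cells <- which(regions$district_id == d)
    sw <- rgamma(length(cells), shape = 2, rate = 1)
    sw <- sw / sum(sw)
    dw <- numeric(grid$n_days)
    for (s in c("pre_monsoon", "post_monsoon")) {
      idx <- which(sod == s)
      w <- rgamma(length(idx), shape = 2, rate = 1)
      frac <- if (s == "pre_monsoon") season_split[[1]] else season_split[[2]]
      dw[idx] <- season_mass * frac * w / sum(w)
    }
    off <- which(sod == "off_season")
    if (length(off) > 0) dw[off] <- (1 - season_mass) / length(off)
    dw <- dw / sum(dw)
    for (k in seq_along(cells)) {
      i <- ((cells[k] - 1L) %% grid$n_lon) + 1L
      j <- ((cells[k] - 1L) %/% grid$n_lon) + 1L
      E[i, j, ] <- E[i, j, ] + total * sw[k] * dw
    }
  }
  emission_inventory(E, resolution = "daily", season_of_day = sod)
}

#' Construct an emission inventory object
#' @param E array (n_lon x n_lat x n_times), kg per cell per step; all >= 0.
#' @param resolution `"daily"` or `"hourly"`.
#' @param species species label (BC+OC treated as one combined PM2.5 species).
#' @param season_of_day factor of length n_days mapping days to seasons.
#' @return object of class `emission_inventory`.
#' @export
emission_inventory <- function(E, resolution = c("daily", "hourly"),
                               species = "PM2.5_BCOC", season_of_day = NULL) {
  resolution <- match.arg(resolution)
  assert_that(is.array(E) && length(dim(E)) == 3, "E must be a 3-d array")
  assert_that(all(E >= 0), "emissions must be non-negative")
  structure(list(E = E, resolution = resolution, species = species,
                 season_of_day = season_of_day),
            class = "emission_inventory")
}

#' @export
print.burn_world <- function(x, ...) {
  g <- x$grid
  cat(sprintf(
    "<burn_world> %dx%d grid (%g km2 cells), %d days x %d steps/day\n",
    g$n_lon, g$n_lat, g$cell_area_km2, g$n_days, g$steps_per_day))
  cat(sprintf("  population %.3g; %d districts / %d states / %d countries\n",
              sum(x$pop), x$regions$n_districts, x$regions$n_states,
              x$regions$n_countries))
  invisible(x)
}
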