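# Independent oracles and small fixtures, built from first principles and
# never through the package's transport step functions.

cell_idx <- function(i, j, n_lon) (j - 1L) * n_lon + i

# dense upwind x-advection matrix (outflow boundaries)
oracle_ax <- function(n_lon, n_lat, u) {
  n <- n_lon * n_lat
  A <- matrix(0, n, n)
  for (j in seq_len(n_lat)) for (i in seq_len(n_lon)) {
    a <- cell_idx(i, j, n_lon)
    A[a, a] <- 1 - abs(u)
    if (u > 0 && i > 1) A[a, cell_idx(i - 1L, j, n_lon)] <- u
    if (u < 0 && i < n_lon) A[a, cell_idx(i + 1L, j, n_lon)] <- abs(u)
  }
  A
}

oracle_ay <- function(n_lon, n_lat, v) {
  n <- n_lon * n_lat
  A <- matrix(0, n, n)
  for (j in seq_len(n_lat)) for (i in seq_len(n_lon)) {
    a <- cell_idx(i, j, n_lon)
    A[a, a] <- 1 - abs(v)
    if (v > 0 && j > 1) A[a, cell_idx(i, j - 1L, n_lon)] <- v
    if (v < 0 && j < n_lat) A[a, cell_idx(i, j + 1L, n_lon)] <- abs(v)
  }
  A
}

oracle_diffusion <- function(n_lon, n_lat, d) {
  n <- n_lon * n_lat
  A <- diag(1 - 4 * d, n)
  for (j in seq_len(n_lat)) for (i in seq_len(n_lon)) {
    a <- cell_idx(i, j, n_lon)
    if (i > 1) A[a, cell_idx(i - 1L, j, n_lon)] <- d
    if (i < n_lon) A[a, cell_idx(i + 1L, j, n_lon)] <- d
    if (j > 1) A[a, cell_idx(i, j - 1L, n_lon)] <- d
    if (j < n_lat) A[a, cell_idx(i, j + 1L, n_lon)] <- d
  }
  A
}

# dense one-step operator: advect x, advect y, diffuse, deposit
oracle_step_matrix <- function(tc, n_lon, n_lat) {
  (1 - tc$deposition_rate) *
    (oracle_diffusion(n_lon, n_lat, tc$diffusion) %*%
       oracle_ay(n_lon, n_lat, tc$v) %*%
       oracle_ax(n_lon, n_lat, tc$u))
}

# dense-matrix forward integration of hourly emissions (flattened vectors)
oracle_forward <- function(E_arr, tc, grid) {
  n <- grid$n_lon * grid$n_lat
  M <- oracle_step_matrix(tc, grid$n_lon, grid$n_lat)
  chi <- array(0, dim = dim(E_arr))
  cur <- numeric(n)
  for (t in seq_len(dim(E_arr)[3])) {
    h <- (t - 1L) %% grid$steps_per_day
    cur <- as.vector(M %*% cur) +
      as.vector(E_arr[, , t]) /
      (grid$cell_area_km2 * tc$mixing_depth_cycle[h + 1L])
    chi[, , t] <- cur
  }
  chi
}

# small worlds with explicit seasons so tiny day counts are valid
tiny_world <- function(n_lon = 4L, n_lat = 4L, n_days = 2L, seed = 7L,
                       urban_fraction = 0.1) {
  n_days <- max(n_days, 2L)  # both burning seasons need a day each
  make_world(world_config(
    n_lon = n_lon, n_lat = n_lat, n_days = n_days,
    n_districts_x = 2L, n_districts_y = 2L, n_states = 2L, n_countries = 1L,
    urban_fraction = urban_fraction,
    seasons = list(pre_monsoon = c(1L, 1L),
                   post_monsoon = c(2L, n_days)),
    seed = seed))
}

random_hourly_inventory <- function(grid, seed, sod = NULL) {
  set.seed(seed)
  E <- array(runif(grid$n_lon * grid$n_lat * grid$n_steps, 0, 100),
             dim = c(grid$n_lon, grid$n_lat, grid$n_steps))
  emission_inventory(E, resolution = "hourly", season_of_day = sod)
}

uniform_kernel <- function(steps = 24L) {
  structure(list(weights = rep(1 / steps, steps), peak_hour = 12,
                 window = c(0, 24), half_base = 12, window_mass = 1),
            class = "diurnal_kernel")
}

# single-draw IER parameter set with hand-chosen values, built by hand
hand_ier_draws <- function(alpha, beta, delta, chi0,
                           causes = c("COPD", "IHD", "LRI", "lung_cancer",
                                      "cerebrovascular")) {
  draws <- lapply(causes, function(h)
    data.frame(draw = 1L, alpha = alpha, beta = beta, delta = delta,
               chi0 = chi0))
  names(draws) <- causes
  structure(list(draws = draws, n_draws = 1L, causes = causes),
            class = "ier_draws")
}

# econ series with hand-set values for transfer-identity tests
hand_econ <- function(g1990 = 36000, gy = 36000, d1990 = 100, dy = 100,
                      ry = 1, year = 2010L, shape = 1.51, scale = 5e6,
                      epsilon1 = 0.7, epsilon2 = 1.5) {
  structure(list(
    series = data.frame(year = c(1990L, year),
                        gdp_per_capita_us = c(g1990, gy),
                        gdp_deflator = c(d1990, dy),
                        ppp_ratio = c(1, ry)),
    vsl_us_1990_shape = shape, vsl_us_1990_scale = scale,
    epsilon1 = epsilon1, epsilon2 = epsilon2), class = "econ_series")
}
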