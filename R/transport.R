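## Linear toy transport: first-order upwind advection (dimensional split),
## five-point diffusion, linear deposition, then emission injection diluted
## by the diurnal mixing-depth cycle. The one-step operator M is linear with
## non-negative entries; its transpose is advection with reversed winds
## (diffusion is symmetric, deposition scalar), which gives the exact
## adjoint of the forward map E -> chi.

# shift a matrix by one row/col, zero-filling (outflow boundary)
shift_w <- function(m) rbind(0, m[-nrow(m), , drop = FALSE])  # from west  (i-1)
shift_e <- function(m) rbind(m[-1, , drop = FALSE], 0)        # from east  (i+1)
shift_s <- function(m) cbind(0, m[, -ncol(m), drop = FALSE])  # from south (j-1)
shift_n <- function(m) cbind(m[, -1, drop = FALSE], 0)        # from north (j+1)

advect_x <- function(chi, u) {
  if (u >= 0) (1 - u) * chi + u * shift_w(chi)
  else (1 + u) * chi - u * shift_e(chi)
}
advect_y <- function(chi, v) {
  if (v >= 0) (1 - v) * chi + v * shift_s(chi)
  else (1 + v) * chi - v * shift_n(chi)
}
diffuse <- function(chi, d) {
  if (d == 0) return(chi)
  (1 - 4 * d) * chi +
    d * (shift_w(chi) + shift_e(chi) + shift_s(chi) + shift_n(chi))
}

# one transport step M (no emission term)
step_forward <- function(chi, tc) {
  (1 - tc$deposition_rate) *
    diffuse(advect_y(advect_x(chi, tc$u), tc$v), tc$diffusion)
}

# exact transpose of step_forward: reverse application order; the upwind
# advection transpose equals advection with the wind sign flipped, and the
# five-point diffusion stencil is symmetric.
step_adjoint <- function(lam, tc) {
  advect_x(advect_y(diffuse((1 - tc$deposition_rate) * lam, tc$diffusion),
                    -tc$v), -tc$u)
}

# per-step emission-to-concentration factor: kg -> ug/m3, diluted by the
# diurnal mixing depth; hour is the zero-based hour-of-day bin
injection_factor <- function(hour, tc, grid) {
  1 / (grid$cell_area_km2 * tc$mixing_depth_cycle[hour + 1L])
}

#' Run the forward transport model
#'
#' Integrates hourly emissions through the linear transport operator: each
#' step the concentration field is advected (outflow boundaries, mass
#' leaving the domain is lost), diffused, depleted by deposition, and then
#' receives that hour's emissions divided by cell area and the hour's
#' mixing-depth multiplier. The map from emissions to concentrations is
#' linear, and non-negative emissions give non-negative concentrations.
#'
#' @param E hourly `emission_inventory` (kg per cell per hour).
#' @param tc `transport_config`.
#' @param grid `grid_spec` with `steps_per_day = 24`.
#' @return object of class `concentration_field`: list with `chi`, an
#'   (n_lon x n_lat x n_steps) array in ug/m3.
#' @export
simulate_forward <- function(E, tc, grid) {
  if (!identical(E$resolution, "hourly"))
    stop("simulate_forward needs hourly emissions; ",
         "disaggregate daily inventories with apply_kernel() first",
         call. = FALSE)
  assert_that(grid$steps_per_day == 24L,
              "hourly transport requires steps_per_day = 24")
  assert_that(all(dim(E$E) == c(grid$n_lon, grid$n_lat, grid$n_steps)),
              "emission array does not match the grid/time dimensions")
  chi <- array(0, dim = dim(E$E))
  cur <- matrix(0, grid$n_lon, grid$n_lat)
  for (t in seq_len(grid$n_steps)) {
    cur <- step_forward(cur, tc) +
      E$E[, , t] * injection_factor(step_hour(t, grid$steps_per_day), tc, grid)
    chi[, , t] <- cur
  }
  structure(list(chi = chi, grid = grid), class = "concentration_field")
}

#' Dense one-step transport matrix (small grids)
#'
#' Materializes the linear one-step operator M on the flattened
#' (column-major) cell space by applying it to unit vectors. Intended for
#' small grids and for validation against matrix-based oracles.
#'
#' @param tc `transport_config`.
#' @param grid `grid_spec`.
#' @return an (n x n) matrix, n = n_lon * n_lat.
#' @export
transport_matrix <- function(tc, grid) {
  n <- grid$n_lon * grid$n_lat
  assert_that(n <= 4096, "transport_matrix is for small grids only")
  M <- matrix(0, n, n)
  for (k in seq_len(n)) {
    e <- matrix(0, grid$n_lon, grid$n_lat)
    e[k] <- 1
    M[, k] <- as.vector(step_forward(e, tc))
  }
  M
}

#' Adjoint sensitivities of population-weighted exposure to emissions
#'
#' Computes S[i,j,t] = dJ/dE[i,j,t], the change in the exposure cost
#' function (person ug/m3 summed over people and hours, optionally
#' restricted to a cell mask) per additional kg emitted in cell (i,j) at
#' hour t. Uses the exact transpose of the forward operator via the
#' backward recursion lambda_t = w + M' lambda_{t+1}, with w the (masked)
#' population weights; S_t is lambda_t scaled by the hour's injection
#' factor.
#'
#' @param tc `transport_config`.
#' @param grid `grid_spec` (hourly).
#' @param pop population matrix (people per cell).
#' @param mask optional logical matrix restricting the receptor population
#'   (e.g. from [population_mask()]); must retain some population.
#' @return object of class `sensitivity_field`: list with `S`
#'   (n_lon x n_lat x n_steps, person ug/m3 per kg), `mask`, `grid`.
#' @export
build_adjoint <- function(tc, grid, pop, mask = NULL) {
  assert_that(grid$steps_per_day == 24L,
              "hourly adjoint requires steps_per_day = 24")
  w <- pop
  if (!is.null(mask)) {
    assert_that(all(dim(mask) == dim(pop)), "mask/population dims differ")
    w <- pop * (mask != 0)
    if (sum(w) == 0)
      stop("mask selects zero population", call. = FALSE)
  }
  S <- array(0, dim = c(grid$n_lon, grid$n_lat, grid$n_steps))
  lam <- w
  for (t in rev(seq_len(grid$n_steps))) {
    S[, , t] <- lam * injection_factor(step_hour(t, grid$steps_per_day),
                                       tc, grid)
    if (t > 1L) lam <- w + step_adjoint(lam, tc)
  }
  structure(list(S = S, grid = grid, mask = mask,
                 cost_function_tag = if (is.null(mask)) "all" else "masked"),
            class = "sensitivity_field")
}
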