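make_contrib <- function(w, seed = 1) {
  Ed <- make_emissions(w$crops, w$regions, w$grid, seed = seed,
                       seasons = w$seasons)
  Eh <- apply_kernel(Ed, build_triangular_kernel())
  S <- build_adjoint(w$transport, w$grid, w$pop)
  list(S = S, Eh = Eh, Ed = Ed,
       contrib = attribute_exposure(S, Eh))
}

test_that("cost function matches a brute-force summation oracle", {
  set.seed(42)
  chi <- array(runif(3 * 3 * 5), c(3, 3, 5))
  pop <- matrix(runif(9, 10, 100), 3, 3)
  hand <- 0
  for (t in 1:5) for (j in 1:3) for (i in 1:3)
    hand <- hand + pop[i, j] * chi[i, j, t]
  J <- cost_function_J(chi, pop)
  expect_equal(J$total, hand)
  expect_equal(J$pw_mean, hand / (sum(pop) * 5))

  # constant field: population-weighted mean recovers the constant
  expect_equal(cost_function_J(array(3.7, c(3, 3, 5)), pop)$pw_mean, 3.7)

  expect_error(cost_function_J(chi, matrix(1, 2, 2)), "do not match")
  expect_error(cost_function_J(chi, pop, mask = matrix(FALSE, 3, 3)),
               "zero population")
})

test_that("population-density masks nest", {
  w <- make_world(world_config(seed = 1))
  m0 <- population_mask(w$pop, w$grid$cell_area_km2, 0)
  expect_equal(m0, w$pop > 0)
  m400 <- population_mask(w$pop, w$grid$cell_area_km2, 400)
  m1000 <- population_mask(w$pop, w$grid$cell_area_km2, 1000)
  expect_true(all(m1000 <= m400))  # dense mask is a subset of urban
  expect_true(all(m400 <= m0))
  expect_error(population_mask(w$pop, w$grid$cell_area_km2, -1), ">= 0")
})

test_that("attribution is the elementwise inner product and is linear", {
  w <- tiny_world(seed = 8)
  S <- build_adjoint(w$transport, w$grid, w$pop)
  E0 <- emission_inventory(array(0, dim(S$S)), "hourly")
  expect_equal(attribute_exposure(S, E0)$total, 0)

  # unit pulse picks out a single sensitivity value
  E1 <- array(0, dim(S$S)); E1[2, 2, 7] <- 1
  expect_equal(attribute_exposure(S, emission_inventory(E1, "hourly"))$total,
               S$S[2, 2, 7])

  Ea <- random_hourly_inventory(w$grid, seed = 1)
  Eb <- random_hourly_inventory(w$grid, seed = 2)
  lin <- attribute_exposure(
    S, emission_inventory(3 * Ea$E + 0.5 * Eb$E, "hourly"))$total
  expect_identical(lin, sum(3 * attribute_exposure(S, Ea)$delta_P +
                              0.5 * attribute_exposure(S, Eb)$delta_P))

  Ed <- emission_inventory(array(1, c(4, 4, 2)), "daily")
  expect_error(attribute_exposure(S, Ed), "apply_kernel")
})

test_that("aggregations are complete partitions with shares summing to 100", {
  w <- make_world(world_config(seed = 2))
  parts <- make_contrib(w, seed = 2)
  contrib <- parts$contrib
  for (by in c("district", "state", "country", "season", "day")) {
    agg <- aggregate_contribution(contrib, w$regions, by)
    expect_equal(sum(agg$delta_P_person_ugm3), contrib$total,
                 tolerance = 1e-9)
    expect_equal(sum(agg$share_percent), 100, tolerance = 1e-9)
  }
})

test_that("a district holding all emissions takes a 100% share", {
  w <- tiny_world(n_days = 2L, seed = 3)
  crops <- w$crops
  crops$burned_fraction[crops$district_id != 1] <- 0
  Ed <- make_emissions(crops, w$regions, w$grid, seed = 3,
                       seasons = w$seasons)
  Eh <- apply_kernel(Ed, build_triangular_kernel())
  S <- build_adjoint(w$transport, w$grid, w$pop)
  agg <- aggregate_contribution(attribute_exposure(S, Eh), w$regions,
                                "district")
  expect_equal(agg$share_percent[agg$key == "district_01"], 100)
})

test_that("the upwind breadbasket district dominates the shares", {
  w <- make_world(world_config(seed = 1))
  parts <- make_contrib(w, seed = 1)
  agg <- aggregate_contribution(parts$contrib, w$regions, "state")
  # state 1 is the upwind high-production state by construction
  expect_equal(which.max(agg$share_percent), 1L)
  expect_gt(max(agg$share_percent), 50)
})

test_that("per-unit metrics satisfy the x*y*production identity", {
  w <- make_world(world_config(seed = 4))
  parts <- make_contrib(w, seed = 4)
  agg <- aggregate_contribution(parts$contrib, w$regions, "district")
  deaths <- data.frame(key = agg$key, deaths = 1500 * agg$share_percent / 100)
  m <- per_unit_metrics(agg, w$crops, deaths)
  expect_equal(m$x_kt_per_mt * m$y_deaths_per_kt * m$production_mt,
               m$deaths, tolerance = 1e-6)

  crops2 <- w$crops
  crops2$burned_fraction[1] <- 2 * crops2$burned_fraction[1]  # double E, same P
  m2 <- per_unit_metrics(agg, crops2, deaths)
  expect_equal(m2$x_kt_per_mt[1], 2 * m$x_kt_per_mt[1])

  crops3 <- w$crops
  crops3$production_mt[2] <- 0
  expect_warning(m3 <- per_unit_metrics(agg, crops3, deaths),
                 "district_02")
  expect_false("district_02" %in% m3$district)
})

test_that("marginal efficacy equals the share-per-1% and an explicit rerun", {
  w <- make_world(world_config(seed = 6))
  parts <- make_contrib(w, seed = 6)
  contrib <- parts$contrib
  eff <- marginal_efficacy(contrib, w$regions, 1, "state", "post_monsoon")
  agg_share <- NULL

  # explicit re-attribution oracle: scale the (region, season) emissions by
  # 99% and recompute the total
  E <- parts$Eh$E
  sel_cells <- w$regions$state_id == 1
  day_of_step <- ((seq_len(dim(E)[3]) - 1L) %/% 24L) + 1L
  sel_steps <- contrib$season_of_day[day_of_step] == "post_monsoon"
  scale <- array(1, dim(E))
  scale[rep(sel_cells, dim(E)[3]) &
          rep(sel_steps, each = prod(dim(E)[1:2]))] <- 0.99
  total99 <- attribute_exposure(
    parts$S, emission_inventory(E * scale, "hourly"))$total
  explicit <- 100 * (contrib$total - total99) / contrib$total
  expect_equal(eff, explicit, tolerance = 1e-9)

  # a region with zero emissions has zero efficacy
  crops0 <- w$crops
  crops0$burned_fraction[w$regions$state_of_district != 1] <- 0
  Ed0 <- make_emissions(crops0, w$regions, w$grid, seed = 6,
                        seasons = w$seasons)
  c0 <- attribute_exposure(parts$S,
                           apply_kernel(Ed0, build_triangular_kernel()))
  expect_equal(marginal_efficacy(c0, w$regions, 3, "state"), 0)
})

test_that("an injected district share is recovered to 1e-6", {
  w <- make_world(world_config(seed = 9))
  parts <- make_contrib(w, seed = 9)
  agg <- aggregate_contribution(parts$contrib, w$regions, "district")
  s_d <- agg$share_percent[4] / 100
  f <- 0.35   # target share for district 4
  a <- f * (1 - s_d) / (s_d * (1 - f))
  E <- parts$Eh$E
  sel <- array(rep(w$regions$district_id == 4, dim(E)[3]), dim(E))
  E[sel] <- a * E[sel]
  agg2 <- aggregate_contribution(
    attribute_exposure(parts$S, emission_inventory(E, "hourly")),
    w$regions, "district")
  expect_equal(agg2$share_percent[4] / 100, f, tolerance = 1e-6)
})

test_that("nested receptor masks order the attributable exposure", {
  w <- make_world(world_config(seed = 1))
  Ed <- make_emissions(w$crops, w$regions, w$grid, seed = 1,
                       seasons = w$seasons)
  Eh <- apply_kernel(Ed, build_triangular_kernel())
  m400 <- population_mask(w$pop, w$grid$cell_area_km2, 400)
  m1000 <- population_mask(w$pop, w$grid$cell_area_km2, 1000)
  tot <- function(mask) attribute_exposure(
    build_adjoint(w$transport, w$grid, w$pop, mask), Eh)$total
  all_pop <- attribute_exposure(
    build_adjoint(w$transport, w$grid, w$pop), Eh)$total
  expect_lte(tot(m1000), tot(m400))
  expect_lte(tot(m400), all_pop)
})

test_that("forward and adjoint agree to machine precision on a dense world", {
  w <- tiny_world(n_days = 2L, seed = 5)
  Ed <- make_emissions(w$crops, w$regions, w$grid, seed = 5,
                       seasons = w$seasons)
  Eh <- apply_kernel(Ed, build_triangular_kernel())
  cc <- consistency_check(w, Eh)
  expect_lte(cc$rel_discrepancy, 1e-8)

  # and against the fully independent dense-matrix forward oracle
  chi_oracle <- oracle_forward(Eh$E, w$transport, w$grid)
  j_oracle <- cost_function_J(chi_oracle, w$pop)$total
  expect_equal(cc$adjoint, j_oracle, tolerance = 1e-10)

  E0 <- emission_inventory(array(0, dim(Eh$E)), "hourly")
  expect_equal(consistency_check(w, E0)$rel_discrepancy, 0)
})
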