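# a 2 x 2 world with one facility and hand-set times/populations
toy_cost <- function(times, n_fac = 1, alloc = NULL) {
  g <- grid_raster(times, cell_size = 100)
  al <- if (is.null(alloc)) matrix(1, nrow(times), ncol(times)) else alloc
  al[!is.finite(times)] <- NA
  structure(list(scenario_name = "toy", direction = "to_facility",
                 facility_ids = sprintf("F%02d", seq_len(n_fac)),
                 travel_time = g,
                 allocation = grid_raster(al, cell_size = 100)),
            class = "cost_surfaces")
}

test_that("per-facility catchment population counts threshold membership", {
  times <- matrix(c(0, 90, 30, 130), 2, 2)     # [0,30; 90,130] row-wise
  pop <- grid_raster(matrix(c(10, 30, 20, 40), 2, 2), cell_size = 100)
  cost <- toy_cost(times)
  expect_equal(facility_catchment_population(cost, pop, 60)$population, 30)
  expect_equal(facility_catchment_population(cost, pop, 120)$population, 60)
  expect_equal(facility_catchment_population(cost, pop, "full")$population, 100)
})

test_that("full catchments partition the reachable population", {
  scn <- random_micro_scene(23, nr = 15, nc = 15)
  src <- random_sources(scn$merged, 3)
  st <- fac_at(src[, 1], src[, 2], grid = scn$merged$grid)
  cs <- accumulate_cost(scn$merged, scn$dem, uniform_walk(4), st)
  set.seed(1)
  pop <- grid_raster(matrix(runif(225) * 10, 15, 15), cell_size = 100)
  full <- facility_catchment_population(cs, pop, "full")
  reachable <- sum(pop$values[is.finite(cs$travel_time$values)])
  expect_equal(sum(full$population), reachable)
  # nesting: pop_1h <= pop_2h <= pop_full per facility
  p60 <- facility_catchment_population(cs, pop, 60)$population
  p120 <- facility_catchment_population(cs, pop, 120)$population
  expect_true(all(p60 <= p120 + 1e-12))
  expect_true(all(p120 <= full$population + 1e-12))
})

test_that("zonal coverage conserves population and nests across thresholds", {
  sc <- generate_scene(scene_config(seed = 19, n_rows = 40, n_cols = 40,
                                    n_settlements = 8, n_hc = 2, n_hp = 8,
                                    total_population = 30000))
  m <- build_merged_landcover(sc$landcover, sc$roads, sc$rivers, sc$lakes,
                              sc$grid)
  fac <- snap_facilities(sc$facilities, m)
  cs <- accumulate_cost(m, sc$dem, default_scenarios()$walking_only, fac)
  cov <- zonal_coverage(cs, sc$population, sc$districts, c(30, 60, 120))
  # conservation, overall and per zone
  expect_equal(cov$overall$pop_covered + cov$overall$pop_uncovered,
               rep(sum(sc$population$values), 3))
  agg <- aggregate(cbind(pop_covered, pop_total) ~ threshold_min,
                   cov$per_zone, sum)
  expect_equal(agg$pop_covered,
               cov$overall$pop_covered[match(agg$threshold_min,
                                             cov$overall$threshold_min)])
  # nesting in the threshold, per zone
  wide <- reshape(cov$per_zone[, c("district_id", "threshold_min", "pct_covered")],
                  idvar = "district_id", timevar = "threshold_min",
                  direction = "wide")
  expect_true(all(wide$pct_covered.30 <= wide$pct_covered.60 + 1e-9,
                  na.rm = TRUE))
  expect_true(all(wide$pct_covered.60 <= wide$pct_covered.120 + 1e-9,
                  na.rm = TRUE))
  # the uncovered raster holds exactly the uncovered population
  expect_equal(sum(cov$uncovered$min60$values, na.rm = TRUE),
               cov$overall$pop_uncovered[cov$overall$threshold_min == 60])
})

test_that("one zone equals overall; an infinite threshold covers the reachable", {
  scn <- random_micro_scene(41, nr = 10, nc = 10, barrier_frac = 0)
  src <- random_sources(scn$merged, 2)
  st <- fac_at(src[, 1], src[, 2], grid = scn$merged$grid)
  cs <- accumulate_cost(scn$merged, scn$dem, uniform_walk(4), st)
  set.seed(2)
  pop <- grid_raster(matrix(runif(100), 10, 10), cell_size = 100)
  zones <- grid_raster(matrix(1, 10, 10), cell_size = 100)
  cov <- zonal_coverage(cs, pop, zones, c(60, 1e9))
  expect_equal(cov$per_zone$pop_covered, cov$overall$pop_covered)
  expect_equal(cov$overall$pct_covered[2], 100)
})

test_that("adding a facility never lowers zonal coverage", {
  scn <- random_micro_scene(61, nr = 12, nc = 12)
  src <- random_sources(scn$merged, 4)
  few <- fac_at(src[1:2, 1], src[1:2, 2], grid = scn$merged$grid)
  all4 <- fac_at(src[, 1], src[, 2], grid = scn$merged$grid)
  set.seed(3)
  pop <- grid_raster(matrix(runif(144) * 5, 12, 12), cell_size = 100)
  zones <- grid_raster(matrix(rep(1:2, each = 72), 12, 12), cell_size = 100)
  c_few <- zonal_coverage(accumulate_cost(scn$merged, scn$dem,
                                          uniform_walk(4), few),
                          pop, zones, 60)
  c_all <- zonal_coverage(accumulate_cost(scn$merged, scn$dem,
                                          uniform_walk(4), all4),
                          pop, zones, 60)
  expect_true(all(c_all$per_zone$pct_covered >=
                    c_few$per_zone$pct_covered - 1e-9))
})

test_that("combined HP+HC coverage dominates HC-only coverage", {
  sc <- generate_scene(scene_config(seed = 29, n_rows = 40, n_cols = 40,
                                    n_settlements = 10, n_hc = 2, n_hp = 10))
  m <- build_merged_landcover(sc$landcover, sc$roads, sc$rivers, sc$lakes,
                              sc$grid)
  fac <- snap_facilities(sc$facilities, m)
  scn <- default_scenarios()$walking_only
  cov_all <- zonal_coverage(accumulate_cost(m, sc$dem, scn, fac),
                            sc$population, sc$districts, c(60, 120))
  cov_hc <- zonal_coverage(accumulate_cost(m, sc$dem, scn,
                                           fac[fac$type == "HC", ]),
                           sc$population, sc$districts, c(60, 120))
  expect_true(all(cov_all$overall$pct_covered >=
                    cov_hc$overall$pct_covered - 1e-9))
})

test_that("catchment-size bands are closed-left, open-right and exhaustive", {
  expect_equal(as.character(classify_catchment_size(17500)), "[15000,25000)")
  expect_equal(as.character(classify_catchment_size(0)), "[0,2000)")
  expect_equal(as.character(classify_catchment_size(5000)), "[5000,15000)")
  expect_equal(as.character(classify_catchment_size(25000)), "[25000,Inf)")
  expect_error(classify_catchment_size(1, breaks = c(0, 5, 5)), "increasing")
  h <- catchment_size_histogram(c(100, 3000, 17000, 40000))
  expect_equal(sum(h$n), 4)
  expect_equal(sum(h$pct), 100)
})
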