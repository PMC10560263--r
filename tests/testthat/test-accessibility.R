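test_that("the normalized slope factor matches its closed form", {
  expect_identical(slope_factor(0), 1)
  expect_equal(slope_factor(-0.05), exp(0.175))        # ~1.1912, the maximum
  expect_equal(slope_factor(0.10), exp(-0.35))         # ~0.7047
  expect_equal(slope_factor(c(-1, 0, 1), correction = "none"), rep(1, 3))
  # the maximum over a slope sweep is at -0.05
  s <- seq(-0.5, 0.5, by = 0.001)
  expect_equal(s[which.max(slope_factor(s))], -0.05)
  expect_true(all(slope_factor(s) > 0))
})

test_that("step costs follow the half-cell harmonic rule", {
  m <- make_merged(matrix(c(1L, 2L), 1, 2))
  dem <- flat_dem(m$classes$values)
  # both cells walk 5 km/h, flat, orthogonal, 100 m -> 1.2 min
  sc5 <- uniform_walk(5)
  expect_equal(edge_cost(c(1, 1), c(1, 2), m, dem, sc5), 1.2)
  # walk 5 km/h <-> walk 2 km/h: 60 * (0.05/5 + 0.05/2) = 2.1 min
  sc_mix <- travel_scenario("mix", data.frame(
    code = c(1L, 2L), label = c("bare", "shrubland"), mode = "walk",
    speed_kmh = c(5, 2), stringsAsFactors = FALSE))
  expect_equal(edge_cost(c(1, 1), c(1, 2), m, dem, sc_mix), 2.1)
  # a barrier endpoint has no edge
  mb <- make_merged(matrix(c(1L, 0L), 1, 2))
  expect_identical(edge_cost(c(1, 1), c(1, 2), mb, dem, sc5), Inf)
  # diagonal steps use the sqrt(2) planar distance
  m2 <- make_merged(matrix(1L, 2, 2))
  expect_equal(edge_cost(c(1, 1), c(2, 2), m2, flat_dem(matrix(1, 2, 2)), sc5),
               1.2 * sqrt(2))
})

test_that("accumulated times on a 1 x 3 uniform corridor are 0, 1.2, 2.4", {
  m <- make_merged(matrix(1L, 1, 3))
  cs <- accumulate_cost(m, flat_dem(m$classes$values), uniform_walk(5),
                        fac_at(1, 1, grid = m$grid))
  expect_equal(as.numeric(cs$travel_time$values), c(0, 1.2, 2.4))
  expect_true(all(cs$allocation$values == 1))
})

test_that("an unbridged river severs the grid; one bridge restores it", {
  codes <- matrix(1L, 5, 5)
  codes[, 3] <- 0L                         # river column: full barrier
  m <- make_merged(codes)
  dem <- flat_dem(codes)
  src <- fac_at(3, 1, grid = m$grid)
  cs <- accumulate_cost(m, dem, uniform_walk(5), src)
  expect_true(all(is.infinite(cs$travel_time$values[, 4:5])))
  expect_true(all(is.finite(cs$travel_time$values[, 1:2])))
  # open one bridge cell
  codes2 <- codes; codes2[3, 3] <- 12L
  m2 <- make_merged(codes2)
  cs2 <- accumulate_cost(m2, dem, uniform_walk(5), src)
  expect_true(all(is.finite(cs2$travel_time$values[, 4:5])))
  # every eastern cell's least-cost path passes the bridge: its time is at
  # least the time to the bridge cell
  t_bridge <- cs2$travel_time$values[3, 3]
  expect_true(all(cs2$travel_time$values[, 4:5] > t_bridge))
})

test_that("facility cells are zero, times non-negative, allocation ties low", {
  scn <- random_micro_scene(101, nr = 12, nc = 12)
  src <- random_sources(scn$merged, 3)
  cs <- accumulate_cost(scn$merged, scn$dem, uniform_walk(4),
                        fac_at(src[, 1], src[, 2], grid = scn$merged$grid))
  expect_true(all(cs$travel_time$values[src] == 0))
  expect_true(all(cs$travel_time$values >= 0))
  al <- cs$allocation$values
  tt <- cs$travel_time$values
  expect_true(all(is.na(al) == !is.finite(tt)))
  # two co-located sources: the lower index wins the tie everywhere
  src2 <- rbind(src[1, ], src[1, ])
  cs2 <- accumulate_cost(scn$merged, scn$dem, uniform_walk(4),
                         fac_at(src2[, 1], src2[, 2], grid = scn$merged$grid))
  expect_true(all(cs2$allocation$values[!is.na(cs2$allocation$values)] == 1))
})

test_that("accumulated times equal the independent oracle on random scenes", {
  for (seed in 1:10) {
    scn <- random_micro_scene(seed)
    for (sc in list(uniform_walk(5),
                    default_scenarios("tobler_normalized")$motorized_walking)) {
      src <- random_sources(scn$merged, sample(1:3, 1))
      got <- accumulate_cost(scn$merged, scn$dem, sc,
                             fac_at(src[, 1], src[, 2],
                                    grid = scn$merged$grid))$travel_time$values
      want <- oracle_times(scn$merged, scn$dem, sc, src)
      fin <- is.finite(want)
      expect_identical(is.finite(got), fin)
      expect_lt(max(abs(got[fin] - want[fin]) / pmax(want[fin], 1e-12)), 1e-9)
    }
  }
})

test_that("with slope correction off the travel metric is symmetric", {
  scn <- random_micro_scene(77, nr = 10, nc = 10)
  pass <- which(!is.na(scn$merged$classes$values) &
                  scn$merged$classes$values != 0, arr.ind = TRUE)
  a <- pass[1, , drop = FALSE]; b <- pass[nrow(pass), , drop = FALSE]
  sc <- uniform_walk(4, slope_correction = "none")
  t_ab <- accumulate_cost(scn$merged, scn$dem, sc,
                          fac_at(b[, 1], b[, 2], grid = scn$merged$grid)
                          )$travel_time$values[a]
  t_ba <- accumulate_cost(scn$merged, scn$dem, sc,
                          fac_at(a[, 1], a[, 2], grid = scn$merged$grid)
                          )$travel_time$values[b]
  expect_equal(t_ab, t_ba)
})

test_that("a flat DEM makes slope correction a no-op, exactly", {
  scn <- random_micro_scene(55, nr = 10, nc = 10)
  dem <- flat_dem(scn$merged$classes$values)
  src <- random_sources(scn$merged, 2)
  st <- fac_at(src[, 1], src[, 2], grid = scn$merged$grid)
  on_ <- accumulate_cost(scn$merged, dem, uniform_walk(5, "tobler_normalized"),
                         st)$travel_time$values
  off <- accumulate_cost(scn$merged, dem, uniform_walk(5, "none"),
                         st)$travel_time$values
  expect_identical(on_, off)
})

test_that("travel time is monotone in speeds and in the facility set", {
  scn <- random_micro_scene(31, nr = 12, nc = 12)
  src <- random_sources(scn$merged, 2)
  st <- fac_at(src[, 1], src[, 2], grid = scn$merged$grid)
  slow <- accumulate_cost(scn$merged, scn$dem, uniform_walk(3), st)
  fast <- accumulate_cost(scn$merged, scn$dem, uniform_walk(6), st)
  fin <- is.finite(slow$travel_time$values)
  expect_true(all(fast$travel_time$values[fin] <=
                    slow$travel_time$values[fin] + 1e-12))
  # adding a facility never increases any cell's time
  more <- random_sources(scn$merged, 4)
  both <- rbind(src, more)
  t_few <- accumulate_cost(scn$merged, scn$dem, uniform_walk(3), st)
  t_more <- accumulate_cost(scn$merged, scn$dem, uniform_walk(3),
                            fac_at(both[, 1], both[, 2],
                                   grid = scn$merged$grid))
  expect_true(all(t_more$travel_time$values <=
                    t_few$travel_time$values + 1e-12))
})

test_that("triangle inequality holds on sampled cell triples", {
  scn <- random_micro_scene(13, nr = 8, nc = 8, barrier_frac = 0)
  sc <- uniform_walk(4, slope_correction = "none")
  pass <- which(scn$merged$classes$values != 0, arr.ind = TRUE)
  set.seed(99)
  for (k in 1:5) {
    abc <- pass[sample(nrow(pass), 3), , drop = FALSE]
    d <- function(i, j)
      accumulate_cost(scn$merged, scn$dem, sc,
                      fac_at(abc[j, 1], abc[j, 2], grid = scn$merged$grid)
                      )$travel_time$values[abc[i, , drop = FALSE]]
    expect_lte(d(1, 3), d(1, 2) + d(2, 3) + 1e-9)
  }
})

test_that("scenario comparison uses infinity-aware differencing", {
  codes <- matrix(1L, 3, 3); codes[, 2] <- 0L
  m <- make_merged(codes)
  dem <- flat_dem(codes)
  src <- fac_at(2, 1, grid = m$grid)
  a <- accumulate_cost(m, dem, uniform_walk(3), src)
  expect_true(all(compare_scenarios(a, a)$values[is.finite(a$travel_time$values)] == 0))
  # east side unreachable in both -> nodata; unreachable minus finite -> Inf
  d <- compare_scenarios(a, a)
  expect_true(all(is.na(d$values[, 3])))
  b <- accumulate_cost(m, dem, uniform_walk(6), src)
  d2 <- compare_scenarios(a, b)
  expect_true(all(d2$values[is.finite(d2$values)] >= 0))
})

test_that("walking-only is never faster than motorized+walking", {
  sc <- generate_scene(scene_config(seed = 17, n_rows = 40, n_cols = 40,
                                    n_settlements = 8, n_hc = 2, n_hp = 8))
  m <- build_merged_landcover(sc$landcover, sc$roads, sc$rivers, sc$lakes,
                              sc$grid)
  fac <- snap_facilities(sc$facilities, m)
  scns <- default_scenarios()
  walk <- accumulate_cost(m, sc$dem, scns$walking_only, fac)
  motor <- accumulate_cost(m, sc$dem, scns$motorized_walking, fac)
  d <- compare_scenarios(walk, motor)$values
  expect_true(all(d[is.finite(d)] >= -1e-9))
})

test_that("scenario YAML round trips and rejects invalid tables", {
  scn <- default_scenarios()$motorized_walking
  p <- file.path(withr::local_tempdir(), "scn.yaml")
  write_scenario(scn, p)
  back <- read_scenario(p)
  expect_equal(back$classes, scn$classes)
  expect_identical(back$slope_correction, scn$slope_correction)
  bad <- scn$classes; bad$speed_kmh[1] <- -1
  expect_error(travel_scenario("bad", bad), "positive")
  bad2 <- scn$classes; bad2$code[1] <- 0L
  expect_error(travel_scenario("bad", bad2), "barrier")
})
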