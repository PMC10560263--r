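toy_hc_table <- function() {
  cadres <- default_cadres()
  nm <- default_benchmark()$national_min
  base <- data.frame(facility_id = sprintf("HC%02d", 1:4), type = "HC",
                     x = 1:4 * 100, y = 1:4 * 100, stringsAsFactors = FALSE)
  for (cd in cadres) base[[cd]] <- unlist(nm[cd])
  base$hew_count <- 0
  # HC01 exactly at minimums; HC02 one nurse short; HC03 short in nurse,
  # midwife and pharmacist; HC04 overstaffed in everything
  base$nurse[2] <- base$nurse[2] - 1
  base$nurse[3] <- 0; base$midwife[3] <- 0; base$pharmacist[3] <- 0
  for (cd in cadres) base[[cd]][4] <- base[[cd]][4] + 2
  base
}

test_that("per-cadre staffing statuses and deficits are scored correctly", {
  fac <- toy_hc_table()
  bm <- default_benchmark()
  sc <- score_hc_staffing(fac, bm)
  pc <- sc$per_cadre
  # exact minimum is adequate, not understaffed
  expect_true(all(pc$status[pc$hc_id == "HC01"] == "adequate"))
  expect_true(sc$per_hc$fully_adequate[sc$per_hc$hc_id == "HC01"])
  # one nurse short: understaffed with deficit 1
  n2 <- pc[pc$hc_id == "HC02" & pc$cadre == "nurse", ]
  expect_equal(n2$status, "understaffed")
  expect_equal(n2$deficit, bm$national_min$nurse - (bm$national_min$nurse - 1))
  # hand recount: share of HCs understaffed in >= 2 cadres is 1 of 4
  expect_equal(mean(sc$per_hc$n_understaffed_cadres >= 2), 0.25)
  # overstaffing never counts as a deficit
  expect_true(all(pc$deficit[pc$hc_id == "HC04"] == 0))
  expect_true(all(pc$status[pc$hc_id == "HC04"] == "overstaffed"))
})

test_that("unknown cadre columns are refused; missing ones impute zero", {
  fac <- toy_hc_table()
  fac$phlebotomist <- 1
  expect_error(score_hc_staffing(fac, default_benchmark()), "phlebotomist")
  fac2 <- toy_hc_table()
  fac2$anesthetist <- NULL
  expect_warning(sc <- score_hc_staffing(fac2, default_benchmark()),
                 "treated as 0")
  expect_true(all(sc$per_cadre$count[sc$per_cadre$cadre == "anesthetist"] == 0))
})

fake_coverage <- function(covered60, covered120, total = 1e5,
                          zones = data.frame(district_id = 1:2,
                                             w = c(0.5, 0.5))) {
  per_zone <- do.call(rbind, lapply(c(60, 120), function(tau) {
    cov <- if (tau == 60) covered60 else covered120
    data.frame(district_id = zones$district_id, threshold_min = tau,
               pop_total = total * zones$w, pop_covered = cov * zones$w,
               pop_uncovered = (total - cov) * zones$w,
               pct_covered = 100 * cov / total)
  }))
  overall <- data.frame(threshold_min = c(60, 120), pop_total = total,
                        pop_covered = c(covered60, covered120),
                        pop_uncovered = total - c(covered60, covered120),
                        pct_covered = 100 * c(covered60, covered120) / total)
  structure(list(scenario_name = "walking_only", facility_ids = "HC01",
                 thresholds = c(60, 120), per_zone = per_zone,
                 overall = overall), class = "coverage_report")
}

test_that("group densities and additional needs follow the ceiling formula", {
  # 5 nurses, 25,000 catchment population, requirement 10 per 10,000:
  # density 2.0 and 25 - 5 = 20 additional workers
  fac <- data.frame(facility_id = "HC01", type = "HC", x = 0, y = 0,
                    nurse = 5, stringsAsFactors = FALSE)
  bm <- staffing_benchmark(national_min = list(nurse = 5),
                           who_density = list(nursing = 10),
                           cadre_map = list(nurse = "nursing"))
  cov <- fake_coverage(covered60 = 25000, covered120 = 50000)
  gd <- group_density(fac, cov, bm)
  g60 <- gd$per_group[gd$per_group$threshold_min == 60, ]
  expect_equal(g60$density_per_10k, 2.0)
  expect_equal(g60$additional_needed, 20)
  # ceiling: 25,010 people need ceil(25.01) = 26 - 5 = 21
  gd2 <- group_density(fac, fake_coverage(25010, 50000), bm)
  expect_equal(gd2$per_group$additional_needed[
    gd2$per_group$threshold_min == 60], 21)
  # already above the benchmark: floored at zero
  fac$nurse <- 500
  gd3 <- group_density(fac, cov, bm)
  expect_true(all(gd3$per_group$additional_needed == 0))
})

test_that("density halves when the catchment doubles, and doubles with staff", {
  fac <- data.frame(facility_id = "HC01", type = "HC", x = 0, y = 0,
                    nurse = 8, stringsAsFactors = FALSE)
  bm <- staffing_benchmark(list(nurse = 5), list(nursing = 10),
                           list(nurse = "nursing"))
  gd <- group_density(fac, fake_coverage(20000, 40000), bm)
  d60 <- gd$per_group$density_per_10k[gd$per_group$threshold_min == 60]
  d120 <- gd$per_group$density_per_10k[gd$per_group$threshold_min == 120]
  expect_equal(d60, 2 * d120)          # same workers, twice the population
  fac2 <- fac; fac2$nurse <- 16
  gd2 <- group_density(fac2, fake_coverage(20000, 40000), bm)
  expect_equal(gd2$per_group$density_per_10k,
               2 * gd$per_group$density_per_10k)
})

test_that("reclassification loses and double-counts no worker", {
  fac <- toy_hc_table()
  bm <- default_benchmark()
  cov <- fake_coverage(30000, 60000)
  gd <- group_density(fac, cov, bm)
  raw_total <- sum(sapply(default_cadres(), function(cd) sum(fac[[cd]])))
  per_thr <- aggregate(workers ~ threshold_min, gd$per_group, sum)
  expect_true(all(per_thr$workers == raw_total))
})

test_that("HEW shortage and surplus are never netted", {
  m <- make_merged(matrix(1L, 6, 6))
  zones <- grid_raster(matrix(rep(1:2, each = 18), 6, 6), cell_size = 100)
  hp <- fac_at(rep(2, 4), 1:4, type = "HP", grid = m$grid)
  hp$hew_count <- c(0, 1, 2, 3)
  hp$type <- "HP"
  cov <- fake_coverage(30000, 60000)
  bm <- default_benchmark()
  # all four HPs sit in zone 1 (cols 1-3) or 2 (col 4): shortage/surplus per
  # district, then totals as sums of district values
  gap <- hew_gap(hp, cov, bm, zones)
  expect_equal(gap$total_shortage, 3)   # 2 + 1 + 0 + 0
  expect_equal(gap$total_surplus, 1)    # 0 + 0 + 0 + 1
  expect_equal(gap$share_hp_meeting_norm, 0.5)
  # all HPs exactly at the norm
  hp2 <- hp; hp2$hew_count <- 2
  gap2 <- hew_gap(hp2, cov, bm, zones)
  expect_equal(gap2$total_shortage, 0)
  expect_equal(gap2$total_surplus, 0)
  # an HP outside every district is an error
  zones_na <- zones; zones_na$values[2, 1] <- NA
  expect_error(hew_gap(hp, cov, bm, zones_na), "outside all districts")
})

test_that("benchmark YAML round trips and validates its maps", {
  bm <- default_benchmark()
  p <- file.path(withr::local_tempdir(), "bm.yaml")
  write_benchmark(bm, p)
  back <- read_benchmark(p)
  expect_equal(back$national_min, bm$national_min)
  expect_equal(back$who_density, bm$who_density)
  expect_equal(back$hew_per_hp, bm$hew_per_hp)
  expect_error(staffing_benchmark(list(nurse = 5), list(nursing = 10),
                                  list()), "cadre_map")
  expect_error(staffing_benchmark(list(nurse = 5), list(),
                                  list(nurse = "nursing")), "who_density")
  expect_error(staffing_benchmark(list(nurse = -1), list(nursing = 10),
                                  list(nurse = "nursing")), ">= 0")
})
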