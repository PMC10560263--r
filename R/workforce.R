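#' Staffing benchmarks
#'
#' Bundles the reference tables the workforce analysis compares against:
#' `national_min` (minimum headcount per cadre that every health center
#' should have), `who_density` (required workers per 10,000 catchment
#' population, per cadre group), `cadre_map` (reclassification from cadres
#' to the groups the density benchmarks are defined on), and `hew_per_hp`
#' (health extension workers required per health post, default 2).
#'
#' The numeric defaults returned by `default_benchmark()` are editable
#' placeholders chosen to be plausible for a rural primary-care system;
#' they are configuration, not authoritative planning figures, and real
#' analyses should load their own tables via [read_benchmark()].
#'
#' @param national_min named list/vector: cadre -> minimum count per HC.
#' @param who_density named list/vector: cadre group -> required workers
#'   per 10,000 population.
#' @param cadre_map named list/vector: cadre -> cadre group.
#' @param hew_per_hp required HEWs per health post.
#' @return an object of class `staffing_benchmark`.
#' @export
staffing_benchmark <- function(national_min, who_density, cadre_map,
                               hew_per_hp = 2) {
  national_min <- as.list(national_min)
  who_density <- as.list(who_density)
  cadre_map <- as.list(cadre_map)
  if (any(unlist(national_min) < 0) || any(unlist(who_density) < 0) ||
      hew_per_hp < 0)
    stop("benchmark values must be >= 0")
  missing_map <- setdiff(names(national_min), names(cadre_map))
  if (length(missing_map))
    stop("cadres missing from cadre_map: ", paste(missing_map, collapse = ", "))
  bad_group <- setdiff(unlist(cadre_map), names(who_density))
  if (length(bad_group))
    stop("cadre groups missing from who_density: ",
         paste(bad_group, collapse = ", "))
  structure(list(national_min = national_min, who_density = who_density,
                 cadre_map = cadre_map, hew_per_hp = hew_per_hp),
            class = "staffing_benchmark")
}

#' @rdname staffing_benchmark
#' @export
default_benchmark <- function() {
  national_min <- list(
    health_officer = 1, nurse = 5, midwife = 2, pharmacist = 1,
    druggist = 1, lab_technologist = 1, lab_technician = 2,
    environmental_health = 1, health_informatics = 1,
    emergency_officer = 1, anesthetist = 1)
  cadre_map <- list(
    health_officer = "medical_assistants",
    emergency_officer = "medical_assistants",
    anesthetist = "medical_assistants",
    nurse = "nursing_midwifery", midwife = "nursing_midwifery",
    pharmacist = "pharmaceutical", druggist = "pharmaceutical",
    lab_technologist = "laboratory", lab_technician = "laboratory",
    environmental_health = "other", health_informatics = "other")
  who_density <- list(medical_assistants = 7, nursing_midwifery = 27,
                      pharmaceutical = 4, laboratory = 4, other = 3)
  staffing_benchmark(national_min, who_density, cadre_map, hew_per_hp = 2)
}

#' Read / write a staffing benchmark as YAML
#'
#' @param path YAML file.
#' @param benchmark a `staffing_benchmark`.
#' @return `read_benchmark` returns a `staffing_benchmark`.
#' @export
read_benchmark <- function(path) {
  y <- yaml::read_yaml(path)
  staffing_benchmark(y$national_min, y$who_density, y$cadre_map,
                     hew_per_hp = y$hew_per_hp %||% 2)
}

#' @rdname read_benchmark
#' @export
write_benchmark <- function(benchmark, path) {
  yaml::write_yaml(unclass(benchmark), path)
  invisible(path)
}

#' Staffing sufficiency of every health center
#'
#' Compares each HC's per-cadre headcount to the national minimum:
#' below the minimum is `understaffed` (with `deficit = min - count`),
#' equal is `adequate`, above is `overstaffed`. A cadre column missing
#' from the table counts as zero staff (a warning reports how many values
#' were imputed). A facility is fully adequate only when no cadre is
#' understaffed.
#'
#' @param facilities facility table (HC rows are scored).
#' @param benchmark a `staffing_benchmark`.
#' @return list with `per_cadre` (long data.frame), `per_hc` (one row per
#'   HC with `n_understaffed_cadres`, `fully_adequate`), and
#'   `n_missing_imputed`.
#' @export
score_hc_staffing <- function(facilities, benchmark) {
  hc <- facilities[facilities$type == "HC", , drop = FALSE]
  if (nrow(hc) == 0L) stop("no health centers in the facility table")
  cadres <- names(benchmark$national_min)
  meta_cols <- c("facility_id", "type", "x", "y", "cell_row", "cell_col",
                 "snapped", "snap_distance_m", "hew_count")
  staffing_cols <- setdiff(colnames(hc), meta_cols)
  extra <- setdiff(staffing_cols, cadres)
  if (length(extra))
    stop("cadres missing from the benchmark: ", paste(extra, collapse = ", "))
  n_missing <- 0L
  per_cadre <- do.call(rbind, lapply(cadres, function(cd) {
    cnt <- if (cd %in% colnames(hc)) hc[[cd]] else {
      n_missing <<- n_missing + nrow(hc)
      rep(0, nrow(hc))
    }
    cnt[is.na(cnt)] <- 0
    m <- benchmark$national_min[[cd]]
    data.frame(hc_id = hc$facility_id, cadre = cd, count = cnt, min = m,
               status = ifelse(cnt < m, "understaffed",
                               ifelse(cnt == m, "adequate", "overstaffed")),
               deficit = pmax(0, m - cnt), stringsAsFactors = FALSE)
  }))
  if (n_missing > 0L)
    warning(sprintf("%d missing staffing values treated as 0", n_missing))
  per_hc <- do.call(rbind, lapply(split(per_cadre, per_cadre$hc_id), function(d)
    data.frame(hc_id = d$hc_id[1],
               n_understaffed_cadres = sum(d$status == "understaffed"),
               total_deficit = sum(d$deficit),
               fully_adequate = !any(d$status == "understaffed"),
               stringsAsFactors = FALSE)))
  rownames(per_hc) <- NULL
  list(per_cadre = per_cadre, per_hc = per_hc, n_missing_imputed = n_missing)
}

#' Workforce density in travel-time catchments vs required density
#'
#' Pools each cadre group's workers over all HCs, relates them to the
#' population within the travel-time threshold of any HC (the union
#' catchment: the overall covered population, never double-counted), and
#' compares the resulting density per 10,000 population to the required
#' benchmark. The additional need is
#' `max(0, ceiling(required_density * pop / 10000) - workers)` -- rounded
#' up, since fractional workers cannot be hired, and floored at zero.
#' A per-district apportionment splits the additional need proportionally
#' to each district's share of the covered population.
#'
#' @param facilities facility table (HC staffing pooled).
#' @param coverage a [zonal_coverage()] report for the HC facility set.
#' @param benchmark a `staffing_benchmark`.
#' @param thresholds minutes; must be present in the coverage report.
#' @return list with `per_group` (data.frame: group, threshold, workers,
#'   catchment_pop, density_per_10k, required_per_10k, additional_needed)
#'   and `per_zone` (district apportionment of `additional_needed`).
#' @export
group_density <- function(facilities, coverage, benchmark,
                          thresholds = c(60, 120)) {
  if (!all(thresholds %in% coverage$thresholds))
    stop("coverage report lacks the requested thresholds")
  hc <- facilities[facilities$type == "HC", , drop = FALSE]
  groups <- unique(unlist(benchmark$cadre_map))
  workers_by_group <- vapply(groups, function(g) {
    cds <- names(benchmark$cadre_map)[unlist(benchmark$cadre_map) == g]
    sum(vapply(cds, function(cd)
      if (cd %in% colnames(hc)) sum(hc[[cd]], na.rm = TRUE) else 0,
      numeric(1)))
  }, numeric(1))

  per_group <- do.call(rbind, lapply(thresholds, function(tau) {
    pop <- coverage$overall$pop_covered[coverage$overall$threshold_min == tau]
    do.call(rbind, lapply(groups, function(g) {
      w <- workers_by_group[[g]]
      req <- benchmark$who_density[[g]]
      dens <- if (pop > 0) w / pop * 1e4 else NA_real_
      need <- if (pop > 0) max(0, ceiling(req * pop / 1e4) - w) else 0
      data.frame(group = g, threshold_min = tau, workers = w,
                 catchment_pop = pop, density_per_10k = dens,
                 required_per_10k = req, additional_needed = need,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(per_group) <- NULL

  per_zone <- do.call(rbind, lapply(thresholds, function(tau) {
    pz <- coverage$per_zone[coverage$per_zone$threshold_min == tau, ]
    tot_cov <- sum(pz$pop_covered)
    do.call(rbind, lapply(groups, function(g) {
      need <- per_group$additional_needed[per_group$group == g &
                                            per_group$threshold_min == tau]
      share <- if (tot_cov > 0) pz$pop_covered / tot_cov else
        rep(0, nrow(pz))
      data.frame(district_id = pz$district_id, group = g,
                 threshold_min = tau,
                 additional_needed_apportioned = need * share,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(per_zone) <- NULL
  list(per_group = per_group, per_zone = per_zone)
}

#' Health-extension-worker gaps per district
#'
#' Per district: the HEW shortage `sum(max(0, hew_per_hp - hew_count))`
#' and surplus `sum(max(0, hew_count - hew_per_hp))` over its health
#' posts. Shortage and surplus are reported separately and never netted
#' against each other (a surplus in one district cannot staff another).
#' Each district row carries the share of its population beyond the 2 h
#' threshold of the combined HP-and-HC network, and a filtered view keeps
#' the districts where less than half the population is within 2 h.
#'
#' @param facilities snapped facility table (HP rows used).
#' @param coverage a [zonal_coverage()] report for the combined HP+HC set
#'   including a 120-minute threshold.
#' @param benchmark a `staffing_benchmark` (for `hew_per_hp`).
#' @param districts district-id `grid_raster` (assigns each HP by its
#'   snapped cell).
#' @return list with `per_zone` (district_id, n_hp, hew_present, required,
#'   shortage, surplus, pct_pop_beyond_2h), `low_coverage_zones` (the
#'   < 50 %-within-2 h subset), `total_shortage`, `total_surplus`,
#'   `share_hp_meeting_norm`.
#' @export
hew_gap <- function(facilities, coverage, benchmark, districts) {
  hp <- facilities[facilities$type == "HP", , drop = FALSE]
  if (nrow(hp) == 0L) stop("no health posts in the facility table")
  if (!120 %in% coverage$thresholds)
    stop("coverage report lacks the 120-minute threshold")
  zid <- districts$values[cbind(hp$cell_row, hp$cell_col)]
  if (anyNA(zid))
    stop("health post outside all districts: ",
         paste(hp$facility_id[is.na(zid)], collapse = ", "))
  need <- benchmark$hew_per_hp
  hew <- hp$hew_count
  hew[is.na(hew)] <- 0
  per_zone <- do.call(rbind, lapply(sort(unique(zid)), function(z) {
    sel <- zid == z
    data.frame(district_id = z, n_hp = sum(sel),
               hew_present = sum(hew[sel]),
               hew_required = need * sum(sel),
               shortage = sum(pmax(0, need - hew[sel])),
               surplus = sum(pmax(0, hew[sel] - need)),
               stringsAsFactors = FALSE)
  }))
  cov2h <- coverage$per_zone[coverage$per_zone$threshold_min == 120, ]
  per_zone$pct_pop_beyond_2h <-
    100 - cov2h$pct_covered[match(per_zone$district_id, cov2h$district_id)]
  low <- per_zone[!is.na(per_zone$pct_pop_beyond_2h) &
                    per_zone$pct_pop_beyond_2h > 50, , drop = FALSE]
  list(per_zone = per_zone,
       low_coverage_zones = low,
       total_shortage = sum(per_zone$shortage),
       total_surplus = sum(per_zone$surplus),
       share_hp_meeting_norm = mean(hew >= need))
}
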