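#' Population inside each facility's catchment
#'
#' A cell's population counts towards facility `f` when the cost-allocation
#' raster assigns the cell to `f` and (unless `threshold = "full"`) the
#' travel time does not exceed the threshold. Thresholded catchments are
#' therefore nested inside the full allocation catchment and never overlap
#' between facilities, so per-facility populations are additive. An
#' overlapping-isochrone mode (`overlap = TRUE`) drops the allocation
#' condition for sensitivity analysis; populations then need not be
#' additive.
#'
#' @param cost a `cost_surfaces`.
#' @param population population `grid_raster` (persons per cell) on the
#'   same grid.
#' @param threshold minutes, or `"full"` for the whole allocation region.
#' @return data.frame `facility_id`, `population`.
#' @export
facility_catchment_population <- function(cost, population, threshold = "full") {
  stop_grid_mismatch(cost$travel_time, population)
  tt <- cost$travel_time$values
  al <- cost$allocation$values
  pop <- population$values
  pop[is.na(pop)] <- 0
  n_fac <- length(cost$facility_ids)
  full <- identical(threshold, "full")
  within <- if (full) is.finite(tt) else is.finite(tt) & tt <= threshold
  out <- numeric(n_fac)
  sel <- within & !is.na(al)
  if (any(sel))
    out <- vapply(seq_len(n_fac), function(f) sum(pop[sel & al == f]),
                  numeric(1))
  data.frame(facility_id = cost$facility_ids, population = out,
             stringsAsFactors = FALSE)
}

#' Overlapping per-facility isochrone populations
#'
#' Sensitivity-analysis alternative to the allocation-based catchments: one
#' cost surface per facility, and every cell within the threshold counts
#' for every facility that reaches it. The resulting populations can
#' double-count and are not additive.
#'
#' @param merged,dem,scenario,facilities as in [accumulate_cost()].
#' @param population population `grid_raster`.
#' @param threshold minutes.
#' @return data.frame `facility_id`, `population`.
#' @export
facility_isochrone_population <- function(merged, dem, scenario, facilities,
                                          population, threshold) {
  pops <- vapply(seq_len(nrow(facilities)), function(i) {
    cs <- accumulate_cost(merged, dem, scenario, facilities[i, , drop = FALSE])
    tt <- cs$travel_time$values
    p <- population$values; p[is.na(p)] <- 0
    sum(p[is.finite(tt) & tt <= threshold])
  }, numeric(1))
  data.frame(facility_id = facilities$facility_id, population = pops,
             stringsAsFactors = FALSE)
}

#' Zonal and overall population coverage
#'
#' For each district (zone) and for the scene overall: the total
#' population, the population within each travel-time threshold of the
#' facility set, and the percentage covered. Population on unreachable
#' cells (including barriers) is uncovered at every threshold. Also emits,
#' per threshold, the uncovered-population raster (population masked to
#' cells beyond the threshold) for mapping.
#'
#' @param cost a `cost_surfaces`.
#' @param population population `grid_raster`.
#' @param zones district-id `grid_raster` (every populated cell must have a
#'   zone id).
#' @param thresholds minutes, default `c(60, 120)`.
#' @return an object of class `coverage_report` with `per_facility`
#'   (thresholds and full), `per_zone`, `overall`, `uncovered` (list of
#'   grid_rasters by threshold), `thresholds`, `scenario_name`,
#'   `facility_ids`.
#' @export
zonal_coverage <- function(cost, population, zones, thresholds = c(60, 120)) {
  stop_grid_mismatch(cost$travel_time, population)
  stop_grid_mismatch(cost$travel_time, zones)
  tt <- cost$travel_time$values
  pop <- population$values
  pop[is.na(pop)] <- 0
  z <- zones$values
  bad <- pop > 0 & is.na(z)
  if (any(bad))
    stop(sprintf("%d populated cells have no zone id (first at row %d, col %d)",
                 sum(bad), which(bad, arr.ind = TRUE)[1, 1],
                 which(bad, arr.ind = TRUE)[1, 2]))
  zid <- sort(unique(z[!is.na(z)]))

  per_zone <- do.call(rbind, lapply(zid, function(zi) {
    inz <- !is.na(z) & z == zi
    tot <- sum(pop[inz])
    do.call(rbind, lapply(thresholds, function(tau) {
      cov <- sum(pop[inz & is.finite(tt) & tt <= tau])
      data.frame(district_id = zi, threshold_min = tau, pop_total = tot,
                 pop_covered = cov, pop_uncovered = tot - cov,
                 pct_covered = if (tot > 0) 100 * cov / tot else NA_real_)
    }))
  }))
  tot_all <- sum(pop)
  overall <- do.call(rbind, lapply(thresholds, function(tau) {
    cov <- sum(pop[is.finite(tt) & tt <= tau])
    data.frame(threshold_min = tau, pop_total = tot_all, pop_covered = cov,
               pop_uncovered = tot_all - cov,
               pct_covered = if (tot_all > 0) 100 * cov / tot_all else NA_real_)
  }))

  per_fac <- lapply(c(as.list(thresholds), list("full")), function(tau)
    facility_catchment_population(cost, population, tau))
  names(per_fac) <- c(paste0("min", thresholds), "full")
  pf <- per_fac[["full"]][, "facility_id", drop = FALSE]
  for (nm in names(per_fac)) pf[[paste0("pop_", nm)]] <- per_fac[[nm]]$population

  g <- grid_of(population)
  uncovered <- lapply(thresholds, function(tau) {
    m <- pop
    m[is.finite(tt) & tt <= tau] <- 0
    m[is.na(population$values)] <- NA
    grid_raster(m, xmin = g$xmin, ymax = g$ymax, cell_size = g$cell_size,
                crs = g$crs)
  })
  names(uncovered) <- paste0("min", thresholds)

  structure(list(scenario_name = cost$scenario_name,
                 facility_ids = cost$facility_ids,
                 thresholds = thresholds,
                 per_facility = pf, per_zone = per_zone, overall = overall,
                 uncovered = uncovered),
            class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("<coverage_report> scenario %s, %d facilities\n",
              x$scenario_name, length(x$facility_ids)))
  ov <- x$overall
  for (i in seq_len(nrow(ov)))
    cat(sprintf("  within %g min: %.1f%% of %.0f persons covered\n",
                ov$threshold_min[i], ov$pct_covered[i], ov$pop_total[i]))
  invisible(x)
}

#' Catchment-size band of a population value
#'
#' Classifies catchment populations into planning bands. Bands are
#' closed-left/open-right intervals covering `[0, Inf)`; the defaults
#' include the 2,000-5,000 band typical of small rural catchments and the
#' 15,000-25,000 band that a health center is planned to serve.
#'
#' @param pop persons (vectorized).
#' @param breaks increasing band edges starting at 0 (an implicit `Inf`
#'   closes the last band).
#' @return factor of band labels like `"[15000,25000)"`.
#' @export
classify_catchment_size <- function(pop,
                                    breaks = c(0, 2000, 5000, 15000, 25000)) {
  if (is.unsorted(breaks, strictly = TRUE) || breaks[1] != 0)
    stop("breaks must be strictly increasing and start at 0")
  edges <- c(breaks, Inf)
  labs <- paste0("[", format(edges[-length(edges)], scientific = FALSE, trim = TRUE),
                 ",", format(edges[-1], scientific = FALSE, trim = TRUE), ")")
  cut(pop, breaks = edges, labels = labs, right = FALSE, include.lowest = TRUE)
}

#' Histogram of facilities over catchment-size bands
#'
#' @param pop per-facility catchment populations.
#' @param breaks see [classify_catchment_size()].
#' @return data.frame `band`, `n`, `pct`.
#' @export
catchment_size_histogram <- function(pop, breaks = c(0, 2000, 5000, 15000, 25000)) {
  b <- classify_catchment_size(pop, breaks)
  tab <- table(b)
  data.frame(band = names(tab), n = as.integer(tab),
             pct = 100 * as.integer(tab) / max(1L, length(pop)),
             stringsAsFactors = FALSE)
}
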