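#' HP-to-HC referral links
#'
#' For every health post, the nearest health center in travel time under a
#' walking-only scenario, travelling from the HP towards the HC and
#' allowing the nearest HC to lie in another district (`mode =
#' "cross_district"`, the default). The referral time is the HC-set
#' accumulated travel-time surface evaluated at the HP cell; the travelled
#' distance is the sum of planar step lengths (cell size, times sqrt(2)
#' diagonally) along the backtraced least-cost path. HPs that cannot reach
#' any HC get `Inf` time and an `NA` HC. With `mode = "within_district"`
#' each HP only considers HCs of its own district (the restructuring-
#' implementation scenario); `districts` is then required.
#'
#' @param facilities snapped facility table containing both HP and HC rows.
#' @param merged a `merged_landcover`.
#' @param dem elevation `grid_raster`.
#' @param scenario a walking-only `travel_scenario`.
#' @param mode `"cross_district"` or `"within_district"`.
#' @param districts district-id `grid_raster` (for `within_district`).
#' @param merge_km,comprehensive_km thresholds for [classify_ohep()].
#' @param distance_basis `"path"` (default) or `"straight"`: which distance
#'   the classification uses.
#' @return data.frame of class `referral_links`: `hp_id`, `hc_id`,
#'   `time_min`, `path_km`, `straight_km`, `reachable`, `classification`.
#' @export
build_referrals <- function(facilities, merged, dem, scenario,
                            mode = c("cross_district", "within_district"),
                            districts = NULL, merge_km = 2,
                            comprehensive_km = 10,
                            distance_basis = c("path", "straight")) {
  mode <- match.arg(mode)
  distance_basis <- match.arg(distance_basis)
  hp <- facilities[facilities$type == "HP", , drop = FALSE]
  hc <- facilities[facilities$type == "HC", , drop = FALSE]
  if (nrow(hc) == 0L) stop("no health centers to refer to")
  if (nrow(hp) == 0L) stop("no health posts")
  grid <- merged$grid
  if (mode == "within_district") {
    if (is.null(districts)) stop("within_district mode needs the district raster")
    hp_d <- districts$values[cbind(hp$cell_row, hp$cell_col)]
    hc_d <- districts$values[cbind(hc$cell_row, hc$cell_col)]
  }

  tg <- build_travel_graph(merged, dem, scenario)
  nc <- grid$n_cols
  hp_cell <- (hp$cell_row - 1L) * nc + hp$cell_col
  hc_cell <- (hc$cell_row - 1L) * nc + hc$cell_col

  # travel time from every cell to each HC (motion towards the facility)
  dmat <- igraph::distances(tg$graph, v = hc_cell, mode = "in")

  n <- nrow(hp)
  hc_id <- rep(NA_character_, n); time_min <- rep(Inf, n)
  path_km <- rep(NA_real_, n); straight_km <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    cand <- seq_len(nrow(hc))
    if (mode == "within_district") {
      cand <- cand[hc_d[cand] == hp_d[i]]
      if (!length(cand)) next
    }
    times <- dmat[cand, hp_cell[i]]
    j <- cand[which.min(times)]              # ties: lowest HC index
    t_ij <- dmat[j, hp_cell[i]]
    if (!is.finite(t_ij)) next
    hc_id[i] <- hc$facility_id[j]
    time_min[i] <- t_ij
    # backtrace the least-cost path HP -> HC and accumulate step lengths
    sp <- igraph::shortest_paths(tg$graph, from = hp_cell[i],
                                 to = hc_cell[j], mode = "out",
                                 output = "vpath")$vpath[[1]]
    vid <- as.integer(sp)
    pr <- (vid - 1L) %/% nc + 1L; pc <- (vid - 1L) %% nc + 1L
    steps <- pmax(abs(diff(pr)), abs(diff(pc)))        # 1 everywhere
    diag_step <- (abs(diff(pr)) + abs(diff(pc))) == 2L
    path_km[i] <- sum(ifelse(diag_step, sqrt(2), 1) * steps) *
      grid$cell_size / 1000
    a <- cell_to_world(grid, hp$cell_row[i], hp$cell_col[i])
    b <- cell_to_world(grid, hc$cell_row[j], hc$cell_col[j])
    straight_km[i] <- sqrt(sum((a - b)^2)) / 1000
  }
  reachable <- is.finite(time_min)
  dist_for_class <- if (distance_basis == "path") path_km else straight_km
  classification <- ifelse(reachable,
                           classify_ohep(dist_for_class, merge_km,
                                         comprehensive_km),
                           "comprehensive_candidate")
  out <- data.frame(hp_id = hp$facility_id, hc_id = hc_id,
                    time_min = time_min, path_km = path_km,
                    straight_km = straight_km, reachable = reachable,
                    classification = classification,
                    stringsAsFactors = FALSE)
  class(out) <- c("referral_links", class(out))
  out
}

#' Backtrace one least-cost path between two snapped facilities
#'
#' The cell-by-cell least-cost route from `from` to `to` under the
#' scenario, as travelled (edges evaluated in the direction of motion).
#'
#' @param merged,dem,scenario as in [accumulate_cost()].
#' @param from,to single-row snapped facility tables (or any rows with
#'   `cell_row`/`cell_col`).
#' @return two-column matrix of (row, col) cells from start to end; zero
#'   rows when unreachable.
#' @export
least_cost_path <- function(merged, dem, scenario, from, to) {
  tg <- build_travel_graph(merged, dem, scenario)
  nc <- merged$grid$n_cols
  a <- (from$cell_row[1] - 1L) * nc + from$cell_col[1]
  b <- (to$cell_row[1] - 1L) * nc + to$cell_col[1]
  sp <- suppressWarnings(
    igraph::shortest_paths(tg$graph, from = a, to = b, mode = "out",
                           output = "vpath")$vpath[[1]])
  vid <- as.integer(sp)
  if (!length(vid)) return(matrix(integer(0), ncol = 2,
                                  dimnames = list(NULL, c("row", "col"))))
  cbind(row = (vid - 1L) %/% nc + 1L, col = (vid - 1L) %% nc + 1L)
}

#' Classify a health post by distance to its nearest health center
#'
#' The restructuring rule for health posts: beyond `comprehensive_km`
#' (default 10 km) the HP is a candidate for upgrading to a comprehensive
#' HP; within `merge_km` (default 2 km) it is close enough to its HC to be
#' a merge candidate; otherwise it stays a basic HP. Bounds are closed on
#' the "within" side: exactly 10 km is within ten kilometers, hence basic.
#'
#' @param distance_km distance to the nearest HC (vectorized); by package
#'   default the along-path travelled distance.
#' @param merge_km,comprehensive_km thresholds in km; `merge_km <
#'   comprehensive_km` required.
#' @return character: `"merge_candidate"`, `"basic"` or
#'   `"comprehensive_candidate"`.
#' @export
classify_ohep <- function(distance_km, merge_km = 2, comprehensive_km = 10) {
  if (merge_km >= comprehensive_km)
    stop("merge_km must be smaller than comprehensive_km")
  ifelse(distance_km > comprehensive_km, "comprehensive_candidate",
         ifelse(distance_km <= merge_km, "merge_candidate", "basic"))
}

#' Summary statistics of a referral table
#'
#' Mean and maximum referral time and mean distance over reachable links,
#' the share of HPs beyond the comprehensive threshold, a per-distance-band
#' time table (min/max time per 1-km band), and the unreachable count
#' reported separately.
#'
#' @param links a [build_referrals()] table.
#' @param comprehensive_km km threshold for the "beyond" share.
#' @param band_width_km width of the distance bands.
#' @return list with `n_links`, `n_unreachable`, `mean_time_min`,
#'   `max_time_min`, `mean_path_km`, `share_beyond_comprehensive`,
#'   `bands` (data.frame).
#' @export
referral_summary <- function(links, comprehensive_km = 10, band_width_km = 1) {
  fin <- links[links$reachable, , drop = FALSE]
  if (nrow(fin) == 0L) stop("no reachable referral links to summarize")
  edges <- seq(0, ceiling(max(fin$path_km) / band_width_km) * band_width_km,
               by = band_width_km)
  if (length(edges) < 2L) edges <- c(0, band_width_km)
  band <- cut(fin$path_km, breaks = edges, right = FALSE,
              include.lowest = TRUE)
  bands <- do.call(rbind, lapply(levels(band), function(b) {
    sel <- band == b
    if (!any(sel)) return(NULL)
    data.frame(band_km = b, n = sum(sel),
               min_time_min = min(fin$time_min[sel]),
               max_time_min = max(fin$time_min[sel]),
               stringsAsFactors = FALSE)
  }))
  list(n_links = nrow(links),
       n_unreachable = sum(!links$reachable),
       mean_time_min = mean(fin$time_min),
       max_time_min = max(fin$time_min),
       mean_path_km = mean(fin$path_km),
       share_beyond_comprehensive = mean(fin$path_km > comprehensive_km),
       bands = bands)
}

#' Human-readable travel time
#'
#' @param minutes numeric minutes.
#' @return character like `"4h 45m"`.
#' @export
format_travel_time <- function(minutes) {
  tot <- round(minutes)
  ifelse(is.finite(minutes),
         sprintf("%.0fh %02.0fm", tot %/% 60, tot %% 60),
         "unreachable")
}
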