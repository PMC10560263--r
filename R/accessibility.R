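#' Travel scenarios
#'
#' A travel scenario maps every passable merged-landcover class to a travel
#' mode (`walk` or `motorized`) and a speed in km/h, and says whether
#' walking speed is corrected for slope. The barrier class never has an
#' entry: it is impassable. Speeds are configuration -- the defaults below
#' are plausible placeholders for an arid rural region, not authoritative
#' values, and are meant to be edited (see [read_scenario()]).
#'
#' `default_scenarios()` returns the two canonical scenarios: `walking_only`
#' (everything on foot) and `motorized_walking` (walk to the nearest road,
#' then a readily available vehicle; no transfer penalty by default).
#'
#' @param name scenario name.
#' @param classes data.frame with columns `code`, `label`, `mode`,
#'   `speed_kmh`.
#' @param slope_correction `"none"` or `"tobler_normalized"`.
#' @param transfer_penalty_min minutes added when a step changes mode.
#' @return an object of class `travel_scenario`.
#' @export
travel_scenario <- function(name, classes,
                            slope_correction = c("none", "tobler_normalized"),
                            transfer_penalty_min = 0) {
  slope_correction <- match.arg(slope_correction)
  stopifnot(is.data.frame(classes),
            all(c("code", "label", "mode", "speed_kmh") %in% names(classes)))
  if (any(classes$code == BARRIER_CODE))
    stop("the barrier class is impassable and may not appear in a scenario")
  if (any(!is.finite(classes$speed_kmh) | classes$speed_kmh <= 0))
    stop("speeds must be finite and positive")
  if (any(!classes$mode %in% c("walk", "motorized")))
    stop("mode must be 'walk' or 'motorized'")
  structure(list(name = name, classes = classes,
                 slope_correction = slope_correction,
                 transfer_penalty_min = transfer_penalty_min),
            class = "travel_scenario")
}

#' @rdname travel_scenario
#' @param slope_correction passed to both scenarios.
#' @export
default_scenarios <- function(slope_correction = "tobler_normalized") {
  base <- landcover_classes()
  base <- base[base$label != "water", ]
  walk_speed <- c(bare = 4, shrubland = 3, built = 5,
                  road_primary = 5, road_secondary = 5, road_tertiary = 4)
  motor_speed <- c(road_primary = 60, road_secondary = 40, road_tertiary = 25)
  walking <- data.frame(code = base$code, label = base$label,
                        mode = "walk",
                        speed_kmh = unname(walk_speed[base$label]),
                        stringsAsFactors = FALSE)
  motor <- walking
  is_road <- motor$label %in% names(motor_speed)
  motor$mode[is_road] <- "motorized"
  motor$speed_kmh[is_road] <- unname(motor_speed[motor$label[is_road]])
  list(
    walking_only = travel_scenario("walking_only", walking,
                                   slope_correction = slope_correction),
    motorized_walking = travel_scenario("motorized_walking", motor,
                                        slope_correction = slope_correction))
}

#' Read / write a travel scenario as YAML
#'
#' @param path YAML file.
#' @param scenario a `travel_scenario`.
#' @return `read_scenario` returns a `travel_scenario`.
#' @export
read_scenario <- function(path) {
  y <- yaml::read_yaml(path)
  cls <- do.call(rbind, lapply(y$classes, function(e)
    data.frame(code = as.integer(e$code), label = e$label, mode = e$mode,
               speed_kmh = as.numeric(e$speed_kmh), stringsAsFactors = FALSE)))
  travel_scenario(y$name, cls, slope_correction = y$slope_correction,
                  transfer_penalty_min = y$transfer_penalty_min %||% 0)
}

#' @rdname read_scenario
#' @export
write_scenario <- function(scenario, path) {
  y <- list(name = scenario$name,
            slope_correction = scenario$slope_correction,
            transfer_penalty_min = scenario$transfer_penalty_min,
            classes = lapply(seq_len(nrow(scenario$classes)), function(i)
              as.list(scenario$classes[i, ])))
  yaml::write_yaml(y, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Slope factor for walking speed
#'
#' Normalized Tobler hiking function: the factor multiplying the configured
#' flat-ground walking speed, `exp(-3.5 * |s + 0.05|) / exp(-3.5 * 0.05)`,
#' where `s` is the slope (rise/run) in the direction of motion (uphill
#' positive). Flat ground gives exactly 1; the maximum (about 1.19) sits at
#' the gentle downhill `s = -0.05`. With `correction = "none"` the factor
#' is identically 1. Applies to walking only; motorized speeds are not
#' slope-corrected.
#'
#' @param s slope, dimensionless rise/run (vectorized).
#' @param correction `"tobler_normalized"` or `"none"`.
#' @return multiplicative speed factor, always > 0.
#' @export
slope_factor <- function(s, correction = "tobler_normalized") {
  if (correction == "none") return(rep(1, length(s)))
  exp(-3.5 * abs(s + 0.05)) / exp(-3.5 * 0.05)
}

# speed lookup table indexed by merged class code
speed_table <- function(scenario, max_code = 32L) {
  sp <- rep(NA_real_, max_code + 1L)
  md <- rep(NA_character_, max_code + 1L)
  sp[scenario$classes$code + 1L] <- scenario$classes$speed_kmh
  md[scenario$classes$code + 1L] <- scenario$classes$mode
  list(speed = sp, mode = md)
}

#' Travel time of one step between adjacent cells
#'
#' The time to move from cell `a` to an 8-adjacent cell `b`: each cell
#' contributes half the step length at its own effective speed, i.e.
#' `cost = (d/2) * (1/v_a + 1/v_b)` minutes, with `d` the planar step
#' (cell size, times sqrt(2) diagonally) and `v_x` the class speed at `x`,
#' slope-adjusted by [slope_factor()] when the mode at `x` is `walk`. The
#' slope is `(elev_b - elev_a) / d`, signed along the direction of motion.
#' A barrier endpoint makes the step impossible (`Inf`).
#'
#' @param cell_a,cell_b `c(row, col)` of the two cells.
#' @param merged a `merged_landcover`.
#' @param dem elevation `grid_raster` (meters).
#' @param scenario a `travel_scenario`.
#' @return minutes (possibly `Inf`).
#' @export
edge_cost <- function(cell_a, cell_b, merged, dem, scenario) {
  dr <- abs(cell_a[1] - cell_b[1]); dc <- abs(cell_a[2] - cell_b[2])
  if (max(dr, dc) != 1L) stop("cells are not 8-adjacent")
  code_a <- merged$classes$values[cell_a[1], cell_a[2]]
  code_b <- merged$classes$values[cell_b[1], cell_b[2]]
  if (is.na(code_a) || is.na(code_b) ||
      code_a == BARRIER_CODE || code_b == BARRIER_CODE) return(Inf)
  st <- speed_table(scenario)
  d <- merged$grid$cell_size * if (dr + dc == 2L) sqrt(2) else 1
  s <- (dem$values[cell_b[1], cell_b[2]] - dem$values[cell_a[1], cell_a[2]]) / d
  f <- slope_factor(s, scenario$slope_correction)
  v_a <- st$speed[code_a + 1L] * if (st$mode[code_a + 1L] == "walk") f else 1
  v_b <- st$speed[code_b + 1L] * if (st$mode[code_b + 1L] == "walk") f else 1
  cost <- (d / 1000 / 2) * (1 / v_a + 1 / v_b) * 60
  if (scenario$transfer_penalty_min > 0 &&
      st$mode[code_a + 1L] != st$mode[code_b + 1L])
    cost <- cost + scenario$transfer_penalty_min
  cost
}

# Directed edge list over passable cells of the grid, with edge costs in
# minutes. Cells are numbered row-major: id = (row - 1) * n_cols + col.
# Edges point in the direction of motion.
build_edge_list <- function(merged, dem, scenario, neighbors = 8L) {
  grid <- merged$grid
  nr <- grid$n_rows; nc <- grid$n_cols; cs <- grid$cell_size
  code <- merged$classes$values
  elev <- dem$values
  pass <- !is.na(code) & code != BARRIER_CODE
  st <- speed_table(scenario, max_code = max(32L, max(code, na.rm = TRUE)))

  offs <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  if (neighbors == 4L) offs <- offs[1:2]

  from <- integer(0); to <- integer(0); w <- numeric(0)
  rows <- matrix(rep(seq_len(nr), nc), nr, nc)
  cols <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  id <- (rows - 1L) * nc + cols
  for (off in offs) {
    r0 <- seq_len(nr); c0 <- seq_len(nc)
    ra <- r0[r0 + off[1] >= 1L & r0 + off[1] <= nr]
    ca <- c0[c0 + off[2] >= 1L & c0 + off[2] <= nc]
    if (!length(ra) || !length(ca)) next
    A <- cbind(rep(ra, times = length(ca)), rep(ca, each = length(ra)))
    B <- cbind(A[, 1] + off[1], A[, 2] + off[2])
    ok <- pass[A] & pass[B]
    if (!any(ok)) next
    A <- A[ok, , drop = FALSE]; B <- B[ok, , drop = FALSE]
    d <- cs * if (abs(off[1]) + abs(off[2]) == 2L) sqrt(2) else 1
    s_ab <- (elev[B] - elev[A]) / d            # slope moving A -> B
    f_ab <- slope_factor(s_ab, scenario$slope_correction)
    f_ba <- slope_factor(-s_ab, scenario$slope_correction)
    ca_code <- code[A] + 1L; cb_code <- code[B] + 1L
    wa <- st$mode[ca_code] == "walk"; wb <- st$mode[cb_code] == "walk"
    v_a_ab <- st$speed[ca_code] * ifelse(wa, f_ab, 1)
    v_b_ab <- st$speed[cb_code] * ifelse(wb, f_ab, 1)
    v_a_ba <- st$speed[ca_code] * ifelse(wa, f_ba, 1)
    v_b_ba <- st$speed[cb_code] * ifelse(wb, f_ba, 1)
    w_ab <- (d / 1000 / 2) * (1 / v_a_ab + 1 / v_b_ab) * 60
    w_ba <- (d / 1000 / 2) * (1 / v_a_ba + 1 / v_b_ba) * 60
    if (scenario$transfer_penalty_min > 0) {
      pen <- (st$mode[ca_code] != st$mode[cb_code]) * scenario$transfer_penalty_min
      w_ab <- w_ab + pen; w_ba <- w_ba + pen
    }
    from <- c(from, id[A], id[B])
    to <- c(to, id[B], id[A])
    w <- c(w, w_ab, w_ba)
  }
  list(from = from, to = to, weight = w, n_cells = nr * nc, pass = pass)
}

build_travel_graph <- function(merged, dem, scenario, neighbors = 8L) {
  el <- build_edge_list(merged, dem, scenario, neighbors)
  g <- igraph::make_empty_graph(n = el$n_cells, directed = TRUE)
  g <- igraph::add_edges(g, rbind(el$from, el$to))
  igraph::E(g)$weight <- el$weight
  list(graph = g, pass = el$pass)
}

#' Accumulated travel-time and allocation surfaces
#'
#' Multi-source least-cost paths over the 8-connected (optionally
#' 4-connected) cell graph with [edge_cost()] step weights. For every cell
#' the minimum travel time to (or from) the nearest source facility is
#' accumulated, and the allocation raster records which facility attains
#' the minimum -- the cost-allocation ("full catchment") partition. Ties go
#' to the lowest facility index. Cells that cannot reach any source,
#' including barrier cells, get `Inf` travel time and `NA` allocation.
#'
#' @param merged a `merged_landcover`.
#' @param dem elevation `grid_raster`.
#' @param scenario a `travel_scenario`.
#' @param sources snapped facility table (rows used as sources, in order).
#' @param direction `"to_facility"` (population travels towards the
#'   facility; the default, and the direction referral analysis uses) or
#'   `"from_facility"`. The distinction only matters when slope correction
#'   is on.
#' @param neighbors 8 or 4.
#' @return an object of class `cost_surfaces`: `travel_time` (minutes,
#'   `grid_raster`), `allocation` (facility index, `grid_raster`),
#'   `facility_ids`, `scenario_name`, `direction`.
#' @export
accumulate_cost <- function(merged, dem, scenario, sources,
                            direction = c("to_facility", "from_facility"),
                            neighbors = 8L) {
  direction <- match.arg(direction)
  stop_grid_mismatch(merged$classes, dem)
  if (nrow(sources) == 0L) stop("empty source facility set")
  if (!all(c("cell_row", "cell_col") %in% names(sources)))
    stop("sources must be snapped first (snap_facilities)")
  grid <- merged$grid
  nr <- grid$n_rows; nc <- grid$n_cols
  tg <- build_travel_graph(merged, dem, scenario, neighbors)
  src_id <- (sources$cell_row - 1L) * nc + sources$cell_col
  if (!any(tg$pass[cbind(sources$cell_row, sources$cell_col)]))
    stop("all source facilities sit on barrier cells")
  mode <- if (direction == "to_facility") "in" else "out"
  dmat <- igraph::distances(tg$graph, v = src_id, mode = mode)
  # dmat: one row per facility, one column per cell
  tt <- apply(dmat, 2L, min)
  alloc <- apply(dmat, 2L, which.min)          # first minimum = lowest index
  alloc[!is.finite(tt)] <- NA_integer_
  tt_m <- matrix(Inf, nr, nc); al_m <- matrix(NA_real_, nr, nc)
  cell_rc <- cbind((seq_len(nr * nc) - 1L) %/% nc + 1L,
                   (seq_len(nr * nc) - 1L) %% nc + 1L)
  tt_m[cell_rc] <- tt
  al_m[cell_rc] <- alloc
  tt_m[!tg$pass] <- Inf; al_m[!tg$pass] <- NA_real_
  structure(list(
    scenario_name = scenario$name,
    direction = direction,
    facility_ids = sources$facility_id,
    travel_time = grid_raster(tt_m, xmin = grid$xmin, ymax = grid$ymax,
                              cell_size = grid$cell_size, crs = grid$crs),
    allocation = grid_raster(al_m, xmin = grid$xmin, ymax = grid$ymax,
                             cell_size = grid$cell_size, crs = grid$crs)),
    class = "cost_surfaces")
}

#' @export
print.cost_surfaces <- function(x, ...) {
  tt <- x$travel_time$values
  fin <- tt[is.finite(tt)]
  cat(sprintf("<cost_surfaces> scenario %s, %d facilities, direction %s\n",
              x$scenario_name, length(x$facility_ids), x$direction))
  cat(sprintf("  travel time: median %.1f min, max %.1f min; unreachable cells: %d\n",
              stats::median(fin), max(fin), sum(!is.finite(tt))))
  invisible(x)
}

#' Cellwise difference of two cost surfaces
#'
#' `a - b` in minutes with infinity-aware semantics: `Inf - finite = Inf`,
#' `Inf - Inf = NA` (nodata), and nodata propagates.
#'
#' @param a,b `cost_surfaces` on the same grid and facility set.
#' @return a `grid_raster` of minute differences.
#' @export
compare_scenarios <- function(a, b) {
  stop_grid_mismatch(a$travel_time, b$travel_time)
  if (!identical(a$facility_ids, b$facility_ids))
    stop("cost surfaces use different facility sets")
  va <- a$travel_time$values; vb <- b$travel_time$values
  d <- va - vb                                  # Inf - Inf = NaN
  d[is.infinite(va) & is.finite(vb)] <- Inf
  d[is.finite(va) & is.infinite(vb)] <- -Inf
  d[is.infinite(va) & is.infinite(vb)] <- NA_real_
  d[is.na(va) | is.na(vb)] <- NA_real_
  g <- grid_of(a$travel_time)
  grid_raster(d, xmin = g$xmin, ymax = g$ymax, cell_size = g$cell_size,
              crs = g$crs)
}
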