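# Micro-scene builders used across the suite.

# Wrap a code matrix directly as a merged landcover (codes: 0 barrier,
# 1 bare, 2 shrubland, 3 built, 11-13 roads).
make_merged <- function(codes, cell_size = 100) {
  r <- hfaccess::grid_raster(as.matrix(codes), cell_size = cell_size)
  structure(list(grid = hfaccess::grid_of(r), classes = r,
                 class_table = rbind(
                   data.frame(code = 0L, label = "barrier",
                              stringsAsFactors = FALSE),
                   hfaccess::landcover_classes())),
            class = "merged_landcover")
}

flat_dem <- function(codes, elev = 500, cell_size = 100) {
  hfaccess::grid_raster(matrix(elev, nrow(as.matrix(codes)),
                               ncol(as.matrix(codes))),
                        cell_size = cell_size)
}

# single-class walking scenario at a uniform speed
uniform_walk <- function(speed = 5, slope_correction = "none") {
  hfaccess::travel_scenario(
    "uniform_walk",
    data.frame(code = c(1L, 2L, 3L, 11L, 12L, 13L),
               label = c("bare", "shrubland", "built", "road_primary",
                         "road_secondary", "road_tertiary"),
               mode = "walk",
               speed_kmh = speed, stringsAsFactors = FALSE),
    slope_correction = slope_correction)
}

# a facility table snapped by construction at the given cells
fac_at <- function(rows, cols, type = "HP", ids = NULL, grid = NULL) {
  n <- length(rows)
  if (is.null(ids)) ids <- sprintf("%s%02d", type, seq_len(n))
  xy <- if (is.null(grid)) cbind(x = cols * 100 - 50, y = NA) else
    hfaccess::cell_to_world(grid, rows, cols)
  data.frame(facility_id = ids, type = rep(type, n),
             x = xy[, 1], y = if (is.null(grid)) 0 else xy[, 2],
             cell_row = rows, cell_col = cols,
             snapped = FALSE, snap_distance_m = 0,
             stringsAsFactors = FALSE)
}

# random mixed-mode micro landscape: barriers, two landcover classes and a
# road corridor; returns merged + dem
random_micro_scene <- function(seed, nr = NULL, nc = NULL,
                               barrier_frac = 0.12, river = FALSE) {
  set.seed(seed)
  if (is.null(nr)) nr <- sample(5:15, 1)
  if (is.null(nc)) nc <- sample(5:15, 1)
  codes <- matrix(sample(c(1L, 2L, 3L), nr * nc, replace = TRUE), nr, nc)
  codes[matrix(runif(nr * nc) < barrier_frac, nr, nc)] <- 0L
  # a road row so motorized scenarios mix modes
  road_row <- sample(nr, 1)
  codes[road_row, ] <- sample(c(11L, 12L, 13L), 1)
  if (river) {
    # a full barrier column, bridged only where the road crosses it
    rc <- sample(nc, 1)
    codes[, rc] <- 0L
    codes[road_row, rc] <- codes[road_row, 1]
  }
  dem <- hfaccess::grid_raster(
    matrix(500 + cumsum(rnorm(nr * nc, 0, 2)), nr, nc), cell_size = 100)
  list(merged = make_merged(codes), dem = dem, nr = nr, nc = nc)
}

# pick k random passable cells of a merged landcover
random_sources <- function(merged, k = 1) {
  pass <- which(!is.na(merged$classes$values) &
                  merged$classes$values != 0, arr.ind = TRUE)
  pass[sample(nrow(pass), min(k, nrow(pass))), , drop = FALSE]
}
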