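#' Configuration of a synthetic study area
#'
#' A synthetic scene emulates the inputs of a facility-accessibility study
#' over an arid, sparsely roaded region: a smooth elevation field, a small
#' set of landcover classes, population clustered around settlements,
#' a skeletal road network joining settlements, rivers crossing the scene
#' (barriers to travel unless bridged by a road), lakes, a district
#' partition, and health posts (HP) roughly ten times more numerous than
#' health centers (HC), with per-cadre staffing that is deficient at a
#' configurable rate.
#'
#' @param seed integer; the single source of randomness for the scene.
#' @param n_rows,n_cols grid shape in cells.
#' @param cell_size cell edge in meters (default 100 m, the working
#'   resolution of gridded population products this emulates).
#' @param n_settlements number of population cluster centers.
#' @param n_hc,n_hp facility counts; `n_hp >= n_hc >= 1`.
#' @param n_districts number of districts partitioning the scene.
#' @param river_count number of rivers crossing the scene.
#' @param bridge_probability probability that a road-river crossing is a
#'   bridge (otherwise the road is interrupted at the river).
#' @param total_population persons, allocated across settlements with
#'   log-normal sizes.
#' @param staffing_deficit_rate probability that a cadre at a facility is
#'   staffed below its minimum.
#' @param n_lakes number of lake polygons.
#' @return an object of class `scene_config`.
#' @export
scene_config <- function(seed = 1L, n_rows = 160L, n_cols = 160L,
                         cell_size = 100, n_settlements = 50L,
                         n_hc = 3L, n_hp = 30L, n_districts = 8L,
                         river_count = 3L, bridge_probability = 0.4,
                         total_population = 150000,
                         staffing_deficit_rate = 0.6, n_lakes = 2L) {
  cfg <- list(seed = as.integer(seed), n_rows = as.integer(n_rows),
              n_cols = as.integer(n_cols), cell_size = cell_size,
              n_settlements = as.integer(n_settlements),
              n_hc = as.integer(n_hc), n_hp = as.integer(n_hp),
              n_districts = as.integer(n_districts),
              river_count = as.integer(river_count),
              bridge_probability = bridge_probability,
              total_population = total_population,
              staffing_deficit_rate = staffing_deficit_rate,
              n_lakes = as.integer(n_lakes))
  class(cfg) <- "scene_config"
  validate_scene_config(cfg)
  cfg
}

validate_scene_config <- function(cfg) {
  if (cfg$cell_size <= 0) stop("cell_size must be > 0")
  counts <- c("n_rows", "n_cols", "n_settlements", "n_hc", "n_hp",
              "n_districts", "river_count", "n_lakes")
  for (f in counts) if (is.na(cfg[[f]]) || cfg[[f]] < 0)
    stop(sprintf("%s must be a non-negative count", f))
  if (cfg$n_rows < 4L || cfg$n_cols < 4L) stop("grid must be at least 4 x 4")
  if (cfg$n_hc < 1L || cfg$n_hp < cfg$n_hc)
    stop("need n_hp >= n_hc >= 1")
  for (f in c("bridge_probability", "staffing_deficit_rate"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop(sprintf("%s must lie in [0, 1]", f))
  if (cfg$total_population < 0) stop("total_population must be >= 0")
  invisible(cfg)
}

# Landcover vocabulary shared with geoprep. Codes are stable across the
# package: base classes 1-4, road classes 11-13, 0 reserved for barriers.
#' Landcover and road class table
#'
#' @return data.frame of the class codes used throughout the package.
#' @export
landcover_classes <- function() {
  data.frame(
    code = c(1L, 2L, 3L, 4L, 11L, 12L, 13L),
    label = c("bare", "shrubland", "built", "water",
              "road_primary", "road_secondary", "road_tertiary"),
    stringsAsFactors = FALSE)
}

BARRIER_CODE <- 0L
WATER_CODE <- 4L
ROAD_CODES <- c(road_primary = 11L, road_secondary = 12L, road_tertiary = 13L)

#' Cadres of the default staffing tables
#'
#' Eleven health-worker cadres used by the synthetic staffing generator and
#' the placeholder benchmark tables. The list and all benchmark numbers are
#' editable configuration, not authoritative planning figures.
#'
#' @return character vector of cadre names.
#' @export
default_cadres <- function() {
  c("health_officer", "nurse", "midwife", "pharmacist", "druggist",
    "lab_technologist", "lab_technician", "environmental_health",
    "health_informatics", "emergency_officer", "anesthetist")
}

# sample from a vector even when it has length 1 (avoids base sample()'s
# scalar expansion)
resample <- function(x, n) x[sample.int(length(x), n)]

strip_dimnames <- function(m) { dimnames(m) <- NULL; m }

# separable gaussian smoothing by explicit banded weight matrices;
# edge rows renormalize so a constant field stays constant
smooth_matrix <- function(m, sigma) {
  kern_mat <- function(n) {
    h <- max(1L, ceiling(3 * sigma))
    idx <- seq_len(n)
    A <- outer(idx, idx, function(i, j) exp(-((i - j)^2) / (2 * sigma^2)))
    A[abs(row(A) - col(A)) > h] <- 0
    A / rowSums(A)
  }
  kern_mat(nrow(m)) %*% m %*% t(kern_mat(ncol(m)))
}

#' Generate a synthetic scene
#'
#' Deterministic given the config: the same seed and parameters reproduce
#' the scene bit for bit. See [scene_config()] for what is generated.
#'
#' @param config a [scene_config()].
#' @return an object of class `scene` with components `dem`, `landcover`,
#'   `population` (grid_raster), `roads`, `rivers`, `lakes` (geometry
#'   lists), `bridges` (crossing points), `districts` (zone-id raster),
#'   `district_seeds`, `facilities` (data.frame) and `config`.
#' @export
generate_scene <- function(config) {
  validate_scene_config(config)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  nr <- config$n_rows; nc <- config$n_cols; cs <- config$cell_size
  grid <- structure(list(n_rows = nr, n_cols = nc, xmin = 0, ymax = nr * cs,
                         cell_size = cs, crs = "EPSG:32638"),
                    class = "analysis_grid")
  xmax <- nc * cs; ymax <- nr * cs

  # --- elevation: smoothed noise rescaled to a plausible relief ---
  dem_v <- smooth_matrix(matrix(stats::rnorm(nr * nc), nr, nc), sigma = 6)
  rng <- range(dem_v)
  dem_v <- 400 + (dem_v - rng[1]) / max(rng[2] - rng[1], 1e-12) * 300
  dem <- grid_raster(dem_v, xmin = 0, ymax = ymax, cell_size = cs)

  # --- base landcover: bare vs shrubland from a second smoothed field ---
  veg <- smooth_matrix(matrix(stats::rnorm(nr * nc), nr, nc), sigma = 4)
  lc_v <- matrix(1, nr, nc)               # bare
  lc_v[veg > stats::quantile(veg, 0.55)] <- 2  # shrubland

  # --- lakes ---
  lakes <- list()
  if (config$n_lakes > 0L) for (k in seq_len(config$n_lakes)) {
    cx <- stats::runif(1, 0.15, 0.85) * xmax
    cy <- stats::runif(1, 0.15, 0.85) * ymax
    rad <- stats::runif(1, 3, 6) * cs
    ang <- seq(0, 2 * pi, length.out = 25L)[-25L]
    wob <- 1 + 0.25 * sin(3 * ang + stats::runif(1, 0, 2 * pi))
    lakes[[k]] <- strip_dimnames(cbind(cx + rad * wob * cos(ang),
                                       cy + rad * wob * sin(ang)))
  }
  lake_hit <- rasterize_polygons(lakes, grid)
  lc_v[lake_hit] <- WATER_CODE

  # --- settlements and population ---
  n_set <- config$n_settlements
  land_cells <- which(lc_v != WATER_CODE)
  set_cells <- sample(land_cells, n_set)
  set_rc <- cbind(row = (set_cells - 1L) %% nr + 1L,
                  col = (set_cells - 1L) %/% nr + 1L)
  set_xy <- cell_to_world(grid, set_rc[, 1], set_rc[, 2])
  sizes <- stats::rlnorm(n_set, meanlog = 0, sdlog = 1)
  set_pop <- config$total_population * sizes / sum(sizes)
  ord <- order(set_pop, decreasing = TRUE)

  pop_v <- matrix(0, nr, nc)
  rows <- matrix(rep(seq_len(nr), nc), nr, nc)
  cols <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  for (s in seq_len(n_set)) {
    sig <- 1.5 + 2.5 * (set_pop[s] / max(set_pop))  # bigger towns sprawl more
    d2 <- (rows - set_rc[s, 1])^2 + (cols - set_rc[s, 2])^2
    w <- exp(-d2 / (2 * sig^2))
    w[d2 > (4 * sig)^2] <- 0
    w[lc_v == WATER_CODE] <- 0
    pop_v <- pop_v + set_pop[s] * w / sum(w)
  }

  # built-up where density is urban-grade (> 25 persons/cell here)
  lc_v[pop_v > 25 & lc_v != WATER_CODE] <- 3

  landcover <- grid_raster(lc_v, xmin = 0, ymax = ymax, cell_size = cs)
  population <- grid_raster(pop_v, xmin = 0, ymax = ymax, cell_size = cs)

  # --- rivers: random-walk polylines crossing the full extent ---
  rivers <- list()
  if (config$river_count > 0L) for (k in seq_len(config$river_count)) {
    vertical <- stats::runif(1) < 0.5
    n_pts <- 40L
    if (vertical) {
      ys <- seq(ymax, 0, length.out = n_pts)
      xs <- stats::runif(1, 0.2, 0.8) * xmax +
        cumsum(stats::rnorm(n_pts, 0, 1.2 * cs))
      xs <- pmin(pmax(xs, 0.02 * xmax), 0.98 * xmax)
    } else {
      xs <- seq(0, xmax, length.out = n_pts)
      ys <- stats::runif(1, 0.2, 0.8) * ymax +
        cumsum(stats::rnorm(n_pts, 0, 1.2 * cs))
      ys <- pmin(pmax(ys, 0.02 * ymax), 0.98 * ymax)
    }
    rivers[[k]] <- strip_dimnames(cbind(xs, ys))
  }

  # --- roads: minimum spanning tree over settlement centers ---
  road_lines <- list(); road_class <- character(0)
  if (n_set >= 2L) {
    dmat <- as.matrix(stats::dist(set_xy))
    g <- igraph::graph_from_adjacency_matrix(dmat, mode = "undirected",
                                             weighted = TRUE)
    mst <- igraph::mst(g)
    el <- igraph::as_edgelist(mst, names = FALSE)
    cls <- sample(names(ROAD_CODES), nrow(el), replace = TRUE,
                  prob = c(0.2, 0.3, 0.5))
    for (i in seq_len(nrow(el))) {
      road_lines[[i]] <- strip_dimnames(rbind(set_xy[el[i, 1], ],
                                              set_xy[el[i, 2], ]))
      road_class[i] <- cls[i]
    }
  }

  # --- bridges: each road-river crossing survives with bridge_probability;
  #     otherwise the road is interrupted so the barrier stays closed ---
  bridges <- matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("x", "y")))
  final_lines <- list(); final_class <- character(0)
  for (i in seq_along(road_lines)) {
    cross <- line_crossings(road_lines[i], rivers)
    if (nrow(cross)) {
      keep <- stats::runif(nrow(cross)) < config$bridge_probability
      bridges <- rbind(bridges, cross[keep, , drop = FALSE])
      cuts <- cross[!keep, , drop = FALSE]
      pieces <- cut_line_gaps(road_lines[[i]], cuts, gap = 2 * cs)
    } else pieces <- road_lines[i]
    for (p in pieces) {
      final_lines[[length(final_lines) + 1L]] <- p
      final_class[length(final_class) + 1L] <- road_class[i]
    }
  }
  roads <- list(lines = final_lines, class = final_class)

  # --- districts: planar partition by nearest seed point ---
  nd <- config$n_districts
  seed_cells <- sample(nr * nc, nd)
  seed_rc <- cbind(row = (seed_cells - 1L) %% nr + 1L,
                   col = (seed_cells - 1L) %/% nr + 1L)
  dist_id <- matrix(1L, nr, nc)
  best <- (rows - seed_rc[1, 1])^2 + (cols - seed_rc[1, 2])^2
  if (nd > 1L) for (k in 2:nd) {
    d2 <- (rows - seed_rc[k, 1])^2 + (cols - seed_rc[k, 2])^2
    upd <- d2 < best            # ties keep the lowest district id
    dist_id[upd] <- k
    best[upd] <- d2[upd]
  }
  districts <- grid_raster(dist_id, xmin = 0, ymax = ymax, cell_size = cs)
  seed_xy <- cell_to_world(grid, seed_rc[, 1], seed_rc[, 2])
  district_seeds <- data.frame(district_id = seq_len(nd),
                               x = seed_xy[, 1], y = seed_xy[, 2])

  # --- facilities: HCs at the largest settlements, HPs at the rest and at
  #     random rural land cells ---
  cadres <- default_cadres()
  nmin <- default_benchmark()$national_min
  fac <- list()
  hc_at <- ord[seq_len(config$n_hc)]
  for (j in seq_len(config$n_hc)) {
    s <- hc_at[j]
    staff <- vapply(cadres, function(cd) {
      m <- nmin[[cd]]
      if (stats::runif(1) < config$staffing_deficit_rate)
        resample(0:max(0L, m - 1L), 1L)
      else m + stats::rpois(1, 0.8)
    }, numeric(1))
    fac[[length(fac) + 1L]] <- c(list(facility_id = sprintf("HC%02d", j),
                                      type = "HC", x = set_xy[s, 1],
                                      y = set_xy[s, 2]),
                                 as.list(staff), list(hew_count = 0))
  }
  # HPs go to a random subset of the remaining settlements (facility siting
  # does not track settlement size), then to random rural cells
  hp_set <- resample(setdiff(ord, hc_at), length(setdiff(ord, hc_at)))
  n_hp_set <- min(length(hp_set), config$n_hp)
  hp_xy <- matrix(numeric(0), ncol = 2)
  if (n_hp_set > 0L) hp_xy <- set_xy[hp_set[seq_len(n_hp_set)], , drop = FALSE]
  n_rural <- config$n_hp - n_hp_set
  if (n_rural > 0L) {
    rural_cells <- sample(land_cells, n_rural)
    rr <- (rural_cells - 1L) %% nr + 1L
    rc <- (rural_cells - 1L) %/% nr + 1L
    hp_xy <- rbind(hp_xy, cell_to_world(grid, rr, rc))
  }
  for (j in seq_len(config$n_hp)) {
    hew <- if (stats::runif(1) < config$staffing_deficit_rate)
      resample(0:1, 1L) else 2L + stats::rbinom(1L, 1L, 0.15)
    zeros <- as.list(stats::setNames(rep(0, length(cadres)), cadres))
    fac[[length(fac) + 1L]] <- c(list(facility_id = sprintf("HP%03d", j),
                                      type = "HP", x = hp_xy[j, 1],
                                      y = hp_xy[j, 2]),
                                 zeros, list(hew_count = hew))
  }
  facilities <- do.call(rbind, lapply(fac, function(f)
    as.data.frame(f, stringsAsFactors = FALSE)))
  rownames(facilities) <- NULL

  structure(list(config = config, grid = grid, dem = dem,
                 landcover = landcover, population = population,
                 roads = roads, rivers = rivers, lakes = lakes,
                 bridges = bridges, districts = districts,
                 district_seeds = district_seeds, facilities = facilities),
            class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<scene> %d x %d cells @ %g m (seed %d)\n",
              cfg$n_rows, cfg$n_cols, cfg$cell_size, cfg$seed))
  cat(sprintf("  population: %.1f persons across %d settlements\n",
              sum(x$population$values), cfg$n_settlements))
  cat(sprintf("  facilities: %d HC, %d HP; %d districts, %d rivers, %d bridges\n",
              sum(x$facilities$type == "HC"), sum(x$facilities$type == "HP"),
              cfg$n_districts, cfg$river_count, nrow(x$bridges)))
  invisible(x)
}

#' @export
plot.scene <- function(x, ...) {
  plot(x$landcover, main = "landcover",
       col = grDevices::hcl.colors(7, "Earth"), ...)
  for (rv in x$rivers) graphics::lines(rv, col = "blue", lwd = 2)
  for (ln in x$roads$lines) graphics::lines(ln, col = "grey20", lwd = 1.5)
  with(x$facilities, graphics::points(x, y, pch = ifelse(type == "HC", 17, 1),
                                      col = ifelse(type == "HC", "red", "black")))
  invisible(x)
}

geojson_lines <- function(lines, props = NULL) {
  feats <- lapply(seq_along(lines), function(i) {
    ft <- list(type = "Feature",
               geometry = list(type = "LineString",
                               coordinates = unname(apply(lines[[i]], 1L,
                                                          function(p) as.list(unname(p)),
                                                          simplify = FALSE))),
               properties = if (is.null(props)) stats::setNames(list(), character(0))
                            else as.list(props[i, , drop = FALSE]))
    ft
  })
  list(type = "FeatureCollection", features = feats)
}

geojson_polygons <- function(polys) {
  feats <- lapply(polys, function(pg) {
    ring <- rbind(pg, pg[1L, , drop = FALSE])
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(unname(apply(ring, 1L,
                                                         function(p) as.list(unname(p)),
                                                         simplify = FALSE)))),
         properties = stats::setNames(list(), character(0)))
  })
  list(type = "FeatureCollection", features = feats)
}

coords_to_matrix <- function(coords) {
  do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
}

#' Write a scene to a directory / read it back
#'
#' Rasters go to ESRI ASCII grids, vector layers to GeoJSON, facilities to
#' CSV, and a JSON manifest records the generating config, the CRS, the
#' class table, bridge points, district seeds and every emitted file.
#' `scene_from_disk` restores an identical scene (values, coordinates and
#' table cells round-trip exactly).
#'
#' @param scene a [generate_scene()] result.
#' @param dir directory to create/fill.
#' @return `scene_to_disk` returns the manifest (invisibly);
#'   `scene_from_disk` returns the scene.
#' @export
scene_to_disk <- function(scene, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create directory: ", dir)
  wf <- function(r, f) { write_asc(r, file.path(dir, f)); f }
  files <- c(dem = wf(scene$dem, "dem.asc"),
             landcover = wf(scene$landcover, "landcover.asc"),
             population = wf(scene$population, "population.asc"),
             districts = wf(scene$districts, "districts.asc"))
  jw <- function(x, f) {
    jsonlite::write_json(x, file.path(dir, f), auto_unbox = TRUE,
                         digits = NA, null = "null")
    f
  }
  files["roads"] <- jw(geojson_lines(scene$roads$lines,
                                     data.frame(class = scene$roads$class,
                                                stringsAsFactors = FALSE)),
                       "roads.geojson")
  files["rivers"] <- jw(geojson_lines(scene$rivers), "rivers.geojson")
  files["lakes"] <- jw(geojson_polygons(scene$lakes), "lakes.geojson")

  fac <- scene$facilities
  fac_chr <- fac
  for (cn in names(fac_chr)) if (is.numeric(fac_chr[[cn]]))
    fac_chr[[cn]] <- sprintf("%.17g", fac_chr[[cn]])
  utils::write.csv(fac_chr, file.path(dir, "facilities.csv"),
                   row.names = FALSE, quote = FALSE)
  files["facilities"] <- "facilities.csv"

  manifest <- list(
    format = "hfaccess-scene/1",
    crs = scene$grid$crs,
    config = unclass(scene$config),
    class_table = landcover_classes(),
    bridges = if (nrow(scene$bridges)) as.data.frame(scene$bridges) else NULL,
    district_seeds = scene$district_seeds,
    files = as.list(files))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "columns")
  invisible(manifest)
}

#' @rdname scene_to_disk
#' @export
scene_from_disk <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) stop("no manifest.json in ", dir)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  crs <- mf$crs
  cfg <- mf$config
  cfg <- scene_config(seed = cfg$seed, n_rows = cfg$n_rows, n_cols = cfg$n_cols,
                      cell_size = cfg$cell_size, n_settlements = cfg$n_settlements,
                      n_hc = cfg$n_hc, n_hp = cfg$n_hp, n_districts = cfg$n_districts,
                      river_count = cfg$river_count,
                      bridge_probability = cfg$bridge_probability,
                      total_population = cfg$total_population,
                      staffing_deficit_rate = cfg$staffing_deficit_rate,
                      n_lakes = cfg$n_lakes)
  rd <- function(f) read_asc(file.path(dir, mf$files[[f]]), crs = crs)
  gj <- function(f) jsonlite::read_json(file.path(dir, mf$files[[f]]),
                                        simplifyVector = FALSE)
  roads_gj <- gj("roads")
  road_lines <- lapply(roads_gj$features,
                       function(ft) coords_to_matrix(ft$geometry$coordinates))
  road_class <- vapply(roads_gj$features,
                       function(ft) ft$properties$class, "")
  rivers_gj <- gj("rivers")
  rivers <- lapply(rivers_gj$features,
                   function(ft) coords_to_matrix(ft$geometry$coordinates))
  lakes_gj <- gj("lakes")
  lakes <- lapply(lakes_gj$features, function(ft) {
    ring <- coords_to_matrix(ft$geometry$coordinates[[1]])
    ring[-nrow(ring), , drop = FALSE]   # drop closing vertex
  })
  fac <- utils::read.csv(file.path(dir, mf$files$facilities),
                         stringsAsFactors = FALSE)
  dem <- rd("dem")
  grid <- grid_of(dem)
  bridges <- if (!is.null(mf$bridges) && length(mf$bridges))
    cbind(x = mf$bridges$x, y = mf$bridges$y)
  else matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("x", "y")))
  structure(list(config = cfg, grid = grid, dem = dem,
                 landcover = rd("landcover"), population = rd("population"),
                 roads = list(lines = road_lines, class = road_class),
                 rivers = rivers, lakes = lakes, bridges = bridges,
                 districts = rd("districts"),
                 district_seeds = as.data.frame(mf$district_seeds),
                 facilities = fac),
            class = "scene")
}
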