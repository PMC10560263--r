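#' Align a raster to an analysis grid
#'
#' All layers of one analysis must share a single grid (shape, georeference,
#' CRS). Three resampling methods are offered: `nearest` for categorical
#' layers, `bilinear` for continuous fields, and `sum` for count layers
#' (each source cell's value is assigned to the target cell containing its
#' center, so totals such as population are conserved exactly).
#'
#' @param source a `grid_raster`.
#' @param grid target `analysis_grid`.
#' @param method `"nearest"`, `"bilinear"` or `"sum"`.
#' @param categorical declare the source categorical; `bilinear` is then an
#'   error.
#' @return a `grid_raster` on `grid`.
#' @export
align_raster <- function(source, grid,
                         method = c("nearest", "bilinear", "sum"),
                         categorical = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(source, "grid_raster"), inherits(grid, "analysis_grid"))
  if (is.null(source$crs) || is.na(source$crs)) stop("source raster has no CRS")
  if (!identical(source$crs, grid$crs))
    stop(sprintf("CRS mismatch (%s vs %s): no transform available",
                 source$crs, grid$crs))
  if (categorical && method == "bilinear")
    stop("bilinear resampling is not defined for categorical rasters")
  if (same_grid(source, grid)) {
    out <- source
    return(out)
  }
  sg <- grid_of(source)
  if (method == "sum") {
    out_v <- matrix(0, grid$n_rows, grid$n_cols)
    src_rc <- cbind(rep(seq_len(sg$n_rows), times = sg$n_cols),
                    rep(seq_len(sg$n_cols), each = sg$n_rows))
    ctr <- cell_to_world(sg, src_rc[, 1], src_rc[, 2])
    tgt <- world_to_cell(grid, ctr[, 1], ctr[, 2])
    vals <- source$values[src_rc]
    ok <- !is.na(tgt[, 1]) & !is.na(vals)
    idx <- cbind(tgt[ok, 1], tgt[ok, 2])
    for (i in seq_len(nrow(idx)))            # accumulate duplicates
      out_v[idx[i, 1], idx[i, 2]] <- out_v[idx[i, 1], idx[i, 2]] + vals[ok][i]
    return(grid_raster(out_v, xmin = grid$xmin, ymax = grid$ymax,
                       cell_size = grid$cell_size, crs = grid$crs))
  }
  tgt_rc <- cbind(rep(seq_len(grid$n_rows), times = grid$n_cols),
                  rep(seq_len(grid$n_cols), each = grid$n_rows))
  ctr <- cell_to_world(grid, tgt_rc[, 1], tgt_rc[, 2])
  if (method == "nearest") {
    src <- world_to_cell(sg, ctr[, 1], ctr[, 2])
    vals <- rep(NA_real_, nrow(src))
    ok <- !is.na(src[, 1])
    vals[ok] <- source$values[src[ok, , drop = FALSE]]
  } else {  # bilinear on source cell centers
    u <- (ctr[, 1] - sg$xmin) / sg$cell_size - 0.5   # col - 1 space
    v <- (sg$ymax - ctr[, 2]) / sg$cell_size - 0.5   # row - 1 space
    c0 <- pmin(pmax(floor(u), 0), sg$n_cols - 1L)
    r0 <- pmin(pmax(floor(v), 0), sg$n_rows - 1L)
    c1 <- pmin(c0 + 1L, sg$n_cols - 1L)
    r1 <- pmin(r0 + 1L, sg$n_rows - 1L)
    fu <- pmin(pmax(u - c0, 0), 1); fv <- pmin(pmax(v - r0, 0), 1)
    g <- function(r, c) source$values[cbind(r + 1L, c + 1L)]
    vals <- (1 - fu) * (1 - fv) * g(r0, c0) + fu * (1 - fv) * g(r0, c1) +
            (1 - fu) * fv * g(r1, c0) + fu * fv * g(r1, c1)
  }
  out_v <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  out_v[tgt_rc] <- vals
  grid_raster(out_v, xmin = grid$xmin, ymax = grid$ymax,
              cell_size = grid$cell_size, crs = grid$crs)
}

#' Build the merged landcover the travel model runs on
#'
#' Overlays the vector layers on the base landcover with a fixed precedence
#' (highest wins): roads > river/lake barrier > base class. A cell crossed
#' by both a road and a river therefore keeps the road's class -- that cell
#' is the bridge, and it is passable; rivers and lakes everywhere else are
#' full barriers. Rasterization is "all-touched": a cell is marked when the
#' geometry intersects it, which keeps linear barriers connected at this
#' resolution.
#'
#' @param landcover base landcover `grid_raster` (codes of
#'   [landcover_classes()]).
#' @param roads list with `lines` (coordinate matrices) and `class`
#'   (road class label per line).
#' @param rivers list of polyline coordinate matrices.
#' @param lakes list of polygon ring coordinate matrices.
#' @param grid target `analysis_grid` (landcover must already be on it).
#' @return an object of class `merged_landcover`: `classes` (grid_raster),
#'   `class_table`, `grid`.
#' @export
build_merged_landcover <- function(landcover, roads = list(lines = list(), class = character(0)),
                                   rivers = list(), lakes = list(),
                                   grid = grid_of(landcover)) {
  stopifnot(inherits(landcover, "grid_raster"))
  if (all(is.na(landcover$values))) stop("landcover raster is empty")
  stop_grid_mismatch(landcover, grid)
  unknown <- setdiff(unique(roads$class), names(ROAD_CODES))
  if (length(unknown))
    stop("unknown road classes: ", paste(unknown, collapse = ", "))

  v <- landcover$values
  v[v == WATER_CODE] <- BARRIER_CODE             # standing water is a barrier
  barrier_hit <- rasterize_lines(rivers, grid) | rasterize_polygons(lakes, grid)
  v[barrier_hit & !is.na(v)] <- BARRIER_CODE
  for (cls in names(ROAD_CODES)) {
    sel <- roads$class == cls
    if (!any(sel)) next
    road_hit <- rasterize_lines(roads$lines[sel], grid)
    v[road_hit & !is.na(v)] <- ROAD_CODES[[cls]] # roads win: bridges passable
  }
  class_table <- rbind(
    data.frame(code = BARRIER_CODE, label = "barrier", stringsAsFactors = FALSE),
    landcover_classes())
  structure(list(grid = grid,
                 classes = grid_raster(v, xmin = grid$xmin, ymax = grid$ymax,
                                       cell_size = grid$cell_size, crs = grid$crs),
                 class_table = class_table),
            class = "merged_landcover")
}

#' @export
print.merged_landcover <- function(x, ...) {
  tab <- table(factor(x$classes$values,
                      levels = x$class_table$code,
                      labels = x$class_table$label))
  cat(sprintf("<merged_landcover> %d x %d cells\n",
              x$grid$n_rows, x$grid$n_cols))
  print(tab[tab > 0])
  invisible(x)
}

is_passable <- function(merged) {
  v <- merged$classes$values
  !is.na(v) & v != BARRIER_CODE
}

#' Snap facilities to valid grid cells
#'
#' Maps facility world coordinates to cells of the merged landcover. A
#' facility that falls on a barrier, on a nodata cell or outside the extent
#' (rasterized rivers can overstate channel width, and GPS coordinates
#' carry error) is relocated to the nearest passable cell by Euclidean
#' distance between cell centers; ties break row-major (smallest row, then
#' smallest column). The relocation distance is recorded per facility.
#' Snapping is idempotent.
#'
#' @param facilities facility data.frame with `facility_id`, `type`, `x`,
#'   `y` columns (plus staffing columns, carried through).
#' @param merged a [build_merged_landcover()] result.
#' @return the facility table with `cell_row`, `cell_col`, `snapped`
#'   (logical) and `snap_distance_m` columns.
#' @export
snap_facilities <- function(facilities, merged) {
  stopifnot(is.data.frame(facilities),
            all(c("facility_id", "type", "x", "y") %in% names(facilities)))
  if (anyDuplicated(facilities$facility_id))
    stop("facility_id values must be unique")
  grid <- merged$grid
  pass <- is_passable(merged)
  if (!any(pass)) stop("merged landcover has no passable cell to snap to")
  pass_idx <- which(pass, arr.ind = TRUE)
  # row-major tie order: sort candidate cells by (row, col) so that in a
  # distance tie the first minimum wins
  ord <- order(pass_idx[, 1], pass_idx[, 2])
  pass_idx <- pass_idx[ord, , drop = FALSE]
  pass_xy <- cell_to_world(grid, pass_idx[, 1], pass_idx[, 2])

  rc <- world_to_cell(grid, facilities$x, facilities$y)
  n <- nrow(facilities)
  out_row <- integer(n); out_col <- integer(n)
  snapped <- logical(n); dist_m <- numeric(n)
  for (i in seq_len(n)) {
    r <- rc[i, 1]; c <- rc[i, 2]
    if (!is.na(r) && pass[r, c]) {
      out_row[i] <- r; out_col[i] <- c
    } else {
      # reference point: the containing cell's center when in extent (so the
      # search is a center-to-center distance), the raw position otherwise
      ref <- if (!is.na(r)) cell_to_world(grid, r, c)
             else cbind(facilities$x[i], facilities$y[i])
      d2 <- (pass_xy[, 1] - ref[1])^2 + (pass_xy[, 2] - ref[2])^2
      j <- which.min(d2)                       # first minimum = row-major tie
      out_row[i] <- pass_idx[j, 1]; out_col[i] <- pass_idx[j, 2]
      snapped[i] <- TRUE
      dist_m[i] <- sqrt(d2[j])
    }
  }
  facilities$cell_row <- out_row
  facilities$cell_col <- out_col
  facilities$snapped <- snapped
  facilities$snap_distance_m <- dist_m
  facilities
}

#' Write the facility snap log
#'
#' @param facilities a snapped facility table.
#' @param path CSV path.
#' @return the path, invisibly.
#' @export
write_snap_log <- function(facilities, path) {
  utils::write.csv(facilities[, c("facility_id", "snapped", "snap_distance_m")],
                   path, row.names = FALSE)
  invisible(path)
}
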