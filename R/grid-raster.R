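#' Georeferenced single-band raster
#'
#' The common spatial currency of the package: a numeric matrix with an
#' affine georeference (square cells, north-up). Row 1 is the northern edge;
#' cells are identified by their centers. Values are stored as-is; missing
#' cells are `NA` in memory and mapped to a declared nodata value on disk.
#'
#' @param values numeric matrix (rows run north to south).
#' @param xmin x coordinate of the western edge (map units, meters).
#' @param ymax y coordinate of the northern edge (map units, meters).
#' @param cell_size square cell edge length in meters; must be > 0.
#' @param crs coordinate reference system identifier (a projected, metric
#'   CRS is assumed throughout; e.g. `"EPSG:32638"`).
#' @return an object of class `grid_raster`.
#' @export
grid_raster <- function(values, xmin = 0, ymax = NULL, cell_size = 100,
                        crs = "EPSG:32638") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a single positive number")
  if (is.null(ymax)) ymax <- nrow(values) * cell_size
  structure(
    list(values = values, xmin = xmin, ymax = ymax,
         cell_size = cell_size, crs = crs),
    class = "grid_raster")
}

#' Analysis grid of a raster
#'
#' Extracts the grid definition (shape, georeference, CRS) shared by all
#' rasters of one analysis.
#'
#' @param r a `grid_raster`.
#' @return an object of class `analysis_grid`.
#' @export
grid_of <- function(r) {
  stopifnot(inherits(r, "grid_raster"))
  structure(
    list(n_rows = nrow(r$values), n_cols = ncol(r$values),
         xmin = r$xmin, ymax = r$ymax, cell_size = r$cell_size, crs = r$crs),
    class = "analysis_grid")
}

#' @export
print.grid_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<grid_raster> %d x %d cells @ %g m, %s\n",
              nrow(v), ncol(v), x$cell_size, x$crs))
  cat(sprintf("  extent: x [%g, %g], y [%g, %g]\n",
              x$xmin, x$xmin + ncol(v) * x$cell_size,
              x$ymax - nrow(v) * x$cell_size, x$ymax))
  fin <- v[is.finite(v)]
  if (length(fin))
    cat(sprintf("  values: min %g, max %g, NA/Inf cells %d\n",
                min(fin), max(fin), sum(!is.finite(v))))
  invisible(x)
}

#' @export
print.analysis_grid <- function(x, ...) {
  cat(sprintf("<analysis_grid> %d x %d cells @ %g m, %s\n",
              x$n_rows, x$n_cols, x$cell_size, x$crs))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-9) {
  ga <- if (inherits(a, "analysis_grid")) a else grid_of(a)
  gb <- if (inherits(b, "analysis_grid")) b else grid_of(b)
  ga$n_rows == gb$n_rows && ga$n_cols == gb$n_cols &&
    abs(ga$xmin - gb$xmin) < tol && abs(ga$ymax - gb$ymax) < tol &&
    abs(ga$cell_size - gb$cell_size) < tol && identical(ga$crs, gb$crs)
}

stop_grid_mismatch <- function(a, b) {
  if (!same_grid(a, b)) stop("rasters are not on the same analysis grid")
  invisible(TRUE)
}

#' Map between world coordinates and grid cells
#'
#' `world_to_cell` returns the (row, col) of the cell containing each point;
#' points outside the extent get `NA`. `cell_to_world` returns cell-center
#' coordinates. Rows and columns are 1-based; row 1 at the north edge.
#'
#' @param grid an `analysis_grid` (or `grid_raster`).
#' @param x,y world coordinates (vectors).
#' @param row,col cell indices (vectors).
#' @return a two-column matrix (`row`,`col` or `x`,`y`).
#' @export
world_to_cell <- function(grid, x, y) {
  g <- if (inherits(grid, "grid_raster")) grid_of(grid) else grid
  col <- floor((x - g$xmin) / g$cell_size) + 1L
  row <- floor((g$ymax - y) / g$cell_size) + 1L
  bad <- row < 1L | row > g$n_rows | col < 1L | col > g$n_cols
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' @rdname world_to_cell
#' @export
cell_to_world <- function(grid, row, col) {
  g <- if (inherits(grid, "grid_raster")) grid_of(grid) else grid
  cbind(x = g$xmin + (col - 0.5) * g$cell_size,
        y = g$ymax - (row - 0.5) * g$cell_size)
}

#' Write / read a raster as ESRI ASCII grid
#'
#' Plain-text raster interchange: a six-line header (ncols, nrows,
#' xllcorner, yllcorner, cellsize, NODATA_value) followed by rows from north
#' to south. Values are written with full double precision so a write/read
#' round trip is exact. The CRS is not part of the format; it is restored
#' from the `crs` argument (scene manifests record it).
#'
#' @param r a `grid_raster`.
#' @param path file path (`.asc`).
#' @param nodata value standing for `NA` on disk (default -9999).
#' @param crs CRS to attach on read.
#' @return `read_asc` returns a `grid_raster`; `write_asc` the path,
#'   invisibly.
#' @export
write_asc <- function(r, path, nodata = -9999) {
  stopifnot(inherits(r, "grid_raster"))
  v <- r$values
  v[!is.finite(v) & !is.na(v)] <- NA  # Inf has no ASCII-grid representation
  v[is.na(v)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", r$xmin),
    sprintf("yllcorner %.10g", r$ymax - nrow(v) * r$cell_size),
    sprintf("cellsize %.10g", r$cell_size),
    sprintf("NODATA_value %.10g", nodata))
  body <- apply(v, 1L, function(row) paste(sprintf("%.17g", row), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_asc
#' @export
read_asc <- function(path, crs = "EPSG:32638") {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  key <- tolower(vapply(hdr, `[`, "", 1L))
  val <- as.numeric(vapply(hdr, `[`, "", 2L))
  names(val) <- key
  nr <- as.integer(val[["nrows"]]); nc <- as.integer(val[["ncols"]])
  body <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  stopifnot(length(body) == nr * nc)
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == val[["nodata_value"]]] <- NA
  grid_raster(m, xmin = val[["xllcorner"]],
              ymax = val[["yllcorner"]] + nr * val[["cellsize"]],
              cell_size = val[["cellsize"]], crs = crs)
}

#' @export
plot.grid_raster <- function(x, main = NULL, col = grDevices::hcl.colors(64),
                             ...) {
  v <- x$values
  v[!is.finite(v)] <- NA
  nr <- nrow(v); nc <- ncol(v)
  # image() draws column-major with origin bottom-left; flip to north-up
  z <- t(v[nr:1, , drop = FALSE])
  xs <- x$xmin + (seq_len(nc) - 0.5) * x$cell_size
  ys <- (x$ymax - nr * x$cell_size) + (seq_len(nr) - 0.5) * x$cell_size
  graphics::image(xs, ys, z, asp = 1, col = col, main = main,
                  xlab = "x (m)", ylab = "y (m)", ...)
  invisible(x)
}
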