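# Internal planar geometry helpers. Geometry collections are plain lists:
# a polyline/ring is a two-column coordinate matrix (x, y); a collection is
# a list of such matrices with an attached data.frame of attributes handled
# by the callers.

# Cells crossed by one segment, "all-touched": every cell whose interior or
# boundary the segment passes through (grid traversal a la Amanatides-Woo).
trace_segment_cells <- function(grid, x0, y0, x1, y1) {
  g <- grid
  cs <- g$cell_size
  # continuous cell coordinates: u along columns, v along rows (north-down)
  u0 <- (x0 - g$xmin) / cs; u1 <- (x1 - g$xmin) / cs
  v0 <- (g$ymax - y0) / cs; v1 <- (g$ymax - y1) / cs
  n_steps <- max(2L, ceiling(2 * max(abs(u1 - u0), abs(v1 - v0))) + 1L)
  t <- seq(0, 1, length.out = 4L * n_steps)  # dense sampling: robust all-touched
  us <- u0 + t * (u1 - u0); vs <- v0 + t * (v1 - v0)
  col <- floor(us) + 1L; row <- floor(vs) + 1L
  keep <- row >= 1L & row <= g$n_rows & col >= 1L & col <= g$n_cols
  unique(cbind(row = row[keep], col = col[keep]))
}

# All cells touched by a list of polylines. Returns a logical matrix.
rasterize_lines <- function(lines, grid) {
  hit <- matrix(FALSE, grid$n_rows, grid$n_cols)
  for (ln in lines) {
    if (is.null(ln) || nrow(ln) < 2L) next
    for (i in seq_len(nrow(ln) - 1L)) {
      rc <- trace_segment_cells(grid, ln[i, 1], ln[i, 2], ln[i + 1L, 1], ln[i + 1L, 2])
      if (nrow(rc)) hit[rc] <- TRUE
    }
  }
  hit
}

# Cells touched by polygons (list of rings): cell centers inside the ring,
# plus all cells crossed by the ring boundary (all-touched).
rasterize_polygons <- function(polys, grid) {
  hit <- matrix(FALSE, grid$n_rows, grid$n_cols)
  if (!length(polys)) return(hit)
  ctr <- cell_to_world(grid,
                       row = rep(seq_len(grid$n_rows), times = grid$n_cols),
                       col = rep(seq_len(grid$n_cols), each = grid$n_rows))
  for (pg in polys) {
    if (is.null(pg) || nrow(pg) < 3L) next
    inside <- sp::point.in.polygon(ctr[, 1], ctr[, 2], pg[, 1], pg[, 2]) > 0
    hit[matrix(inside, grid$n_rows, grid$n_cols)] <- TRUE
    ring <- rbind(pg, pg[1L, , drop = FALSE])
    for (i in seq_len(nrow(ring) - 1L)) {
      rc <- trace_segment_cells(grid, ring[i, 1], ring[i, 2],
                                ring[i + 1L, 1], ring[i + 1L, 2])
      if (nrow(rc)) hit[rc] <- TRUE
    }
  }
  hit
}

# Intersection points of two segment sets (each a list of polylines).
# Returns a matrix of x,y crossing points (possibly 0 rows).
line_crossings <- function(lines_a, lines_b) {
  segs <- function(lines) {
    out <- list()
    for (ln in lines) if (!is.null(ln) && nrow(ln) >= 2L)
      for (i in seq_len(nrow(ln) - 1L))
        out[[length(out) + 1L]] <- c(ln[i, ], ln[i + 1L, ])
    out
  }
  sa <- segs(lines_a); sb <- segs(lines_b)
  pts <- matrix(numeric(0), ncol = 2)
  for (A in sa) for (B in sb) {
    p <- A[1:2]; r <- A[3:4] - p
    q <- B[1:2]; s <- B[3:4] - q
    denom <- r[1] * s[2] - r[2] * s[1]
    if (abs(denom) < 1e-12) next  # parallel
    qp <- q - p
    t <- (qp[1] * s[2] - qp[2] * s[1]) / denom
    u <- (qp[1] * r[2] - qp[2] * r[1]) / denom
    if (t >= 0 && t <= 1 && u >= 0 && u <= 1)
      pts <- rbind(pts, p + t * r)
  }
  colnames(pts) <- c("x", "y")
  pts
}

# Remove from a polyline every portion within `gap` of any of `points`
# (used to leave river crossings unbridged). Returns a list of sub-lines.
cut_line_gaps <- function(line, points, gap) {
  if (is.null(points) || nrow(points) == 0L) return(list(line))
  # densify, then drop vertices near any cut point and split on the holes
  dens <- densify_line(line, step = gap / 4)
  near <- rep(FALSE, nrow(dens))
  for (k in seq_len(nrow(points))) {
    d <- sqrt((dens[, 1] - points[k, 1])^2 + (dens[, 2] - points[k, 2])^2)
    near <- near | d < gap
  }
  runs <- rle(!near)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  out <- list()
  for (j in seq_along(runs$values)) {
    if (runs$values[j] && runs$lengths[j] >= 2L)
      out[[length(out) + 1L]] <- dens[starts[j]:ends[j], , drop = FALSE]
  }
  out
}

densify_line <- function(line, step) {
  out <- line[1L, , drop = FALSE]
  for (i in seq_len(nrow(line) - 1L)) {
    p <- line[i, ]; q <- line[i + 1L, ]
    len <- sqrt(sum((q - p)^2))
    n <- max(1L, ceiling(len / step))
    t <- seq_len(n) / n
    out <- rbind(out, cbind(p[1] + t * (q[1] - p[1]), p[2] + t * (q[2] - p[2])))
  }
  out
}

line_length <- function(line) {
  if (nrow(line) < 2L) return(0)
  sum(sqrt(rowSums((line[-1L, , drop = FALSE] - line[-nrow(line), , drop = FALSE])^2)))
}
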