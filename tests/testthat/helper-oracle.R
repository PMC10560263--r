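# Independent shortest-path oracle: explicit per-cell loops for the edge
# costs and textbook Bellman-Ford relaxation. Deliberately shares no code
# with the package's vectorized edge builder or with igraph.

oracle_edge_list <- function(merged, dem, scenario, neighbors = 8L) {
  nr <- merged$grid$n_rows; nc <- merged$grid$n_cols
  cs <- merged$grid$cell_size
  code <- merged$classes$values
  elev <- dem$values
  sp <- numeric(0); names(sp) <- character(0)
  for (i in seq_len(nrow(scenario$classes)))
    sp[as.character(scenario$classes$code[i])] <- scenario$classes$speed_kmh[i]
  md <- character(0)
  for (i in seq_len(nrow(scenario$classes)))
    md[as.character(scenario$classes$code[i])] <- scenario$classes$mode[i]
  tob <- function(s) {
    if (scenario$slope_correction == "none") return(1)
    exp(-3.5 * abs(s + 0.05)) / exp(-3.5 * 0.05)
  }
  offs <- list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0),
               c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  if (neighbors == 4L) offs <- offs[1:4]
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    ca <- code[r, c]
    if (is.na(ca) || ca == 0) next
    for (off in offs) {
      r2 <- r + off[1]; c2 <- c + off[2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      cb <- code[r2, c2]
      if (is.na(cb) || cb == 0) next
      d <- cs * sqrt(off[1]^2 + off[2]^2)
      s <- (elev[r2, c2] - elev[r, c]) / d
      f <- tob(s)
      va <- sp[[as.character(ca)]] * (if (md[[as.character(ca)]] == "walk") f else 1)
      vb <- sp[[as.character(cb)]] * (if (md[[as.character(cb)]] == "walk") f else 1)
      cost <- (d / 1000) / 2 * (1 / va + 1 / vb) * 60
      from <- c(from, (r - 1L) * nc + c)
      to <- c(to, (r2 - 1L) * nc + c2)
      w <- c(w, cost)
    }
  }
  list(from = from, to = to, w = w, n = nr * nc)
}

# distance from every cell to the nearest of src_ids, moving along edge
# direction (edges above point in the direction of motion)
oracle_times <- function(merged, dem, scenario, src_rc, neighbors = 8L) {
  el <- oracle_edge_list(merged, dem, scenario, neighbors)
  nc <- merged$grid$n_cols
  src <- (src_rc[, 1] - 1L) * nc + src_rc[, 2]
  d <- rep(Inf, el$n)
  d[src] <- 0
  repeat {
    # relax every edge: moving from 'from' to 'to' costs w, so a cell's
    # distance-to-facility can improve via d[from] <- w + d[to]
    cand <- el$w + d[el$to]
    better <- which(cand < d[el$from] - 1e-300)
    if (!length(better)) break
    agg <- tapply(cand[better], el$from[better], min)
    idx <- as.integer(names(agg))
    d[idx] <- pmin(d[idx], agg)
  }
  matrix(d, merged$grid$n_rows, nc, byrow = TRUE)  # ids are row-major
}
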