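# Fixture builders shared across the suite. Everything is constructed in
# code; coordinates are chosen near (35 E, 3.5 S) so the local planar
# frame is realistic.

fixture_origin <- c(35.0, -3.5)

# A square camp of the given half-width (metres) centred on the fixture
# origin.
square_camp <- function(half = 100, cell_size = 10) {
  g <- cpfmove::local_unproject(c(-half, half, half, -half),
                                c(-half, -half, half, half), fixture_origin)
  cpfmove::camp_context("testcamp", 2020, cbind(g$lon, g$lat),
                        cell_size = cell_size)
}

# Build a cpf_track from planar metre coordinates and relative seconds.
track_from_xy <- function(x, y, dt = 5, person_id = "P1", camp_id = "testcamp",
                          t0 = as.POSIXct("2020-07-01 05:00:00", tz = "UTC"),
                          times = NULL) {
  g <- cpfmove::local_unproject(x, y, fixture_origin)
  tt <- if (is.null(times)) t0 + (seq_along(x) - 1) * dt else t0 + times
  cpfmove::cpf_track(person_id, camp_id, tt, g$lon, g$lat)
}

# Projected + classified track straight from planar coordinates.
ptrack_from_xy <- function(x, y, camp = square_camp(), ...) {
  pt <- cpfmove::project_to_local(track_from_xy(x, y, ...), camp)
  cpfmove::classify_in_camp(pt, camp)
}

# An out-and-back day: dwell in camp, straight out to (0, apex), dwell,
# straight back, dwell. Step length ~ speed * dt.
out_and_back_xy <- function(apex = 2000, step = 6, n_dwell = 20) {
  ys <- seq(0, apex, by = step)
  y <- c(rep(0, n_dwell), ys, rep(apex, n_dwell), rev(ys), rep(0, n_dwell))
  list(x = rep(0, length(y)), y = y)
}

# Independent supercover oracle: sample the segment at `res` metre
# resolution and collect the (half-open) cells containing the samples.
sampled_cells <- function(x0, y0, x1, y1, cell_size = 10, res = 0.01) {
  len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  ts <- seq(0, 1, length.out = max(2, ceiling(len / res) + 1))
  i <- floor((x0 + ts * (x1 - x0)) / cell_size)
  j <- floor((y0 + ts * (y1 - y0)) / cell_size)
  unique(paste(i, j, sep = ","))
}

# Exact test: does the segment intersect the closed cell square?
# (Liang-Barsky clipping.) Complements the sampling oracle, which can
# miss sub-resolution traversals near lattice corners.
segment_intersects_cell <- function(x0, y0, x1, y1, i, j, cell_size = 10) {
  lo <- c(i, j) * cell_size; hi <- lo + cell_size
  p <- c(-(x1 - x0), x1 - x0, -(y1 - y0), y1 - y0)
  q <- c(x0 - lo[1], hi[1] - x0, y0 - lo[2], hi[2] - y0)
  t0 <- 0; t1 <- 1
  for (k in 1:4) {
    if (abs(p[k]) < 1e-15) { if (q[k] < -1e-9) return(FALSE) }
    else {
      r <- q[k] / p[k]
      if (p[k] < 0) t0 <- max(t0, r) else t1 <- min(t1, r)
    }
  }
  t0 <= t1 + 1e-9
}

# Published camp-level land summaries bundled with the package.
camp_land_table <- function() {
  utils::read.csv(system.file("extdata", "hadza_camp_land.csv",
                              package = "cpfmove"))
}
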