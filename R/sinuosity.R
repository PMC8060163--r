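# Path sinuosity: the ratio of distance actually travelled between two
# locations to the straight-line distance between them (>= 1). Computed
# for the outbound and inbound halves of each day's principal foray,
# and, geographically weighted, for every grid cell a track crosses.

#' Sinuosity of an ordered planar path
#'
#' Total path length divided by the straight-line (chord) distance
#' between first and last point.
#'
#' @param x,y planar coordinates in metres.
#' @param eps chord floor in metres; loops with a shorter chord have
#'   undefined sinuosity and return `NA` (default 1 m).
#' @return ratio `>= 1`, or `NA` for a degenerate chord.
#' @export
path_sinuosity <- function(x, y, eps = 1) {
  n <- length(x)
  stopifnot(n == length(y))
  if (n < 2) return(NA_real_)
  chord <- sqrt((x[n] - x[1])^2 + (y[n] - y[1])^2)
  if (chord < eps) return(NA_real_)
  path_length(x, y) / chord
}

#' Outbound and inbound sinuosity of a day's principal bout
#'
#' Each half of the bout (camp departure to apex, apex to camp return)
#' is scored as its path length divided by its chord. Gap-bridged spans
#' would bias the shape toward a straight line, so segments touching a
#' gap-filled fix are excluded from the path lengths, and the record is
#' dropped entirely when more than `max_gap_fraction` of the bout's
#' fixes are gap-filled.
#'
#' @param ptrack the annotated `cpf_ptrack` the bout indexes into.
#' @param bout a `cpf_bout` from [extract_primary_bout()].
#' @param max_gap_fraction skip threshold on the gap-filled fraction.
#' @param eps chord floor in metres.
#' @return one-row data frame (`person_id`, `date`, `outbound`,
#'   `inbound`), or `NULL` when the bout is skipped or degenerate.
#' @export
bout_sinuosity <- function(ptrack, bout, max_gap_fraction = 0.2, eps = 1) {
  if (is.null(bout)) return(NULL)
  if (bout$gap_fraction > max_gap_fraction) return(NULL)
  seg_sum <- function(rng) {
    if (length(rng) < 2) return(0)
    dl <- seg_lengths(ptrack$x[rng], ptrack$y[rng])
    gf <- ptrack$gap_filled[rng]
    sum(dl[!(gf[-1] | gf[-length(gf)])])
  }
  if (bout$outbound_chord < eps || bout$inbound_chord < eps) return(NULL)
  data.frame(person_id = ptrack$person_id, date = ptrack$date,
             outbound = seg_sum(bout$start:bout$apex) / bout$outbound_chord,
             inbound = seg_sum(bout$apex:bout$end) / bout$inbound_chord,
             stringsAsFactors = FALSE)
}

# Split a track's out-of-camp travel into per-cell passes. A pass is a
# maximal stretch of travel inside one grid cell, extended to the exact
# boundary-crossing points where the path enters and leaves the cell;
# its sinuosity is the in-cell path length over the entry-exit chord.
# Returns a data frame (i, j, sinuosity); dwell passes with chord < eps
# are skipped.
cell_passes <- function(ptrack, grid = ptrack$camp$grid, eps = 1) {
  ic <- ptrack$in_camp
  if (any(is.na(ic))) stop("in_camp labels missing; run classify_in_camp() first")
  s <- grid$cell_size
  res_i <- integer(0); res_j <- integer(0); res_v <- numeric(0)
  out_runs <- rle(!ic)
  ends <- cumsum(out_runs$lengths)
  starts <- ends - out_runs$lengths + 1L
  for (k in which(out_runs$values & out_runs$lengths >= 2)) {
    u <- (ptrack$x[starts[k]:ends[k]] - grid$origin[1]) / s
    v <- (ptrack$y[starts[k]:ends[k]] - grid$origin[2]) / s
    n <- length(u)
    ci <- floor(u[1]); cj <- floor(v[1])      # current cell
    ex <- u[1]; ey <- v[1]                    # pass entry point
    px <- u[1]; py <- v[1]                    # previous position
    acc <- 0                                  # in-cell path length
    close_pass <- function(qx, qy) {
      chord <- sqrt((qx - ex)^2 + (qy - ey)^2) * s
      if (chord >= eps) {
        res_i[length(res_i) + 1L] <<- ci
        res_j[length(res_j) + 1L] <<- cj
        res_v[length(res_v) + 1L] <<- (acc * s) / chord
      }
    }
    for (p in 2:n) {
      x1 <- u[p]; y1 <- v[p]
      ni <- floor(x1); nj <- floor(y1)
      if (ni == ci && nj == cj) {
        acc <- acc + sqrt((x1 - px)^2 + (y1 - py)^2)
        px <- x1; py <- y1
        next
      }
      # boundary crossings of the segment (px,py)-(x1,y1)
      du <- x1 - px; dv <- y1 - py
      tx <- if (du != 0) (seq(ceiling(min(px, x1)), floor(max(px, x1))) - px) / du else numeric(0)
      ty <- if (dv != 0) (seq(ceiling(min(py, y1)), floor(max(py, y1))) - py) / dv else numeric(0)
      ts <- sort(unique(pmin(pmax(c(tx, ty), 0), 1)))
      ts <- ts[ts > 1e-12]
      if (length(ts) == 0 || ts[length(ts)] < 1) ts <- c(ts, 1)
      t_prev <- 0
      for (t in ts) {
        qx <- px + t * du; qy <- py + t * dv
        acc <- acc + (t - t_prev) * sqrt(du^2 + dv^2)
        tm <- (t_prev + t) / 2
        mi <- floor(px + tm * du); mj <- floor(py + tm * dv)
        if (mi != ci || mj != cj) {
          # entered a new cell at the previous crossing: close the open
          # pass at that boundary point and start the next one there
          bx <- px + t_prev * du; by <- py + t_prev * dv
          acc <- acc - (t - t_prev) * sqrt(du^2 + dv^2)
          close_pass(bx, by)
          ci <- mi; cj <- mj; ex <- bx; ey <- by
          acc <- (t - t_prev) * sqrt(du^2 + dv^2)
        }
        t_prev <- t
      }
      px <- x1; py <- y1
    }
    close_pass(px, py)
  }
  data.frame(i = res_i, j = res_j, sinuosity = res_v)
}

#' Geographically weighted sinuosity
#'
#' Out-of-camp travel is segmented by the camp raster: each traversal of
#' a cell ("pass") is scored as in-cell path length over the
#' entry-to-exit chord, and a cell's value for a track is the mean over
#' that track's passes. Population statistics (mean and 99th percentile
#' over all cell values of all tracks) are computed once per run; a
#' track's cell is counted `high` if its value strictly exceeds the
#' population mean and `very_high` if it strictly exceeds the 99th
#' percentile.
#'
#' @param ptracks list of annotated `cpf_ptrack`s (one run).
#' @param grid a [grid_spec()]; defaults to the first track's camp grid.
#' @param eps pass chord floor in metres.
#' @return list with `population` (`mean`, `p99`, `n_cells`),
#'   `per_track` (data frame `person_id`, `date`, `n_cells`, `n_high`,
#'   `n_very_high`) and `cells` (per-track per-cell mean values).
#' @export
gw_sinuosity <- function(ptracks, grid = ptracks[[1]]$camp$grid, eps = 1) {
  if (inherits(ptracks, "cpf_ptrack")) ptracks <- list(ptracks)
  per <- lapply(ptracks, function(pt) {
    ps <- cell_passes(pt, grid, eps)
    if (nrow(ps) == 0)
      return(data.frame(person_id = character(0), date = as.Date(character(0)),
                        i = integer(0), j = integer(0), value = numeric(0)))
    agg <- stats::aggregate(sinuosity ~ i + j, data = ps, FUN = mean)
    data.frame(person_id = pt$person_id, date = pt$date,
               i = agg$i, j = agg$j, value = agg$sinuosity,
               stringsAsFactors = FALSE)
  })
  cells <- do.call(rbind, per)
  if (is.null(cells) || nrow(cells) == 0)
    return(list(population = list(mean = NA_real_, p99 = NA_real_, n_cells = 0L),
                per_track = data.frame(), cells = data.frame()))
  pop_mean <- mean(cells$value)
  pop_p99 <- stats::quantile(cells$value, 0.99, names = FALSE)
  per_track <- do.call(rbind, lapply(per, function(d) {
    if (nrow(d) == 0) return(NULL)
    data.frame(person_id = d$person_id[1], date = d$date[1],
               n_cells = nrow(d),
               n_high = sum(d$value > pop_mean),
               n_very_high = sum(d$value > pop_p99),
               stringsAsFactors = FALSE)
  }))
  list(population = list(mean = pop_mean, p99 = pop_p99,
                         n_cells = nrow(cells)),
       per_track = per_track, cells = cells)
}
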