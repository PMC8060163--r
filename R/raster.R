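# Raster measures of land visitation. Every track is overlaid on a grid
# of square cells (default 10 m x 10 m, area A = 100 m2) anchored at the
# camp centroid; the set of cells a track intersects is the basis of
# daily land visited, cumulative land explored and gender segregation.

cell_key <- function(i, j) paste(i, j, sep = ",")

new_cellset <- function(i, j, grid, owner = NULL) {
  if (length(i)) {
    k <- cell_key(i, j)
    keep <- !duplicated(k)
    i <- i[keep]; j <- j[keep]
  }
  structure(data.frame(i = as.integer(i), j = as.integer(j)),
            class = c("cpf_cellset", "data.frame"), grid = grid, owner = owner)
}

#' @export
print.cpf_cellset <- function(x, ...) {
  g <- attr(x, "grid")
  cat(sprintf("<cpf_cellset> %d cells of %g m (%.0f m2 visited)\n",
              nrow(x), g$cell_size, nrow(x) * g$cell_size^2))
  invisible(x)
}

# Supercover of one segment in cell units (origin subtracted, divided by
# cell size): every cell whose closed square the segment intersects,
# corner touches included. Returns an integer matrix of (i, j).
segment_supercover <- function(u0, v0, u1, v1) {
  c0 <- c(floor(u0), floor(v0)); c1 <- c(floor(u1), floor(v1))
  if (all(c0 == c1)) return(matrix(c0, ncol = 2))
  du <- u1 - u0; dv <- v1 - v0
  tx <- if (du != 0) {
    ks <- seq(ceiling(min(u0, u1)), floor(max(u0, u1)))
    (ks - u0) / du
  } else numeric(0)
  ty <- if (dv != 0) {
    ks <- seq(ceiling(min(v0, v1)), floor(max(v0, v1)))
    (ks - v0) / dv
  } else numeric(0)
  ts <- sort(unique(c(0, pmin(pmax(c(tx, ty), 0), 1), 1)))
  tm <- (ts[-1] + ts[-length(ts)]) / 2
  cells <- cbind(floor(u0 + tm * du), floor(v0 + tm * dv))
  cells <- rbind(cells, c0, c1)
  # a crossing where x and y boundaries coincide is a lattice-corner
  # touch: the two diagonal cells also intersect the segment there
  if (length(tx) && length(ty)) {
    corner <- tx[vapply(tx, function(t) any(abs(ty - t) < 1e-12), logical(1))]
    for (t in corner) {
      cu <- round(u0 + t * du); cv <- round(v0 + t * dv)
      cells <- rbind(cells, cbind(cu + c(-1, -1, 0, 0), cv + c(-1, 0, -1, 0)))
    }
  }
  cells
}

#' Grid cells traversed by a track
#'
#' Supercover rasterisation: for every consecutive fix pair, every cell
#' whose closed square the straight segment intersects is collected,
#' corner touches included. Cells are half-open squares indexed from the
#' grid origin, so each point belongs to exactly one cell.
#'
#' @param ptrack a `cpf_ptrack` (or anything with `x`/`y` fields).
#' @param grid a [grid_spec()]; defaults to the camp's grid.
#' @return a `cpf_cellset` (data frame of unique cell indices `i`, `j`).
#' @export
cells_traversed <- function(ptrack, grid = ptrack$camp$grid) {
  s <- grid$cell_size
  u <- (ptrack$x - grid$origin[1]) / s
  v <- (ptrack$y - grid$origin[2]) / s
  n <- length(u)
  owner <- list(person_id = ptrack$person_id, date = ptrack$date)
  if (n == 0) return(new_cellset(integer(0), integer(0), grid, owner))
  fi <- floor(u); fj <- floor(v)
  if (n == 1) return(new_cellset(fi, fj, grid, owner))
  # segments staying inside one cell contribute just that cell; only
  # boundary-crossing segments need the full traversal
  same <- fi[-n] == fi[-1] & fj[-n] == fj[-1]
  parts <- list(cbind(fi, fj))
  for (k in which(!same))
    parts[[length(parts) + 1L]] <-
      segment_supercover(u[k], v[k], u[k + 1], v[k + 1])
  cells <- do.call(rbind, parts)
  new_cellset(cells[, 1], cells[, 2], grid, owner)
}

#' Daily land visited
#'
#' Number of unique cells a day's track intersected times the cell area
#' A (in m2): with the default 10 m grid, 50 cells is 5,000 m2.
#'
#' @param cellset a `cpf_cellset`.
#' @return square metres.
#' @export
daily_land_visited <- function(cellset) {
  nrow(cellset) * attr(cellset, "grid")$cell_size^2
}

#' Cumulative land explored across days
#'
#' Value at day i is the area of the union of the cell sets of days 1
#' through i -- non-decreasing by construction, and bounded above by the
#' sum of daily visits.
#'
#' @param cellsets list of `cpf_cellset` in day order, sharing one grid.
#' @return numeric vector of square metres, one value per day.
#' @export
cumulative_land_explored <- function(cellsets) {
  if (length(cellsets) == 0) return(numeric(0))
  sizes <- vapply(cellsets, function(cs) attr(cs, "grid")$cell_size, numeric(1))
  if (length(unique(sizes)) != 1)
    stop("all cell sets must share one grid")
  A <- sizes[1]^2
  seen <- character(0)
  out <- numeric(length(cellsets))
  for (k in seq_along(cellsets)) {
    seen <- union(seen, cell_key(cellsets[[k]]$i, cellsets[[k]]$j))
    out[k] <- length(seen) * A
  }
  out
}

#' Geographic segregation of visited land by gender
#'
#' Unions the cells visited by male and by female trackees and
#' intersects them: land visited by both genders is land visited by at
#' least one man and one woman. Cell-count conservation is exact:
#' male-only + female-only + both = total.
#'
#' @param cellsets list of `cpf_cellset` whose owners appear in `persons`.
#' @param persons person metadata (see [read_persons_csv()]).
#' @param camp_id camp identifier for the summary row.
#' @param year observation year.
#' @return object of class `cpf_segregation`: areas in km2, the
#'   male:female area ratio (`NA` when no female cells) and the overlap
#'   percentage of total.
#' @export
gender_segregation <- function(cellsets, persons, camp_id = NA, year = NA) {
  gender_of <- stats::setNames(persons$gender, persons$person_id)
  keys <- list(male = character(0), female = character(0))
  for (cs in cellsets) {
    pid <- attr(cs, "owner")$person_id
    g <- gender_of[[pid]]
    if (is.null(g) || is.na(g)) stop("no gender for person ", pid)
    keys[[g]] <- union(keys[[g]], cell_key(cs$i, cs$j))
  }
  if (length(keys$male) == 0 || length(keys$female) == 0)
    stop("need at least one track per gender; gender-imbalanced camps are excluded")
  A_km2 <- (attr(cellsets[[1]], "grid")$cell_size^2) / 1e6
  n_male <- length(keys$male); n_female <- length(keys$female)
  n_both <- length(intersect(keys$male, keys$female))
  n_total <- n_male + n_female - n_both
  structure(list(
    camp_id = camp_id, year = year,
    total_km2 = n_total * A_km2,
    male_km2 = n_male * A_km2,
    female_km2 = n_female * A_km2,
    both_km2 = n_both * A_km2,
    male_female_ratio = if (n_female > 0) n_male / n_female else NA_real_,
    overlap_pct = 100 * n_both / n_total
  ), class = "cpf_segregation")
}

#' @export
print.cpf_segregation <- function(x, ...) {
  cat(sprintf("<cpf_segregation> camp %s: total %.1f km2, male %.1f, female %.1f (ratio %.1f), both %.1f km2 (%.1f%% of total)\n",
              x$camp_id, x$total_km2, x$male_km2, x$female_km2,
              x$male_female_ratio, x$both_km2, x$overlap_pct))
  invisible(x)
}

#' Minimum convex polygon home-range area
#'
#' The conventional MCP estimate: discard the `ceiling((1 - fraction) *
#' n)` points farthest from the points' centroid (arithmetic mean) and
#' take the convex hull of the rest. With the default `fraction = 0.95`
#' this is the familiar 95 percent MCP.
#'
#' @param x,y planar coordinates in metres.
#' @param fraction fraction of points the polygon must encompass.
#' @return list with `polygon` (two-column matrix, hull vertices) and
#'   `area_km2`. Collinear points give area 0 with a warning.
#' @export
mcp_area <- function(x, y, fraction = 0.95) {
  n <- length(x)
  stopifnot(n == length(y))
  if (n < 5) stop("need at least 5 points for an MCP")
  ndrop <- ceiling(round((1 - fraction) * n, 9))
  if (ndrop > 0) {
    d <- sqrt((x - mean(x))^2 + (y - mean(y))^2)
    keep <- order(d)[seq_len(n - ndrop)]
    x <- x[keep]; y <- y[keep]
  }
  h <- grDevices::chull(x, y)
  poly <- cbind(x[h], y[h])
  a <- polygon_area(poly)
  if (a == 0) warning("all retained points are collinear; degenerate hull with zero area")
  list(polygon = poly, area_km2 = a / 1e6)
}
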