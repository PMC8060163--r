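# Interindividual proximity while travelling out of camp: a stratified
# random sample of out-of-camp fixes (at most 100 per person-day), each
# annotated with the straight-line distance to the nearest neighbour
# among campmates with a GPS fix within +/- 60 s, and whether that
# neighbour was within 5 m.

#' Draw the per-track sociality sample
#'
#' Uniform sample without replacement of `n` out-of-camp fix indices;
#' when fewer than `n` out-of-camp fixes exist, all of them are taken.
#'
#' @param ptrack a `cpf_ptrack` with `in_camp` labels.
#' @param n sample size cap (default 100).
#' @return integer vector of fix indices (sorted); empty when the track
#'   never leaves camp.
#' @export
draw_sociality_sample <- function(ptrack, n = 100) {
  out <- which(!ptrack$in_camp)
  if (length(out) <= n) return(out)
  sort(sample(out, n))
}

# For a vector of sample instants, the temporally closest fix of one
# other track within the window; returns distances (NA when no fix
# qualifies).
closest_fix_distance <- function(ts, xs, ys, other, window = 60) {
  to <- other$t
  idx <- findInterval(ts, to)
  lo <- pmax(idx, 1L); hi <- pmin(idx + 1L, length(to))
  pick <- ifelse(abs(to[lo] - ts) <= abs(to[hi] - ts), lo, hi)
  ok <- abs(to[pick] - ts) <= window
  d <- rep(NA_real_, length(ts))
  d[ok] <- sqrt((other$x[pick[ok]] - xs[ok])^2 + (other$y[pick[ok]] - ys[ok])^2)
  d
}

#' Nearest neighbour of one sampled fix
#'
#' For each other individual, their temporally closest fix within
#' `window` seconds of the sample instant contributes a candidate
#' distance; the nearest-neighbour distance is the minimum over
#' individuals and `n_concurrent` counts the individuals contributing.
#'
#' @param ptrack the sampled individual's `cpf_ptrack`.
#' @param index fix index of the sample point.
#' @param others list of other individuals' `cpf_ptrack`s (same camp
#'   frame).
#' @param window half-width of the temporal window in seconds.
#' @return list with `nn_distance` (`NA` when no individual has a
#'   qualifying fix) and `n_concurrent`.
#' @export
nearest_neighbour <- function(ptrack, index, others, window = 60) {
  ds <- vapply(others, function(o)
    closest_fix_distance(ptrack$t[index], ptrack$x[index], ptrack$y[index],
                         o, window), numeric(1))
  ok <- !is.na(ds)
  list(nn_distance = if (any(ok)) min(ds[ok]) else NA_real_,
       n_concurrent = sum(ok))
}

#' Build the sociality table for a set of co-tracked person-days
#'
#' For every track, draws the out-of-camp sociality sample and annotates
#' each sampled fix with its distance from camp, nearest-neighbour
#' distance among all other individuals (of either gender) tracked the
#' same day, the within-5 m indicator (inclusive boundary), and the
#' number of individuals with a concurrent fix.
#'
#' @param ptracks list of annotated `cpf_ptrack`s sharing a camp.
#' @param persons person metadata (see [read_persons_csv()]).
#' @param n per-track sample cap (default 100).
#' @param window temporal window half-width in seconds.
#' @param proximity_m the "close proximity" threshold (default 5 m,
#'   decided as `<=`).
#' @param seed optional seed for the sample draws.
#' @return data frame with one row per sampled fix: `person_id`,
#'   `gender`, `age`, `timestamp`, `dist_from_camp_m`, `nn_dist_m`,
#'   `within_5m`, `n_concurrent`.
#' @export
sociality_table <- function(ptracks, persons, n = 100, window = 60,
                            proximity_m = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  meta <- persons[match(vapply(ptracks, `[[`, "", "person_id"),
                        persons$person_id), ]
  dates <- vapply(ptracks, function(p) as.character(p$date), "")
  rows <- list()
  for (k in seq_along(ptracks)) {
    pt <- ptracks[[k]]
    idx <- draw_sociality_sample(pt, n)
    if (length(idx) == 0) next
    same_day <- which(dates == dates[k] &
                        seq_along(ptracks) != k &
                        vapply(ptracks, `[[`, "", "camp_id") == pt$camp_id)
    nn <- rep(NA_real_, length(idx))
    ncc <- integer(length(idx))
    for (o in same_day) {
      d <- closest_fix_distance(pt$t[idx], pt$x[idx], pt$y[idx],
                                ptracks[[o]], window)
      ok <- !is.na(d)
      ncc[ok] <- ncc[ok] + 1L
      nn[ok] <- pmin(nn[ok], d[ok], na.rm = TRUE)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      person_id = pt$person_id, gender = meta$gender[k], age = meta$age[k],
      timestamp = as.POSIXct(pt$t[idx], origin = "1970-01-01", tz = "UTC"),
      dist_from_camp_m = pt$dist_from_camp[idx],
      nn_dist_m = nn,
      within_5m = ifelse(is.na(nn), NA, nn <= proximity_m),
      n_concurrent = ncc, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(person_id = character(0), gender = character(0),
                      age = numeric(0), timestamp = as.POSIXct(character(0)),
                      dist_from_camp_m = numeric(0), nn_dist_m = numeric(0),
                      within_5m = logical(0), n_concurrent = integer(0)))
  do.call(rbind, rows)
}

#' Empirical proximity probability by distance from camp
#'
#' Per gender, bins the sociality sample by distance from camp and
#' reports the empirical probability of being within 5 m of the nearest
#' neighbour with its binomial standard error `sqrt(p (1 - p) / n)` --
#' a descriptive companion to smooth model fits of the same quantity.
#'
#' @param soc a [sociality_table()] data frame.
#' @param bin_width bin width in metres (default 1000).
#' @return data frame: `gender`, `bin_lo_m`, `bin_hi_m`, `n`, `p`,
#'   `se`. Rows with no non-missing samples are omitted.
#' @export
proximity_by_distance_curve <- function(soc, bin_width = 1000) {
  soc <- soc[!is.na(soc$within_5m), , drop = FALSE]
  if (nrow(soc) == 0)
    return(data.frame(gender = character(0), bin_lo_m = numeric(0),
                      bin_hi_m = numeric(0), n = integer(0),
                      p = numeric(0), se = numeric(0)))
  bin <- floor(soc$dist_from_camp_m / bin_width)
  out <- do.call(rbind, lapply(split(soc, list(soc$gender, bin), drop = TRUE),
    function(d) {
      b <- floor(d$dist_from_camp_m[1] / bin_width)
      p <- mean(d$within_5m)
      data.frame(gender = d$gender[1], bin_lo_m = b * bin_width,
                 bin_hi_m = (b + 1) * bin_width, n = nrow(d), p = p,
                 se = sqrt(p * (1 - p) / nrow(d)),
                 stringsAsFactors = FALSE)
    }))
  out <- out[order(out$gender, out$bin_lo_m), ]
  rownames(out) <- NULL
  out
}
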