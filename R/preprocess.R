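# Track cleaning and annotation: projection to a camp-centred planar
# frame, speed filtering, vehicle-day exclusion, resampling to an even
# 5 s interval, in/out-of-camp labelling, the eight-hour inclusion rule,
# daily distance, and extraction of each day's principal out-of-camp bout.

new_ptrack <- function(track, x, y, t, camp,
                       in_camp = rep(NA, length(x)),
                       gap_filled = rep(FALSE, length(x))) {
  structure(list(
    person_id = track$person_id, camp_id = track$camp_id, date = track$date,
    t = t, x = x, y = y,
    in_camp = in_camp, gap_filled = gap_filled,
    dist_from_camp = sqrt(x^2 + y^2),
    camp = camp
  ), class = "cpf_ptrack")
}

#' @export
print.cpf_ptrack <- function(x, ...) {
  cat(sprintf("<cpf_ptrack> person %s, %s: %d fixes, %.1f km travelled, max %.0f m from camp\n",
              x$person_id, format(x$date), length(x$t),
              path_length(x$x, x$y) / 1000,
              if (length(x$t)) max(x$dist_from_camp) else 0))
  invisible(x)
}

#' @export
length.cpf_ptrack <- function(x) length(x$t)

#' Project a track into the camp-centred planar frame
#'
#' Equirectangular projection about the camp centroid (see
#' [local_project()]); the centroid maps to `(0, 0)` and per-point
#' distance from camp is the planar distance to the origin.
#'
#' @param track a [cpf_track].
#' @param camp a [camp_context()].
#' @param max_extent_m refuse points farther than this from the centroid
#'   (projection validity guard; default 200 km).
#' @return object of class `cpf_ptrack`.
#' @export
project_to_local <- function(track, camp, max_extent_m = 2e5) {
  p <- local_project(track$lon, track$lat, camp$centroid)
  d <- sqrt(p$x^2 + p$y^2)
  if (any(d > max_extent_m))
    stop(sprintf("track point %d is %.0f km from camp; beyond the %.0f km projection validity bound",
                 which.max(d), max(d) / 1000, max_extent_m / 1000))
  new_ptrack(track, p$x, p$y, as.numeric(track$time), camp)
}

# Speed of each fix implied by each neighbour, as a two-column matrix
# (to previous, to next); NA at the ends.
neighbour_speeds <- function(x, y, t) {
  n <- length(x)
  dt <- diff(t); dl <- seg_lengths(x, y)
  sp <- ifelse(dt > 0, dl / dt, Inf * (dl > 0))
  cbind(prev = c(NA, sp), nxt = c(sp, NA))
}

#' Remove spatially errant fixes by speed filtering
#'
#' Two passes, mirroring filtering by maximum and by modal movement
#' speed. First, any fix whose implied speed from *both* neighbours
#' exceeds `max_speed` is removed, iterating to a fixed point (a single
#' teleported fix implies impossible speed on both sides; its honest
#' neighbours do not). Second, the modal movement speed is estimated as
#' the midpoint of the most populated 0.1 m/s bin among moving fixes
#' (speed above `moving_floor`), and fixes faster than
#' `modal_multiplier` times the mode from both neighbours are removed.
#'
#' @param ptrack a `cpf_ptrack`.
#' @param max_speed hard ceiling in m/s (default 20 km/h, a generous
#'   pedestrian bound).
#' @param modal_multiplier multiplier on the modal moving speed.
#' @param moving_floor m/s below which a fix is considered stationary
#'   when estimating the mode.
#' @return filtered `cpf_ptrack`; attribute `"removed"` counts removed
#'   fixes. More than 10 percent removed warns; more than 50 percent is
#'   an error (track unusable).
#' @export
filter_speed <- function(ptrack, max_speed = 20 / 3.6, modal_multiplier = 10,
                         moving_floor = 0.3) {
  n0 <- length(ptrack$t)
  if (n0 < 3) return(ptrack)
  x <- ptrack$x; y <- ptrack$y; t <- ptrack$t
  repeat {
    sp <- neighbour_speeds(x, y, t)
    drop <- which(sp[, 1] > max_speed & sp[, 2] > max_speed)
    if (length(drop) == 0) break
    x <- x[-drop]; y <- y[-drop]; t <- t[-drop]
    if (length(x) < 3) break
  }
  if (length(x) >= 3) {
    sp <- neighbour_speeds(x, y, t)
    spmin <- pmin(sp[, 1], sp[, 2], na.rm = TRUE)
    moving <- spmin[is.finite(spmin) & spmin >= moving_floor]
    if (length(moving) > 0) {
      bins <- floor(moving / 0.1)
      mode_bin <- as.numeric(names(which.max(table(bins))))
      modal_speed <- (mode_bin + 0.5) * 0.1
      thr <- modal_multiplier * modal_speed
      sp <- neighbour_speeds(x, y, t)
      drop <- which(sp[, 1] > thr & sp[, 2] > thr)
      if (length(drop) > 0) {
        x <- x[-drop]; y <- y[-drop]; t <- t[-drop]
      }
    }
  }
  removed <- n0 - length(x)
  if (removed > 0.5 * n0)
    stop(sprintf("speed filter removed %d of %d fixes; track unusable", removed, n0))
  if (removed > 0.1 * n0)
    warning(sprintf("speed filter removed %d of %d fixes (%.1f%%)",
                    removed, n0, 100 * removed / n0))
  keep <- match(t, ptrack$t)
  out <- new_ptrack(ptrack, x, y, t, ptrack$camp,
                    in_camp = ptrack$in_camp[keep],
                    gap_filled = ptrack$gap_filled[keep])
  attr(out, "removed") <- removed
  out
}

#' Decide whether a person-day is contaminated by vehicle travel
#'
#' Person-days containing sustained travel faster than a pedestrian can
#' manage (motorcycle or bicycle rides) are dropped wholesale so that
#' every analysed day is pedestrian travel only.
#'
#' @param ptrack a `cpf_ptrack` (ideally resampled).
#' @param speed_threshold m/s above which travel is considered vehicular
#'   (default 3.5 m/s, 12.6 km/h).
#' @param min_duration seconds of continuous supra-threshold travel that
#'   triggers the drop (default 120 s; short running bursts survive).
#' @return `TRUE` to keep the day, `FALSE` to drop it; attribute
#'   `"evidence"` gives the longest supra-threshold run in seconds.
#' @export
filter_vehicle_day <- function(ptrack, speed_threshold = 3.5, min_duration = 120) {
  n <- length(ptrack$t)
  if (n < 2) return(structure(TRUE, evidence = 0))
  dt <- diff(ptrack$t)
  sp <- ifelse(dt > 0, seg_lengths(ptrack$x, ptrack$y) / dt, 0)
  fast <- sp > speed_threshold
  longest <- 0
  if (any(fast)) {
    r <- rle(fast)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    durs <- vapply(which(r$values), function(k)
      sum(dt[starts[k]:ends[k]]), numeric(1))
    longest <- max(durs)
  }
  structure(longest <= min_duration, evidence = longest)
}

#' Resample a track to an even time grid by linear interpolation
#'
#' Positions are linearly interpolated onto the grid `t0, t0 + interval,
#' ...` up to the last recorded instant; there is no extrapolation.
#' Output points that fall strictly inside a recording gap longer than
#' `max_gap` are bridged but flagged `gap_filled`, so shape statistics
#' can exclude them while distance totals keep them.
#'
#' @param ptrack a `cpf_ptrack`.
#' @param interval grid spacing in seconds (default 5).
#' @param max_gap seconds; input gaps longer than this mark interpolated
#'   points as gap-filled (default 300).
#' @return resampled `cpf_ptrack`.
#' @export
resample_5s <- function(ptrack, interval = 5, max_gap = 300) {
  t <- ptrack$t
  if (length(t) < 2) return(ptrack)
  tg <- seq(t[1], t[length(t)], by = interval)
  x <- stats::approx(t, ptrack$x, xout = tg)$y
  y <- stats::approx(t, ptrack$y, xout = tg)$y
  idx <- findInterval(tg, t)
  idx2 <- pmin(idx + 1L, length(t))
  in_gap <- (t[idx2] - t[idx]) > max_gap & tg > t[idx] & tg < t[idx2]
  new_ptrack(ptrack, x, y, tg, ptrack$camp, gap_filled = in_gap)
}

#' Label fixes as in or out of camp
#'
#' Even-odd point-in-polygon test against the camp boundary; fixes on
#' the boundary count as in camp.
#'
#' @param ptrack a `cpf_ptrack`.
#' @param camp a [camp_context()]; defaults to the one the track was
#'   projected with.
#' @return `cpf_ptrack` with the `in_camp` labels set.
#' @export
classify_in_camp <- function(ptrack, camp = ptrack$camp) {
  ptrack$in_camp <- point_in_polygon(ptrack$x, ptrack$y, camp$boundary_xy)
  ptrack
}

#' Keep only tracks recorded for at least a minimum span
#'
#' The inclusion rule compares the recorded span (last minus first
#' timestamp) against `min_hours`; a span of exactly `min_hours` is
#' included.
#'
#' @param tracks list of [cpf_track] or `cpf_ptrack` objects.
#' @param min_hours minimum recorded span (default 8).
#' @return filtered list; attribute `"excluded"` counts dropped tracks.
#' @export
apply_inclusion <- function(tracks, min_hours = 8) {
  span <- vapply(tracks, function(tr) {
    tt <- if (inherits(tr, "cpf_ptrack")) tr$t else as.numeric(tr$time)
    if (length(tt) < 2) 0 else (tt[length(tt)] - tt[1]) / 3600
  }, numeric(1))
  keep <- span >= min_hours
  structure(tracks[keep], excluded = sum(!keep))
}

#' Total distance travelled in a day
#'
#' Sum of consecutive planar segment lengths over the whole day, in-camp
#' and out-of-camp travel alike (gap-bridged spans included).
#'
#' @param ptrack a resampled, speed-filtered `cpf_ptrack`.
#' @return kilometres.
#' @export
daily_distance <- function(ptrack) {
  if (length(ptrack$t) < 2) {
    warning("fewer than 2 fixes; daily distance reported as 0 km")
    return(0)
  }
  path_length(ptrack$x, ptrack$y) / 1000
}

#' Extract the day's principal out-of-camp bout
#'
#' A bout is a maximal run of out-of-camp fixes extended to its
#' bracketing in-camp fixes (the last fix before leaving and the first
#' after returning), so segment chords are camp-anchored. Bouts whose
#' maximum distance from the camp centroid is below `min_range` are
#' discarded; among the rest the bout with the greatest total path
#' length is selected and split at its apex -- the fix farthest from the
#' camp centroid, ties broken to the earliest.
#'
#' @param ptrack a `cpf_ptrack` with `in_camp` labels.
#' @param min_range metres the bout must reach from camp (default 500).
#' @return object of class `cpf_bout`, or `NULL` when no bout qualifies.
#' @export
extract_primary_bout <- function(ptrack, min_range = 500) {
  ic <- ptrack$in_camp
  if (any(is.na(ic))) stop("in_camp labels missing; run classify_in_camp() first")
  n <- length(ic)
  if (n < 3 || !any(!ic)) return(NULL)
  r <- rle(!ic)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  best <- NULL; best_len <- -Inf
  for (k in which(r$values)) {
    s <- max(starts[k] - 1L, 1L)       # last in-camp fix before departure
    e <- min(ends[k] + 1L, n)          # first in-camp fix after return
    rng <- s:e
    if (max(ptrack$dist_from_camp[rng]) < min_range) next
    len <- path_length(ptrack$x[rng], ptrack$y[rng])
    if (len > best_len) { best_len <- len; best <- c(s, e) }
  }
  if (is.null(best)) return(NULL)
  rng <- best[1]:best[2]
  apex <- rng[which.max(ptrack$dist_from_camp[rng])]
  ob <- best[1]:apex; ib <- apex:best[2]
  structure(list(
    person_id = ptrack$person_id, date = ptrack$date,
    start = best[1], apex = apex, end = best[2],
    outbound_path_length = path_length(ptrack$x[ob], ptrack$y[ob]),
    inbound_path_length = path_length(ptrack$x[ib], ptrack$y[ib]),
    outbound_chord = sqrt((ptrack$x[apex] - ptrack$x[best[1]])^2 +
                          (ptrack$y[apex] - ptrack$y[best[1]])^2),
    inbound_chord = sqrt((ptrack$x[best[2]] - ptrack$x[apex])^2 +
                         (ptrack$y[best[2]] - ptrack$y[apex])^2),
    apex_distance = ptrack$dist_from_camp[apex],
    gap_fraction = mean(ptrack$gap_filled[rng])
  ), class = "cpf_bout")
}

#' @export
print.cpf_bout <- function(x, ...) {
  cat(sprintf("<cpf_bout> person %s, %s: apex %.0f m from camp; out %.0f m / chord %.0f m, in %.0f m / chord %.0f m\n",
              x$person_id, format(x$date), x$apex_distance,
              x$outbound_path_length, x$outbound_chord,
              x$inbound_path_length, x$inbound_chord))
  invisible(x)
}

#' Run the full per-track preprocessing chain
#'
#' Project, speed-filter, resample to 5 s, and label in/out of camp.
#' Returns `NULL` when the vehicle filter drops the day.
#'
#' @param track a [cpf_track].
#' @param camp a [camp_context()].
#' @param interval resampling interval in seconds.
#' @param ... passed to [filter_speed()].
#' @return annotated `cpf_ptrack`, or `NULL` for a vehicle day.
#' @export
preprocess_track <- function(track, camp, interval = 5, ...) {
  pt <- project_to_local(track, camp)
  pt <- filter_speed(pt, ...)
  pt <- resample_5s(pt, interval = interval)
  if (!isTRUE(as.logical(filter_vehicle_day(pt)))) return(NULL)
  classify_in_camp(pt, camp)
}
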