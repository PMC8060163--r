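# Domain containers and file I/O for person-day GPS tracks, camp geometry
# and person metadata. A "track" is one individual's ordered fix sequence
# for one local calendar day -- the unit every downstream metric is
# computed on.

#' Construct a person-day track
#'
#' @param person_id,camp_id identifiers (coerced to character).
#' @param time `POSIXct` (UTC) timestamps, strictly increasing after
#'   duplicate removal.
#' @param lon,lat numeric degrees WGS84.
#' @param ele optional elevation in metres (carried, unused downstream).
#' @param sampling_mode `"fixed"` or `"adaptive"` logging.
#' @param tz_offset_hours local-time offset from UTC used to assign the
#'   calendar day (default +3, East Africa Time).
#' @param split_overnight flag marking tracks produced by splitting an
#'   overnight recording at local midnight.
#' @return object of class `cpf_track`.
#' @export
cpf_track <- function(person_id, camp_id, time, lon, lat, ele = NULL,
                      sampling_mode = c("fixed", "adaptive"),
                      tz_offset_hours = 3, split_overnight = FALSE) {
  sampling_mode <- match.arg(sampling_mode)
  stopifnot(inherits(time, "POSIXct"), length(time) == length(lon),
            length(lon) == length(lat))
  if (any(!is.finite(lon)) || any(lon < -180 | lon > 180))
    stop("longitudes must be finite and within [-180, 180]")
  if (any(!is.finite(lat)) || any(lat < -90 | lat > 90))
    stop("latitudes must be finite and within [-90, 90]")
  if (any(is.na(time))) stop("timestamps must all be finite")
  o <- order(time)
  time <- time[o]; lon <- lon[o]; lat <- lat[o]
  if (!is.null(ele)) ele <- ele[o]
  keep <- !duplicated(as.numeric(time)) # duplicate instants: keep first
  time <- time[keep]; lon <- lon[keep]; lat <- lat[keep]
  if (!is.null(ele)) ele <- ele[keep]
  structure(list(
    person_id = as.character(person_id)[1],
    camp_id = as.character(camp_id)[1],
    date = local_date(time[1], tz_offset_hours),
    time = time, lon = lon, lat = lat, ele = ele,
    sampling_mode = sampling_mode,
    tz_offset_hours = tz_offset_hours,
    split_overnight = isTRUE(split_overnight)
  ), class = "cpf_track")
}

#' @export
print.cpf_track <- function(x, ...) {
  cat(sprintf("<cpf_track> person %s, camp %s, %s: %d fixes spanning %.2f h\n",
              x$person_id, x$camp_id, format(x$date), length(x$time),
              track_span_hours(x)))
  invisible(x)
}

#' @export
length.cpf_track <- function(x) length(x$time)

#' Recorded span of a track in hours
#' @param track a `cpf_track`.
#' @return numeric hours between first and last fix.
#' @export
track_span_hours <- function(track) {
  if (length(track$time) < 2) return(0)
  as.numeric(difftime(track$time[length(track$time)], track$time[1],
                      units = "hours"))
}

# Local calendar day of a UTC instant under a fixed UTC offset.
local_date <- function(time, tz_offset_hours = 3) {
  as.Date(as.POSIXct(as.numeric(time) + tz_offset_hours * 3600,
                     origin = "1970-01-01", tz = "UTC"))
}

# Split a fix sequence at local midnight into one cpf_track per local day.
# Overnight recordings thus become several person-day tracks, each flagged.
split_person_days <- function(person_id, camp_id, time, lon, lat, ele = NULL,
                              sampling_mode = "fixed", tz_offset_hours = 3) {
  d <- local_date(time, tz_offset_hours)
  days <- unique(d)
  lapply(days, function(day) {
    sel <- d == day
    cpf_track(person_id, camp_id, time[sel], lon[sel], lat[sel],
              ele = if (is.null(ele)) NULL else ele[sel],
              sampling_mode = sampling_mode,
              tz_offset_hours = tz_offset_hours,
              split_overnight = length(days) > 1)
  })
}

#' Read tracks from a GPX 1.1 file
#'
#' Each `<trkseg>` becomes one or more person-day tracks (recordings that
#' span local midnight are split). The person id is taken from the `<trk>`
#' `<name>` element, falling back to the file name. Every point must carry
#' a `<time>` child; points sharing a timestamp are collapsed to the first.
#'
#' @param path GPX file.
#' @param camp_id camp identifier to attach (GPX has no standard slot).
#' @param tz_offset_hours local offset used for person-day assignment.
#' @return list of [cpf_track] objects.
#' @export
read_gpx <- function(path, camp_id = NA_character_, tz_offset_hours = 3) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  trks <- xml2::xml_find_all(doc, ".//trk")
  out <- list()
  for (trk in trks) {
    nm <- xml2::xml_text(xml2::xml_find_first(trk, "./name"))
    if (is.na(nm) || !nzchar(nm))
      nm <- sub("\\.gpx$", "", basename(path), ignore.case = TRUE)
    for (seg in xml2::xml_find_all(trk, ".//trkseg")) {
      pts <- xml2::xml_find_all(seg, "./trkpt")
      if (length(pts) == 0) next
      lat <- as.numeric(xml2::xml_attr(pts, "lat"))
      lon <- as.numeric(xml2::xml_attr(pts, "lon"))
      tstr <- xml2::xml_text(xml2::xml_find_first(pts, "./time"))
      bad <- which(is.na(tstr) | !nzchar(tstr))
      if (length(bad) > 0)
        stop(sprintf("GPX parse error in %s: track point %d has no <time>",
                     basename(path), bad[1]))
      tm <- parse_iso8601(tstr)
      if (anyNA(tm))
        stop(sprintf("GPX parse error in %s: unparseable <time> '%s'",
                     basename(path), tstr[which(is.na(tm))[1]]))
      elestr <- xml2::xml_text(xml2::xml_find_first(pts, "./ele"))
      ele <- if (all(is.na(elestr))) NULL else as.numeric(elestr)
      out <- c(out, split_person_days(nm, camp_id, tm, lon, lat, ele,
                                      tz_offset_hours = tz_offset_hours))
    }
  }
  out
}

#' Write tracks to a GPX 1.1 file
#'
#' One `<trk>` per track, named by person id, with per-point ISO-8601 UTC
#' times. Coordinates are written at 1e-7 degree precision so that a
#' write/read cycle is lossless at GPS accuracy.
#'
#' @param tracks a `cpf_track` or list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gpx <- function(tracks, path) {
  if (inherits(tracks, "cpf_track")) tracks <- list(tracks)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c('<?xml version="1.0" encoding="UTF-8"?>',
               '<gpx version="1.1" creator="cpfmove" xmlns="http://www.topografix.com/GPX/1/1">'),
             con)
  for (tr in tracks) {
    writeLines(sprintf("  <trk><name>%s</name><trkseg>", tr$person_id), con)
    ts <- format(tr$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    ele <- if (is.null(tr$ele)) rep("", length(ts))
           else sprintf("<ele>%.2f</ele>", tr$ele)
    writeLines(sprintf('    <trkpt lat="%.7f" lon="%.7f">%s<time>%s</time></trkpt>',
                       tr$lat, tr$lon, ele, ts), con)
    writeLines("  </trkseg></trk>", con)
  }
  writeLines("</gpx>", con)
  invisible(path)
}

# ISO-8601 'YYYY-MM-DDTHH:MM:SS[Z]' to POSIXct UTC; fractional seconds kept.
parse_iso8601 <- function(x) {
  x <- sub("Z$", "", x)
  as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
}

#' Read tracks from a CSV file
#'
#' Expected header: `person_id,camp_id,timestamp,lon,lat[,ele]` with
#' ISO-8601 UTC timestamps. Rows are grouped into person-day tracks by
#' person and local calendar day (UTC offset `tz_offset_hours`). Rows
#' with unparseable timestamps or out-of-range coordinates are rejected
#' individually and reported; if more than `max_bad_fraction` of rows are
#' bad the whole file is refused.
#'
#' @param path CSV file.
#' @param tz_offset_hours local offset for day assignment.
#' @param max_bad_fraction abort threshold for the rejected-row fraction.
#' @return list of [cpf_track]; attribute `"rejected"` holds a data frame
#'   of rejected rows (line numbers and reasons).
#' @export
read_tracks_csv <- function(path, tz_offset_hours = 3, max_bad_fraction = 0.01) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("person_id", "camp_id", "timestamp", "lon", "lat")
  if (!all(need %in% names(df)))
    stop("tracks CSV must have columns: ", paste(need, collapse = ", "))
  tm <- parse_iso8601(df$timestamp)
  lon <- suppressWarnings(as.numeric(df$lon))
  lat <- suppressWarnings(as.numeric(df$lat))
  reason <- rep(NA_character_, nrow(df))
  reason[is.na(tm)] <- "unparseable timestamp"
  reason[is.na(lon) | lon < -180 | lon > 180] <- "longitude out of range"
  reason[is.na(lat) | lat < -90 | lat > 90] <- "latitude out of range"
  bad <- !is.na(reason)
  rejected <- data.frame(line = which(bad) + 1L, reason = reason[bad],
                         stringsAsFactors = FALSE)
  if (nrow(df) > 0 && mean(bad) > max_bad_fraction)
    stop(sprintf("%.1f%% of rows are invalid (limit %.1f%%); first: line %d (%s)",
                 100 * mean(bad), 100 * max_bad_fraction,
                 rejected$line[1], rejected$reason[1]))
  df <- df[!bad, , drop = FALSE]
  tm <- tm[!bad]; lon <- lon[!bad]; lat <- lat[!bad]
  ele <- if ("ele" %in% names(df)) suppressWarnings(as.numeric(df$ele)) else NULL
  out <- list()
  for (pid in unique(df$person_id)) {
    sel <- df$person_id == pid
    out <- c(out, split_person_days(
      pid, df$camp_id[sel][1], tm[sel], lon[sel], lat[sel],
      ele = if (is.null(ele)) NULL else ele[sel],
      tz_offset_hours = tz_offset_hours))
  }
  attr(out, "rejected") <- rejected
  out
}

#' Write tracks to CSV (`person_id,camp_id,timestamp,lon,lat[,ele]`)
#' @param tracks a `cpf_track` or list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tracks_csv <- function(tracks, path) {
  if (inherits(tracks, "cpf_track")) tracks <- list(tracks)
  rows <- lapply(tracks, function(tr) {
    d <- data.frame(person_id = tr$person_id, camp_id = tr$camp_id,
                    timestamp = format(tr$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                    lon = sprintf("%.7f", tr$lon), lat = sprintf("%.7f", tr$lat),
                    stringsAsFactors = FALSE)
    if (!is.null(tr$ele)) d$ele <- sprintf("%.2f", tr$ele)
    d
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a person-metadata table
#'
#' Header: `person_id,gender,age,has_dependent_infant,camp_id`. Gender is
#' `male`/`female`; `has_dependent_infant` flags women caring for a
#' co-resident child aged two years or younger. The flag is only
#' meaningful for females; a set flag on a male row triggers a warning,
#' not an error.
#'
#' @param path CSV file.
#' @return data frame of person metadata.
#' @export
read_persons_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("person_id", "gender", "age", "has_dependent_infant", "camp_id")
  if (!all(need %in% names(df)))
    stop("persons CSV must have columns: ", paste(need, collapse = ", "))
  df$person_id <- as.character(df$person_id)
  df$gender <- tolower(df$gender)
  if (!all(df$gender %in% c("male", "female")))
    stop("gender must be 'male' or 'female'")
  df$age <- as.numeric(df$age)
  if (any(is.na(df$age) | df$age < 0 | df$age > 120))
    stop("ages must be within [0, 120]")
  df$has_dependent_infant <- as.logical(df$has_dependent_infant)
  if (any(df$has_dependent_infant & df$gender == "male"))
    warning("has_dependent_infant is set for one or more males; ",
            "the flag is interpreted for females only")
  df
}

#' Construct a camp context
#'
#' The camp context carries the boundary polygon (used to classify fixes
#' as in or out of camp), its area centroid (origin of the local planar
#' frame and anchor of the raster grid) and the grid specification.
#'
#' @param camp_id identifier.
#' @param year integer observation year.
#' @param boundary two-column matrix of `(lon, lat)` vertices of a simple
#'   polygon.
#' @param cell_size raster cell edge in metres (default 10, giving the
#'   100 m2 cells used for land-visitation measures).
#' @return object of class `cpf_camp`.
#' @export
camp_context <- function(camp_id, year = NA_integer_, boundary, cell_size = 10) {
  boundary <- as.matrix(boundary)
  stopifnot(ncol(boundary) == 2, nrow(boundary) >= 3)
  if (polygon_self_intersects(boundary))
    stop("camp boundary polygon is self-intersecting")
  # project about the vertex mean, take the area centroid there, unproject
  ref <- c(mean(boundary[, 1]), mean(boundary[, 2]))
  p <- local_project(boundary[, 1], boundary[, 2], ref)
  if (polygon_area(cbind(p$x, p$y)) < 1e-9)
    stop("camp boundary polygon is degenerate (zero area)")
  cen_xy <- polygon_centroid(cbind(p$x, p$y))
  cen <- local_unproject(cen_xy[1], cen_xy[2], ref)
  centroid <- c(cen$lon, cen$lat)
  pb <- local_project(boundary[, 1], boundary[, 2], centroid)
  structure(list(
    camp_id = as.character(camp_id)[1], year = year,
    boundary = boundary, centroid = centroid,
    boundary_xy = cbind(pb$x, pb$y),
    grid = grid_spec(cell_size = cell_size)
  ), class = "cpf_camp")
}

#' @export
print.cpf_camp <- function(x, ...) {
  cat(sprintf("<cpf_camp> %s (%s): %d boundary vertices, area %.3f ha, %g m grid\n",
              x$camp_id, ifelse(is.na(x$year), "year ?", x$year),
              nrow(x$boundary), polygon_area(x$boundary_xy) / 1e4,
              x$grid$cell_size))
  invisible(x)
}

#' Raster grid specification
#'
#' Cells are half-open squares `[ox + i*s, ox + (i+1)*s) x [oy + j*s,
#' oy + (j+1)*s)` in the camp-centred planar frame, anchored at the camp
#' centroid. Cell area `A = s^2` is the unit of all land measures.
#'
#' @param cell_size cell edge in metres.
#' @param origin planar `(x, y)` of the grid anchor.
#' @return object of class `cpf_grid`.
#' @export
grid_spec <- function(cell_size = 10, origin = c(0, 0)) {
  stopifnot(cell_size > 0)
  structure(list(cell_size = cell_size, origin = origin), class = "cpf_grid")
}

#' Read a camp boundary from GeoJSON
#'
#' Accepts a `Polygon` geometry, a `Feature` wrapping one, or a
#' `FeatureCollection` whose first feature does, with `camp_id` and
#' `year` properties.
#'
#' @param path GeoJSON file (RFC 7946).
#' @param cell_size raster cell edge in metres.
#' @return a [camp_context()] object.
#' @export
read_camp_geojson <- function(path, cell_size = 10) {
  g <- jsonlite::read_json(path)
  feat <- switch(g$type,
    FeatureCollection = g$features[[1]],
    Feature = g,
    Polygon = list(geometry = g, properties = list()),
    stop("unsupported GeoJSON type: ", g$type))
  if (feat$geometry$type != "Polygon")
    stop("camp geometry must be a Polygon, got ", feat$geometry$type)
  ring <- feat$geometry$coordinates[[1]]
  boundary <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
  props <- feat$properties
  camp_context(camp_id = props$camp_id %||% "camp",
               year = as.integer(props$year %||% NA),
               boundary = boundary, cell_size = cell_size)
}

#' Write a camp boundary to GeoJSON
#' @param camp a `cpf_camp`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_camp_geojson <- function(camp, path) {
  ring <- camp$boundary
  if (!all(ring[1, ] == ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
  obj <- list(type = "Feature",
              properties = list(camp_id = camp$camp_id, year = camp$year),
              geometry = list(type = "Polygon",
                              coordinates = list(lapply(seq_len(nrow(ring)),
                                function(i) as.list(unname(ring[i, ]))))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
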