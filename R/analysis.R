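# End-to-end driver: preprocess a set of person-day tracks against a
# camp, compute every movement metric, and return one object with
# print/summary/plot methods.

#' Run the full movement analysis on a set of tracks
#'
#' Applies the inclusion rule (recorded span of at least `min_hours`),
#' the per-track preprocessing chain (project, speed-filter, resample
#' to `interval` seconds, vehicle-day exclusion, in/out-of-camp
#' labelling), and computes per person-day daily distance, land
#' visited, cumulative land explored, bout sinuosity, geographically
#' weighted sinuosity, the sociality sample, gender segregation of the
#' visited landscape and 95 percent MCP areas by gender.
#'
#' @param tracks list of [cpf_track] objects.
#' @param camp a [camp_context()].
#' @param persons person metadata (see [read_persons_csv()]).
#' @param min_hours inclusion threshold on the recorded span.
#' @param interval resampling interval in seconds.
#' @param sociality_n per-track sociality sample cap.
#' @param seed seed for the sociality sample draws.
#' @param mcp_fraction fraction of fixes the MCPs must encompass.
#' @return object of class `cpf_analysis` with elements `per_day`
#'   (metrics data frame), `segregation`, `mcp` (per gender), `gw`
#'   (geographically weighted sinuosity), `sociality`, `proximity_curve`,
#'   `camp`, `persons`, and counts of excluded tracks.
#' @export
forage_analysis <- function(tracks, camp, persons, min_hours = 8,
                            interval = 5, sociality_n = 100, seed = 1,
                            mcp_fraction = 0.95) {
  included <- apply_inclusion(tracks, min_hours)
  n_short <- attr(included, "excluded")
  ptracks <- list()
  n_vehicle <- 0L
  for (tr in included) {
    pt <- preprocess_track(tr, camp, interval = interval)
    if (is.null(pt)) n_vehicle <- n_vehicle + 1L else
      ptracks[[length(ptracks) + 1L]] <- pt
  }
  if (length(ptracks) == 0) stop("no usable person-days after filtering")

  cellsets <- lapply(ptracks, cells_traversed)
  per_day <- do.call(rbind, lapply(seq_along(ptracks), function(k) {
    pt <- ptracks[[k]]
    bout <- extract_primary_bout(pt)
    sr <- bout_sinuosity(pt, bout)
    data.frame(person_id = pt$person_id, date = pt$date,
               daily_km = daily_distance(pt),
               daily_m2 = daily_land_visited(cellsets[[k]]),
               outbound = if (is.null(sr)) NA_real_ else sr$outbound,
               inbound = if (is.null(sr)) NA_real_ else sr$inbound,
               stringsAsFactors = FALSE)
  }))
  per_day$gender <- persons$gender[match(per_day$person_id, persons$person_id)]
  # cumulative exploration per person, in date order
  per_day$cumulative_m2 <- NA_real_
  per_day$day_index <- NA_integer_
  for (pid in unique(per_day$person_id)) {
    sel <- which(per_day$person_id == pid)
    sel <- sel[order(per_day$date[sel])]
    per_day$cumulative_m2[sel] <- cumulative_land_explored(cellsets[sel])
    per_day$day_index[sel] <- seq_along(sel)
  }

  seg <- if (length(unique(per_day$gender)) == 2)
    gender_segregation(cellsets, persons, camp$camp_id, camp$year) else NULL
  mcp <- lapply(stats::setNames(nm = unique(per_day$gender)), function(g) {
    ks <- which(per_day$gender == g)
    x <- unlist(lapply(ptracks[ks], `[[`, "x"))
    y <- unlist(lapply(ptracks[ks], `[[`, "y"))
    mcp_area(x, y, mcp_fraction)
  })
  gw <- gw_sinuosity(ptracks, camp$grid)
  soc <- sociality_table(ptracks, persons, n = sociality_n, seed = seed)
  structure(list(per_day = per_day, segregation = seg, mcp = mcp, gw = gw,
                 sociality = soc,
                 proximity_curve = proximity_by_distance_curve(soc),
                 camp = camp, persons = persons, ptracks = ptracks,
                 cellsets = cellsets,
                 n_excluded_short = n_short, n_excluded_vehicle = n_vehicle),
            class = "cpf_analysis")
}

#' @export
print.cpf_analysis <- function(x, ...) {
  cat(sprintf("<cpf_analysis> camp %s: %d person-days (%d excluded <8 h, %d vehicle days)\n",
              x$camp$camp_id, nrow(x$per_day), x$n_excluded_short,
              x$n_excluded_vehicle))
  for (g in unique(x$per_day$gender)) {
    sel <- x$per_day$gender == g
    cat(sprintf("  %-6s mean daily distance %5.1f km, mean daily land %6.0f m2, mean outbound sinuosity %s\n",
                g, mean(x$per_day$daily_km[sel]),
                mean(x$per_day$daily_m2[sel]),
                ifelse(all(is.na(x$per_day$outbound[sel])), "NA",
                       sprintf("%.2f", mean(x$per_day$outbound[sel], na.rm = TRUE)))))
  }
  if (!is.null(x$segregation)) print(x$segregation)
  invisible(x)
}

#' @export
summary.cpf_analysis <- function(object, ...) {
  pd <- object$per_day
  by_gender <- do.call(rbind, lapply(split(pd, pd$gender), function(d) {
    soc <- object$sociality
    soc <- soc[soc$gender == d$gender[1] & !is.na(soc$nn_dist_m), ]
    data.frame(gender = d$gender[1], n_person_days = nrow(d),
               mean_daily_km = mean(d$daily_km),
               mean_daily_m2 = mean(d$daily_m2),
               mean_outbound = mean(d$outbound, na.rm = TRUE),
               mean_inbound = mean(d$inbound, na.rm = TRUE),
               median_nn_m = if (nrow(soc)) stats::median(soc$nn_dist_m) else NA_real_,
               p_within_5m = if (nrow(soc)) mean(soc$within_5m) else NA_real_,
               mcp_km2 = object$mcp[[d$gender[1]]]$area_km2)
  }))
  rownames(by_gender) <- NULL
  out <- list(by_gender = by_gender, segregation = object$segregation,
              n_person_days = nrow(pd))
  class(out) <- "summary.cpf_analysis"
  out
}

#' @export
print.summary.cpf_analysis <- function(x, ...) {
  cat("Per-gender movement summary (", x$n_person_days, " person-days):\n", sep = "")
  print(x$by_gender, digits = 3)
  if (!is.null(x$segregation)) print(x$segregation)
  invisible(x)
}

#' Map of tracks, camp boundary and MCP home ranges
#'
#' @param x a `cpf_analysis`.
#' @param ... passed to [plot()].
#' @export
plot.cpf_analysis <- function(x, ...) {
  cols <- c(male = "#2166AC", female = "#B2182B")
  xs <- unlist(lapply(x$ptracks, `[[`, "x"))
  ys <- unlist(lapply(x$ptracks, `[[`, "y"))
  graphics::plot(NA, xlim = range(xs), ylim = range(ys), asp = 1,
                 xlab = "east (m)", ylab = "north (m)",
                 main = paste("Camp", x$camp$camp_id), ...)
  for (pt in x$ptracks) {
    g <- x$persons$gender[match(pt$person_id, x$persons$person_id)]
    graphics::lines(pt$x, pt$y, col = grDevices::adjustcolor(cols[[g]], 0.35))
  }
  for (g in names(x$mcp))
    graphics::polygon(x$mcp[[g]]$polygon, border = cols[[g]], lwd = 2)
  graphics::polygon(x$camp$boundary_xy, border = "black", lwd = 2)
  graphics::legend("topright", legend = names(cols), col = cols, lty = 1, bty = "n")
  invisible(x)
}
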