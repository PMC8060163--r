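# Synthetic central-place-forager GPS tracks. A person-day is built as
# dwell at a camp hearth, one out-and-back foray simulated as a biased
# random walk (von Mises headings aimed at a drawn apex, concentration
# kappa), an apex dwell, and a return walk, with autocorrelated GPS fix
# noise and occasional errant fixes layered on top. The generator's
# knobs map one-to-one onto the movement contrasts the pipeline
# measures: day range, path sinuosity, and party cohesion.

#' Draw von Mises random deviates
#'
#' Best-Fisher rejection sampler; `kappa = 0` gives the circular
#' uniform.
#'
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param kappa concentration (>= 0).
#' @return numeric vector of angles in `(-pi, pi]` around `mu`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 1e-8) return(((stats::runif(n) * 2 - 1) * pi) + mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- sign(u[3] - 0.5) * acos(pmin(1, pmax(-1, f)))
      i <- i + 1L
    }
  }
  mu + out
}

# Mean resultant length A(kappa) = I1(kappa)/I0(kappa): the expected
# per-step progress of a kappa-concentrated walk toward its target, so
# 1/A(kappa) is the expected sinuosity of the walk.
vm_mean_resultant <- function(kappa) {
  ifelse(kappa < 1e-8, 0,
         besselI(kappa, 1, expon.scaled = TRUE) /
           besselI(kappa, 0, expon.scaled = TRUE))
}

#' Forager movement profile
#'
#' @param gender `"male"` or `"female"`.
#' @param mean_day_range_km mean total distance walked per day.
#' @param sd_day_range_km between-day SD of the planned day range.
#' @param turning_concentration von Mises concentration `kappa` of step
#'   headings about the bearing to the current goal; low values give
#'   tortuous search-like travel, high values near-straight travel
#'   (expected sinuosity is `1 / (I1(k)/I0(k))`).
#' @param party_size individuals sharing a foray (1 = solitary).
#' @param party_spacing_m stationary SD of each member's smooth spatial
#'   offset from the shared path.
#' @param out_time_h mean device-recording span in hours.
#' @param speed_ms walking speed.
#' @return object of class `cpf_profile`.
#' @export
forager_profile <- function(gender, mean_day_range_km, sd_day_range_km = 0.18 * mean_day_range_km,
                            turning_concentration = 2, party_size = 1,
                            party_spacing_m = 0, out_time_h = 11.5,
                            speed_ms = 1.25) {
  stopifnot(mean_day_range_km > 0, turning_concentration >= 0,
            party_size >= 1, party_spacing_m >= 0, out_time_h > 0, speed_ms > 0)
  structure(list(gender = match.arg(gender, c("male", "female")),
                 mean_day_range_km = mean_day_range_km,
                 sd_day_range_km = sd_day_range_km,
                 turning_concentration = turning_concentration,
                 party_size = as.integer(party_size),
                 party_spacing_m = party_spacing_m,
                 out_time_h = out_time_h, speed_ms = speed_ms),
            class = "cpf_profile")
}

#' Default gendered movement profiles
#'
#' Encode the study conditions the simulator emulates: adult men
#' average ~14 km/day of tortuous, mostly solitary travel; adult women
#' ~8 km/day of straighter travel in cohesive parties a few metres
#' apart.
#'
#' @return named list with `male` and `female` [forager_profile()]s.
#' @export
default_profiles <- function() {
  list(
    male = forager_profile("male", mean_day_range_km = 14,
                           turning_concentration = 1.5,
                           party_size = 1, party_spacing_m = 0),
    female = forager_profile("female", mean_day_range_km = 8,
                             turning_concentration = 4,
                             party_size = 4, party_spacing_m = 2)
  )
}

#' Simulation configuration
#'
#' @param profiles named list of [forager_profile()]s (default
#'   [default_profiles()]).
#' @param n_per_gender individuals per gender.
#' @param n_days days of observation.
#' @param camp_radius_m radius of the auto-generated circular camp.
#' @param camp_lonlat geographic centre of the camp.
#' @param sample_interval fix interval in seconds.
#' @param adaptive emulate adaptive logging: thin fixes to one per 15 s
#'   while instantaneous speed is below 0.2 m/s.
#' @param fix_noise_sd stationary SD (m) of the AR(1) GPS error.
#' @param fix_noise_rho lag-one autocorrelation of the GPS error at the
#'   fix interval (GPS error drifts over minutes, so close to 1).
#' @param errant_fix_rate per-fix probability of replacement by a
#'   uniform draw in a 5 km disc (exercises the speed filter).
#' @param vehicle_days number of person-days to contaminate with a
#'   10-minute 8 m/s vehicle segment (exercises vehicle-day exclusion).
#' @param start_date first observation date.
#' @param seed integer master seed; per-person-day substreams are
#'   derived from it by stable hashing so each track is reproducible in
#'   isolation.
#' @return object of class `cpf_simconfig`.
#' @export
sim_config <- function(profiles = default_profiles(), n_per_gender = 10,
                       n_days = 5, camp_radius_m = 100,
                       camp_lonlat = c(35.0, -3.5), sample_interval = 5,
                       adaptive = FALSE, fix_noise_sd = 1.0,
                       fix_noise_rho = 0.998, errant_fix_rate = 5e-5,
                       vehicle_days = 0, start_date = as.Date("2020-07-01"),
                       seed = 1) {
  stopifnot(n_days >= 1, sample_interval > 0)
  structure(list(profiles = profiles, n_per_gender = n_per_gender,
                 n_days = n_days, camp_radius_m = camp_radius_m,
                 camp_lonlat = camp_lonlat, sample_interval = sample_interval,
                 adaptive = adaptive, fix_noise_sd = fix_noise_sd,
                 fix_noise_rho = fix_noise_rho,
                 errant_fix_rate = errant_fix_rate,
                 vehicle_days = vehicle_days, start_date = start_date,
                 seed = as.integer(seed)),
            class = "cpf_simconfig")
}

# Stable 31-bit string hash for per-person-day RNG substreams.
hash_seed <- function(seed, ...) {
  s <- paste(c(seed, ...), collapse = "|")
  h <- 0
  for (cc in utf8ToInt(s)) h <- (h * 31 + cc) %% 2147483647
  as.integer((h + as.numeric(seed) * 7919) %% 2147483647)
}

#' Build a circular camp polygon
#' @param camp_id identifier.
#' @param radius_m camp radius in metres.
#' @param lonlat geographic centre.
#' @param year observation year.
#' @param n_vertices polygon resolution.
#' @param cell_size raster cell edge for the camp grid.
#' @return a [camp_context()].
#' @export
make_circular_camp <- function(camp_id = "simcamp", radius_m = 100,
                               lonlat = c(35.0, -3.5), year = 2020,
                               n_vertices = 36, cell_size = 10) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  g <- local_unproject(radius_m * cos(th), radius_m * sin(th), lonlat)
  camp_context(camp_id, year, cbind(g$lon, g$lat), cell_size = cell_size)
}

# Biased walk from `from` until within one step of `to`: headings drawn
# von Mises about the bearing to the goal. Returns a matrix of positions
# (excluding the start point).
walk_toward <- function(from, to, step_len, kappa, max_steps = 200000) {
  pos <- from
  path <- matrix(NA_real_, nrow = max_steps, ncol = 2)
  k <- 0L
  while (k < max_steps) {
    d <- sqrt(sum((to - pos)^2))
    if (d <= step_len) break
    bearing <- atan2(to[2] - pos[2], to[1] - pos[1])
    h <- rvonmises(1, bearing, kappa)
    pos <- pos + step_len * c(cos(h), sin(h))
    k <- k + 1L
    path[k, ] <- pos
  }
  path[seq_len(k), , drop = FALSE]
}

# The noiseless planned day: positions at the fix interval plus phase
# bookkeeping. Uses the current RNG stream.
plan_person_day <- function(profile, camp, span_h, interval) {
  step_len <- profile$speed_ms * interval
  kap <- profile$turning_concentration
  # hearth: fixed point well inside the camp
  r_camp <- max(sqrt(rowSums(camp$boundary_xy^2)))
  hr <- 0.3 * r_camp * sqrt(stats::runif(1))
  ha <- stats::runif(1, 0, 2 * pi)
  hearth <- c(hr * cos(ha), hr * sin(ha))
  # planned walking budget and the apex that spends it: an out-and-back
  # kappa-walk covers ~ 2 * D / A(kappa), so D = L * A(kappa) / 2
  L <- -1
  while (L < 4 * r_camp)
    L <- stats::rnorm(1, profile$mean_day_range_km, profile$sd_day_range_km) * 1000
  D <- L * vm_mean_resultant(kap) / 2
  aa <- stats::runif(1, 0, 2 * pi)
  apex <- hearth + D * c(cos(aa), sin(aa))
  out_path <- walk_toward(hearth, apex, step_len, kap)
  in_path <- walk_toward(apex, hearth, step_len, kap)
  n_total <- max(2, round(span_h * 3600 / interval))
  n_walk <- nrow(out_path) + nrow(in_path) + 2L
  leftover <- max(0L, n_total - n_walk)
  n_pre <- round(0.35 * leftover)
  n_apex <- round(0.25 * leftover)
  n_post <- leftover - n_pre - n_apex
  xy <- rbind(
    matrix(hearth, n_pre, 2, byrow = TRUE),
    hearth, out_path,
    matrix(apex, n_apex, 2, byrow = TRUE),
    apex, in_path,
    matrix(hearth, n_post, 2, byrow = TRUE)
  )
  moving <- c(rep(FALSE, n_pre), TRUE, rep(TRUE, nrow(out_path)),
              rep(FALSE, n_apex), TRUE, rep(TRUE, nrow(in_path)),
              rep(FALSE, n_post))
  list(xy = xy, moving = moving, hearth = hearth, apex = apex,
       planned_range_m = L, apex_dist_m = sqrt(sum(apex^2)))
}

# Stationary AR(1) noise series, vectorised.
ar1_noise <- function(n, sd, rho) {
  if (sd <= 0 || n == 0) return(numeric(n))
  innov <- stats::rnorm(n, 0, sd * sqrt(1 - rho^2))
  innov[1] <- stats::rnorm(1, 0, sd)
  as.numeric(stats::filter(innov, rho, method = "recursive"))
}

# Layer GPS imperfections onto planned coordinates and build the track.
realize_track <- function(person_id, camp, xy, time, config) {
  n <- nrow(xy)
  x <- xy[, 1] + ar1_noise(n, config$fix_noise_sd, config$fix_noise_rho)
  y <- xy[, 2] + ar1_noise(n, config$fix_noise_sd, config$fix_noise_rho)
  err <- stats::runif(n) < config$errant_fix_rate
  if (any(err)) {
    m <- sum(err)
    rr <- 5000 * sqrt(stats::runif(m))
    th <- stats::runif(m, 0, 2 * pi)
    x[err] <- rr * cos(th); y[err] <- rr * sin(th)
  }
  mode <- "fixed"
  if (isTRUE(config$adaptive)) {
    sp <- c(Inf, seg_lengths(x, y) / diff(time))
    slow <- sp < 0.2
    keep <- !slow | (seq_len(n) %% round(15 / config$sample_interval) == 0L)
    keep[c(1, n)] <- TRUE
    x <- x[keep]; y <- y[keep]; time <- time[keep]
    mode <- "adaptive"
  }
  g <- local_unproject(x, y, camp$centroid)
  cpf_track(person_id, camp$camp_id, as.POSIXct(time, origin = "1970-01-01", tz = "UTC"),
            g$lon, g$lat, sampling_mode = mode)
}

#' Simulate one person-day track
#'
#' @param profile a [forager_profile()].
#' @param camp a [camp_context()].
#' @param date observation date.
#' @param config a [sim_config()] (noise and interval settings).
#' @param seed optional substream seed; when `NULL` the current RNG
#'   state is used.
#' @return a [cpf_track]; attribute `"truth"` records the noiseless
#'   realized day range, planned range and apex distance.
#' @export
simulate_person_day <- function(profile, camp, date = as.Date("2020-07-01"),
                                config = sim_config(), seed = NULL,
                                person_id = paste0(toupper(substr(profile$gender, 1, 1)), "01")) {
  if (!is.null(seed)) set.seed(seed)
  span_h <- min(13, max(9, stats::rnorm(1, profile$out_time_h, 1)))
  start <- as.numeric(as.POSIXct(paste(date, "04:45:00"), tz = "UTC")) +
    stats::rnorm(1, 0, 900)
  plan <- plan_person_day(profile, camp, span_h, config$sample_interval)
  time <- start + (seq_len(nrow(plan$xy)) - 1) * config$sample_interval
  tr <- realize_track(person_id, camp, plan$xy, time, config)
  attr(tr, "truth") <- data.frame(
    person_id = person_id, date = date, gender = profile$gender,
    true_day_range_km = path_length(plan$xy[, 1], plan$xy[, 2]) / 1000,
    planned_range_km = plan$planned_range_m / 1000,
    apex_dist_m = plan$apex_dist_m, party_size = 1L)
  tr
}

#' Simulate a party sharing one foray
#'
#' All members follow one planned path; each member's realized path is
#' the shared path plus a smooth AR(1) spatial offset with stationary SD
#' `party_spacing_m` that evolves only while the party is moving (the
#' party sits together during dwells). Timestamps are aligned across
#' members.
#'
#' @param profile a [forager_profile()] with `party_size >= 1`.
#' @param person_ids ids of the members (length = party size).
#' @param camp,date,config,seed as in [simulate_person_day()].
#' @return list of [cpf_track], one per member, each carrying a
#'   `"truth"` attribute.
#' @export
simulate_party <- function(profile, person_ids, camp,
                           date = as.Date("2020-07-01"),
                           config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- length(person_ids)
  span_h <- min(13, max(9, stats::rnorm(1, profile$out_time_h, 1)))
  start <- as.numeric(as.POSIXct(paste(date, "04:45:00"), tz = "UTC")) +
    stats::rnorm(1, 0, 900)
  plan <- plan_person_day(profile, camp, span_h, config$sample_interval)
  n <- nrow(plan$xy)
  time <- start + (seq_len(n) - 1) * config$sample_interval
  lapply(seq_len(m), function(k) {
    xy <- plan$xy
    if (profile$party_spacing_m > 0 && m > 1) {
      nm <- sum(plan$moving)
      ox <- oy <- numeric(n)
      ox[plan$moving] <- ar1_noise(nm, profile$party_spacing_m, 0.97)
      oy[plan$moving] <- ar1_noise(nm, profile$party_spacing_m, 0.97)
      # freeze the offset through dwells at its last moving value
      ox <- fill_forward(ox, plan$moving)
      oy <- fill_forward(oy, plan$moving)
      xy <- xy + cbind(ox, oy)
    }
    tr <- realize_track(person_ids[k], camp, xy, time, config)
    attr(tr, "truth") <- data.frame(
      person_id = person_ids[k], date = date, gender = profile$gender,
      true_day_range_km = path_length(xy[, 1], xy[, 2]) / 1000,
      planned_range_km = plan$planned_range_m / 1000,
      apex_dist_m = plan$apex_dist_m, party_size = as.integer(m))
    tr
  })
}

# Carry the last value at TRUE positions forward over FALSE runs.
fill_forward <- function(v, valid) {
  idx <- ifelse(valid, seq_along(v), NA)
  idx <- cummax(ifelse(is.na(idx), 0L, idx))
  out <- v
  has <- idx > 0
  out[has] <- v[idx[has]]
  out[!has] <- if (any(valid)) v[which(valid)[1]] else 0
  out
}

#' Simulate a full camp of gendered foragers
#'
#' Generates `n_per_gender` individuals of each gender observed for
#' `n_days` days. Males forage solo; females forage in parties of the
#' profile's `party_size` (re-drawn each day). Each person-day uses an
#' RNG substream derived by stable hashing of `(seed, date, party)`, so
#' any track can be regenerated in isolation and reordering leaves
#' results unchanged.
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory: writes one GPX per person-day,
#'   `persons.csv`, `camp.geojson` and `manifest.csv` (ground truth).
#' @return list with `tracks` (list of [cpf_track]), `persons` (metadata
#'   data frame), `camp` (a `cpf_camp`) and `manifest` (per-person-day
#'   ground truth: realized noiseless day range, planned range, apex
#'   distance, party size).
#' @export
simulate_camp <- function(config = sim_config(), out_dir = NULL) {
  camp <- make_circular_camp(radius_m = config$camp_radius_m,
                             lonlat = config$camp_lonlat)
  pr <- config$profiles
  set.seed(hash_seed(config$seed, "persons"))
  persons <- do.call(rbind, lapply(names(pr), function(g) {
    n <- config$n_per_gender
    ids <- sprintf("%s%02d", toupper(substr(g, 1, 1)), seq_len(n))
    data.frame(person_id = ids, gender = g,
               age = round(stats::runif(n, 18, 60)),
               has_dependent_infant = g == "female" & stats::runif(n) < 0.3,
               camp_id = camp$camp_id, stringsAsFactors = FALSE)
  }))
  tracks <- list()
  manifest <- list()
  for (d in seq_len(config$n_days)) {
    date <- config$start_date + (d - 1)
    for (g in names(pr)) {
      prof <- pr[[g]]
      ids <- persons$person_id[persons$gender == g]
      # party assignment: shuffle, then consecutive groups of party_size
      set.seed(hash_seed(config$seed, "parties", format(date), g))
      ids <- sample(ids)
      groups <- split(ids, ceiling(seq_along(ids) / prof$party_size))
      for (grp in groups) {
        trs <- simulate_party(prof, grp, camp, date, config,
                              seed = hash_seed(config$seed, format(date), grp[1]))
        tracks <- c(tracks, trs)
        manifest <- c(manifest, lapply(trs, attr, "truth"))
      }
    }
  }
  manifest <- do.call(rbind, manifest)
  if (config$vehicle_days > 0) {
    set.seed(hash_seed(config$seed, "vehicle"))
    vsel <- sample(length(tracks), min(config$vehicle_days, length(tracks)))
    for (k in vsel) tracks[[k]] <- inject_vehicle_segment(tracks[[k]], camp)
    manifest$vehicle_contaminated <- seq_len(nrow(manifest)) %in% vsel
  } else manifest$vehicle_contaminated <- FALSE
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (tr in tracks)
      write_gpx(tr, file.path(out_dir, sprintf("%s_%s.gpx", tr$person_id,
                                               format(tr$date))))
    utils::write.csv(persons, file.path(out_dir, "persons.csv"), row.names = FALSE)
    write_camp_geojson(camp, file.path(out_dir, "camp.geojson"))
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  }
  list(tracks = tracks, persons = persons, camp = camp, manifest = manifest)
}

# Replace ten minutes of the day's tail with an 8 m/s straight ride.
inject_vehicle_segment <- function(track, camp, speed = 8, duration = 600) {
  p <- local_project(track$lon, track$lat, camp$centroid)
  n <- length(track$time)
  dt <- stats::median(diff(as.numeric(track$time)))
  m <- max(2, round(duration / dt))
  if (n < m + 2) return(track)
  i0 <- n - m
  th <- stats::runif(1, 0, 2 * pi)
  steps <- speed * dt
  x <- p$x; y <- p$y
  x[i0:n] <- x[i0] + (0:m) * steps * cos(th)
  y[i0:n] <- y[i0] + (0:m) * steps * sin(th)
  g <- local_unproject(x, y, camp$centroid)
  cpf_track(track$person_id, track$camp_id, track$time, g$lon, g$lat,
            sampling_mode = track$sampling_mode)
}
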