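test_that("local projection matches closed forms and the haversine oracle", {
  camp <- square_camp()
  # centroid maps to the origin
  tr0 <- cpf_track("P1", "c", as.POSIXct("2020-07-01 05:00:00", tz = "UTC") + c(0, 5),
                   rep(camp$centroid[1], 2), rep(camp$centroid[2], 2))
  p <- project_to_local(tr0, camp)
  expect_equal(p$x, c(0, 0), tolerance = 1e-9)
  expect_equal(p$y, c(0, 0), tolerance = 1e-9)

  # 0.001 degrees due north is R * dphi = 111.195 m
  q <- local_project(camp$centroid[1], camp$centroid[2] + 0.001, camp$centroid)
  expect_equal(q$y, 111.195, tolerance = 0.001)

  # planar vs haversine distances for random pairs within 20 km
  set.seed(7)
  n <- 200
  a <- local_unproject(runif(n, -1e4, 1e4), runif(n, -1e4, 1e4), camp$centroid)
  b <- local_unproject(runif(n, -1e4, 1e4), runif(n, -1e4, 1e4), camp$centroid)
  pa <- local_project(a$lon, a$lat, camp$centroid)
  pb <- local_project(b$lon, b$lat, camp$centroid)
  planar <- sqrt((pa$x - pb$x)^2 + (pa$y - pb$y)^2)
  hav <- haversine_m(a$lon, a$lat, b$lon, b$lat)
  keep <- hav > 100
  expect_lt(max(abs(planar[keep] - hav[keep]) / hav[keep]), 0.001)
  if (requireNamespace("geosphere", quietly = TRUE)) {
    ref <- geosphere::distHaversine(cbind(a$lon, a$lat), cbind(b$lon, b$lat),
                                    r = 6371008.8)
    expect_equal(hav, ref, tolerance = 1e-6)
  }

  far <- cpf_track("P1", "c", as.POSIXct("2020-07-01 05:00:00", tz = "UTC") + c(0, 5),
                   c(camp$centroid[1], camp$centroid[1] + 3),
                   c(camp$centroid[2], camp$centroid[2]))
  expect_error(project_to_local(far, camp), "projection validity")
})

test_that("speed filter removes a teleported fix and leaves clean tracks alone", {
  # constant 1.4 m/s walk: untouched
  n <- 500
  clean <- ptrack_from_xy(seq(0, by = 7, length.out = n), rep(0, n))
  filtered <- filter_speed(clean)
  expect_equal(length(filtered$t), n)
  expect_equal(attr(filtered, "removed"), 0)

  # one fix teleported 3 km between 5 s neighbours: exactly that fix goes
  x <- seq(0, by = 7, length.out = n)
  y <- rep(0, n)
  y[250] <- 3000
  dirty <- ptrack_from_xy(x, y)
  out <- filter_speed(dirty)
  expect_equal(attr(out, "removed"), 1)
  expect_lt(max(abs(out$y)), 1) # the 3 km excursion is gone
  expect_equal(out$t, dirty$t[-250])

  # all fixes identical (speed 0): untouched
  still <- ptrack_from_xy(rep(5, 100), rep(5, 100))
  expect_equal(length(filter_speed(still)$t), 100)
})

test_that("vehicle-day rule drops sustained fast travel but keeps running bursts", {
  walk <- c(seq(0, by = 6, length.out = 500))
  # 10 minutes at 8 m/s appended
  ride <- max(walk) + seq(40, by = 40, length.out = 120)
  day <- ptrack_from_xy(c(walk, ride), rep(0, 620))
  keep <- filter_vehicle_day(day)
  expect_false(as.logical(keep))
  expect_gte(attr(keep, "evidence"), 600)

  # 60 s at 4 m/s: below the minimum duration, kept
  burst <- max(walk) + seq(20, by = 20, length.out = 12)
  day2 <- ptrack_from_xy(c(walk, burst), rep(0, 512))
  expect_true(as.logical(filter_vehicle_day(day2)))

  expect_true(as.logical(filter_vehicle_day(ptrack_from_xy(walk, rep(0, 500)))))
})

test_that("5 s resampling is idempotent, non-extrapolating and length-contracting", {
  # already on the grid: identity
  on_grid <- ptrack_from_xy(seq(0, by = 7, length.out = 200), rep(0, 200), dt = 5)
  rs <- resample_5s(on_grid)
  expect_equal(rs$t, on_grid$t)
  expect_equal(rs$x, on_grid$x, tolerance = 1e-12)

  # constant-velocity straight segment whose span is a multiple of the
  # grid interval: length preserved
  straight <- ptrack_from_xy(seq(0, by = 11, length.out = 101), rep(0, 101), dt = 7)
  rs2 <- resample_5s(straight)
  len0 <- sum(sqrt(diff(straight$x)^2 + diff(straight$y)^2))
  len2 <- sum(sqrt(diff(rs2$x)^2 + diff(rs2$y)^2))
  expect_equal(len2 / len0, 1, tolerance = 1e-9)
  expect_lte(max(rs2$t), max(straight$t))

  # random tracks: resampled path length never exceeds the original
  set.seed(42)
  for (k in 1:20) {
    n <- 50
    x <- cumsum(rnorm(n, 0, 8)); y <- cumsum(rnorm(n, 0, 8))
    tt <- cumsum(c(0, runif(n - 1, 1, 20)))
    pt <- ptrack_from_xy(x, y, times = tt)
    r <- resample_5s(pt)
    expect_lte(sum(sqrt(diff(r$x)^2 + diff(r$y)^2)),
               sum(sqrt(diff(pt$x)^2 + diff(pt$y)^2)) + 1e-9)
  }

  # resampling twice equals resampling once
  set.seed(43)
  pt <- ptrack_from_xy(cumsum(rnorm(60, 0, 8)), cumsum(rnorm(60, 0, 8)),
                       times = cumsum(c(0, runif(59, 1, 12))))
  r1 <- resample_5s(pt)
  r2 <- resample_5s(r1)
  expect_equal(r2$t, r1$t)
  expect_equal(r2$x, r1$x, tolerance = 1e-12)
})

test_that("gaps longer than 300 s are bridged but flagged", {
  tt <- c(0, 5, 10, 400, 405)
  pt <- ptrack_from_xy(c(0, 5, 10, 400, 405), rep(0, 5), times = tt)
  r <- resample_5s(pt)
  inside <- r$t > 10 + pt$t[1] & r$t < 400 + pt$t[1]
  expect_true(all(r$gap_filled[inside]))
  expect_false(any(r$gap_filled[!inside]))
})

test_that("in/out-of-camp labels follow the boundary with vertices inside", {
  camp <- square_camp(100)
  pts <- ptrack_from_xy(c(0, 10000, 100, 99.9999, 100.0001),
                        c(0, 0, 100, 0, 0), camp = camp)
  expect_equal(pts$in_camp, c(TRUE, FALSE, TRUE, TRUE, FALSE))
})

test_that("the eight-hour rule includes exactly the tracks spanning >= 8 h", {
  mk <- function(hours) track_from_xy(c(0, 10), c(0, 0),
                                      times = c(0, hours * 3600))
  kept <- apply_inclusion(list(mk(7.99), mk(8), mk(11)))
  expect_length(kept, 2)
  expect_equal(attr(kept, "excluded"), 1)
})

test_that("daily distance sums all travel and is reversal-invariant", {
  oab <- out_and_back_xy(5000, step = 5)
  pt <- ptrack_from_xy(oab$x, oab$y)
  expect_equal(daily_distance(pt), 10, tolerance = 0.005)
  rev_pt <- ptrack_from_xy(rev(oab$x), rev(oab$y))
  expect_equal(daily_distance(rev_pt), daily_distance(pt))
  expect_warning(d0 <- daily_distance(ptrack_from_xy(0, 0)), "fewer than 2")
  expect_equal(d0, 0)
})

test_that("primary bout extraction selects the longest qualifying bout and splits at the apex", {
  camp <- square_camp(100)
  # never beyond 500 m: no bout
  near <- out_and_back_xy(400)
  expect_null(extract_primary_bout(ptrack_from_xy(near$x, near$y, camp = camp)))

  # single out-and-back with apex 2 km
  oab <- out_and_back_xy(2000)
  pt <- ptrack_from_xy(oab$x, oab$y, camp = camp)
  b <- extract_primary_bout(pt)
  expect_equal(b$apex_distance, max(pt$dist_from_camp))
  expect_equal(b$apex, which.max(pt$dist_from_camp))
  expect_gte(b$outbound_path_length, b$outbound_chord)
  expect_gte(b$inbound_path_length, b$inbound_chord)

  # two bouts: 1 km out-and-back then 3 km out-and-back; longer one wins
  b1 <- out_and_back_xy(1000); b2 <- out_and_back_xy(3000)
  x <- c(b1$x, b2$x); y <- c(b1$y, b2$y)
  pt2 <- ptrack_from_xy(x, y, camp = camp)
  bb <- extract_primary_bout(pt2)
  expect_equal(bb$apex_distance, max(pt2$dist_from_camp))
  expect_gt(bb$apex, length(b1$x)) # apex lies in the second bout
})

test_that("every input fix is kept, speed-filtered, or dropped with its vehicle day", {
  set.seed(9)
  sim <- simulate_camp(sim_config(n_per_gender = 1, n_days = 1,
                                  errant_fix_rate = 2e-3, seed = 5))
  camp <- sim$camp
  for (tr in sim$tracks) {
    pt <- project_to_local(tr, camp)
    fs <- filter_speed(pt)
    removed <- attr(fs, "removed")
    if (is.null(removed)) removed <- 0
    expect_equal(length(fs$t) + removed, length(pt$t))
  }
})
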