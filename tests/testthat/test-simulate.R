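test_that("simulation is deterministic given the seed", {
  cfg <- sim_config(n_per_gender = 2, n_days = 2, seed = 77)
  a <- simulate_camp(cfg)
  b <- simulate_camp(cfg)
  expect_identical(lapply(a$tracks, `[`, c("lon", "lat", "time")),
                   lapply(b$tracks, `[`, c("lon", "lat", "time")))
  expect_identical(a$manifest, b$manifest)
  # different seed: same schema, different tracks
  c2 <- simulate_camp(sim_config(n_per_gender = 2, n_days = 2, seed = 78))
  expect_identical(names(c2$manifest), names(a$manifest))
  expect_false(identical(a$tracks[[1]]$lon, c2$tracks[[1]]$lon))
})

test_that("a noiseless high-concentration foray is a straight out-and-back", {
  prof <- forager_profile("male", mean_day_range_km = 4,
                          turning_concentration = 5000)
  camp <- make_circular_camp(radius_m = 100)
  cfg <- sim_config(fix_noise_sd = 0, errant_fix_rate = 0)
  tr <- simulate_person_day(prof, camp, config = cfg, seed = 3)
  pt <- classify_in_camp(resample_5s(project_to_local(tr, camp)), camp)
  sr <- bout_sinuosity(pt, extract_primary_bout(pt))
  expect_equal(sr$outbound, 1, tolerance = 0.01)
  # track begins and ends inside the camp polygon
  expect_true(pt$in_camp[1])
  expect_true(pt$in_camp[length(pt$in_camp)])
})

test_that("noiseless realized day range tracks the planned walking budget", {
  camp <- make_circular_camp(radius_m = 100)
  cfg <- sim_config(fix_noise_sd = 0, errant_fix_rate = 0)
  for (s in 1:5) {
    prof <- forager_profile("female", mean_day_range_km = 6,
                            turning_concentration = 8)
    tr <- simulate_person_day(prof, camp, config = cfg, seed = 200 + s)
    truth <- attr(tr, "truth")
    # realized path length within a CRW's fluctuation of the plan
    expect_equal(truth$true_day_range_km / truth$planned_range_km, 1,
                 tolerance = 0.1)
  }
})

test_that("measured sinuosity is larger at low concentration than at high", {
  camp <- make_circular_camp(radius_m = 100)
  cfg <- sim_config(fix_noise_sd = 0, errant_fix_rate = 0)
  one <- function(kappa, seed) {
    prof <- forager_profile("male", 4, turning_concentration = kappa)
    tr <- simulate_person_day(prof, camp, config = cfg, seed = seed)
    pt <- classify_in_camp(resample_5s(project_to_local(tr, camp)), camp)
    sr <- bout_sinuosity(pt, extract_primary_bout(pt))
    if (is.null(sr)) NA_real_ else sr$outbound
  }
  lo <- vapply(1:10, function(s) one(2, 300 + s), numeric(1))
  hi <- vapply(1:10, function(s) one(50, 300 + s), numeric(1))
  expect_gt(mean(lo, na.rm = TRUE), mean(hi, na.rm = TRUE))
})

test_that("party members share a plan and spacing controls cohesion", {
  camp <- make_circular_camp(radius_m = 100)
  cfg <- sim_config(fix_noise_sd = 0, errant_fix_rate = 0)
  # spacing 0: identical tracks up to fix noise (here exactly identical)
  prof0 <- forager_profile("female", 6, turning_concentration = 8,
                           party_size = 2, party_spacing_m = 0)
  trs <- simulate_party(prof0, c("F1", "F2"), camp, config = cfg, seed = 9)
  expect_equal(trs[[1]]$lon, trs[[2]]$lon)
  expect_identical(as.numeric(trs[[1]]$time), as.numeric(trs[[2]]$time))

  # spacing 2 m: median inter-member distance at matched times in [1, 6] m
  prof2 <- forager_profile("female", 6, turning_concentration = 8,
                           party_size = 2, party_spacing_m = 2)
  trs2 <- simulate_party(prof2, c("F1", "F2"), camp, config = cfg, seed = 9)
  p1 <- project_to_local(trs2[[1]], camp); p2 <- project_to_local(trs2[[2]], camp)
  moving <- which(c(FALSE, sqrt(diff(p1$x)^2 + diff(p1$y)^2) > 1))
  d <- sqrt((p1$x - p2$x)^2 + (p1$y - p2$y)^2)[moving]
  expect_gt(median(d), 1)
  expect_lt(median(d), 6)

  # cohesion decreases with spacing
  prof8 <- forager_profile("female", 6, turning_concentration = 8,
                           party_size = 2, party_spacing_m = 8)
  trs8 <- simulate_party(prof8, c("F1", "F2"), camp, config = cfg, seed = 9)
  q1 <- project_to_local(trs8[[1]], camp); q2 <- project_to_local(trs8[[2]], camp)
  d8 <- sqrt((q1$x - q2$x)^2 + (q1$y - q2$y)^2)[moving]
  expect_lt(mean(d <= 5), 1 + 0)  # sanity: probabilities are probabilities
  expect_gt(mean(d <= 5), mean(d8 <= 5))
})

test_that("camp simulation yields the configured person-day counts and files", {
  cfg <- sim_config(n_per_gender = 3, n_days = 2, seed = 5, vehicle_days = 1)
  out <- withr::local_tempdir()
  sim <- simulate_camp(cfg, out_dir = out)
  expect_length(sim$tracks, 12)
  expect_equal(nrow(sim$persons), 6)
  expect_equal(nrow(sim$manifest), 12)
  expect_equal(sum(sim$manifest$vehicle_contaminated), 1)
  expect_true(file.exists(file.path(out, "persons.csv")))
  expect_true(file.exists(file.path(out, "camp.geojson")))
  expect_true(file.exists(file.path(out, "manifest.csv")))
  expect_length(list.files(out, pattern = "\\.gpx$"), 12)
  # round-trip through the on-disk formats
  tracks <- unlist(lapply(list.files(out, pattern = "\\.gpx$", full.names = TRUE),
                          read_gpx, camp_id = "simcamp"), recursive = FALSE)
  expect_length(tracks, 12)
  camp <- read_camp_geojson(file.path(out, "camp.geojson"))
  expect_equal(camp$centroid, sim$camp$centroid, tolerance = 1e-8)
})

test_that("a vehicle-contaminated day is dropped by preprocessing", {
  cfg <- sim_config(n_per_gender = 1, n_days = 1, seed = 31, vehicle_days = 1)
  sim <- simulate_camp(cfg)
  bad <- which(sim$manifest$vehicle_contaminated)[1]
  expect_null(preprocess_track(sim$tracks[[bad]], sim$camp))
})

test_that("adaptive logging thins stationary spans and survives resampling", {
  cfg <- sim_config(n_per_gender = 1, n_days = 1, seed = 8, adaptive = TRUE)
  sim <- simulate_camp(cfg)
  tr <- sim$tracks[[1]]
  expect_equal(tr$sampling_mode, "adaptive")
  dt <- diff(as.numeric(tr$time))
  expect_gt(max(dt), 5) # stationary spans thinned
  pt <- preprocess_track(tr, sim$camp)
  expect_equal(median(diff(pt$t)), 5) # back on the even grid
})
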