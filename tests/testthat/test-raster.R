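test_that("supercover rasterisation matches stated cell sets", {
  grid <- grid_spec(10)
  # stationary point at (5, 5): its containing cell only
  cs <- cells_traversed(list(x = 5, y = 5), grid)
  expect_equal(nrow(cs), 1)
  expect_equal(c(cs$i, cs$j), c(0, 0))

  # segment (5,5) -> (25,5): three cells in a row
  cs2 <- cells_traversed(list(x = c(5, 25), y = c(5, 5)), grid)
  expect_setequal(paste(cs2$i, cs2$j), c("0 0", "1 0", "2 0"))

  # exact diagonal through the corner (10,10): both diagonal neighbours
  # of the corner are touched
  cs3 <- cells_traversed(list(x = c(5, 15), y = c(5, 15)), grid)
  expect_setequal(paste(cs3$i, cs3$j), c("0 0", "1 1", "0 1", "1 0"))
})

test_that("supercover equals a 1 cm sampling oracle on random short segments", {
  set.seed(11)
  grid <- grid_spec(10)
  for (k in 1:1000) {
    x0 <- runif(1, -50, 50); y0 <- runif(1, -50, 50)
    ang <- runif(1, 0, 2 * pi); len <- runif(1, 0.5, 30)
    x1 <- x0 + len * cos(ang); y1 <- y0 + len * sin(ang)
    cs <- cells_traversed(list(x = c(x0, x1), y = c(y0, y1)), grid)
    impl <- paste(cs$i, cs$j, sep = ",")
    orc <- sampled_cells(x0, y0, x1, y1)
    # every sampled cell is found, and any cell the sampler missed (a
    # sub-centimetre corner graze) genuinely intersects the segment
    expect_true(all(orc %in% impl))
    for (extra in setdiff(impl, orc)) {
      ij <- as.integer(strsplit(extra, ",")[[1]])
      expect_true(segment_intersects_cell(x0, y0, x1, y1, ij[1], ij[2]))
    }
  }
})

test_that("supercover contains the containing cell of every track point", {
  set.seed(12)
  grid <- grid_spec(10)
  for (k in 1:20) {
    x <- cumsum(runif(30, -15, 15)); y <- cumsum(runif(30, -15, 15))
    cs <- cells_traversed(list(x = x, y = y), grid)
    expect_true(all(paste(floor(x / 10), floor(y / 10)) %in% paste(cs$i, cs$j)))
  }
})

test_that("land visited and cumulative exploration follow the worked two-day example", {
  grid <- grid_spec(10)
  # day 1: straight east through 50 cells
  day1 <- cells_traversed(list(x = c(5, 495), y = c(5, 5)), grid)
  expect_equal(nrow(day1), 50)
  expect_equal(daily_land_visited(day1), 5000)
  # day 2: re-walks 10 of day 1's cells then 50 new ones in the next row
  day2 <- cells_traversed(list(x = c(5, 95, 95, 585), y = c(5, 5, 15, 15)), grid)
  expect_equal(nrow(day2), 60)
  expect_equal(daily_land_visited(day2), 6000)
  cum <- cumulative_land_explored(list(day1, day2))
  expect_equal(cum, c(5000, 10000))
  # definitional identities
  expect_equal(cum[1], daily_land_visited(day1))
  expect_equal(cumulative_land_explored(list(day1, day1)), c(5000, 5000))
  expect_error(cumulative_land_explored(list(day1, cells_traversed(list(x = 1, y = 1), grid_spec(20)))),
               "one grid")
})

test_that("cumulative exploration is non-decreasing and bounded by summed visits", {
  set.seed(13)
  grid <- grid_spec(10)
  days <- lapply(1:6, function(k)
    cells_traversed(list(x = cumsum(runif(40, -12, 12)),
                         y = cumsum(runif(40, -12, 12))), grid))
  cum <- cumulative_land_explored(days)
  expect_true(all(diff(cum) >= 0))
  expect_true(all(cum <= cumsum(vapply(days, daily_land_visited, 1))))
})

test_that("gender segregation areas obey hand-enumerated set arithmetic", {
  grid <- grid_spec(10)
  persons <- data.frame(person_id = c("M1", "F1"), gender = c("male", "female"))
  mk <- function(x, pid) {
    cs <- cells_traversed(list(x = x, y = rep(5, length(x))), grid)
    attr(cs, "owner") <- list(person_id = pid)
    cs
  }
  # male cells {0,1,2}, female {2,3}: total 4, both 1, overlap 25%
  seg <- gender_segregation(list(mk(c(5, 25), "M1"), mk(c(25, 35), "F1")), persons)
  expect_equal(seg$total_km2 / 1e-4, 4)
  expect_equal(seg$both_km2 / 1e-4, 1)
  expect_equal(seg$overlap_pct, 25)
  expect_equal(seg$male_km2 + seg$female_km2 - seg$both_km2, seg$total_km2)

  # disjoint: zero overlap; identical: ratio 1 and full overlap
  seg2 <- gender_segregation(list(mk(c(5, 25), "M1"), mk(c(105, 125), "F1")), persons)
  expect_equal(seg2$both_km2, 0)
  expect_equal(seg2$overlap_pct, 0)
  seg3 <- gender_segregation(list(mk(c(5, 25), "M1"), mk(c(5, 25), "F1")), persons)
  expect_equal(seg3$male_female_ratio, 1)
  expect_equal(seg3$overlap_pct, 100)

  expect_error(gender_segregation(list(mk(c(5, 25), "M1")), persons), "per gender")
})

test_that("MCP areas follow the centroid-exclusion convention", {
  # 4 corners of a 10 m square at fraction 1: 100 m2 (needs >= 5 points)
  x <- c(0, 10, 10, 0, 5); y <- c(0, 0, 10, 10, 5)
  expect_equal(mcp_area(x, y, fraction = 1)$area_km2 * 1e6, 100)

  # 95 inliers + 5 distant outliers at fraction 0.95: hull of inliers only
  set.seed(14)
  xi <- runif(95); yi <- runif(95)
  xo <- runif(5, 9000, 10000); yo <- runif(5, 9000, 10000)
  m <- mcp_area(c(xi, xo), c(yi, yo), fraction = 0.95)
  expect_lt(m$area_km2 * 1e6, 1.01) # within the unit square
  full <- mcp_area(c(xi, xo), c(yi, yo), fraction = 1)
  expect_gte(full$area_km2, m$area_km2) # monotone in the fraction

  expect_warning(deg <- mcp_area(1:10, 1:10, fraction = 1), "collinear")
  expect_equal(deg$area_km2, 0)
})

test_that("raster and MCP gender ratios agree in direction on synthetic data", {
  sim <- simulate_camp(sim_config(n_per_gender = 3, n_days = 2, seed = 21))
  an <- forage_analysis(sim$tracks, sim$camp, sim$persons, seed = 21)
  raster_ratio <- an$segregation$male_female_ratio
  mcp_ratio <- an$mcp$male$area_km2 / an$mcp$female$area_km2
  expect_gt(raster_ratio, 1)
  expect_gt(mcp_ratio, 1)
})
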