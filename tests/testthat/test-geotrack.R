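test_that("great-circle distance matches the textbook haversine", {
  expect_equal(haversine_km(12, 34, 12, 34), 0)
  expect_equal(haversine_km(0, 0, 0, 180), pi * 6371, tolerance = 1e-6)
  expect_equal(haversine_km(0, 0, 90, 0), pi * 6371 / 2, tolerance = 1e-6)

  set.seed(14)
  lat1 <- runif(50, -90, 90); lon1 <- runif(50, -180, 180)
  lat2 <- runif(50, -90, 90); lon2 <- runif(50, -180, 180)
  expect_equal(haversine_km(lat1, lon1, lat2, lon2),
               haversine_formula(lat1, lon1, lat2, lon2), tolerance = 1e-9)
  # symmetry, non-negativity, triangle inequality
  d12 <- haversine_km(lat1, lon1, lat2, lon2)
  expect_equal(d12, haversine_km(lat2, lon2, lat1, lon1))
  expect_true(all(d12 >= 0))
  lat3 <- runif(50, -90, 90); lon3 <- runif(50, -180, 180)
  d13 <- haversine_km(lat1, lon1, lat3, lon3)
  d32 <- haversine_km(lat3, lon3, lat2, lon2)
  expect_true(all(d12 <= d13 + d32 + 1e-9))

  expect_error(haversine_km(91, 0, 0, 0), "out of range")
})

make_track <- function(id, lat, lon) {
  data.frame(animal_id = id,
             timestamp = sprintf("2010-01-01T%02d:00:00Z",
                                 seq_along(lat) - 1),
             lat = lat, lon = lon)
}

test_that("geographic runs apply the buffer rules with strict < r", {
  # k out-of-range fixes then one in range: single event of size k + 1
  tr <- as_geotracks(make_track("a", c(-40, -40, -40, -35), c(130, 131, 132, 135)))
  st <- geo_station_set(data.frame(lat = -35, lon = 135), radius_km = 10)
  run <- run_geo(tr, st)
  expect_equal(nrow(run$events), 1L)
  expect_equal(run$events$time, 4L)
  expect_equal(run$events$size, 4L)
  expect_equal(run$T_mean, 1)  # everything flushed on the last fix

  # track entirely in range: transfer 1, one event per fix
  tr2 <- as_geotracks(make_track("b", rep(-35, 5), 135 + 0.001 * (0:4)))
  run2 <- run_geo(tr2, st)
  expect_equal(run2$T_mean, 1)
  expect_equal(run2$events$size, rep(1L, 5))

  # no station within range: nothing transmitted, conservation holds
  far <- geo_station_set(data.frame(lat = 60, lon = 0), radius_km = 10)
  run3 <- run_geo(tr, far)
  expect_equal(run3$T_mean, 0)
  expect_equal(unname(run3$stored + run3$transmitted), unname(run3$generated))

  # boundary is strict: a fix exactly at radius distance does not flush
  d <- haversine_km(-40, 130, -35, 135)
  exact <- geo_station_set(data.frame(lat = -35, lon = 135), radius_km = d)
  expect_equal(run_geo(as_geotracks(make_track("c", -40, 130)), exact)$T_mean, 0)
})

test_that("geographic station placement respects the track bounding box", {
  tr <- as_geotracks(make_track("a", seq(-40, -35, length.out = 20),
                                seq(130, 136, length.out = 20)))
  st <- place_geo_random(tr, 10, radius_km = 50, seed = 3)
  expect_equal(nrow(st$positions), 10L)
  expect_true(all(st$positions$lat >= -40 & st$positions$lat <= -35))
  expect_true(all(st$positions$lon >= 130 & st$positions$lon <= 136))
  expect_identical(place_geo_random(tr, 10, radius_km = 50, seed = 3)$positions,
                   st$positions)
  expect_equal(nrow(place_geo_random(tr, 0, radius_km = 50)$positions), 0L)
  single <- as_geotracks(make_track("a", -35, 135))
  expect_error(place_geo_random(single, 2, radius_km = 50), "degenerate")
})

test_that("at-home geographic placement uses first fixes", {
  tr <- as_geotracks(rbind(make_track("a", c(-35, -36), c(135, 136)),
                           make_track("b", c(-38, -39), c(131, 132))))
  st <- place_geo_at_homes(tr, 2, radius_km = 50, seed = 1)
  got <- st$positions[order(st$positions$lat), ]
  expect_equal(got$lat, c(-38, -35))
  expect_equal(got$lon, c(131, 135))
  st1 <- place_geo_at_homes(tr, 1, radius_km = 50, seed = 2)
  expect_true(any(st1$positions$lat == -35 & st1$positions$lon == 135) ||
              any(st1$positions$lat == -38 & st1$positions$lon == 131))
})

test_that("synthetic tracks follow the tangent-plane central-place law", {
  # a = 1: every post-start fix sits one step-scale from home
  tr <- generate_synthetic_geotracks(a = 1, n_animals = 3, n_steps = 50,
                                     step_km = 5, seed = 6)
  homes <- attr(tr, "homes")
  for (i in seq_len(nrow(homes))) {
    d <- tr[tr$animal_id == homes$animal_id[i], ]
    dist <- haversine_km(d$lat[-1], d$lon[-1], homes$lat[i], homes$lon[i])
    expect_equal(dist, rep(5, length(dist)), tolerance = 1e-3)
  }
  expect_identical(
    generate_synthetic_geotracks(a = 1, n_animals = 3, n_steps = 50,
                                 step_km = 5, seed = 6),
    tr)
  expect_error(generate_synthetic_geotracks(home_lat = 89.5, seed = 1),
               "pole")

  # weak attraction ranges much farther than strong attraction: compare
  # per-animal track extents (the pooled bounding box is dominated by the
  # scatter of the colonies themselves)
  weak <- generate_synthetic_geotracks("weak", n_animals = 5, n_steps = 400,
                                       seed = 7)
  strong <- generate_synthetic_geotracks("strong", n_animals = 5,
                                         n_steps = 400, seed = 7)
  span <- function(tr) mean(sapply(split(tr, tr$animal_id), function(d)
    diff(range(d$lat)) * diff(range(d$lon))))
  expect_gt(span(weak), 4 * span(strong))
})

test_that("track CSV round-trips and validates", {
  tr <- generate_synthetic_geotracks("strong", n_animals = 2, n_steps = 10,
                                     seed = 9)
  f <- tempfile(fileext = ".csv")
  write_geotracks(tr, f)
  back <- read_geotracks(f)
  expect_equal(as.data.frame(back), as.data.frame(tr), ignore_attr = TRUE,
               tolerance = 1e-12)
  bad <- data.frame(animal_id = "x", timestamp = "t", lat = 95, lon = 0)
  expect_error(as_geotracks(bad), "out of range")
})

test_that("geographic transfer sweep fits the saturating law", {
  tracks <- generate_synthetic_geotracks("weak", n_animals = 8, n_steps = 300,
                                         seed = 10)
  res <- transfer_vs_area_geo(tracks, counts = c(0, 2, 5, 10, 20, 40),
                              radius_km = 60, n_realizations = 5,
                              base_seed = 4)
  expect_equal(res$sweep$T_mean[res$sweep$n_stations == 0], 0)
  expect_equal(res$sweep$covered_area[res$sweep$n_stations == 10],
               10 * pi * 60^2)
  expect_false(is.null(res$fit))
  expect_gt(res$fit$estimate["d"], 0)
})
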