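geom1 <- function(lat_center, cellsize = 1) {
  structure(list(p = matrix(1L, 1, 1), xmin = 0,
                 ymax = lat_center + cellsize / 2, cellsize = cellsize,
                 scenario = "t"), class = "nk_map")
}

test_that("spherical cell areas match the closed form", {
  R <- 6371
  # one 1-degree cell centered on the equator
  a_eq <- area_by_class(matrix(1L, 1, 1), geom1(0))$area_km2
  expect_equal(a_eq, R^2 * (pi / 180) * 2 * sin(0.5 * pi / 180),
               tolerance = 1e-12)
  expect_equal(a_eq / 1e4, 1.2364, tolerance = 1e-4)

  # at 60 N the same cell shrinks by exactly cos(60): band sines telescope
  a_60 <- area_by_class(matrix(1L, 1, 1), geom1(60))$area_km2
  expect_equal(a_60 / a_eq, cos(60 * pi / 180), tolerance = 1e-12)

  # empty class has zero area
  ab <- area_by_class(matrix(0L, 1, 1), geom1(0))
  expect_equal(ab$area_km2[ab$class == 0], a_eq)
  expect_false(1 %in% ab$class)
})

test_that("class areas partition the total valid area", {
  withr::with_seed(14, cls <- matrix(sample(0:3, 30 * 40, TRUE), 30, 40))
  cls[sample(length(cls), 100)] <- NA
  geom <- structure(list(p = cls, xmin = -10, ymax = 50, cellsize = 0.25,
                         scenario = "t"), class = "nk_map")
  ab <- area_by_class(cls, geom)
  total <- sum(nichekit:::cell_area_matrix(geom)[!is.na(cls)])
  expect_equal(sum(ab$area_km2), total, tolerance = 1e-9)
})

test_that("change maps obey the gain/loss identities", {
  withr::with_seed(15, now <- matrix(rbinom(400, 1, 0.4), 20, 20))
  geom <- structure(list(p = now, xmin = 0, ymax = 20, cellsize = 1,
                         scenario = "t"), class = "nk_map")
  areas <- nichekit:::cell_area_matrix(geom)

  same <- change_map(now, now, geom)
  expect_equal(sum(same$areas$area_km2[same$areas$class %in% c(1, 2)]), 0)

  flip <- change_map(now, 1 - now, geom)
  expect_equal(flip$areas$area_km2[flip$areas$class == 1],
               sum(areas[now == 0]))
  expect_equal(flip$areas$area_km2[flip$areas$class == 2],
               sum(areas[now == 1]))

  one <- now; i <- which(one == 0)[1]; one[i] <- 1
  ch <- change_map(now, one, geom)
  expect_equal(ch$areas$area_km2[ch$areas$class == 1], areas[i],
               tolerance = 1e-12)

  # gain - loss = suitable(future) - suitable(now), exactly
  withr::with_seed(16, fut <- matrix(rbinom(400, 1, 0.5), 20, 20))
  ch2 <- change_map(now, fut, geom)
  gain <- ch2$areas$area_km2[ch2$areas$class == 1]
  loss <- ch2$areas$area_km2[ch2$areas$class == 2]
  expect_equal(gain - loss, sum(areas[fut == 1]) - sum(areas[now == 1]),
               tolerance = 1e-9)
  expect_error(change_map(now, matrix(1, 2, 2), geom), "mismatch")
})

test_that("suitable-area centroids are area-weighted and symmetric", {
  # mask symmetric about the equator and about lon 10: centroid at (10, 0)
  geom <- structure(list(p = matrix(1L, 4, 4), xmin = 8, ymax = 2,
                         cellsize = 1, scenario = "t"), class = "nk_map")
  cen <- centroid_suitable(matrix(1L, 4, 4), geom)
  expect_equal(cen$lon, 10)
  expect_equal(cen$lat, 0, tolerance = 1e-12)

  single <- matrix(0L, 4, 4); single[2, 3] <- 1L
  cs <- centroid_suitable(single, geom)
  expect_equal(c(cs$lon, cs$lat), c(10.5, 0.5))

  # two-cell mask at different latitudes: direct weight-computation oracle
  two <- matrix(0L, 4, 4); two[1, 2] <- 1L; two[4, 2] <- 1L
  w <- nichekit:::cell_area_matrix(geom)[cbind(c(1, 4), c(2, 2))]
  lats <- c(1.5, -1.5)
  got <- centroid_suitable(two, geom)
  expect_equal(got$lat, sum(lats * w) / sum(w), tolerance = 1e-12)

  expect_error(centroid_suitable(matrix(0L, 4, 4), geom), "no suitable")

  wide <- structure(list(p = matrix(1L, 1, 360), xmin = -180, ymax = 1,
                         cellsize = 1, scenario = "t"), class = "nk_map")
  mask <- matrix(0L, 1, 360); mask[1, 1] <- 1L; mask[1, 360] <- 1L
  expect_error(centroid_suitable(mask, wide), "antimeridian")
})

test_that("centroid shifts agree with an independent haversine implementation", {
  skip_if_not_installed("geosphere")
  from <- tibble::tibble(lon = -56.68, lat = -28.67)
  to <- tibble::tibble(lon = -55.50, lat = -31.56)
  got <- centroid_shift(from, to)
  ref_km <- geosphere::distHaversine(c(from$lon, from$lat), c(to$lon, to$lat),
                                     r = 6371000) / 1000
  # f = 0: spherical (not ellipsoidal) initial bearing
  ref_bearing <- geosphere::bearing(c(from$lon, from$lat), c(to$lon, to$lat),
                                    a = 6371000, f = 0)
  expect_equal(got$distance_km, ref_km, tolerance = 1e-9)
  expect_equal(got$bearing_deg, ref_bearing %% 360, tolerance = 1e-6)
  expect_equal(centroid_shift(from, from)$distance_km, 0)
})

test_that("projection propagates nodata and constant stacks give constant maps", {
  con <- manual_ensemble(list(constant_model(0.42)))
  st <- generate_landscape(3, 10, 10, 0, seed = 5, cellsize = 1, ymax = 10)
  st$layers$env2[3, 4] <- NA
  m <- project_suitability(con, st)
  expect_true(is.na(m$p[3, 4]))
  expect_true(all(m$p[!is.na(m$p)] == 420L))

  expect_error(
    project_suitability(con, env_stack(list(env1 = matrix(0, 8, 8),
                                            env2 = matrix(0, 8, 8)))),
    "env3")
})
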