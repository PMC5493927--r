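test_that("hiking speed follows the exponential slope law", {
  expect_equal(hiking_speed(-0.05), 6)
  expect_equal(hiking_speed(0), 6 * exp(-0.175))
  expect_lt(hiking_speed(0.10), hiking_speed(0))
  # speed is positive for any finite slope
  expect_true(all(hiking_speed(seq(-2, 2, by = 0.1)) > 0))
  expect_error(hiking_speed(NA), "finite")
  f2 <- hiking_function(max_speed = 5, slope_sensitivity = 2,
                        slope_offset = 0)
  expect_equal(hiking_speed(0, f2), 5)
})

test_that("ascii grid files round-trip bit-consistently and reject bad input", {
  dem <- synth_dem("plane", 6, 7, cell_size = 30, base_elev = 100,
                   slope_x = 0.01)
  dem$elevation[2, 3] <- NA
  path <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(dem, path)
  hdr <- readLines(path, n = 6)
  expect_equal(hdr[1], "ncols 7")
  expect_equal(hdr[2], "nrows 6")
  back <- read_ascii_grid(path)
  expect_equal(back$elevation, dem$elevation, tolerance = 1e-6)
  expect_equal(back$cell_size, 30)
  expect_true(is.na(back$elevation[2, 3]))

  writeLines(c("ncols 2", "nrows 2", "xllcorner 0", "yllcorner 0",
               "cellsize 10", "1 2 3"), path)
  expect_error(read_ascii_grid(path), "expected 4 cells")
})

test_that("flat and inclined planes match closed-form travel times", {
  # straight axis-aligned 10 km on flat ground
  dem <- synth_dem("plane", 5, 12, cell_size = 1000)
  s <- travel_time_surface(dem, source_cell = c(3, 1))
  expect_equal(s$times[3, 1], 0)
  expect_equal(s$times[3, 11], 10 / hiking_speed(0), tolerance = 1e-9)

  # inclined plane: anisotropic, both directions match closed forms
  demi <- synth_dem("plane", 5, 12, cell_size = 1000, slope_x = 0.05)
  up <- travel_time_surface(demi, source_cell = c(3, 1))
  down <- travel_time_surface(demi, source_cell = c(3, 11))
  expect_equal(up$times[3, 11], 10 / hiking_speed(0.05), tolerance = 1e-9)
  expect_equal(down$times[3, 1], 10 / hiking_speed(-0.05), tolerance = 1e-9)
  expect_gt(up$times[3, 11], down$times[3, 1])
})

test_that("Dijkstra times equal brute-force Bellman-Ford on small noisy grids", {
  for (seed in c(2, 5)) {
    dem <- synth_dem("plane", 9, 9, cell_size = 500, slope_x = 0.03,
                     slope_y = -0.02, noise_sd = 15, seed = seed)
    s <- travel_time_surface(dem, source_cell = c(4, 4))
    oracle <- bellman_ford_times(dem$elevation, 500, c(4, 4))
    expect_equal(s$times, oracle, tolerance = 1e-9)
  }
  # and with nodata holes
  dem <- synth_dem("plane", 8, 8, cell_size = 500, noise_sd = 10, seed = 3)
  dem$elevation[3, 3:6] <- NA
  s <- travel_time_surface(dem, source_cell = c(1, 1))
  oracle <- bellman_ford_times(dem$elevation, 500, c(1, 1))
  expect_equal(s$times[!is.na(dem$elevation)],
               oracle[!is.na(dem$elevation)], tolerance = 1e-9)
  expect_true(all(is.na(s$times[is.na(dem$elevation)])))
})

test_that("triangle inequality holds on every edge of seeded fixtures", {
  for (seed in 1:5) {
    dem <- synth_dem("plane", 10, 10, cell_size = 800, slope_x = 0.02,
                     noise_sd = 20, seed = seed)
    s <- travel_time_surface(dem, source_cell = c(5, 5))
    e <- s$edges
    tt <- as.numeric(t(s$times))
    expect_true(all(tt[e$to] <= tt[e$from] + e$hours + 1e-9))
  }
})

test_that("16-connectivity is never slower than 8-connectivity", {
  dem <- synth_dem("cone", 11, 11, cell_size = 1000, apex_elev = 4500,
                   grade = 0.04, noise_sd = 5, seed = 8)
  s8 <- travel_time_surface(dem, source_cell = c(6, 6), connectivity = 8)
  s16 <- travel_time_surface(dem, source_cell = c(6, 6), connectivity = 16)
  expect_true(all(s16$times <= s8$times + 1e-9))
  expect_lt(min(s16$times[1, ] / s8$times[1, ]), 1)  # strictly better somewhere
})

test_that("raising a cell never shortens any arrival time in the monotone regime", {
  for (seed in 1:5) {
    dem <- synth_dem("plane", 8, 8, cell_size = 1000)
    s0 <- travel_time_surface(dem, source_cell = c(1, 1))
    set.seed(seed)
    rc <- cbind(sample(2:7, 3), sample(2:7, 3))
    dem2 <- dem
    # +40 m over a 1 km cell keeps every slope within [-0.05, ...]
    dem2$elevation[rc] <- dem2$elevation[rc] + 40
    s1 <- travel_time_surface(dem2, source_cell = c(1, 1))
    expect_true(all(s1$times >= s0$times - 1e-9))
  }
})

test_that("cone descent at the optimal grade matches the analytic oracle", {
  dem <- synth_dem("cone", 11, 11, cell_size = 1000, apex_elev = 4500,
                   grade = 0.05)
  r <- time_to_contour(dem, source_cell = c(6, 6),
                       contour_elevation = 4300)
  # the cheapest below-contour cell is the third diagonal neighbour,
  # 3*sqrt(2) km out on a pure radial (-5% grade) line, walked at the
  # full 6 km/h optimum
  expect_true(r$reached)
  expect_equal(r$length_km, 3 * sqrt(2), tolerance = 1e-9)
  expect_equal(r$hours, 3 * sqrt(2) / 6, tolerance = 0.02)
  expect_equal(r$round_trip_km, 2 * r$length_km)
})

test_that("contour routing handles trivial, unreachable and no-target cases", {
  dem <- synth_dem("plane", 5, 8, cell_size = 1000, base_elev = 2000)
  r <- time_to_contour(dem, source_cell = c(2, 2))
  expect_equal(r$hours, 0)
  expect_equal(nrow(r$path), 1)

  high <- synth_dem("plane", 5, 8, cell_size = 1000, base_elev = 4000)
  r2 <- time_to_contour(high, source_cell = c(2, 2))
  expect_false(r2$reached)
  expect_equal(r2$reason, "no target")

  # below-contour cells exist but are ringed by nodata
  mix <- synth_dem("plane", 5, 8, cell_size = 1000, base_elev = 4000)
  mix$elevation[, 8] <- 2000
  mix$elevation[, 7] <- NA
  r3 <- time_to_contour(mix, source_cell = c(2, 2))
  expect_false(r3$reached)
  expect_equal(r3$reason, "contour unreachable")
})

test_that("isochrone bands partition reachable cells by travel-time interval", {
  dem <- synth_dem("plane", 9, 9, cell_size = 1000)
  s <- travel_time_surface(dem, source_cell = c(5, 5))
  iso <- isochrones(s, interval = 1)
  expect_equal(sum(!is.na(iso)), sum(is.finite(s$times)))
  expect_true(all(unclass(iso) == floor(s$times / 1), na.rm = TRUE))
  expect_equal(iso[5, 5], 0)
  expect_error(isochrones(s, interval = 0), "positive")
})

test_that("geographic grids use latitude-dependent great-circle spacing", {
  # flat geographic raster far from the equator: east-west steps are
  # shorter than north-south steps of equal degree size
  dem <- dem_raster(matrix(3000, 5, 5), cell_size = 0.1, xll = -70,
                    yll = -17, crs_kind = "geographic_degrees")
  s <- travel_time_surface(dem, source_cell = c(3, 3))
  expect_lt(s$times[3, 4], s$times[2, 3])
  # one 0.1 degree meridional step is about 11.1 km of flat walking
  expect_equal(s$times[2, 3], 11.12 / hiking_speed(0), tolerance = 0.01)
})

test_that("routes and isochrones serialise to GeoJSON, summaries to CSV", {
  dem <- synth_dem("plane", 5, 10, cell_size = 1000, base_elev = 2600,
                   slope_x = -0.02)
  r <- time_to_contour(dem, source_cell = c(3, 1))
  gj <- withr::local_tempfile(fileext = ".geojson")
  write_geojson(r, dem, gj)
  parsed <- jsonlite::fromJSON(gj, simplifyVector = FALSE)
  expect_equal(parsed$type, "FeatureCollection")
  expect_equal(parsed$features[[1]]$geometry$type, "LineString")

  s <- travel_time_surface(dem, source_cell = c(3, 1))
  write_geojson(isochrones(s, 0.5), dem, gj)
  parsed2 <- jsonlite::fromJSON(gj, simplifyVector = FALSE)
  expect_gte(length(parsed2$features), 2)

  cs <- withr::local_tempfile(fileext = ".csv")
  write_travel_summary(r, cs)
  summ <- read.csv(cs)
  expect_equal(summ$round_trip_km, 2 * summ$one_way_km)

  # travel-time surface re-exported in the same grid dialect
  out <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(as_dem_raster(s$times, dem), out)
  expect_equal(read_ascii_grid(out)$elevation, s$times, tolerance = 1e-5)
})
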