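test_that("curve files parse, reject malformed input with line numbers, and round-trip", {
  path <- withr::local_tempfile(fileext = ".14c")
  writeLines(c("# comment", "100,550,12", "110, 560, 12", "120 575 13"),
             path)
  cc <- read_curve(path)
  expect_s3_class(cc, "calibration_curve")
  expect_equal(cc$cal_bp, c(100, 110, 120))
  expect_equal(cc$sigma, c(12, 12, 13))

  writeLines(c("100,550,12", "90,560,12", "120,575,13"), path)
  expect_error(read_curve(path), "line 2")
  writeLines(c("100,550", "110,560,12"), path)
  expect_error(read_curve(path), "line 1")

  cc2 <- synth_curve(seed = 3, span = c(0, 500), step = 5)
  p2 <- withr::local_tempfile(fileext = ".14c")
  write_curve(cc2, p2)
  expect_equal(as.data.frame(read_curve(p2)), as.data.frame(cc2))
})

test_that("a constant curve yields a uniform posterior", {
  cc <- calibration_curve(1:50, rep(500, 50), rep(10, 50))
  d <- calibrate(500, 20, cc)
  expect_equal(d$probability, rep(1 / 50, 50), tolerance = 1e-12)
})

test_that("identity curve with tiny curve error recovers the date's mean and sd", {
  cc <- synth_curve(seed = 1, span = c(4000, 6000), step = 1,
                    wiggle_amplitude = 0, curve_sigma = 1e-9)
  d <- calibrate(5000, 30, cc)
  expect_equal(sum(d$probability), 1, tolerance = 1e-12)
  m <- sum(d$cal_bp * d$probability)
  s <- sqrt(sum(d$probability * (d$cal_bp - m)^2))
  expect_equal(m, 5000, tolerance = 1)   # within one grid step
  expect_equal(s, 30, tolerance = 1)
  h <- hpd(d)
  expect_equal(nrow(h), 1)
  # central 95% interval matches +/- 1.96 sd within one grid step
  expect_equal(h$lo, 5000 - 1.96 * 30, tolerance = 2)
  expect_equal(h$hi, 5000 + 1.96 * 30, tolerance = 2)
  expect_gte(sum(h$mass), 0.95)
})

test_that("calibration is invariant to the grid direction of the input curve", {
  asc <- calibration_curve(1:100, (1:100) + 5, rep(10, 100))
  desc <- calibration_curve(100:1, (100:1) + 5, rep(10, 100))
  expect_equal(as.data.frame(calibrate(55, 8, asc)),
               as.data.frame(calibrate(55, 8, desc)))
})

test_that("a plateau curve produces a multi-interval HPD covering the level", {
  grid <- seq(1, 300)
  mu <- ifelse((grid >= 60 & grid <= 90) | (grid >= 200 & grid <= 230),
               1000, 2000)
  cc <- calibration_curve(grid, mu, rep(10, 300))
  d <- calibrate(1000, 10, cc)
  h <- hpd(d, 0.95)
  expect_gte(nrow(h), 2)
  expect_gte(sum(h$mass), 0.95)
  # intervals are disjoint and sorted
  expect_true(all(diff(h$lo) > 0))
  expect_true(all(h$hi[-nrow(h)] < h$lo[-1]))
})

test_that("HPD of a uniform density takes the forced cell count, ties to older cells", {
  cc <- calibration_curve(1:100, rep(50, 100), rep(10, 100))
  d <- calibrate(50, 10, cc)
  h <- hpd(d, 0.95)
  expect_equal(sum(h$hi - h$lo + 1), ceiling(0.95 * 100))
  expect_equal(h$hi[nrow(h)], 100)  # older (larger cal BP) cells preferred

  # near-point mass: one cell already exceeds the level
  cc2 <- calibration_curve(1:20, c(rep(5000, 1), rep(9000, 19)), rep(1, 20))
  d2 <- calibrate(5000, 1, cc2)
  h2 <- hpd(d2, 0.95)
  expect_equal(nrow(h2), 1)
  expect_equal(h2$lo, h2$hi)
  expect_error(hpd(d2, 1.2), "level")
})

test_that("grid refinement moves HPD endpoints by at most one coarse step", {
  cc <- synth_curve(seed = 9, span = c(3000, 7000), step = 10,
                    wiggle_amplitude = 30)
  d_coarse <- calibrate(5000, 40, cc)
  d_fine <- calibrate(5000, 40, cc, resolution = 5)
  expect_equal(sum(d_fine$probability), 1, tolerance = 1e-12)
  h1 <- hpd(d_coarse); h2 <- hpd(d_fine)
  expect_lte(abs(min(h1$lo) - min(h2$lo)), 10)
  expect_lte(abs(max(h1$hi) - max(h2$hi)), 10)
})

test_that("out-of-coverage dates and invalid inputs are rejected", {
  cc <- calibration_curve(1:100, 1:100, rep(5, 100))
  expect_error(calibrate(5000, 10, cc), "coverage")
  expect_error(calibrate(50, -1, cc), "sigma")
  expect_error(calibrate(-5, 10, cc), ">= 0")
  expect_error(calibration_curve(c(1, 1, 2), 1:3, rep(1, 3)), "monotone")
  expect_error(calibration_curve(1:3, 1:3, c(1, 0, 1)), "positive")
})

test_that("synthetic curves are reproducible under a seed", {
  a <- synth_curve(seed = 42, span = c(0, 1000))
  b <- synth_curve(seed = 42, span = c(0, 1000))
  c2 <- synth_curve(seed = 43, span = c(0, 1000))
  expect_identical(a, b)
  expect_false(identical(a$c14_age, c2$c14_age))
})
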