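test_that("collagen QC passes exactly the stated rectangle, boundaries inclusive", {
  ok <- collagen_qc(44, 16)
  expect_equal(ok$atomic_cn_ratio, (44 / 12.011) / (16 / 14.007))
  expect_equal(round(ok$atomic_cn_ratio, 1), 3.2)
  expect_true(ok$passes)

  # equal mole counts give ratio exactly 1, below the 2.9 floor
  expect_false(collagen_qc(12.011, 14.007)$passes)
  expect_equal(collagen_qc(12.011, 14.007)$atomic_cn_ratio, 1)

  # boundary mass fractions are inclusive but can fail on the ratio:
  # (35, 11) has C:N 3.711 > 3.6
  b <- collagen_qc(35, 11)
  expect_equal(round(b$atomic_cn_ratio, 3), 3.711)
  expect_false(b$passes)

  # a point inside on every margin, sitting exactly on three boundaries
  expect_true(collagen_qc(35, 14.007 * 35 / 12.011 / 2.9)$passes)
  expect_error(collagen_qc(44, 0), "\\(0, 100\\]")
  expect_error(collagen_qc(-1, 12), "\\(0, 100\\]")
})

test_that("zone classification is strict at the threshold and monotone", {
  expect_equal(as.character(classify_zone(c(-13.46, -8, -5))),
               c("highland", "lowland", "lowland"))
  # monotone: lowering a value never flips highland -> lowland
  set.seed(11)
  v <- runif(100, -20, 0)
  z1 <- classify_zone(v) == "highland"
  z2 <- classify_zone(v - runif(100, 0, 5)) == "highland"
  expect_true(all(z2 >= z1))
  expect_error(classify_zone(NA_real_), "finite")
})

test_that("KS statistic matches brute-force ECDF enumeration and is symmetric", {
  expect_equal(ks_two_sample(1:5, 1:5)$D, 0)
  expect_equal(ks_two_sample(c(1, 2, 3), c(10, 11, 12))$D, 1)
  expect_equal(ks_two_sample(c(1, 2), c(1.5, 2.5))$D, 0.5)
  set.seed(7)
  for (i in 1:40) {
    a <- round(rnorm(sample(1:20, 1)), 1)
    b <- round(rnorm(sample(1:20, 1), mean = runif(1, -2, 2)), 1)
    r <- ks_two_sample(a, b)
    expect_equal(r$D, ks_oracle_D(a, b), tolerance = 1e-12)
    expect_true(r$D >= 0 && r$D <= 1)
    expect_equal(r$D, ks_two_sample(b, a)$D)
  }
  expect_error(ks_two_sample(numeric(0), 1), "non-empty")
})

test_that("the packaged fixture loads with the published structure", {
  b <- smp_burials()
  expect_equal(nrow(b), 16)
  expect_equal(sum(b$sex == "f"), 8)
  expect_equal(sum(b$sex == "m"), 5)
  expect_true(all(b$d18O_mw_vsmow >= -18 & b$d18O_mw_vsmow <= -12))
  expect_true(all(b$age_min <= b$age_max))
  expect_true(all(b$d18o_source == "corrected_input"))
})

test_that("raw values are corrected through the default chain on read", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(burial_id = 1:2, bone_element = "rib",
                       d18O_carbonate_vpdb = c(-30, NA),
                       d18O_mw_vsmow = c(NA, -14),
                       sex = c("f", "m"), age_min = c(20, 30),
                       age_max = c(30, 40)),
            path, row.names = FALSE)
  x <- read_samples(path)
  expect_equal(x$d18o_source, c("chain_applied", "corrected_input"))
  expect_equal(x$d18O_mw_vsmow[1],
               apply_chain(-30, default_d18o_chain()), tolerance = 1e-12)
  expect_equal(x$d18O_mw_vsmow[2], -14)
})

test_that("window evaluation counts membership inclusively and flags support", {
  b <- smp_burials()
  w <- model_windows("table2")
  h18 <- evaluate_isotope_hypothesis(b, w, "d18o")
  perm <- h18[h18$model == "permanent", ]
  expect_equal(perm$n_inside, 16)
  expect_true(perm$supported)
  logi <- h18[h18$model == "logistical", ]
  expect_equal(logi$n_inside, 0)
  expect_false(logi$supported)

  # inclusive endpoints: a value exactly on the window edge is inside
  s <- data.frame(burial_id = 1, bone_element = "rib",
                  d18O_mw_vsmow = -8, d13C_diet_vpdb = NA,
                  sex = "f", age_min = 20, age_max = 30)
  h <- evaluate_isotope_hypothesis(s, w, "d18o")
  expect_true(h$supported[h$model == "permanent"])
  expect_true(h$supported[h$model == "logistical"])

  # a degenerate (empty) window supports nothing
  w_bad <- data.frame(model = "permanent", proxy = "d18o", lo = -5, hi = -8)
  expect_false(evaluate_isotope_hypothesis(s, w_bad, "d18o")$supported)

  # missing values are listed, not dropped silently
  s2 <- rbind(s, s); s2$burial_id <- 1:2; s2$d18O_mw_vsmow[2] <- NA
  h2 <- evaluate_isotope_hypothesis(s2, w, "d18o")
  expect_equal(attr(h2, "missing"), 2)
  expect_equal(h2$n_total[1], 1)
})

test_that("reference distribution tables are validated on read", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(label = "altiplano water", proxy = "water_d18O",
                       value = c(-15, -12)), path, row.names = FALSE)
  expect_equal(nrow(read_reference_distributions(path)), 2)
  write.csv(data.frame(label = "x", proxy = "bogus", value = 1), path,
            row.names = FALSE)
  expect_error(read_reference_distributions(path), "proxy")
})
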