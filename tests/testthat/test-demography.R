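test_that("interval apportionment spreads unit mass by bin overlap", {
  mk <- function(lo, hi) data.frame(burial_id = seq_along(lo),
                                    bone_element = "rib",
                                    d18O_mw_vsmow = -15,
                                    d13C_diet_vpdb = -22,
                                    sex = "f", age_min = lo, age_max = hi)
  # a point age lands wholly in its bin
  p <- build_profile(mk(25, 25))
  expect_equal(p$age_histogram$mass[p$age_histogram$bin_lo == 20], 1)
  # an interval inside one bin stays there
  p2 <- build_profile(mk(4, 6))
  expect_equal(p2$age_histogram$mass[p2$age_histogram$bin_lo == 0], 1)
  # an interval straddling two bins splits by overlap
  p3 <- build_profile(mk(15, 25))
  expect_equal(p3$age_histogram$mass[p3$age_histogram$bin_lo %in% c(10, 20)],
               c(0.5, 0.5))
  # midpoint mode pushes the whole unit into one bin
  p4 <- build_profile(mk(15, 25), method = "midpoint")
  expect_equal(p4$age_histogram$mass[p4$age_histogram$bin_lo == 20], 1)
})

test_that("histogram mass is conserved for any bin width", {
  b <- smp_burials()
  for (bw in c(5, 10, 20)) {
    p <- build_profile(b, bin_width = bw)
    expect_equal(sum(p$age_histogram$mass), p$n_aged, tolerance = 1e-9)
    expect_equal(p$n_aged, 16)
  }
})

test_that("individuals without ages are excluded and reported", {
  b <- smp_burials()
  b$age_min[3] <- NA
  p <- build_profile(b)
  expect_equal(p$n_aged, 15)
  expect_equal(p$excluded, 3)
  expect_equal(sum(p$age_histogram$mass), 15, tolerance = 1e-9)
})

test_that("parity chi-square matches the closed form, is symmetric, zero iff equal", {
  r <- sex_parity_chisq(8, 5)
  expect_equal(round(r$chi2, 2), 0.69)
  expect_equal(round(r$p, 2), 0.41)
  expect_equal(r$df, 1)
  expect_equal(sex_parity_chisq(5, 5)$chi2, 0)
  expect_equal(sex_parity_chisq(5, 5)$p, 1)
  expect_equal(sex_parity_chisq(10, 0)$chi2, 10)
  for (fm in list(c(3, 9), c(7, 2), c(1, 1))) {
    expect_equal(sex_parity_chisq(fm[1], fm[2])$chi2,
                 sex_parity_chisq(fm[2], fm[1])$chi2)
    expect_equal(sex_parity_chisq(fm[1], fm[2])$chi2 == 0,
                 fm[1] == fm[2])
  }
  expect_error(sex_parity_chisq(0, 0), "at least one")
})

test_that("asymptotic parity p tracks the exact binomial test at moderate n", {
  # the doubled exact p overshoots near 50:50 splits; the documented
  # asymptotic gap for totals of 10..20 stays below 0.25
  for (n in 10:20) for (f in 0:n) {
    d <- abs(sex_parity_chisq(f, n - f)$p - binom_parity_p(f, n - f))
    expect_lt(d, 0.25)
  }
})

test_that("cohort flags use interval intersection with the 4-8 and 50+ bands", {
  mk <- function(lo, hi, sex = "f") data.frame(
    burial_id = seq_along(lo), bone_element = "rib", d18O_mw_vsmow = -15,
    d13C_diet_vpdb = -22, sex = sex, age_min = lo, age_max = hi)
  p <- build_profile(mk(c(9, 20), c(15, 30)))
  expect_false(p$young_children_present)
  expect_false(p$old_adults_present)
  p2 <- build_profile(mk(c(7, 45), c(10, 55)))
  expect_true(p2$young_children_present)
  expect_true(p2$old_adults_present)
})

test_that("demographic scoring separates task groups from residential groups", {
  b <- smp_burials()
  res <- evaluate_demography(build_profile(b))
  expect_equal(res$supported, c(FALSE, TRUE, TRUE))
  parity <- attr(res, "parity")
  expect_equal(round(parity$chi2, 2), 0.69)

  # an all-male adult-only group supports only the logistical model
  task <- data.frame(burial_id = 1:12, bone_element = "rib",
                     d18O_mw_vsmow = -6, d13C_diet_vpdb = -25,
                     sex = "m", age_min = 20, age_max = 40)
  res2 <- evaluate_demography(build_profile(task))
  expect_equal(res2$supported, c(TRUE, FALSE, FALSE))

  # an empty profile is explicitly indeterminate
  empty <- task[0, ]
  res3 <- evaluate_demography(build_profile(empty))
  expect_true(all(is.na(res3$supported)))
})

test_that("profile CSV and parity JSON reports are written", {
  p <- build_profile(smp_burials())
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_profile(p, csv, js)
  hist <- read.csv(csv)
  expect_equal(sum(hist$mass), 16, tolerance = 1e-9)
  rep <- jsonlite::fromJSON(js)
  expect_equal(round(rep$chi2, 2), 0.69)
  expect_true(rep$young_children_present)
  expect_equal(rep$apportionment, "uniform")
})
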