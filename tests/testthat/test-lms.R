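test_that("LMS z-score formula handles both Box-Cox branches", {
  # value at the median is z = 0 for any L, S
  expect_equal(lms_zscore(10, L = 2, M = 10, S = 0.1), 0)
  expect_equal(lms_zscore(57.3, L = 0, M = 57.3, S = 0.04), 0)
  expect_equal(lms_zscore(18, L = -1.7, M = 18, S = 0.13), 0)
  # log-branch identity: value = M * exp(S) gives z = 1
  expect_equal(lms_zscore(20 * exp(0.13), L = 0, M = 20, S = 0.13), 1)
  # L = 1 reduces to (value - M) / (M * S)
  expect_equal(lms_zscore(22, L = 1, M = 20, S = 0.1), (22 - 20) / 2)
  expect_error(lms_zscore(-1, 1, 10, 0.1), "positive")
  expect_error(lms_zscore(10, 1, -1, 0.1), "M > 0")
})

test_that("inverse transform is the exact inverse over the valid domain", {
  for (L in c(-2, 0, 2)) {
    for (z in seq(-3, 3, by = 0.5)) {
      v <- zscore_to_value(z, L, M = 15, S = 0.1)
      expect_equal(lms_zscore(v, L, 15, 0.1), z, tolerance = 1e-9)
    }
  }
  # round-trip through a z picked via the closed-form inverse
  v <- zscore_to_value(1.5, L = 2, M = 10, S = 0.1)
  expect_equal(lms_zscore(v, 2, 10, 0.1), 1.5, tolerance = 1e-12)
  expect_equal(zscore_to_value(0, -1.3, 42.5, 0.2), 42.5)
  expect_error(zscore_to_value(-10, L = 2, M = 10, S = 0.1), "domain")
})

test_that("z-score is continuous in L across L = 0 and monotone in value", {
  eps <- 1e-8
  for (v in c(8, 15, 30)) {
    expect_equal(lms_zscore(v, L = eps, M = 15, S = 0.12),
                 lms_zscore(v, L = 0, M = 15, S = 0.12), tolerance = 1e-6)
  }
  for (L in c(-1.5, 0, 1.5)) {
    z <- lms_zscore(seq(5, 50, by = 5), L, M = 20, S = 0.15)
    expect_true(all(diff(z) > 0))
  }
})

test_that("LMS interpolation is linear between grid rows and range-checked", {
  tab <- lms_table(data.frame(
    sex = rep(c("male", "female"), each = 3),
    age_months = rep(c(60, 72, 84), 2),
    L = c(1.0, 0.8, 0.6, 1.1, 0.9, 0.7),
    M = c(18, 20, 22, 17.5, 19.5, 21.5),
    S = c(0.10, 0.12, 0.14, 0.11, 0.13, 0.15)), measure = "weight")
  # exact grid age returns the row
  expect_equal(as.numeric(interpolate_lms(tab, "male", 72)),
               c(0.8, 20, 0.12))
  # midway query: arithmetic mean of bracketing rows, per parameter
  expect_equal(as.numeric(interpolate_lms(tab, "female", 66)),
               c((1.1 + 0.9) / 2, (17.5 + 19.5) / 2, (0.11 + 0.13) / 2))
  expect_error(interpolate_lms(tab, "male", 50), "outside")
  expect_error(interpolate_lms(tab, "male", 90), "outside")
})

test_that("standardization matches independent evaluation of the closed form", {
  tab <- lms_table(data.frame(
    sex = "male", age_months = c(60, 72),
    L = c(1, 1), M = c(18, 20), S = c(0.10, 0.10)), measure = "weight")
  birth <- as.Date("2005-01-01")
  patients <- tibble::tibble(patient_id = "A", sex = "male",
                             birth_date = birth)
  # weight = M(1 + S) at the interpolated reference gives z = 1
  visit60 <- birth + ceiling(60 / 12 * 365.25)
  age60 <- as.numeric(visit60 - birth) * 12 / 365.25
  M60 <- 18 + (20 - 18) * (age60 - 60) / 12
  meas <- tibble::tibble(patient_id = "A", date = visit60, type = "weight",
                         value = M60 * 1.10, unit = "kg")
  std <- standardize_measurements(meas, patients, tab)
  expect_equal(std$z, 1, tolerance = 1e-9)
  # weight equal to interpolated M gives z = 0
  visit66 <- birth + round(66 / 12 * 365.25)
  meas2 <- tibble::tibble(patient_id = "A", date = visit66, type = "weight",
                          value = 19, unit = "kg")
  age_m <- as.numeric(visit66 - birth) * 12 / 365.25
  M_interp <- 18 + (20 - 18) * (age_m - 60) / 12
  meas2$value <- M_interp
  expect_equal(standardize_measurements(meas2, patients, tab)$z, 0,
               tolerance = 1e-9)
  # hand-evaluated batch: z = (v/M - 1)/S for L = 1 at interpolated M
  vals <- c(17.2, 21.4, 19.0)
  meas3 <- tibble::tibble(patient_id = "A", date = visit66, type = "weight",
                          value = vals, unit = "kg")
  std3 <- standardize_measurements(meas3, patients, tab)
  expect_equal(std3$z, (vals / M_interp - 1) / 0.10, tolerance = 1e-9)
  expect_equal(std3$percentile, 100 * pnorm(std3$z))
  # out-of-range ages are dropped with a warning
  meas4 <- tibble::tibble(patient_id = "A", date = birth + 3000,
                          type = "weight", value = 25, unit = "kg")
  expect_warning(out <- standardize_measurements(meas4, patients, tab),
                 "outside")
  expect_equal(nrow(out), 0)
  # unit mismatch is an error
  meas5 <- tibble::tibble(patient_id = "A", date = visit60, type = "weight",
                          value = 40, unit = "cm")
  expect_error(standardize_measurements(meas5, patients, tab), "kg")
})

test_that("percentile labels round half away from zero", {
  expect_identical(z_to_percentile_label(0), 50L)
  expect_identical(z_to_percentile_label(0.070), 53L)
  expect_identical(z_to_percentile_label(0.419), 66L)
  expect_identical(z_to_percentile_label(0.062), 52L)
  expect_identical(z_to_percentile_label(0.3835), 65L)
  expect_identical(z_to_percentile_label(c(-5, 5)), c(0L, 100L))
})

test_that("reasonableness filter keeps the inclusive [-4.5, 4.5] band", {
  expect_true(reasonableness_filter(0))
  expect_true(reasonableness_filter(4.5))
  expect_true(reasonableness_filter(-4.5))
  expect_false(reasonableness_filter(4.51))
  expect_false(reasonableness_filter(-4.51))
  expect_equal(reasonableness_filter(c(-4.5, -4.51, 0, 4.5, 4.51)),
               c(TRUE, FALSE, TRUE, TRUE, FALSE))
})

test_that("LMS tables reject malformed input and round-trip through CSV", {
  expect_error(lms_table(data.frame(sex = "male", age_months = c(10, 10),
                                    L = 1, M = 10, S = 0.1), "weight"),
               "duplicate")
  expect_error(lms_table(data.frame(sex = "male", age_months = 10,
                                    L = 1, M = -1, S = 0.1), "weight"),
               "M > 0")
  tab <- make_synthetic_lms_table("height", age_months = seq(24, 240, 12))
  path <- withr::local_tempfile(fileext = ".csv")
  write_lms_table(tab, path)
  back <- read_lms_table(path, "height")
  expect_equal(as.data.frame(back), as.data.frame(tab), tolerance = 1e-12)
  # CDC-style wide layout with numeric sex codes
  cdc <- data.frame(sex = c(1, 1, 2, 2), agemos = c(24, 36, 24, 36),
                    L = 1, M = c(12, 14, 11.5, 13.5), S = 0.1)
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(cdc, path2, row.names = FALSE)
  tab2 <- read_lms_table(path2, "weight")
  expect_equal(sort(unique(tab2$sex)), c("female", "male"))
  expect_equal(tab2$M[tab2$sex == "male"], c(12, 14))
})
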