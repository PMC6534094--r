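rx <- function(start, days, drug = "drugA", dose = "d1",
               class = "stimulant") {
  tibble::tibble(patient_id = "X", drug_name = drug, drug_class = class,
                 dose_label = dose, start_date = as.Date(start),
                 days_supply = as.integer(days))
}

test_that("gap allowance is 30 days except when the gap touches June-August", {
  expect_equal(gap_allowance("2010-10-10", "2010-11-20"), 30)
  expect_equal(gap_allowance("2010-06-15", "2010-09-30"), 121)
  # spans the boundary: any June day triggers the summer allowance
  expect_equal(gap_allowance("2010-05-20", "2010-06-02"), 121)
  expect_equal(gap_allowance("2010-09-01", "2010-09-02"), 30)
  expect_equal(gap_allowance("2010-12-01", "2011-05-30"), 30)
  # a gap spanning a whole year necessarily contains a summer
  expect_equal(gap_allowance("2010-09-01", "2011-09-02"), 121)
  expect_error(gap_allowance("2010-02-02", "2010-02-01"), "empty")
})

test_that("episodes merge across allowable gaps and split at longer ones", {
  # two 30-day prescriptions with a 10-day November gap: one episode
  p <- dplyr::bind_rows(rx("2010-10-01", 30), rx("2010-11-10", 30))
  eps <- build_episodes(p, "stimulant", "2010-10-01")
  expect_equal(nrow(eps), 1)
  expect_equal(eps$start_date, as.Date("2010-10-01"))
  expect_equal(eps$discontinuation_date, as.Date("2010-12-09"))
  # a 45-day February gap ends the first episode on the last covered day
  p2 <- dplyr::bind_rows(rx("2010-01-01", 30), rx("2010-03-17", 30))
  eps2 <- build_episodes(p2, "stimulant", "2010-01-01")
  expect_equal(nrow(eps2), 2)
  expect_equal(eps2$discontinuation_date[1], as.Date("2010-01-30"))
  # a 92-day gap entirely within June-August stays one episode
  p3 <- dplyr::bind_rows(rx("2010-04-16", 46), rx("2010-09-01", 30))
  eps3 <- build_episodes(p3, "stimulant", "2010-04-16")
  expect_equal(nrow(eps3), 1)
  # adjacent prescriptions create no gap
  p4 <- dplyr::bind_rows(rx("2010-01-01", 30), rx("2010-01-31", 30))
  expect_equal(nrow(build_episodes(p4, "stimulant", "2010-01-01")), 1)
  expect_equal(nrow(build_episodes(p4, "guanfacine", "2010-01-01")), 0)
})

test_that("per-dose prescribed amount sums lengths ignoring overlaps", {
  p <- dplyr::bind_rows(rx("2010-01-01", 30), rx("2010-02-01", 30),
                        rx("2010-03-05", 30), rx("2010-04-10", 30))
  expect_identical(prescribed_amount_per_dose(p), 120L)
  expect_identical(prescribed_amount_per_dose(p[0, ]), 0L)
  # two identical-day fills still count dispensed supply
  p2 <- dplyr::bind_rows(rx("2010-01-01", 30), rx("2010-01-01", 30))
  expect_identical(prescribed_amount_per_dose(p2), 60L)
  # clipping to a window
  expect_identical(
    prescribed_amount_per_dose(p, window = as.Date(c("2010-01-01",
                                                     "2010-01-15"))), 15L)
  expect_error(prescribed_amount_per_dose(
    dplyr::bind_rows(rx("2010-01-01", 30), rx("2010-01-01", 30, dose = "d2"))),
    "streams")
})

test_that("total prescribed amount caps between-stream overlap at 90 days", {
  # no overlaps: plain sum
  p <- dplyr::bind_rows(rx("2010-01-01", 30), rx("2010-02-15", 30, "drugB"))
  expect_identical(total_prescribed_amount(p), 60L)
  # 60 days of overlap <= 90: no reduction
  p2 <- dplyr::bind_rows(rx("2010-01-01", 100),
                         rx("2010-02-10", 100, "drugB"))
  expect_identical(total_prescribed_amount(p2), 200L)
  # two fully overlapping 200-day streams: T = 400, O = 200, keep 290
  p3 <- dplyr::bind_rows(rx("2010-01-01", 200),
                         rx("2010-01-01", 200, dose = "d2"))
  expect_identical(total_prescribed_amount(p3), 290L)
  # same-stream overlap adds supply but no capped overlap
  p4 <- dplyr::bind_rows(rx("2010-01-01", 200), rx("2010-01-01", 200))
  expect_identical(total_prescribed_amount(p4), 400L)
})

test_that("MPR is supply over episode length capped at one", {
  expect_equal(mpr(120, 120), 1)
  expect_equal(mpr(60, 120), 0.5)
  expect_equal(mpr(150, 120), 1)
  expect_error(mpr(10, 0), ">= 1")
})

test_that("exposure metrics summarise the first episode", {
  p <- dplyr::bind_rows(rx("2010-01-01", 30), rx("2010-02-05", 30),
                        rx("2010-12-01", 30))
  em <- exposure_metrics(p, "stimulant", "2010-01-01")
  # 5-day gap merges the first two fills; the 275-day autumn gap splits
  expect_equal(em$start_date, as.Date("2010-01-01"))
  expect_equal(em$discontinuation_date, as.Date("2010-03-06"))
  expect_equal(em$episode_length_days, 65L)
  expect_equal(em$prescribed_amount_days, 60L)
  expect_equal(em$mpr, 60 / 65)
  # censoring truncates the episode
  em2 <- exposure_metrics(p, "stimulant", "2010-01-01",
                          censor_date = "2010-02-10")
  expect_equal(em2$discontinuation_date, as.Date("2010-02-10"))
  expect_equal(nrow(exposure_metrics(p, "guanfacine", "2010-01-01")), 0)
})

test_that("episode building and amounts agree exactly with the daily-grid oracle", {
  set.seed(4021)
  for (rep in 1:150) {
    p <- random_rx_set()
    from <- min(p$start_date)
    got <- build_episodes(p, "stimulant", from)
    want <- oracle_episodes(p, "stimulant", from)
    expect_identical(got$start_date, want$start_date)
    expect_identical(got$discontinuation_date, want$discontinuation_date)
    win <- c(from, max(p$start_date + p$days_supply - 1))
    expect_identical(total_prescribed_amount(p, win),
                     oracle_total_amount(p, win))
  }
})

test_that("episode coverage responds monotonically to adding prescriptions", {
  set.seed(77)
  for (rep in 1:25) {
    p <- random_rx_set()
    from <- min(p$start_date)
    win <- c(from, max(p$start_date + p$days_supply - 1))
    full_amt <- total_prescribed_amount(p, win)
    full_ep <- build_episodes(p, "stimulant", from)
    full_end <- max(full_ep$discontinuation_date)
    if (nrow(p) > 1) {
      drop1 <- p[-sample.int(nrow(p), 1), , drop = FALSE]
      # removing a prescription never lengthens coverage or supply
      sub_from <- min(drop1$start_date)
      sub_ep <- build_episodes(drop1, "stimulant", sub_from)
      expect_lte(max(sub_ep$discontinuation_date), full_end)
      expect_lte(total_prescribed_amount(drop1, win), full_amt)
    }
  }
})

test_that("MPR is 1 for gapless single-stream coverage", {
  p <- dplyr::bind_rows(rx("2010-01-01", 30), rx("2010-01-31", 30),
                        rx("2010-03-02", 30))
  em <- exposure_metrics(p, "stimulant", "2010-01-01")
  expect_equal(em$mpr, 1)
})
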