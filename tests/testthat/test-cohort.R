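mk_rx <- function(class, start, days = 30L, drug = class, dose = "d1") {
  tibble::tibble(patient_id = "P1", drug_name = drug, drug_class = class,
                 dose_label = dose, start_date = as.Date(start),
                 days_supply = as.integer(days))
}
no_rx <- mk_rx("stimulant", "2010-01-01")[0, ]
dx_at <- function(date, code = "314.01") {
  tibble::tibble(patient_id = "P1", date = as.Date(date), icd9_code = code)
}

test_that("index date prefers study medication, then ADHD diagnosis", {
  cfg <- study_config()
  p_stim <- mk_rx("stimulant", "2010-05-01")
  expect_equal(find_index_date(p_stim, dx_at("2009-02-01"), cfg),
               as.Date("2010-05-01"))
  # diagnosis only
  expect_equal(find_index_date(no_rx, dx_at("2010-03-03"), cfg),
               as.Date("2010-03-03"))
  # atomoxetine is not a study medication
  expect_equal(find_index_date(mk_rx("atomoxetine", "2009-06-01"),
                               dx_at("2010-03-03"), cfg),
               as.Date("2010-03-03"))
  # all events before the study period: not indexable
  expect_true(is.na(find_index_date(no_rx, dx_at("2008-01-01"), cfg)))
  # prescriptions before the period are ignored for indexing
  expect_equal(find_index_date(mk_rx("stimulant", "2008-06-01"),
                               dx_at("2009-04-04"), cfg),
               as.Date("2009-04-04"))
})

test_that("censoring takes the earliest of age 20, study end, follow-up end", {
  cfg <- study_config()
  # 20th birthday during the study
  expect_equal(censor_date(as.Date("1992-06-15"), as.Date("2013-06-30"), cfg),
               as.Date("1992-06-15") + round(20 * 365.25) - 1)
  # active past the study end
  expect_equal(censor_date(as.Date("2004-01-01"), as.Date("2014-02-01"), cfg),
               as.Date("2013-06-30"))
  # lost to follow-up first
  expect_equal(censor_date(as.Date("2004-01-01"), as.Date("2011-03-01"), cfg),
               as.Date("2011-03-01"))
})

test_that("guanfacine subgroups follow the 28-day concurrency rule", {
  g0 <- as.Date("2011-03-01")
  gua <- mk_rx("guanfacine", g0)
  # no stimulant at all: first-line monotherapy
  expect_equal(assign_cohort(gua)$subgroup, "first_line_guanfacine_mono")
  # stimulant coverage ends 20 days after the first guanfacine fill
  stim20 <- mk_rx("stimulant", g0 + 20 - 29)          # covers to g0 + 20
  a <- assign_cohort(dplyr::bind_rows(gua, stim20))
  expect_equal(a$cohort, "guanfacine")
  expect_equal(a$subgroup, "nonfirst_line_guanfacine_mono")
  expect_equal(a$guanfacine_initiation_date, g0)
  # coverage ending exactly at day +28 still counts as monotherapy
  stim28 <- mk_rx("stimulant", g0 + 28 - 29)
  expect_equal(assign_cohort(dplyr::bind_rows(gua, stim28))$subgroup,
               "nonfirst_line_guanfacine_mono")
  # stimulant exposure ongoing at g0 and concurrent for 40 days: combined
  stim40 <- mk_rx("stimulant", g0 - 10, days = 51)
  expect_equal(assign_cohort(dplyr::bind_rows(gua, stim40))$subgroup,
               "combined_pharmacotherapy")
  # simultaneous stimulant fill on the initiation day: combined
  stim_sim <- mk_rx("stimulant", g0)
  expect_equal(assign_cohort(dplyr::bind_rows(gua, stim_sim))$subgroup,
               "combined_pharmacotherapy")
  # refill chain continuing past day 28 through post-initiation fills
  chain <- dplyr::bind_rows(mk_rx("stimulant", g0 - 40),
                            mk_rx("stimulant", g0 - 10),
                            mk_rx("stimulant", g0 + 21))
  expect_equal(assign_cohort(dplyr::bind_rows(gua, chain))$subgroup,
               "combined_pharmacotherapy")
  # stimulant-only patient and unmedicated patient
  expect_equal(assign_cohort(mk_rx("stimulant", "2010-02-02"))$cohort,
               "first_line_stimulant")
  expect_equal(assign_cohort(no_rx)$cohort, "unmedicated")
  # atomoxetine-only regimens belong to no cohort
  expect_true(is.na(assign_cohort(mk_rx("atomoxetine", "2010-02-02"))$cohort))
})

test_that("eligibility screens age, history, washout and measurements", {
  cfg <- study_config()
  patient <- tibble::tibble(patient_id = "P1",
                            birth_date = as.Date("2000-01-01"),
                            emr_start = as.Date("2007-01-01"),
                            emr_end = as.Date("2013-06-30"))
  idx <- as.Date("2010-06-01")
  cens <- as.Date("2013-06-30")
  std <- tibble::tibble(
    patient_id = "P1",
    date = as.Date(c("2010-03-01", "2010-08-01")),
    measure = "weight", raw_value = c(35, 36),
    age_years = 10.4, z = c(0.2, 0.3), percentile = 55)
  ok <- check_eligibility(patient, no_rx, dx_at("2009-01-15"), idx, idx,
                          cens, std, cens, cfg)
  expect_true(ok$eligible)
  # age: an 18.2-year-old at index is excluded
  old <- patient; old$birth_date <- idx - round(18.2 * 365.25)
  expect_match(check_eligibility(old, no_rx, dx_at("2009-01-15"), idx, idx,
                                 cens, std, cens, cfg)$reasons,
               "age_at_index", all = FALSE)
  # washout: atomoxetine six months pre-index
  atx <- mk_rx("atomoxetine", idx - 180)
  expect_match(check_eligibility(patient, atx, dx_at("2009-01-15"), idx, idx,
                                 cens, std, cens, cfg)$reasons,
               "washout_violation", all = FALSE)
  # missing baseline measurement
  post_only <- std[std$date >= idx, ]
  expect_match(check_eligibility(patient, no_rx, dx_at("2009-01-15"), idx,
                                 idx, cens, post_only, cens, cfg)$reasons,
               "no_baseline_measurement", all = FALSE)
  # no ADHD diagnosis anywhere
  expect_match(check_eligibility(patient, no_rx, dx_at("2009-01-15",
                                                       code = "296.2"),
                                 idx, idx, cens, std, cens, cfg)$reasons,
               "no_adhd_diagnosis", all = FALSE)
  # short EMR history
  late <- patient; late$emr_start <- idx - 100
  expect_match(check_eligibility(late, no_rx, dx_at("2009-01-15"), idx, idx,
                                 cens, std, cens, cfg)$reasons,
               "insufficient_emr_history", all = FALSE)
})

test_that("analysis measurements impute baseline to 0 and honour the 60-day tail", {
  cfg <- study_config()
  time0 <- as.Date("2011-01-01")
  disc <- as.Date("2011-06-30")
  cens <- as.Date("2013-06-30")
  std <- tibble::tibble(
    patient_id = "P1",
    date = c(time0 - 66, time0, disc + 59, disc + 61),
    measure = "weight", raw_value = 30,
    age_years = 9, z = c(0.5, 0.4, 0.3, 0.2), percentile = 60)
  sel <- select_analysis_measurements(std, time0, disc, cens, cfg)
  # baseline measured 66 days pre-initiation appears at t = 0
  expect_equal(sel$time_years[1], 0)
  expect_true(sel$baseline[1])
  expect_equal(sel$z[1], 0.5)
  # measurement 59 days after discontinuation is in; 61 days is out
  expect_equal(nrow(sel), 3)
  expect_false(any(sel$date == disc + 61))
  expect_equal(sel$time_years[-1],
               as.numeric(c(time0, disc + 59) - time0) / 365.25)
  # unmedicated: window runs to the censor date
  sel2 <- select_analysis_measurements(std, time0, NULL, cens, cfg)
  expect_equal(nrow(sel2), 4)
  # measurements past the censor date are never used
  sel3 <- select_analysis_measurements(std, time0, NULL, disc, cfg)
  expect_equal(nrow(sel3), 2)
  # z-values outside the reasonableness band are dropped
  std_bad <- std; std_bad$z[3] <- 4.6
  sel4 <- select_analysis_measurements(std_bad, time0, disc, cens, cfg)
  expect_false(any(sel4$z > 4.5))
})

test_that("cohort assignment recovers generator labels on synthetic patients", {
  pop <- simulate_population(sim_config(
    n_patients = 250, seed = 915,
    cohort_mix = c(first_line_guanfacine = 0.2,
                   nonfirst_line_guanfacine = 0.2, combined = 0.2,
                   first_line_stimulant = 0.2, unmedicated = 0.2)))
  std_w <- standardize_measurements(pop$measurements, pop$patients,
                                    pop$lms_weight)
  std_h <- standardize_measurements(pop$measurements, pop$patients,
                                    pop$lms_height)
  cb <- build_cohorts(pop$patients, pop$prescriptions, pop$diagnoses,
                      std_w, std_h)
  m <- merge(cb$assignments, pop$truth$patients, by = "patient_id")
  expect_equal(m$cohort, vapply(m$regimen, regimen_cohort, ""),
               ignore_attr = TRUE)
  expect_equal(m$subgroup, vapply(m$regimen, regimen_subgroup, ""),
               ignore_attr = TRUE)
  # cohorts partition patients; subgroups partition the guanfacine cohort
  expect_true(all(table(m$patient_id) == 1))
  expect_true(all(m$subgroup[m$cohort == "guanfacine"] != "none"))
  expect_true(all(m$subgroup[m$cohort != "guanfacine"] == "none"))
  # conservation: every patient is eligible or logged as excluded, per measure
  for (meas in c("weight", "height")) {
    excl_ids <- unique(cb$exclusions$patient_id[
      cb$exclusions$measure == meas])
    elig_ids <- cb$assignments$patient_id[
      cb$assignments[[paste0("eligible_", meas)]]]
    expect_equal(sort(c(excl_ids, elig_ids)),
                 sort(pop$patients$patient_id))
    expect_length(intersect(excl_ids, elig_ids), 0)
  }
  # no analysis measurement may postdate censoring
  s <- growthtraj:::build_analysis_set(cb$assignments, std_w, pop$patients,
                                       "weight")
  joined <- merge(s$observations, cb$assignments[c("patient_id",
                                                   "censor_date")])
  expect_true(all(joined$date <= joined$censor_date))
})
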