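ADHD_CODES <- c("314.0", "314.00", "314.01")
STUDY_CLASSES <- c("guanfacine", "stimulant")

#' Default study configuration
#'
#' Study-window and rule parameters used throughout cohort derivation.
#'
#' @param study_period_start,study_period_end Study period bounds (Date).
#' @param washout_months Pre-index months required free of ADHD medication.
#' @param tail_days Days after episode discontinuation still contributing
#'   measurements in the medicated cohorts.
#' @param combined_threshold_days Maximum days of stimulant coverage after
#'   the first guanfacine fill compatible with "monotherapy".
#' @param max_age_years Censoring age (observation ends the day before this
#'   birthday).
#' @return Named list of settings.
#' @export
study_config <- function(study_period_start = as.Date("2009-01-01"),
                         study_period_end = as.Date("2013-06-30"),
                         washout_months = 12,
                         tail_days = 60,
                         combined_threshold_days = 28,
                         max_age_years = 20) {
  list(study_period_start = as.Date(study_period_start),
       study_period_end = as.Date(study_period_end),
       washout_months = washout_months,
       tail_days = tail_days,
       combined_threshold_days = combined_threshold_days,
       max_age_years = max_age_years)
}

days_per_month <- 365.25 / 12

#' Index date for one patient
#'
#' The first date within the study period on which the patient received a
#' study-medication prescription (guanfacine or stimulant; atomoxetine is
#' not a study medication), or, failing that, the first in-period ADHD
#' diagnosis.
#'
#' @param prescriptions,diagnoses The patient's records.
#' @param config [study_config()].
#' @return A Date, or `NA` when the patient has no indexing event.
#' @export
find_index_date <- function(prescriptions, diagnoses, config = study_config()) {
  in_period <- function(d) d >= config$study_period_start &
    d <= config$study_period_end
  rx <- prescriptions[prescriptions$drug_class %in% STUDY_CLASSES &
                        in_period(prescriptions$start_date), , drop = FALSE]
  if (nrow(rx) > 0L) return(min(rx$start_date))
  dx <- diagnoses[diagnoses$icd9_code %in% ADHD_CODES &
                    in_period(diagnoses$date), , drop = FALSE]
  if (nrow(dx) > 0L) return(min(dx$date))
  as.Date(NA)
}

#' Censoring date for one patient
#'
#' Observation ends at the earliest of: the day before the patient's 20th
#' birthday, the end of the study period, and loss to follow-up (the last
#' encounter of any type in the extract).
#'
#' @param birth_date,emr_end Patient dates.
#' @param config [study_config()].
#' @return A Date.
#' @export
censor_date <- function(birth_date, emr_end, config = study_config()) {
  birthday20 <- as.Date(birth_date) +
    round(config$max_age_years * 365.25)
  min(birthday20 - 1L, config$study_period_end, as.Date(emr_end))
}

# Last covered day of stimulant exposure ongoing at or before `ref`:
# stimulant episodes (refill chains within the seasonal gap allowance) that
# begin on or before `ref` may extend past it through later refills.
stimulant_cov_end <- function(prescriptions, ref) {
  st <- prescriptions[prescriptions$drug_class == "stimulant", , drop = FALSE]
  if (nrow(st) == 0L || min(st$start_date) > ref) return(as.Date(NA))
  eps <- build_episodes(st, "stimulant", min(st$start_date))
  eps <- eps[eps$start_date <= ref, , drop = FALSE]
  if (nrow(eps) == 0L) return(as.Date(NA))
  max(eps$discontinuation_date)
}

#' Cohort and guanfacine-subgroup assignment for one patient
#'
#' * guanfacine cohort: any in-period guanfacine prescription; subgroup by
#'   stimulant exposure around the first guanfacine fill G0 --
#'   first-line monotherapy (no stimulant on or before G0),
#'   nonfirst-line monotherapy (stimulant coverage ends on or before
#'   G0 + 28 days and no stimulant starts on G0), or combined
#'   pharmacotherapy (a stimulant starts on G0 or stimulant coverage runs
#'   past G0 + 28 days).
#' * first-line stimulant monotherapy: in-period stimulant prescriptions and
#'   no guanfacine prescription at any time.
#' * unmedicated: no ADHD-medication prescriptions at all.
#' * atomoxetine-only regimens satisfy no cohort definition and are flagged.
#'
#' @param prescriptions One patient's prescriptions.
#' @param config [study_config()].
#' @return List with `cohort`, `subgroup`, `guanfacine_initiation_date`.
#' @export
assign_cohort <- function(prescriptions, config = study_config()) {
  in_period <- prescriptions$start_date >= config$study_period_start &
    prescriptions$start_date <= config$study_period_end
  gua <- prescriptions[prescriptions$drug_class == "guanfacine" & in_period, ,
                       drop = FALSE]
  if (nrow(gua) > 0L) {
    g0 <- min(gua$start_date)
    simultaneous <- any(prescriptions$drug_class == "stimulant" &
                          prescriptions$start_date == g0)
    cov_end <- stimulant_cov_end(prescriptions, g0)
    subgroup <-
      if (is.na(cov_end) && !simultaneous) {
        "first_line_guanfacine_mono"
      } else if (simultaneous ||
                 as.numeric(cov_end - g0) > config$combined_threshold_days) {
        "combined_pharmacotherapy"
      } else {
        "nonfirst_line_guanfacine_mono"
      }
    return(list(cohort = "guanfacine", subgroup = subgroup,
                guanfacine_initiation_date = g0))
  }
  any_guanfacine <- any(prescriptions$drug_class == "guanfacine")
  any_stim <- any(prescriptions$drug_class == "stimulant" & in_period)
  if (!any_guanfacine && any_stim) {
    return(list(cohort = "first_line_stimulant", subgroup = "none",
                guanfacine_initiation_date = as.Date(NA)))
  }
  adhd_rx <- prescriptions$drug_class %in%
    c(STUDY_CLASSES, "atomoxetine")
  if (!any(adhd_rx)) {
    return(list(cohort = "unmedicated", subgroup = "none",
                guanfacine_initiation_date = as.Date(NA)))
  }
  list(cohort = NA_character_, subgroup = "none",
       guanfacine_initiation_date = as.Date(NA))
}

#' Eligibility check for one patient
#'
#' Verifies, against one measure's standardized measurements: ADHD diagnosis
#' at any time; age at index in [4, 18) years; EMR history of at least
#' `washout_months` before index; no guanfacine/stimulant/atomoxetine
#' prescription during the washout; a baseline measurement (most recent in
#' the 12 months before time 0); and at least one eligible postbaseline
#' measurement. `time0` is the guanfacine initiation date for the
#' guanfacine cohort, the index date otherwise.
#'
#' @param patient One patient row (`birth_date`, `emr_start`, `emr_end`).
#' @param prescriptions,diagnoses The patient's records.
#' @param index_date,time0,censor Dates from indexing/assignment.
#' @param std Standardized measurements for one measure (may be empty).
#' @param analysis_end Last day measurements may contribute (episode end +
#'   tail for medicated cohorts, censor date otherwise).
#' @param config [study_config()].
#' @return List `eligible` (logical) and `reasons` (character vector).
#' @export
check_eligibility <- function(patient, prescriptions, diagnoses, index_date,
                              time0, censor, std, analysis_end,
                              config = study_config()) {
  reasons <- character()
  if (!any(diagnoses$icd9_code %in% ADHD_CODES)) {
    reasons <- c(reasons, "no_adhd_diagnosis")
  }
  if (is.na(index_date)) {
    reasons <- c(reasons, "not_indexable")
    return(list(eligible = FALSE, reasons = reasons))
  }
  age_idx <- as.numeric(index_date - patient$birth_date) / 365.25
  if (age_idx < 4 || age_idx >= 18) reasons <- c(reasons, "age_at_index")
  washout_start <- index_date - round(config$washout_months * days_per_month)
  if (patient$emr_start > washout_start) {
    reasons <- c(reasons, "insufficient_emr_history")
  }
  wash_rx <- prescriptions$drug_class %in%
    c(STUDY_CLASSES, "atomoxetine") &
    prescriptions$start_date >= washout_start &
    prescriptions$start_date < index_date
  if (any(wash_rx)) reasons <- c(reasons, "washout_violation")
  base <- baseline_measurement(std, time0)
  if (is.null(base)) {
    reasons <- c(reasons, "no_baseline_measurement")
  } else if (!reasonableness_filter(base$z)) {
    reasons <- c(reasons, "baseline_fails_reasonableness")
  }
  post <- std[std$date >= time0 & std$date <= min(analysis_end, censor) &
                reasonableness_filter(std$z), , drop = FALSE]
  if (nrow(post) == 0L) reasons <- c(reasons, "no_postbaseline_measurement")
  list(eligible = length(reasons) == 0L, reasons = reasons)
}

# most recent measurement in the 12 months strictly before time0
baseline_measurement <- function(std, time0) {
  window_start <- time0 - 365L
  b <- std[std$date >= window_start & std$date < time0, , drop = FALSE]
  if (nrow(b) == 0L) return(NULL)
  b[which.max(b$date), , drop = FALSE]
}

#' Select the measurements entering the trajectory analysis
#'
#' The baseline measurement (most recent in the 12 months before time 0) is
#' imputed to time 0; postbaseline measurements run from time 0 (inclusive)
#' through discontinuation + `tail_days` for medicated cohorts or through
#' the censor date for the unmedicated cohort, never past censoring. All
#' values must pass the reasonableness filter. Time is in years
#' (days/365.25) from time 0.
#'
#' @param std One patient's standardized measurements for one measure.
#' @param time0 Guanfacine initiation date (guanfacine cohort) or index
#'   date (other cohorts).
#' @param discontinuation_date Episode end; `NULL` for unmedicated.
#' @param censor Censor date.
#' @param config [study_config()].
#' @return Tibble `date`, `time_years`, `z`, `baseline` (logical) --
#'   zero rows if there is no baseline or no postbaseline measurement.
#' @export
select_analysis_measurements <- function(std, time0, discontinuation_date,
                                         censor, config = study_config()) {
  empty <- tibble::tibble(date = as.Date(character()), time_years = numeric(),
                          z = numeric(), baseline = logical())
  base <- baseline_measurement(std, time0)
  if (is.null(base) || !reasonableness_filter(base$z)) return(empty)
  end <- if (is.null(discontinuation_date) || is.na(discontinuation_date)) {
    censor
  } else {
    min(as.Date(discontinuation_date) + config$tail_days, censor)
  }
  post <- std[std$date >= time0 & std$date <= end &
                reasonableness_filter(std$z), , drop = FALSE]
  if (nrow(post) == 0L) return(empty)
  tibble::tibble(
    date = c(base$date, post$date),
    time_years = c(0, as.numeric(post$date - time0) / 365.25),
    z = c(base$z, post$z),
    baseline = c(TRUE, rep(FALSE, nrow(post))))
}

#' Derive cohort assignments for a whole extract
#'
#' Runs indexing, cohort/subgroup assignment, censoring and per-measure
#' eligibility over every patient, and computes the initial-episode exposure
#' metrics for medicated cohorts.
#'
#' @param patients,prescriptions,diagnoses EMR extract tables.
#' @param std_weight,std_height Standardized measurements from
#'   [standardize_measurements()].
#' @param config [study_config()].
#' @return List with `assignments` (one row per patient: cohort, subgroup,
#'   dates, exposure metrics, per-measure eligibility and exclusion
#'   reasons) and `exclusions` (one row per excluded patient x measure x
#'   reason).
#' @export
build_cohorts <- function(patients, prescriptions, diagnoses,
                          std_weight, std_height, config = study_config()) {
  rx_by <- split(prescriptions, prescriptions$patient_id)
  dx_by <- split(diagnoses, diagnoses$patient_id)
  w_by <- split(std_weight, std_weight$patient_id)
  h_by <- split(std_height, std_height$patient_id)
  empty_rx <- prescriptions[0, , drop = FALSE]
  empty_dx <- diagnoses[0, , drop = FALSE]
  empty_std <- std_weight[0, , drop = FALSE]

  n <- nrow(patients)
  na_date <- as.Date(NA)
  acc <- list(
    patient_id = character(n), cohort = character(n), subgroup = character(n),
    index_date = rep(na_date, n), guanfacine_initiation_date = rep(na_date, n),
    time0 = rep(na_date, n), censor_date = rep(na_date, n),
    episode_start = rep(na_date, n), discontinuation_date = rep(na_date, n),
    episode_length_days = rep(NA_integer_, n),
    prescribed_amount_days = rep(NA_integer_, n), mpr = rep(NA_real_, n),
    stimulant_days_preguanfacine = integer(n),
    atomoxetine_before = logical(n), atomoxetine_during = logical(n),
    eligible_weight = logical(n), eligible_height = logical(n))
  excl_pid <- character(); excl_measure <- character()
  excl_reason <- character()
  for (i in seq_len(nrow(patients))) {
    p <- patients[i, , drop = FALSE]
    pid <- p$patient_id
    rx <- if (!is.null(rx_by[[pid]])) rx_by[[pid]] else empty_rx
    dx <- if (!is.null(dx_by[[pid]])) dx_by[[pid]] else empty_dx
    idx <- find_index_date(rx, dx, config)
    asg <- assign_cohort(rx, config)
    cens <- censor_date(p$birth_date, p$emr_end, config)
    time0 <- if (!is.na(asg$guanfacine_initiation_date)) {
      asg$guanfacine_initiation_date
    } else idx

    # initial exposure episode of the cohort-defining class
    exp_class <- switch(asg$cohort %or% "none",
                        guanfacine = "guanfacine",
                        first_line_stimulant = "stimulant",
                        NULL)
    em <- NULL
    if (!is.null(exp_class) && !is.na(time0)) {
      em <- exposure_metrics(rx, exp_class, time0, censor_date = cens)
      if (nrow(em) == 0L) em <- NULL
    }
    disc <- if (!is.null(em)) em$discontinuation_date else as.Date(NA)
    analysis_end <- if (!is.null(exp_class)) {
      if (!is.na(disc)) disc + config$tail_days else as.Date(NA)
    } else cens

    # stimulant supply before guanfacine initiation (guanfacine cohort)
    stim_pre <- 0L
    if (identical(asg$cohort, "guanfacine")) {
      st <- rx[rx$drug_class == "stimulant" & rx$start_date < time0, ,
               drop = FALSE]
      if (nrow(st) > 0L) {
        stim_pre <- total_prescribed_amount(
          st, window = c(min(st$start_date), time0 - 1L))
      }
    }
    atx_before <- FALSE; atx_during <- FALSE
    if (!is.na(time0)) {
      atx <- rx[rx$drug_class == "atomoxetine", , drop = FALSE]
      atx_before <- any(atx$start_date < time0)
      atx_during <- !is.na(disc) && any(atx$start_date >= time0 &
                                          atx$start_date <= disc)
    }

    per_measure <- list()
    for (meas in c("weight", "height")) {
      std_all <- if (meas == "weight") w_by[[pid]] else h_by[[pid]]
      if (is.null(std_all)) std_all <- empty_std
      ok <- if (is.na(asg$cohort) || is.na(time0) ||
                (!is.null(exp_class) && is.na(analysis_end))) {
        list(eligible = FALSE,
             reasons = if (is.na(asg$cohort)) "no_cohort" else
               if (is.na(time0)) "not_indexable" else "no_exposure_episode")
      } else {
        check_eligibility(p, rx, dx, idx, time0, cens, std_all,
                          analysis_end %or% cens, config)
      }
      per_measure[[meas]] <- ok
      if (!ok$eligible) {
        k <- length(ok$reasons)
        excl_pid <- c(excl_pid, rep(pid, k))
        excl_measure <- c(excl_measure, rep(meas, k))
        excl_reason <- c(excl_reason, ok$reasons)
      }
    }

    acc$patient_id[i] <- pid
    acc$cohort[i] <- asg$cohort
    acc$subgroup[i] <- asg$subgroup
    acc$index_date[i] <- idx
    acc$guanfacine_initiation_date[i] <- asg$guanfacine_initiation_date
    acc$time0[i] <- time0
    acc$censor_date[i] <- cens
    if (!is.null(em)) {
      acc$episode_start[i] <- em$start_date
      acc$discontinuation_date[i] <- em$discontinuation_date
      acc$episode_length_days[i] <- em$episode_length_days
      acc$prescribed_amount_days[i] <- em$prescribed_amount_days
      acc$mpr[i] <- em$mpr
    }
    acc$stimulant_days_preguanfacine[i] <- stim_pre
    acc$atomoxetine_before[i] <- atx_before
    acc$atomoxetine_during[i] <- atx_during
    acc$eligible_weight[i] <- per_measure$weight$eligible
    acc$eligible_height[i] <- per_measure$height$eligible
  }
  list(assignments = tibble::as_tibble(acc),
       exclusions = tibble::tibble(patient_id = excl_pid,
                                   measure = excl_measure,
                                   reason = excl_reason))
}

`%or%` <- function(x, y) if (is.null(x) || (length(x) == 1 && is.na(x))) y else x
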