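#' Simulation configuration for the synthetic EMR generator
#'
#' Defaults emulate the structure of the source EMR extract: ages at index
#' 4-17 years skewed young, ~2:1 male predominance, regimen mix dominated
#' by first-line stimulant monotherapy, stimulant-cohort growth
#' trajectories declining then recovering (time -0.71, time^2 0.21 on the
#' z scale per year), near-flat unmedicated trajectories (0.0143, -0.0002),
#' guanfacine-cohort trajectories with subgroup-specific time paths, and
#' refill chains with 30-day fills, occasional refill delays, summer drug
#' holidays and eventual discontinuation.
#'
#' @param n_patients Number of patients to simulate.
#' @param seed Integer seed; fully determines the output.
#' @param study_period_start,study_period_end Study period (Date).
#' @param cohort_mix Named proportions over regimens
#'   `first_line_guanfacine`, `nonfirst_line_guanfacine`, `combined`,
#'   `first_line_stimulant`, `unmedicated`; must sum to 1.
#' @param growth_params Data frame of per-regimen truth: `regimen`,
#'   `level_weight`, `level_height` (pre-initiation z levels),
#'   `time_weight`, `time2_weight`, `time_height`, `time2_height`
#'   (post-initiation trajectory coefficients), `delta_weight`,
#'   `delta_height` (step shifts at initiation).
#' @param random_effect_sd Length-3 SDs of the per-patient random
#'   intercept/slope/quadratic deviations.
#' @param random_effect_corr Common pairwise correlation of the random
#'   effects (the implied 3x3 covariance must be PSD).
#' @param residual_sd Measurement noise SD on the z scale.
#' @param visit_rate Mean measurement visits per year.
#' @param dropout_retention Named annual retention (probability of
#'   remaining under observation one year) for `medicated` and
#'   `unmedicated` patients.
#' @param rx_params List: `days_supply` (fill length), `gap_mean` (mean
#'   refill delay, days), `holiday_prob` (probability of a summer drug
#'   holiday per chain), `dose_change_prob` (per-refill probability of
#'   switching to a new dose stream), `exposure_mean_days` (mean intended
#'   treatment duration).
#' @param prob_male Probability a simulated patient is male.
#' @param height_measure_prob Probability a visit records height as well
#'   as weight.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(
    n_patients = 2000,
    seed = 20090101,
    study_period_start = as.Date("2009-01-01"),
    study_period_end = as.Date("2013-06-30"),
    cohort_mix = c(first_line_guanfacine = 0.020,
                   nonfirst_line_guanfacine = 0.017,
                   combined = 0.035,
                   first_line_stimulant = 0.688,
                   unmedicated = 0.240),
    growth_params = default_growth_params(),
    random_effect_sd = c(0.95, 0.15, 0.05),
    random_effect_corr = -0.1,
    residual_sd = 0.15,
    visit_rate = 3,
    dropout_retention = c(medicated = 0.5, unmedicated = 0.6),
    rx_params = list(days_supply = 30L, gap_mean = 6, holiday_prob = 0.25,
                     dose_change_prob = 0.1, exposure_mean_days = 250),
    prob_male = 0.67,
    height_measure_prob = 0.85) {
  if (abs(sum(cohort_mix) - 1) > 1e-8 || any(cohort_mix < 0)) {
    stop("cohort_mix must be non-negative and sum to 1", call. = FALSE)
  }
  need <- c("first_line_guanfacine", "nonfirst_line_guanfacine", "combined",
            "first_line_stimulant", "unmedicated")
  if (!setequal(names(cohort_mix), need)) {
    stop("cohort_mix must name exactly: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(random_effect_sd < 0) || residual_sd < 0) {
    stop("variances must be non-negative", call. = FALSE)
  }
  G <- re_covariance(random_effect_sd, random_effect_corr)
  if (min(eigen(G, symmetric = TRUE, only.values = TRUE)$values) < -1e-10) {
    stop("random-effect covariance is not positive semidefinite",
         call. = FALSE)
  }
  structure(list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    study_period_start = as.Date(study_period_start),
    study_period_end = as.Date(study_period_end),
    cohort_mix = cohort_mix[need], growth_params = growth_params,
    random_effect_sd = random_effect_sd,
    random_effect_corr = random_effect_corr,
    random_effect_covariance = G,
    residual_sd = residual_sd, visit_rate = visit_rate,
    dropout_retention = dropout_retention, rx_params = rx_params,
    prob_male = prob_male, height_measure_prob = height_measure_prob),
    class = "sim_config")
}

re_covariance <- function(sd3, corr) {
  R <- matrix(corr, 3, 3); diag(R) <- 1
  diag(sd3) %*% R %*% diag(sd3)
}

#' Default per-regimen growth truth
#'
#' Pre-initiation z levels follow typical baseline means of the respective
#' cohorts (slightly above the reference median; lower after prior
#' stimulant exposure); post-initiation time paths are declining-then-
#' recovering for stimulant-containing regimens and near flat otherwise.
#'
#' @return Data frame consumed by [sim_config()].
#' @export
default_growth_params <- function() {
  tibble::tribble(
    ~regimen,                   ~level_weight, ~level_height,
      ~time_weight, ~time2_weight, ~time_height, ~time2_height,
      ~delta_weight, ~delta_height,
    "first_line_guanfacine",     0.348,  0.166,
      0.16,  -0.052,  -0.021, 0.0098,  0.0648, -0.0087,
    "nonfirst_line_guanfacine",  0.075,  0.074,
      0.174, -0.052,  -0.044, 0.0098,  0,       0,
    "combined",                 -0.090,  0.000,
      -0.021, -0.052, -0.167, 0.0098,  0,       0,
    "first_line_stimulant",      0.419,  0.198,
      -0.7100, 0.2127, -0.2141, 0.0296, -0.1346, -0.0242,
    "unmedicated",               0.378,  0.223,
      0.0143, -0.0002, -0.0133, 0.0033, 0,       0
  )
}

#' Synthetic LMS reference table
#'
#' Smooth, plausible L/M/S curves over a 24-240 month grid (median weight
#' rising sigmoidally from ~10 to ~74 kg, height saturating toward adult
#' stature, males slightly larger), for testing the pipeline without an
#' external reference download.
#'
#' @param measure `"weight"` or `"height"`.
#' @param age_months Monotone grid of ages in months.
#' @return An [lms_table()].
#' @export
make_synthetic_lms_table <- function(measure = c("weight", "height"),
                                     age_months = seq(24, 240.5, by = 1)) {
  measure <- match.arg(measure)
  if (is.unsorted(age_months, strictly = TRUE)) {
    stop("age grid must be strictly increasing", call. = FALSE)
  }
  rows <- do.call(rbind, lapply(c("male", "female"), function(sx) {
    y <- age_months / 12
    bump <- if (sx == "male") 1.03 else 1.00
    if (measure == "weight") {
      M <- bump * (8 + 70 / (1 + exp(-(y - 12) / 3)))
      L <- 1.2 - 2.2 * (y - 2) / 18
      S <- 0.12 + 0.06 * (y - 2) / 18
    } else {
      M <- bump * (85 + 95 * (1 - exp(-(y - 2) / 9)))
      L <- rep(1, length(y))
      S <- 0.042 - 0.004 * (y - 2) / 18
    }
    data.frame(sex = sx, age_months = age_months, L = L, M = M, S = S)
  }))
  lms_table(rows, measure = measure)
}

# gapless refill chain whose coverage ends exactly on `end` (last fill
# truncated); used where the subgroup definition depends on the precise
# coverage end relative to guanfacine initiation
chain_exact <- function(patient_id, drug_class, start, end, days_supply) {
  start <- as.Date(start); end <- as.Date(end)
  total <- as.integer(end - start) + 1L
  n_full <- total %/% days_supply
  rem <- total %% days_supply
  starts <- start + days_supply * seq_len(n_full + (rem > 0)) - days_supply
  supplies <- c(rep(days_supply, n_full), if (rem > 0) rem)
  drug_name <- switch(drug_class, guanfacine = "guanfacine ER",
                      stimulant = "methylphenidate", drug_class)
  tibble::tibble(patient_id = patient_id, drug_name = drug_name,
                 drug_class = drug_class,
                 dose_label = paste0(drug_name, " dose-1"),
                 start_date = starts, days_supply = as.integer(supplies))
}

# gamma-increment renewal process of visit dates in [from, to]
sim_visit_dates <- function(from, to, rate) {
  if (to < from) return(as.Date(character()))
  mean_gap <- 365.25 / rate
  dates <- c()
  d <- from + round(stats::rgamma(1, shape = 2, scale = mean_gap / 2))
  while (d <= to) {
    dates <- c(dates, d)
    d <- d + max(1, round(stats::rgamma(1, shape = 2, scale = mean_gap / 2)))
  }
  as.Date(dates, origin = "1970-01-01")
}

#' Simulate a refill chain of prescriptions
#'
#' Generates consecutive fills of `days_supply` days for one drug class,
#' with small random refill delays, an optional summer drug holiday (a gap
#' of up to 121 days anchored inside June-August), and occasional dose
#' changes that open a new dose stream. The chain ends when the intended
#' exposure duration is exhausted or `until` is reached.
#'
#' @param patient_id Patient identifier.
#' @param drug_class `"guanfacine"`, `"stimulant"` or `"atomoxetine"`.
#' @param start Date of the first fill.
#' @param intended_days Target total treatment duration in days.
#' @param rx_params See [sim_config()].
#' @param until Hard stop; no fill starts after this date.
#' @return Tibble of prescription records.
#' @export
simulate_prescriptions <- function(patient_id, drug_class, start,
                                   intended_days, rx_params,
                                   until = as.Date("2013-06-30")) {
  ds <- rx_params$days_supply
  drug_name <- switch(drug_class, guanfacine = "guanfacine ER",
                      stimulant = "methylphenidate", drug_class)
  dose_level <- 1L
  holiday_left <- stats::runif(1) < rx_params$holiday_prob
  starts <- integer(); doses <- integer()
  d <- as.Date(start)
  supplied <- 0L
  while (supplied < intended_days && d <= until) {
    starts <- c(starts, as.integer(d))
    doses <- c(doses, dose_level)
    supplied <- supplied + ds
    gap <- if (rx_params$gap_mean > 0) {
      stats::rpois(1, rx_params$gap_mean)
    } else 0L
    nxt <- d + ds + gap
    # one summer holiday per chain: jump past a June-August interruption
    if (holiday_left && as.integer(format(nxt, "%m")) %in% 6:8) {
      nxt <- nxt + sample(40:110, 1)
      holiday_left <- FALSE
    }
    if (stats::runif(1) < rx_params$dose_change_prob) {
      dose_level <- dose_level + 1L
    }
    d <- nxt
  }
  k <- length(starts)
  tibble::new_tibble(list(
    patient_id = rep(patient_id, k), drug_name = rep(drug_name, k),
    drug_class = rep(drug_class, k),
    dose_label = paste0(drug_name, " dose-", doses),
    start_date = as.Date(starts, origin = "1970-01-01"),
    days_supply = rep(ds, k)), nrow = k)
}

#' Simulate growth measurements for one patient
#'
#' Generates weight/height z-scores at the visit dates from the
#' random-coefficients truth: a flat pre-initiation level, then (from time
#' 0 = `time0`) a step shift plus quadratic time trend, with per-patient
#' random intercept/slope/quadratic deviations and Gaussian measurement
#' noise. z-scores are converted to raw kg/cm through the inverse LMS
#' transform so the downstream pipeline ingests raw measurements.
#'
#' @param patient_id,sex,birth_date Patient attributes.
#' @param visit_dates Measurement dates.
#' @param time0 Treatment-initiation/index anchor date.
#' @param truth_row One row of `growth_params` for the patient's regimen.
#' @param b Length-3 random-effect vector (intercept, slope, quadratic).
#' @param config [sim_config()].
#' @param lms_weight,lms_height Active LMS tables.
#' @return List `measurements` (raw records) and `z_true` (tibble of the
#'   generated z-scores before unit conversion, for verification).
#' @export
simulate_growth <- function(patient_id, sex, birth_date, visit_dates, time0,
                            truth_row, b, config, lms_weight, lms_height) {
  t_years <- as.numeric(visit_dates - time0) / 365.25
  post <- t_years >= 0
  tpos <- pmax(t_years, 0)
  meas <- list(); ztru <- list()
  for (meas_type in c("weight", "height")) {
    keep <- if (meas_type == "height") {
      stats::runif(length(visit_dates)) <= config$height_measure_prob
    } else rep(TRUE, length(visit_dates))
    if (!any(keep)) next
    lv <- truth_row[[paste0("level_", meas_type)]]
    b1 <- truth_row[[paste0("time_", meas_type)]]
    b2 <- truth_row[[paste0("time2_", meas_type)]]
    dl <- truth_row[[paste0("delta_", meas_type)]]
    z <- lv + b[1] + post * dl +
      (b1 + b[2]) * tpos + (b2 + b[3]) * tpos^2 +
      stats::rnorm(length(visit_dates), sd = config$residual_sd)
    z <- z[keep]
    dts <- visit_dates[keep]
    table <- if (meas_type == "weight") lms_weight else lms_height
    age_m <- as.numeric(dts - birth_date) * 12 / 365.25
    rng <- range(table$age_months)
    ok <- age_m >= rng[1] & age_m <= rng[2]
    z <- z[ok]; dts <- dts[ok]; age_m <- age_m[ok]
    if (!length(z)) next
    lms <- interpolate_lms(table, sex, age_m)
    # z-scores beyond the Box-Cox domain have no raw-value counterpart;
    # such extremes are absent from real charts and are dropped here
    valid <- lms$L == 0 | (1 + lms$L * lms$S * z) > 1e-8
    if (!all(valid)) {
      z <- z[valid]; dts <- dts[valid]; lms <- lms[valid, , drop = FALSE]
      if (!length(z)) next
    }
    raw <- zscore_to_value(z, lms$L, lms$M, lms$S)
    k <- length(z)
    meas[[meas_type]] <- tibble::new_tibble(list(
      patient_id = rep(patient_id, k), date = dts,
      type = rep(meas_type, k), value = raw,
      unit = rep(if (meas_type == "weight") "kg" else "cm", k)), nrow = k)
    ztru[[meas_type]] <- tibble::new_tibble(list(
      patient_id = rep(patient_id, k), date = dts,
      type = rep(meas_type, k), z_true = z), nrow = k)
  }
  list(measurements = dplyr::bind_rows(meas), z_true = dplyr::bind_rows(ztru))
}

#' Simulate a synthetic EMR extract
#'
#' Draws a population under the configured regimen mix and growth truth and
#' emits the four extract tables (patients, prescriptions, diagnoses,
#' measurements) plus the generator labels needed for label-recovery and
#' parameter-recovery checks. Output is fully determined by
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @param lms_weight,lms_height LMS tables used to convert generated
#'   z-scores to raw units; default synthetic tables.
#' @return List of tibbles: `patients`, `prescriptions`, `diagnoses`,
#'   `measurements`, `truth` (per-patient regimen labels, time 0, random
#'   effects, true z-scores joined by patient/date/type), and the two LMS
#'   tables used.
#' @export
simulate_population <- function(config = sim_config(),
                                lms_weight = make_synthetic_lms_table("weight"),
                                lms_height = make_synthetic_lms_table("height")) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_patients
  regimens <- sample(names(config$cohort_mix), n, replace = TRUE,
                     prob = config$cohort_mix)
  Gchol <- chol(config$random_effect_covariance +
                  diag(1e-12, 3))
  rx <- vector("list", n); ms <- vector("list", n); ztr <- vector("list", n)
  na_date <- rep(as.Date(NA), n)
  P <- list(patient_id = character(n), sex = character(n),
            birth_date = na_date, emr_start = na_date, emr_end = na_date)
  D <- list(patient_id = character(n), date = na_date,
            icd9_code = character(n))
  TR <- list(patient_id = character(n), regimen = character(n),
             index_date = na_date, guanfacine_initiation_date = na_date,
             time0 = na_date, b0 = numeric(n), b1 = numeric(n),
             b2 = numeric(n))
  for (i in seq_len(n)) {
    pid <- sprintf("P%05d", i)
    reg <- regimens[i]
    sex <- if (stats::runif(1) < config$prob_male) "male" else "female"
    # index dates in the first ~3.5 years leave room for follow-up
    idx <- config$study_period_start +
      sample.int(as.integer(config$study_period_end - 180 -
                              config$study_period_start), 1)
    # ages skewed young: ~80% of guanfacine patients aged <= 9
    age_idx <- 4 + 14 * stats::rbeta(1, if (grepl("guanfacine|combined", reg))
      1.3 else 1.8, 3.2)
    birth <- idx - round(age_idx * 365.25)

    # treatment layout per regimen: time0 anchors the analysis clock
    stim_start <- as.Date(NA); g0 <- as.Date(NA)
    if (reg == "first_line_guanfacine") {
      g0 <- idx
    } else if (reg == "nonfirst_line_guanfacine") {
      stim_start <- idx
      g0 <- idx + sample(200:500, 1)
    } else if (reg == "combined") {
      stim_start <- idx
      g0 <- idx + sample(200:500, 1)
    } else if (reg == "first_line_stimulant") {
      stim_start <- idx
    }
    time0 <- if (!is.na(g0)) g0 else idx
    if (time0 > config$study_period_end - 90) {
      time0 <- config$study_period_end - 90
      if (!is.na(g0)) g0 <- time0 else idx <- time0
      if (reg %in% c("nonfirst_line_guanfacine", "combined")) {
        idx <- min(idx, g0 - 200)
        stim_start <- idx
      }
    }

    # EMR span: history covers the washout; loss to follow-up ~ exponential
    ret <- if (reg == "unmedicated") config$dropout_retention[["unmedicated"]]
           else config$dropout_retention[["medicated"]]
    followup_days <- round(365.25 *
      stats::rexp(1, rate = -log(max(ret, 1e-6)))) + 90
    emr_start <- idx - round(370 + stats::rexp(1, 1 / 200))
    emr_end <- min(time0 + followup_days, config$study_period_end)
    cens <- min(birth + round(20 * 365.25) - 1, config$study_period_end,
                emr_end)

    # diagnoses: everyone carries an ADHD code at or shortly before index
    D$patient_id[i] <- pid
    D$date[i] <- if (reg == "unmedicated") idx else idx - sample(0:30, 1)
    D$icd9_code[i] <- sample(c("314.00", "314.01"), 1)

    # prescriptions
    p_rx <- list()
    rxp <- config$rx_params
    if (!is.na(stim_start)) {
      if (reg == "nonfirst_line_guanfacine") {
        # stimulant coverage ends unambiguously <= 28 days after g0
        stim_end <- g0 + sample(c(-80:-1, 1:20), 1)
        ch <- chain_exact(pid, "stimulant", stim_start, stim_end,
                          rxp$days_supply)
        # a fill starting exactly on g0 would read as combined therapy
        p_rx[[length(p_rx) + 1L]] <- ch[ch$start_date != g0, , drop = FALSE]
      } else if (reg == "combined") {
        # stimulant coverage runs well past guanfacine initiation
        stim_end <- g0 + sample(60:200, 1)
        p_rx[[length(p_rx) + 1L]] <- chain_exact(
          pid, "stimulant", stim_start, stim_end, rxp$days_supply)
      } else {
        stim_days <- round(stats::rexp(1, 1 / rxp$exposure_mean_days)) +
          rxp$days_supply
        p_rx[[length(p_rx) + 1L]] <- simulate_prescriptions(
          pid, "stimulant", stim_start, stim_days, rxp,
          until = config$study_period_end)
      }
    }
    if (!is.na(g0)) {
      gua_days <- round(stats::rexp(1, 1 / rxp$exposure_mean_days)) +
        rxp$days_supply
      p_rx[[length(p_rx) + 1L]] <- simulate_prescriptions(
        pid, "guanfacine", g0, gua_days, rxp,
        until = config$study_period_end)
      # occasional atomoxetine use around guanfacine therapy; fills during
      # the washout year before the index date are never generated
      if (g0 - idx > 90 && stats::runif(1) < 0.08) {
        atx_start <- idx + sample.int(as.integer(g0 - idx) - 60, 1) + 29
        p_rx[[length(p_rx) + 1L]] <- simulate_prescriptions(
          pid, "atomoxetine", atx_start, 30, rxp, until = g0 - 1)
      }
      if (stats::runif(1) < 0.06) {
        p_rx[[length(p_rx) + 1L]] <- simulate_prescriptions(
          pid, "atomoxetine", g0 + 30, 30, rxp,
          until = config$study_period_end)
      }
    }
    rx[[i]] <- if (length(p_rx)) dplyr::bind_rows(p_rx) else NULL

    # visits: one guaranteed baseline-window visit + renewal process
    baseline_visit <- time0 - sample(10:160, 1)
    visits <- sort(unique(c(baseline_visit,
                            sim_visit_dates(time0, cens,
                                            config$visit_rate))))
    visits <- visits[visits >= emr_start & visits <= cens]

    b <- as.numeric(stats::rnorm(3) %*% Gchol)
    truth_row <- config$growth_params[
      config$growth_params$regimen == reg, , drop = FALSE]
    g <- simulate_growth(pid, sex, birth, visits, time0, truth_row, b,
                         config, lms_weight, lms_height)
    ms[[i]] <- g$measurements
    ztr[[i]] <- g$z_true

    P$patient_id[i] <- pid; P$sex[i] <- sex; P$birth_date[i] <- birth
    P$emr_start[i] <- emr_start; P$emr_end[i] <- max(emr_end, idx)
    TR$patient_id[i] <- pid; TR$regimen[i] <- reg; TR$index_date[i] <- idx
    TR$guanfacine_initiation_date[i] <- g0; TR$time0[i] <- time0
    TR$b0[i] <- b[1]; TR$b1[i] <- b[2]; TR$b2[i] <- b[3]
  }
  list(patients = tibble::as_tibble(P),
       prescriptions = dplyr::bind_rows(rx),
       diagnoses = tibble::as_tibble(D),
       measurements = dplyr::bind_rows(ms),
       truth = list(patients = tibble::as_tibble(TR),
                    z_true = dplyr::bind_rows(ztr),
                    growth_params = config$growth_params),
       lms_weight = lms_weight, lms_height = lms_height)
}

#' Simulate balanced data straight from the random-coefficients model
#'
#' A compact generator for parameter-recovery studies: every patient gets
#' `visits` equally spaced observations on `[0, t_max]` years with
#' z following `beta0 + beta1 t + beta2 t^2` plus multivariate-normal
#' random effects and Gaussian noise.
#'
#' @param n_patients,visits Design size.
#' @param beta Length-3 fixed effects (intercept, time, time^2).
#' @param re_sd Length-3 random-effect SDs.
#' @param re_corr Common random-effect correlation.
#' @param residual_sd Noise SD.
#' @param t_max Last visit time in years.
#' @param seed Integer seed.
#' @return Tibble `patient_id`, `time_years`, `z`.
#' @export
simulate_model_data <- function(n_patients, visits = 4,
                                beta = c(0.4, -0.71, 0.21),
                                re_sd = c(0.9, 0.2, 0.05), re_corr = 0,
                                residual_sd = 0.15, t_max = 1.5,
                                seed = 1L) {
  set.seed(seed)
  G <- re_covariance(re_sd, re_corr)
  Gchol <- chol(G + diag(1e-12, 3))
  tt <- seq(0, t_max, length.out = visits)
  b <- matrix(stats::rnorm(3 * n_patients), n_patients) %*% Gchol
  out <- lapply(seq_len(n_patients), function(i) {
    z <- (beta[1] + b[i, 1]) + (beta[2] + b[i, 2]) * tt +
      (beta[3] + b[i, 3]) * tt^2 +
      stats::rnorm(visits, sd = residual_sd)
    tibble::tibble(patient_id = sprintf("S%05d", i), time_years = tt, z = z)
  })
  dplyr::bind_rows(out)
}

#' Write a synthetic extract to CSV files
#'
#' @param pop Result of [simulate_population()].
#' @param dir Output directory (created if needed).
#' @return Named vector of file paths, invisibly.
#' @export
write_extract <- function(pop, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(patients = "patients.csv", prescriptions = "prescriptions.csv",
             diagnoses = "diagnoses.csv", measurements = "measurements.csv")
  for (nm in names(paths)) {
    utils::write.csv(pop[[nm]], file.path(dir, paths[nm]), row.names = FALSE,
                     quote = FALSE)
  }
  utils::write.csv(pop$truth$patients, file.path(dir, "truth_patients.csv"),
                   row.names = FALSE, quote = FALSE)
  write_lms_table(pop$lms_weight, file.path(dir, "lms_weight.csv"))
  write_lms_table(pop$lms_height, file.path(dir, "lms_height.csv"))
  invisible(file.path(dir, c(paths, "truth_patients.csv", "lms_weight.csv",
                             "lms_height.csv")))
}
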