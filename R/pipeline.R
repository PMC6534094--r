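#' Read an EMR extract from a directory of CSV files
#'
#' Expects `patients.csv`, `prescriptions.csv`, `diagnoses.csv`,
#' `measurements.csv` with the documented schemas; date columns are parsed
#' as ISO-8601.
#'
#' @param dir Directory path.
#' @return List of tibbles.
#' @export
read_extract <- function(dir) {
  read1 <- function(name, date_cols) {
    path <- file.path(dir, name)
    if (!file.exists(path)) stop("missing input file: ", path, call. = FALSE)
    d <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
    for (col in date_cols) {
      d[[col]] <- as.Date(d[[col]])
      if (any(is.na(d[[col]]))) {
        stop("unparseable date(s) in ", name, " column ", col, call. = FALSE)
      }
    }
    d
  }
  list(
    patients = read1("patients.csv", c("birth_date", "emr_start", "emr_end")),
    prescriptions = read1("prescriptions.csv", "start_date"),
    diagnoses = read1("diagnoses.csv", "date"),
    measurements = read1("measurements.csv", "date"))
}

# assemble per-measure analysis observations + model covariates
build_analysis_set <- function(assignments, std, patients, measure,
                               config = study_config()) {
  elig_col <- paste0("eligible_", measure)
  asg <- assignments[assignments[[elig_col]], , drop = FALSE]
  std_by <- split(std, std$patient_id)
  pt <- patients[match(asg$patient_id, patients$patient_id), , drop = FALSE]
  obs <- vector("list", nrow(asg))
  keep <- logical(nrow(asg))
  age_base <- base_days <- numeric(nrow(asg))
  for (i in seq_len(nrow(asg))) {
    pid <- asg$patient_id[i]
    s <- std_by[[pid]]
    if (is.null(s)) next
    disc <- if (asg$cohort[i] == "unmedicated") NULL else
      asg$discontinuation_date[i]
    sel <- select_analysis_measurements(s, asg$time0[i], disc,
                                        asg$censor_date[i], config)
    if (nrow(sel) == 0L) next
    sel$patient_id <- pid
    obs[[i]] <- sel
    keep[i] <- TRUE
    base_date <- sel$date[1]
    age_base[i] <- as.numeric(base_date - pt$birth_date[i]) / 365.25
    base_days[i] <- as.numeric(base_date - asg$time0[i])
  }
  covs <- tibble::tibble(
    patient_id = asg$patient_id, cohort = asg$cohort,
    subgroup = asg$subgroup, sex = pt$sex,
    age_at_baseline = age_base, baseline_days_before = base_days,
    mpr = asg$mpr,
    stimulant_days_preguanfacine = asg$stimulant_days_preguanfacine,
    atomoxetine_before = asg$atomoxetine_before,
    atomoxetine_during = asg$atomoxetine_during)[keep, , drop = FALSE]
  list(observations = dplyr::bind_rows(obs[keep]), covariates = covs)
}

#' Baseline summary of an analysis population
#'
#' Per cohort (and guanfacine subgroup): n, mean baseline z-score with
#' normal-theory 95% CI, the integer percentile label of the mean, timing
#' of the baseline measurement relative to time 0, and the distribution of
#' postbaseline measurement counts (1 / 2 / 3 / >= 4).
#'
#' @param analysis_set Result of the internal analysis-set builder: list
#'   with `observations` and `covariates`.
#' @param conf_level Confidence level for the mean CI.
#' @return Tibble, one row per cohort/subgroup.
#' @export
summarize_baseline <- function(analysis_set, conf_level = 0.95) {
  obs <- analysis_set$observations
  covs <- analysis_set$covariates
  base <- obs[obs$baseline, c("patient_id", "z")]
  npost <- dplyr::count(obs[!obs$baseline, ], .data$patient_id,
                        name = "n_post")
  d <- covs |>
    dplyr::left_join(base, by = "patient_id") |>
    dplyr::left_join(npost, by = "patient_id")
  d$n_post[is.na(d$n_post)] <- 0L
  d$group <- ifelse(d$cohort == "guanfacine", d$subgroup, d$cohort)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  summarize_one <- function(g) {
    n <- nrow(g)
    m <- mean(g$z)
    se <- stats::sd(g$z) / sqrt(n)
    tibble::tibble(
      n = n, mean_z = m,
      ci_lower = m - zq * se, ci_upper = m + zq * se,
      percentile = z_to_percentile_label(m),
      baseline_days_mean = mean(g$baseline_days_before),
      baseline_days_sd = stats::sd(g$baseline_days_before),
      n_post_1 = sum(g$n_post == 1), n_post_2 = sum(g$n_post == 2),
      n_post_3 = sum(g$n_post == 3), n_post_4plus = sum(g$n_post >= 4))
  }
  groups <- split(d, d$group)
  out <- dplyr::bind_rows(lapply(groups, summarize_one), .id = "group")
  empty <- setdiff(c("first_line_guanfacine_mono",
                     "nonfirst_line_guanfacine_mono",
                     "combined_pharmacotherapy", "first_line_stimulant",
                     "unmedicated"), out$group)
  if (length(empty)) {
    warning("empty cohort/subgroup omitted from baseline summary: ",
            paste(empty, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(out)
}

fit_family_models <- function(analysis_set, family, measure) {
  covs <- analysis_set$covariates
  fam_covs <- switch(family,
    guanfacine = covs[covs$cohort == "guanfacine", ],
    first_line_stimulant = covs[covs$cohort == "first_line_stimulant", ],
    unmedicated = covs[covs$cohort == "unmedicated", ])
  fits <- list()
  for (stratum in c("all", "male", "female")) {
    cc <- if (stratum == "all") fam_covs else
      fam_covs[fam_covs$sex == stratum, ]
    if (nrow(cc) < 10L) next
    spec <- trajectory_spec(paste0(measure, "_z"), family, stratum)
    obs <- analysis_set$observations[
      analysis_set$observations$patient_id %in% cc$patient_id, ]
    d <- build_design(obs, cc, spec)
    fit <- tryCatch(fit_random_coefficients(d, spec),
                    error = function(e) e)
    fits[[stratum]] <- fit
  }
  fits
}

coef_table <- function(fits_nested) {
  rows <- list()
  for (measure in names(fits_nested)) {
    for (family in names(fits_nested[[measure]])) {
      for (stratum in names(fits_nested[[measure]][[family]])) {
        f <- fits_nested[[measure]][[family]][[stratum]]
        if (inherits(f, "trajectory_fit")) {
          fe <- f$fixed_effects
          fe$measure <- measure; fe$cohort_family <- family
          fe$stratum <- stratum
          rows[[length(rows) + 1L]] <- fe
        }
      }
    }
  }
  if (!length(rows)) return(tibble::tibble())
  dplyr::bind_rows(rows)[, c("measure", "cohort_family", "stratum", "term",
                             "estimate", "se", "df", "t", "p")]
}

#' Run the full growth-trajectory pipeline
#'
#' Orchestrates simulate (or load) -> standardize -> cohorts -> exposure ->
#' trajectory models -> pre/post models -> shift classification -> report.
#' Deterministic given the configuration and seed: rerunning with identical
#' inputs reproduces identical output files.
#'
#' @param config Either a path to a YAML file or a list with keys:
#'   `simulate` (arguments for [sim_config()]) or `input_dir` (an extract
#'   directory) and optional `lms_weight`/`lms_height` CSV paths; `study`
#'   (overrides for [study_config()]); `out_dir`; `seed` (overrides the
#'   simulate seed); `time_grid` (prediction times, years).
#' @return A run report (list): per-stage record counts, fitted model
#'   summaries, output manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  study <- do.call(study_config, config$study %||NULL% list())
  out_dir <- config$out_dir %||NULL% tempfile("growthtraj_run")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # --- inputs -------------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    if (!is.null(config$seed)) sim_args$seed <- config$seed
    if (!is.null(sim_args$cohort_mix)) {
      sim_args$cohort_mix <- unlist(sim_args$cohort_mix)
    }
    scfg <- do.call(sim_config, sim_args)
    pop <- simulate_population(scfg)
    lms_w <- pop$lms_weight; lms_h <- pop$lms_height
  } else if (!is.null(config$input_dir)) {
    pop <- read_extract(config$input_dir)
    lms_w <- if (!is.null(config$lms_weight)) {
      read_lms_table(config$lms_weight, "weight")
    } else make_synthetic_lms_table("weight")
    lms_h <- if (!is.null(config$lms_height)) {
      read_lms_table(config$lms_height, "height")
    } else make_synthetic_lms_table("height")
  } else {
    stop("config must provide either a `simulate` block or `input_dir`",
         call. = FALSE)
  }

  # --- standardize ----------------------------------------------------------
  std_w <- standardize_measurements(pop$measurements, pop$patients, lms_w)
  std_h <- standardize_measurements(pop$measurements, pop$patients, lms_h)

  # --- cohorts & exposure ---------------------------------------------------
  cb <- build_cohorts(pop$patients, pop$prescriptions, pop$diagnoses,
                      std_w, std_h, study)
  asg <- cb$assignments

  # --- analysis sets ---------------------------------------------------------
  sets <- list(
    weight = build_analysis_set(asg, std_w, pop$patients, "weight", study),
    height = build_analysis_set(asg, std_h, pop$patients, "height", study))

  # --- trajectory models ------------------------------------------------------
  families <- c("guanfacine", "first_line_stimulant", "unmedicated")
  fits <- list()
  for (measure in names(sets)) {
    fits[[measure]] <- list()
    for (family in families) {
      fits[[measure]][[family]] <- fit_family_models(sets[[measure]],
                                                     family, measure)
    }
  }
  coefs <- coef_table(fits)

  # --- predicted trajectories -------------------------------------------------
  grid <- config$time_grid %||NULL% seq(0, 2, by = 0.25)
  preds <- list()
  for (measure in names(fits)) {
    for (family in names(fits[[measure]])) {
      f <- fits[[measure]][[family]][["all"]]
      if (!inherits(f, "trajectory_fit")) next
      pr <- suppressWarnings(predict_trajectory(f, grid))
      pr$measure <- measure; pr$cohort_family <- family
      preds[[length(preds) + 1L]] <- pr
    }
  }
  preds <- dplyr::bind_rows(preds)

  # --- pre/post models ----------------------------------------------------------
  prepost_rows <- list()
  prepost_groups <- list(
    first_line_guanfacine_mono = function(c) c$subgroup ==
      "first_line_guanfacine_mono",
    first_line_stimulant = function(c) c$cohort == "first_line_stimulant",
    unmedicated = function(c) c$cohort == "unmedicated")
  for (measure in names(sets)) {
    covs <- sets[[measure]]$covariates
    obs <- sets[[measure]]$observations
    for (grp in names(prepost_groups)) {
      sel <- prepost_groups[[grp]](covs)
      for (sx in c("male", "female")) {
        ids <- covs$patient_id[sel & covs$sex == sx]
        d <- obs[obs$patient_id %in% ids, ]
        if (nrow(d) < 20L || !any(d$baseline) || !any(!d$baseline)) next
        d$post <- !d$baseline
        f <- tryCatch(fit_prepost(d), error = function(e) NULL)
        if (is.null(f)) next
        prepost_rows[[length(prepost_rows) + 1L]] <- tibble::tibble(
          measure = measure, group = grp, sex = sx,
          n = f$fit_meta$n_patients,
          intercept = f$intercept, ci_lower = f$intercept_ci[1],
          ci_upper = f$intercept_ci[2],
          percentile = z_to_percentile_label(f$intercept),
          coefficient = f$prepost_coefficient, se = f$se, t = f$t, p = f$p)
      }
    }
  }
  prepost <- dplyr::bind_rows(prepost_rows)

  # --- shift analysis (guanfacine subgroups) -----------------------------------
  shift_rows <- list()
  for (measure in names(sets)) {
    obs <- sets[[measure]]$observations
    covs <- sets[[measure]]$covariates
    gua <- covs[covs$cohort == "guanfacine", ]
    for (i in seq_len(nrow(gua))) {
      po <- obs[obs$patient_id == gua$patient_id[i], ]
      zb <- po$z[po$baseline][1]
      zf <- po$z[which.max(ifelse(po$baseline, -Inf, po$time_years))]
      cs <- classify_shift(zb, zf)
      shift_rows[[length(shift_rows) + 1L]] <- tibble::tibble(
        patient_id = gua$patient_id[i], measure = measure,
        z_baseline = zb, z_final = zf,
        lines_crossed = cs$lines_crossed, direction = cs$direction)
    }
  }
  shifts <- dplyr::bind_rows(shift_rows)
  shift_tabs <- if (nrow(shifts) > 0) {
    gua_asg <- dplyr::inner_join(
      asg[asg$cohort %in% "guanfacine", c("patient_id", "subgroup")],
      pop$patients[c("patient_id", "sex")], by = "patient_id")
    shift_table(shifts, gua_asg)
  } else NULL

  # --- baseline summaries ---------------------------------------------------
  base_sum <- list()
  for (measure in names(sets)) {
    bs <- suppressWarnings(summarize_baseline(sets[[measure]]))
    if (nrow(bs)) { bs$measure <- measure; base_sum[[measure]] <- bs }
  }
  base_sum <- dplyr::bind_rows(base_sum)

  # --- write artifacts ---------------------------------------------------------
  wr <- function(obj, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(as.data.frame(obj), path, row.names = FALSE)
    path
  }
  manifest <- c(
    wr(asg, "cohort_assignments.csv"),
    wr(cb$exclusions, "exclusions.csv"),
    wr(coefs, "model_coefficients.csv"),
    wr(preds, "predicted_trajectories.csv"),
    wr(prepost, "prepost_models.csv"),
    wr(base_sum, "baseline_summary.csv"),
    if (!is.null(shift_tabs)) wr(shift_tabs$by_cell, "shift_table.csv"),
    if (!is.null(shift_tabs)) wr(shift_tabs$pooled_monotherapy,
                                 "shift_pooled_monotherapy.csv"))

  counts <- list(
    patients_in = nrow(pop$patients),
    weight_eligible = sum(asg$eligible_weight),
    height_eligible = sum(asg$eligible_height),
    weight_excluded = nrow(pop$patients) - sum(asg$eligible_weight),
    height_excluded = nrow(pop$patients) - sum(asg$eligible_height))
  meta <- list(package_version = as.character(utils::packageVersion("growthtraj")),
               seed = config$seed %||NULL% (config$simulate$seed %||NULL% NA),
               counts = counts)
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  list(counts = counts, out_dir = out_dir,
       manifest = c(manifest, file.path(out_dir, "run_metadata.json")),
       assignments = asg, exclusions = cb$exclusions,
       analysis_sets = sets, fits = fits, coefficients = coefs,
       predicted = preds, prepost = prepost, shifts = shifts,
       shift_tables = shift_tabs, baseline_summary = base_sum)
}

`%||NULL%` <- function(x, y) if (is.null(x)) y else x
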