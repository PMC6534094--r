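#' Specify a z-score trajectory model
#'
#' Encodes the fixed-effect term list of one cohort family and sex stratum.
#' All families share the random design per patient: intercept, time, and
#' time squared with an unstructured 3x3 covariance. Fixed terms:
#' * guanfacine family: age at baseline, gender (all-patients stratum
#'   only), guanfacine MPR, stimulant prescribed amount preguanfacine,
#'   atomoxetine before/during exposure, treatment-regimen subgroup
#'   (reference = combined pharmacotherapy) and time x subgroup.
#' * first-line stimulant family: age at baseline, gender (all only),
#'   stimulant MPR.
#' * unmedicated family: age at baseline, gender (all only).
#'
#' @param response `"weight_z"` or `"height_z"` (bookkeeping only; the data
#'   carry the z column).
#' @param cohort_family `"guanfacine"`, `"first_line_stimulant"` or
#'   `"unmedicated"`.
#' @param sex_stratum `"all"`, `"male"` or `"female"`.
#' @return List of class `trajectory_spec` with a `fixed_terms` character
#'   vector and the model formula.
#' @export
trajectory_spec <- function(response = c("weight_z", "height_z"),
                            cohort_family = c("guanfacine",
                                              "first_line_stimulant",
                                              "unmedicated"),
                            sex_stratum = c("all", "male", "female")) {
  response <- match.arg(response)
  cohort_family <- match.arg(cohort_family)
  sex_stratum <- match.arg(sex_stratum)
  terms <- "age_at_baseline"
  if (sex_stratum == "all") terms <- c(terms, "sex")
  terms <- switch(cohort_family,
    guanfacine = c(terms, "mpr", "stimulant_days_preguanfacine",
                   "atomoxetine_before", "atomoxetine_during", "subgroup",
                   "time_years:subgroup"),
    first_line_stimulant = c(terms, "mpr"),
    unmedicated = terms)
  fixed <- paste(c(terms, "time_years", "I(time_years^2)"), collapse = " + ")
  fml <- stats::as.formula(paste(
    "z ~", fixed, "+ (1 + time_years + I(time_years^2) | patient_id)"))
  structure(list(response = response, cohort_family = cohort_family,
                 sex_stratum = sex_stratum, fixed_terms = terms,
                 formula = fml),
            class = "trajectory_spec")
}

#' Build the model frame for a trajectory fit
#'
#' Joins per-patient analysis measurements to their covariates, coerces
#' factors to the reference levels the models assume (sex reference male;
#' subgroup reference combined pharmacotherapy; binary covariates reference
#' "no"), and fails loudly when a required covariate is missing.
#'
#' @param observations Long tibble: `patient_id`, `time_years`, `z` (and
#'   optionally `baseline`).
#' @param covariates One row per patient: `patient_id`, `age_at_baseline`,
#'   `sex`, and the family-specific columns used by `spec`.
#' @param spec A [trajectory_spec()].
#' @return A data frame ready for [fit_random_coefficients()].
#' @export
build_design <- function(observations, covariates, spec) {
  stopifnot(inherits(spec, "trajectory_spec"))
  base_terms <- setdiff(unique(unlist(strsplit(spec$fixed_terms, ":"))),
                        "time_years")
  missing_cols <- setdiff(c("patient_id", base_terms), names(covariates))
  if (length(missing_cols)) {
    stop("covariates missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  d <- dplyr::inner_join(observations, covariates, by = "patient_id")
  for (term in base_terms) {
    bad <- is.na(d[[term]])
    if (any(bad)) {
      stop("missing covariate '", term, "' for patient(s) ",
           paste(utils::head(unique(d$patient_id[bad]), 5), collapse = ", "),
           call. = FALSE)
    }
  }
  if ("sex" %in% base_terms) {
    d$sex <- factor(d$sex, levels = c("male", "female"))
    if (any(is.na(d$sex))) stop("unknown sex level", call. = FALSE)
  }
  if ("subgroup" %in% base_terms) {
    lev <- c("combined_pharmacotherapy", "first_line_guanfacine_mono",
             "nonfirst_line_guanfacine_mono")
    if (!all(d$subgroup %in% lev)) {
      stop("unknown subgroup level: ",
           paste(setdiff(unique(d$subgroup), lev), collapse = ", "),
           call. = FALSE)
    }
    d$subgroup <- factor(d$subgroup, levels = lev)
  }
  for (term in intersect(c("atomoxetine_before", "atomoxetine_during"),
                         base_terms)) {
    d[[term]] <- as.logical(d[[term]])
  }
  d$patient_id <- factor(d$patient_id)
  d
}

#' Fit a random-coefficients growth model
#'
#' REML linear mixed model with the spec's fixed design and per-patient
#' random intercept, linear and quadratic time under an unstructured
#' covariance (all variances and covariances free). Residuals are
#' independent. Reported p-values are nominal, two-sided, on residual
#' degrees of freedom (n_obs - n_fixed).
#'
#' @param data Model frame from [build_design()].
#' @param spec A [trajectory_spec()].
#' @param REML Use REML (default) or ML.
#' @return Object of class `trajectory_fit`: `fixed_effects` tibble (term,
#'   estimate, se, t, df, p), `random_covariance` (3x3), `residual_variance`,
#'   `time_fixed`, `fit_meta` (convergence/singularity flags, REML
#'   criterion, n_obs, n_patients) and the underlying `lme4` fit.
#' @export
fit_random_coefficients <- function(data, spec, REML = TRUE) {
  stopifnot(inherits(spec, "trajectory_spec"))
  # canonical row order: estimates must not depend on input ordering
  data <- data[order(data$patient_id, data$time_years), , drop = FALSE]
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  fit <- lme4::lmer(spec$formula, data = data, REML = REML, control = ctrl)
  summarize_lmm(fit, spec = spec)
}

summarize_lmm <- function(fit, spec = NULL) {
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  n_obs <- stats::nobs(fit)
  df_resid <- n_obs - length(beta)
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), df = df_resid, lower.tail = FALSE)
  vc <- lme4::VarCorr(fit)
  G <- as.matrix(vc[[1]])
  attr(G, "stddev") <- NULL
  attr(G, "correlation") <- NULL
  fixed <- tibble::tibble(term = names(beta), estimate = unname(beta),
                          se = unname(se), df = df_resid,
                          t = unname(tval), p = unname(pval))
  time_terms <- grep("^time_years$|^I\\(time_years\\^2\\)$", names(beta))
  structure(list(
    fixed_effects = fixed,
    random_covariance = G,
    residual_variance = attr(vc, "sc")^2,
    time_fixed = beta[time_terms],
    fit_meta = list(
      converged = length(fit@optinfo$conv$lme4$messages) == 0L,
      singular = lme4::isSingular(fit),
      criterion = as.numeric(lme4::REMLcrit(fit)),
      n_obs = n_obs,
      n_patients = nlevels(fit@frame$patient_id)),
    spec = spec,
    lme4_fit = fit
  ), class = "trajectory_fit")
}

#' @export
print.trajectory_fit <- function(x, ...) {
  meta <- x$fit_meta
  if (!is.null(x$spec)) {
    cat(sprintf("Random-coefficients model: %s, %s cohort, %s stratum\n",
                x$spec$response, x$spec$cohort_family, x$spec$sex_stratum))
  }
  cat(sprintf("%d observations, %d patients; REML criterion %.1f%s\n",
              meta$n_obs, meta$n_patients, meta$criterion,
              if (meta$singular) " (singular random-effect fit)" else ""))
  print(as.data.frame(x$fixed_effects), digits = 4)
  invisible(x)
}

#' Predict population-level trajectories from a fitted model
#'
#' Fixed-effect prediction over a time grid with every non-time covariate
#' held constant at its overall mean in the analysis population (factor
#' covariates at their observed dummy-column means, i.e. population
#' composition). When the model carries a time x subgroup interaction,
#' each subgroup gets its own path with the subgroup indicator set
#' exactly (other covariates stay at the overall means).
#'
#' @param fit A `trajectory_fit`.
#' @param time_grid Times in years from time 0.
#' @param by_subgroup Emit one path per treatment-regimen subgroup
#'   (requires the subgroup terms in the model); default auto-detects.
#' @param warn_extrapolation Warn when the grid extends beyond the fitted
#'   time range.
#' @return Tibble `time_years`, `z_hat` (plus `subgroup` when present).
#' @export
predict_trajectory <- function(fit, time_grid, by_subgroup = NULL,
                               warn_extrapolation = TRUE) {
  stopifnot(inherits(fit, "trajectory_fit"))
  frame <- fit$lme4_fit@frame
  obs_rng <- range(frame$time_years)
  if (warn_extrapolation &&
      (min(time_grid) < obs_rng[1] || max(time_grid) > obs_rng[2])) {
    warning("prediction grid extends beyond the observed time range (",
            sprintf("%.2f..%.2f", obs_rng[1], obs_rng[2]), " years)",
            call. = FALSE)
  }
  X <- lme4::getME(fit$lme4_fit, "X")
  beta <- lme4::fixef(fit$lme4_fit)
  xbar <- colMeans(X)
  cn <- names(xbar)
  sg_cols <- grep("^subgroup", cn, value = TRUE)
  if (is.null(by_subgroup)) by_subgroup <- length(sg_cols) > 0
  subgroups <- if (by_subgroup) levels(frame$subgroup) else NA_character_
  rows <- list()
  for (sg in subgroups) {
    for (tt in time_grid) {
      x <- xbar
      x["time_years"] <- tt
      if ("I(time_years^2)" %in% cn) x["I(time_years^2)"] <- tt^2
      if (!is.na(sg)) {
        for (col in sg_cols) {
          if (grepl(":", col, fixed = TRUE)) next
          on <- as.numeric(identical(col, paste0("subgroup", sg)))
          x[col] <- on
          for (int_col in c(paste0("time_years:", col),
                            paste0(col, ":time_years"))) {
            if (int_col %in% cn) x[int_col] <- tt * on
          }
        }
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subgroup = sg, time_years = tt,
        z_hat = as.numeric(sum(x * beta)))
    }
  }
  out <- dplyr::bind_rows(rows)
  if (all(is.na(out$subgroup))) out$subgroup <- NULL
  out
}

#' Pre/post treatment-initiation model
#'
#' Mixed model of z-score on a binary indicator of whether the measurement
#' was made before or on/after the index date, with random intercept and
#' random linear and quadratic time. The intercept is the modeled z-score
#' at time 0 for the pre period; the indicator's coefficient is the mean
#' z-score change after initiation versus before, across all time.
#'
#' @param data Tibble with `patient_id`, `time_years`, `z` and a logical
#'   `post` flag (baseline measurements imputed at time 0 carry
#'   `post = FALSE` by default; set `true_times = TRUE` upstream to keep
#'   their real negative times instead).
#' @param REML Use REML (default) or ML.
#' @param conf_level Confidence level for the intercept interval.
#' @return List of class `prepost_fit`: `intercept`, `intercept_ci`,
#'   `prepost_coefficient`, `se`, `t`, `df`, `p`, `fit_meta`.
#' @export
fit_prepost <- function(data, REML = TRUE, conf_level = 0.95) {
  if (!any(!data$post)) stop("no pre-period observations", call. = FALSE)
  if (!any(data$post)) stop("no post-period observations", call. = FALSE)
  data$post <- as.logical(data$post)
  data$patient_id <- factor(data$patient_id)
  data <- data[order(data$patient_id, data$time_years, data$post), ,
               drop = FALSE]
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  fit <- lme4::lmer(
    z ~ post + (1 + time_years + I(time_years^2) | patient_id),
    data = data, REML = REML, control = ctrl)
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  n_obs <- stats::nobs(fit)
  df_resid <- n_obs - length(beta)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  tval <- beta[["postTRUE"]] / se[["postTRUE"]]
  structure(list(
    intercept = beta[["(Intercept)"]],
    intercept_ci = beta[["(Intercept)"]] +
      c(-1, 1) * zq * se[["(Intercept)"]],
    prepost_coefficient = beta[["postTRUE"]],
    se = se[["postTRUE"]],
    t = tval,
    df = df_resid,
    p = 2 * stats::pt(abs(tval), df = df_resid, lower.tail = FALSE),
    fit_meta = list(converged = length(fit@optinfo$conv$lme4$messages) == 0L,
                    singular = lme4::isSingular(fit),
                    n_obs = n_obs,
                    n_patients = nlevels(data$patient_id)),
    lme4_fit = fit
  ), class = "prepost_fit")
}

#' @export
print.prepost_fit <- function(x, ...) {
  cat(sprintf("Pre/post initiation model (%d obs, %d patients)\n",
              x$fit_meta$n_obs, x$fit_meta$n_patients))
  cat(sprintf("  modeled z at time 0: %.4f [%.4f, %.4f]\n",
              x$intercept, x$intercept_ci[1], x$intercept_ci[2]))
  cat(sprintf("  post-initiation shift: %.4f (se %.4f, t %.2f, p %.3g)\n",
              x$prepost_coefficient, x$se, x$t, x$p))
  invisible(x)
}
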