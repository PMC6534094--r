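#' LMS (Box-Cox) z-score for a single measurement
#'
#' Converts a raw anthropometric value to an age- and sex-standardized
#' z-score using the LMS parameterisation of a growth reference:
#' \deqn{z = \frac{(x/M)^L - 1}{L\,S} \quad (L \neq 0), \qquad
#'       z = \frac{\log(x/M)}{S} \quad (L = 0).}
#' The two branches join continuously at \eqn{L = 0}.
#'
#' @param value Positive raw measurement (kg for weight, cm for height).
#' @param L Box-Cox power of the reference at this age/sex.
#' @param M Positive reference median.
#' @param S Positive reference coefficient of variation.
#' @return Numeric z-score(s); vectorised over all arguments.
#' @seealso [zscore_to_value()] for the exact inverse.
#' @export
#' @examples
#' lms_zscore(10, L = 2, M = 10, S = 0.1)  # value at the median -> 0
lms_zscore <- function(value, L, M, S) {
  if (any(!is.finite(value)) || any(value <= 0)) {
    stop("`value` must be positive and finite", call. = FALSE)
  }
  if (any(M <= 0) || any(S <= 0)) {
    stop("LMS parameters require M > 0 and S > 0", call. = FALSE)
  }
  n <- max(length(value), length(L), length(M), length(S))
  value <- rep_len(value, n); L <- rep_len(L, n)
  M <- rep_len(M, n); S <- rep_len(S, n)
  r <- value / M
  ifelse(L == 0, log(r) / S, (r^L - 1) / (L * S))
}

#' Raw measurement corresponding to an LMS z-score
#'
#' Exact inverse of [lms_zscore()]:
#' \eqn{x = M (1 + L S z)^{1/L}} for \eqn{L \neq 0} and
#' \eqn{x = M e^{S z}} for \eqn{L = 0}.
#'
#' @param z Finite z-score(s).
#' @inheritParams lms_zscore
#' @return Positive raw value(s) on the measurement scale.
#' @export
zscore_to_value <- function(z, L, M, S) {
  if (any(!is.finite(z))) stop("`z` must be finite", call. = FALSE)
  if (any(M <= 0) || any(S <= 0)) {
    stop("LMS parameters require M > 0 and S > 0", call. = FALSE)
  }
  n <- max(length(z), length(L), length(M), length(S))
  z <- rep_len(z, n); L <- rep_len(L, n)
  M <- rep_len(M, n); S <- rep_len(S, n)
  base <- 1 + L * S * z
  if (any(L != 0 & base <= 0)) {
    stop("z outside the domain of the inverse transform (1 + L*S*z <= 0)",
         call. = FALSE)
  }
  ifelse(L == 0, M * exp(S * z), M * base^(1 / L))
}

#' Construct an LMS reference table
#'
#' Bundles per-sex (L, M, S) rows on an age-in-months grid into a validated
#' reference table for one measure.
#'
#' @param rows Data frame with columns `sex` ("male"/"female"),
#'   `age_months`, `L`, `M`, `S`.
#' @param measure `"weight"` or `"height"`.
#' @return A tibble of class `lms_table` with a `measure` attribute.
#' @export
lms_table <- function(rows, measure = c("weight", "height")) {
  measure <- match.arg(measure)
  req <- c("sex", "age_months", "L", "M", "S")
  if (!all(req %in% names(rows))) {
    stop("LMS table needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  rows <- tibble::as_tibble(rows[req])
  if (!all(rows$sex %in% c("male", "female"))) {
    stop("`sex` must be 'male' or 'female'", call. = FALSE)
  }
  if (any(rows$M <= 0) || any(rows$S <= 0)) {
    stop("LMS rows require M > 0 and S > 0", call. = FALSE)
  }
  if (any(rows$age_months < 0)) stop("ages must be non-negative", call. = FALSE)
  rows <- dplyr::arrange(rows, .data$sex, .data$age_months)
  dup <- duplicated(rows[c("sex", "age_months")])
  if (any(dup)) stop("duplicate (sex, age_months) rows in LMS table",
                     call. = FALSE)
  structure(rows, class = c("lms_table", class(rows)), measure = measure)
}

#' Read an LMS reference table from CSV
#'
#' Accepts the published CDC growth-chart layout (`sex` coded 1 = male,
#' 2 = female; columns `agemos`, `L`, `M`, `S`; one file per measure) or a
#' long-format dialect with an explicit `measure` column and `sex` given as
#' "male"/"female".
#'
#' @param path Path to the CSV file.
#' @param measure Measure the file describes; for the long dialect the file
#'   is filtered to this measure.
#' @return An [lms_table()].
#' @export
read_lms_table <- function(path, measure = c("weight", "height")) {
  measure <- match.arg(measure)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(raw) <- tolower(names(raw))
  if ("measure" %in% names(raw)) {
    raw <- raw[raw$measure == measure, , drop = FALSE]
    if (nrow(raw) == 0L) {
      stop("no rows for measure '", measure, "' in ", path, call. = FALSE)
    }
  }
  age_col <- if ("agemos" %in% names(raw)) "agemos" else "age_months"
  if (!age_col %in% names(raw)) {
    stop("LMS CSV must have an 'agemos' or 'age_months' column", call. = FALSE)
  }
  sex <- raw$sex
  if (is.numeric(sex)) sex <- c("male", "female")[sex]
  lms_table(
    data.frame(sex = sex, age_months = raw[[age_col]],
               L = raw$l, M = raw$m, S = raw$s),
    measure = measure
  )
}

#' Write an LMS table in the long CSV dialect
#'
#' @param table An [lms_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_lms_table <- function(table, path) {
  stopifnot(inherits(table, "lms_table"))
  out <- data.frame(measure = attr(table, "measure"), as.data.frame(table))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Interpolate LMS parameters at an arbitrary age
#'
#' The reference grid is discrete; queries at arbitrary ages interpolate
#' L, M and S linearly (and independently) between the two bracketing grid
#' rows of the requested sex. Exact grid ages return the grid row.
#'
#' @param table An [lms_table()].
#' @param sex `"male"` or `"female"` (recycled against `age_months`).
#' @param age_months Ages in months; must lie within the grid range.
#' @return A tibble with columns `L`, `M`, `S` (one row per query).
#' @export
interpolate_lms <- function(table, sex, age_months) {
  stopifnot(inherits(table, "lms_table"))
  n <- max(length(sex), length(age_months))
  sex <- rep_len(sex, n); age_months <- rep_len(age_months, n)
  out <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("L", "M", "S")))
  for (sx in unique(sex)) {
    rows <- table[table$sex == sx, ]
    if (nrow(rows) < 2L) stop("LMS table has < 2 rows for sex ", sx,
                              call. = FALSE)
    idx <- which(sex == sx)
    a <- age_months[idx]
    if (any(a < min(rows$age_months) | a > max(rows$age_months))) {
      stop("age outside the LMS reference range [",
           min(rows$age_months), ", ", max(rows$age_months), "] months",
           call. = FALSE)
    }
    for (p in c("L", "M", "S")) {
      out[idx, p] <- stats::approx(rows$age_months, rows[[p]], xout = a,
                                   method = "linear", ties = "ordered")$y
    }
  }
  tibble::as_tibble(as.data.frame(out))
}

#' Standardize raw measurements against an LMS reference
#'
#' Joins measurements to patient sex and birth date, computes age in months
#' as days-since-birth x 12/365.25, interpolates the reference and attaches
#' the z-score and exact percentile (100 x Phi(z)). Measurements whose age
#' falls outside the reference grid are dropped with a warning.
#'
#' @param measurements Data frame with `patient_id`, `date` (Date),
#'   `type` ("weight"/"height"), `value`, `unit` ("kg"/"cm").
#' @param patients Data frame with `patient_id`, `sex`, `birth_date`.
#' @param table [lms_table()] matching `measure`.
#' @param measure Which measurement type to standardize.
#' @return Tibble with `patient_id`, `date`, `measure`, `raw_value`,
#'   `age_years`, `z`, `percentile`.
#' @export
standardize_measurements <- function(measurements, patients, table,
                                     measure = attr(table, "measure")) {
  stopifnot(inherits(table, "lms_table"))
  if (measure != attr(table, "measure")) {
    stop("measure '", measure, "' does not match the supplied LMS table (",
         attr(table, "measure"), ")", call. = FALSE)
  }
  m <- measurements[measurements$type == measure, , drop = FALSE]
  expected_unit <- if (measure == "weight") "kg" else "cm"
  if ("unit" %in% names(m) && any(m$unit != expected_unit)) {
    stop(measure, " measurements must be recorded in ", expected_unit,
         call. = FALSE)
  }
  m <- dplyr::inner_join(m, patients[c("patient_id", "sex", "birth_date")],
                         by = "patient_id")
  if (any(m$date < m$birth_date)) {
    stop("measurement dated before birth", call. = FALSE)
  }
  m$age_months <- as.numeric(m$date - m$birth_date) * 12 / 365.25
  rng <- range(table$age_months)
  in_range <- m$age_months >= rng[1] & m$age_months <= rng[2]
  if (any(!in_range)) {
    warning(sum(!in_range), " ", measure,
            " measurement(s) outside the LMS reference age range dropped",
            call. = FALSE)
    m <- m[in_range, , drop = FALSE]
  }
  if (nrow(m) == 0L) {
    return(tibble::tibble(patient_id = character(), date = as.Date(character()),
                          measure = character(), raw_value = numeric(),
                          age_years = numeric(), z = numeric(),
                          percentile = numeric()))
  }
  lms <- interpolate_lms(table, m$sex, m$age_months)
  z <- lms_zscore(m$value, lms$L, lms$M, lms$S)
  tibble::tibble(
    patient_id = m$patient_id,
    date = m$date,
    measure = measure,
    raw_value = m$value,
    age_years = m$age_months / 12,
    z = z,
    percentile = 100 * stats::pnorm(z)
  )
}

#' Integer percentile label for a z-score
#'
#' Rounds 100 x Phi(z) to the nearest integer, halves away from zero, the
#' convention under which printed summary tables label mean z-scores (e.g.
#' z = 0.070 -> 53rd percentile).
#'
#' @param z Finite z-score(s).
#' @return Integer percentile label(s) in `[0, 100]`.
#' @export
z_to_percentile_label <- function(z) {
  if (any(!is.finite(z))) stop("`z` must be finite", call. = FALSE)
  p <- 100 * stats::pnorm(z)
  as.integer(sign(p) * floor(abs(p) + 0.5))
}

#' Reasonableness filter for standardized measurements
#'
#' Keeps a measurement iff its z-score lies in the inclusive interval
#' `[lower, upper]`; defaults reproduce the -4.5 <= z <= 4.5 plausibility
#' screen applied to EMR anthropometrics.
#'
#' @param z z-score(s).
#' @param lower,upper Inclusive bounds.
#' @return Logical vector: `TRUE` = keep.
#' @export
reasonableness_filter <- function(z, lower = -4.5, upper = 4.5) {
  is.finite(z) & z >= lower & z <= upper
}
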