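#' Percentile grid for growth-chart shift monitoring
#'
#' The chart lines recommended for monitoring growth under ADHD
#' pharmacotherapy: the 5th, 10th, 25th, 50th, 75th, 90th and 95th
#' percentiles, expressed as standard-normal quantiles on the z scale.
#'
#' @param percentiles Ordered percentile lines.
#' @return List with `percentiles` and `z_cutpoints`.
#' @export
percentile_grid <- function(percentiles = c(5, 10, 25, 50, 75, 90, 95)) {
  if (is.unsorted(percentiles, strictly = TRUE)) {
    stop("percentile lines must be strictly increasing", call. = FALSE)
  }
  list(percentiles = percentiles, z_cutpoints = stats::qnorm(percentiles / 100))
}

#' Classify an individual baseline-to-final z-score shift
#'
#' Counts the grid cutpoints lying strictly between the baseline and final
#' z-scores (a value sitting exactly on a line does not count it as
#' crossed). A shift crossing at least two lines is classified as a
#' potentially clinically meaningful increase or decrease by the sign of
#' the change; otherwise the direction is `"none"`.
#'
#' @param z_baseline,z_final Finite z-scores (vectorised).
#' @param grid A [percentile_grid()].
#' @return Tibble `z_baseline`, `z_final`, `lines_crossed`, `direction`.
#' @export
classify_shift <- function(z_baseline, z_final, grid = percentile_grid()) {
  if (any(!is.finite(z_baseline)) || any(!is.finite(z_final))) {
    stop("z-scores must be finite", call. = FALSE)
  }
  n <- max(length(z_baseline), length(z_final))
  z_baseline <- rep_len(z_baseline, n); z_final <- rep_len(z_final, n)
  lo <- pmin(z_baseline, z_final)
  hi <- pmax(z_baseline, z_final)
  crossed <- vapply(seq_len(n), function(i) {
    sum(grid$z_cutpoints > lo[i] & grid$z_cutpoints < hi[i])
  }, integer(1))
  direction <- ifelse(crossed >= 2L,
                      ifelse(z_final > z_baseline, "increase", "decrease"),
                      "none")
  tibble::tibble(z_baseline = z_baseline, z_final = z_final,
                 lines_crossed = crossed, direction = direction)
}

#' Tabulate shift classifications by subgroup, sex and measure
#'
#' Counts and percentages of increases and decreases per
#' subgroup x sex x measure cell (denominator = patients in the cell), plus
#' a pooled monotherapy summary combining the first-line and nonfirst-line
#' guanfacine monotherapy subgroups across sexes.
#'
#' @param shifts Tibble with `patient_id`, `measure`, `direction` (one row
#'   per patient per measure).
#' @param assignments Tibble with `patient_id`, `subgroup`, `sex`.
#' @return List with `by_cell` (subgroup x sex x measure x direction,
#'   percentages to 2 decimals), `by_subgroup` (sexes pooled, 1 decimal)
#'   and `pooled_monotherapy` (both monotherapy subgroups and sexes
#'   pooled, 1 decimal).
#' @export
shift_table <- function(shifts, assignments) {
  d <- dplyr::inner_join(shifts,
                         assignments[c("patient_id", "subgroup", "sex")],
                         by = "patient_id")
  if (any(duplicated(d[c("patient_id", "measure")]))) {
    stop("more than one shift result per patient and measure", call. = FALSE)
  }
  cells <- tidyr::expand_grid(
    subgroup = unique(assignments$subgroup),
    sex = c("male", "female"),
    measure = unique(shifts$measure),
    direction = c("increase", "decrease"))
  denom <- dplyr::count(d, .data$subgroup, .data$sex, .data$measure,
                        name = "n")
  hits <- dplyr::count(d, .data$subgroup, .data$sex, .data$measure,
                       .data$direction, name = "count")
  by_cell <- cells |>
    dplyr::left_join(denom, by = c("subgroup", "sex", "measure")) |>
    dplyr::left_join(hits, by = c("subgroup", "sex", "measure", "direction")) |>
    dplyr::mutate(
      n = dplyr::coalesce(.data$n, 0L),
      count = dplyr::coalesce(.data$count, 0L),
      percent = round(ifelse(.data$n > 0, 100 * .data$count / .data$n, 0), 2))

  by_subgroup <- tidyr::expand_grid(
    subgroup = unique(assignments$subgroup),
    measure = unique(shifts$measure),
    direction = c("increase", "decrease")) |>
    dplyr::left_join(dplyr::count(d, .data$subgroup, .data$measure,
                                  name = "n"),
                     by = c("subgroup", "measure")) |>
    dplyr::left_join(dplyr::count(d, .data$subgroup, .data$measure,
                                  .data$direction, name = "count"),
                     by = c("subgroup", "measure", "direction")) |>
    dplyr::mutate(
      n = dplyr::coalesce(.data$n, 0L),
      count = dplyr::coalesce(.data$count, 0L),
      percent = round(ifelse(.data$n > 0, 100 * .data$count / .data$n, 0), 1))

  mono <- d[d$subgroup %in% c("first_line_guanfacine_mono",
                              "nonfirst_line_guanfacine_mono"), , drop = FALSE]
  pooled <- tidyr::expand_grid(measure = unique(shifts$measure),
                               direction = c("increase", "decrease")) |>
    dplyr::left_join(dplyr::count(mono, .data$measure, name = "n"),
                     by = "measure") |>
    dplyr::left_join(dplyr::count(mono, .data$measure, .data$direction,
                                  name = "count"),
                     by = c("measure", "direction")) |>
    dplyr::mutate(
      n = dplyr::coalesce(.data$n, 0L),
      count = dplyr::coalesce(.data$count, 0L),
      percent = round(ifelse(.data$n > 0, 100 * .data$count / .data$n, 0), 1))
  list(by_cell = by_cell, by_subgroup = by_subgroup,
       pooled_monotherapy = pooled)
}
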