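#' Allowable gap length for a coverage gap
#'
#' Refill gaps of up to 30 days are tolerated during the school months
#' (September-May); gaps touching any day of June-August are allowed up to
#' 121 days to accommodate structured summer drug holidays. A gap spanning
#' the season boundary uses the summer allowance if it intersects any
#' June 1 - August 31 day.
#'
#' @param gap_start,gap_end First and last uncovered day (Date, inclusive).
#' @return Integer allowance in days: 30 or 121.
#' @export
gap_allowance <- function(gap_start, gap_end) {
  gap_start <- as.Date(gap_start); gap_end <- as.Date(gap_end)
  if (any(gap_end < gap_start)) stop("empty gap interval", call. = FALSE)
  n <- max(length(gap_start), length(gap_end))
  gap_start <- rep_len(gap_start, n); gap_end <- rep_len(gap_end, n)
  touches_summer <- function(s, e) {
    if (as.numeric(e - s) >= 365) return(TRUE)
    any(as.integer(format(seq(s, e, by = "day"), "%m")) %in% 6:8)
  }
  ifelse(mapply(touches_summer, gap_start, gap_end), 121L, 30L)
}

# last covered day of each prescription (closed, whole-day interval)
rx_end <- function(prescriptions) {
  prescriptions$start_date + prescriptions$days_supply - 1L
}

#' Build drug-exposure episodes from prescription records
#'
#' Merges the coverage intervals
#' `[start_date, start_date + days_supply - 1]` of one drug class into
#' maximal covered blocks, then splits them into episodes wherever the
#' uncovered gap between consecutive blocks exceeds its seasonal
#' [gap_allowance()]. The patient is considered to have discontinued on the
#' last day covered by the prescription preceding a terminating gap (drug is
#' assumed taken as dispensed until exhausted).
#'
#' @param prescriptions Data frame of one patient's prescriptions
#'   (`drug_class`, `start_date`, `days_supply`, ...).
#' @param class Drug class to build episodes for.
#' @param from_date Episode clock origin (guanfacine initiation or index
#'   date); prescriptions starting before it are ignored.
#' @return Tibble with one row per episode: `episode`, `start_date`,
#'   `discontinuation_date`, `n_prescriptions`.
#' @export
build_episodes <- function(prescriptions, class, from_date) {
  from_date <- as.Date(from_date)
  rx <- prescriptions[prescriptions$drug_class == class &
                        prescriptions$start_date >= from_date, , drop = FALSE]
  empty <- tibble::new_tibble(list(
    episode = integer(), start_date = as.Date(character()),
    discontinuation_date = as.Date(character()),
    n_prescriptions = integer()), nrow = 0L)
  if (nrow(rx) == 0L) return(empty)
  rx <- rx[order(rx$start_date), , drop = FALSE]
  s <- rx$start_date
  e <- rx_end(rx)
  # merge into maximal covered blocks (adjacent days: no gap)
  blk_start <- s[1]; blk_end <- e[1]
  blocks <- list()
  nrx <- c()
  cur_n <- 1L
  for (i in seq_len(nrow(rx))[-1]) {
    if (as.numeric(s[i] - blk_end) <= 1) {   # overlapping or adjacent
      blk_end <- max(blk_end, e[i])
      cur_n <- cur_n + 1L
    } else {
      blocks[[length(blocks) + 1L]] <- c(blk_start, blk_end)
      nrx <- c(nrx, cur_n)
      blk_start <- s[i]; blk_end <- e[i]; cur_n <- 1L
    }
  }
  blocks[[length(blocks) + 1L]] <- c(blk_start, blk_end)
  nrx <- c(nrx, cur_n)

  # chain blocks into episodes while gaps stay within the allowance
  ep_start <- blocks[[1]][1]; ep_end <- blocks[[1]][2]
  ep_n <- nrx[1]
  starts <- ends <- as.Date(character()); ns <- integer()
  for (j in seq_along(blocks)[-1]) {
    gap_s <- ep_end + 1L
    gap_e <- blocks[[j]][1] - 1L
    gap_len <- as.numeric(gap_e - gap_s) + 1
    if (gap_len > gap_allowance(gap_s, gap_e)) {
      starts <- c(starts, ep_start); ends <- c(ends, ep_end)
      ns <- c(ns, ep_n)
      ep_start <- blocks[[j]][1]; ep_end <- blocks[[j]][2]; ep_n <- nrx[j]
    } else {
      ep_end <- blocks[[j]][2]
      ep_n <- ep_n + nrx[j]
    }
  }
  starts <- c(starts, ep_start); ends <- c(ends, ep_end); ns <- c(ns, ep_n)
  tibble::new_tibble(list(episode = seq_along(starts), start_date = starts,
                          discontinuation_date = ends,
                          n_prescriptions = as.integer(ns)),
                     nrow = length(starts))
}

clip_days <- function(start, end, window) {
  # covered days of [start, end] within the closed window, per record
  lo <- pmax(start, window[1])
  hi <- pmin(end, window[2])
  pmax(0, as.numeric(hi - lo) + 1)
}

#' Prescribed amount for one drug at one dose
#'
#' Sum of the days-supply of all prescriptions for a single drug/dose
#' stream, ignoring overlaps (dispensed supply, not distinct covered days),
#' clipped to an evaluation window. Four 30-day prescriptions give 120 days.
#'
#' @param prescriptions Prescriptions sharing `drug_name` and `dose_label`.
#' @param window Length-2 Date vector (closed interval); defaults to the
#'   full span of the prescriptions.
#' @return Integer days of supply.
#' @export
prescribed_amount_per_dose <- function(prescriptions, window = NULL) {
  if (nrow(prescriptions) == 0L) return(0L)
  key <- unique(prescriptions[c("drug_name", "dose_label")])
  if (nrow(key) > 1L) {
    stop("records span multiple drug/dose streams", call. = FALSE)
  }
  e <- rx_end(prescriptions)
  if (is.null(window)) window <- c(min(prescriptions$start_date), max(e))
  window <- as.Date(window)
  as.integer(sum(clip_days(prescriptions$start_date, e, window)))
}

#' Total prescribed amount of a study-medication class
#'
#' Sums the per-stream prescribed amounts (a stream = one drug at one dose)
#' over all streams of the class, then caps the between-stream overlap at
#' 90 days: with T = total supplied days and O = days covered by more than
#' one stream (counted with multiplicity), the result is
#' `T - max(0, O - 90)`. Same-stream overlaps (early refills) add to T but
#' not to O.
#'
#' @param prescriptions Prescriptions of a single `drug_class`.
#' @param window Length-2 Date evaluation window; defaults to the span of
#'   the prescriptions.
#' @return Integer days.
#' @export
total_prescribed_amount <- function(prescriptions, window = NULL) {
  if (nrow(prescriptions) == 0L) return(0L)
  if (length(unique(prescriptions$drug_class)) > 1L) {
    stop("records span multiple drug classes", call. = FALSE)
  }
  e <- rx_end(prescriptions)
  if (is.null(window)) window <- c(min(prescriptions$start_date), max(e))
  window <- as.Date(window)
  total <- sum(clip_days(prescriptions$start_date, e, window))
  # inter-stream overlap: day counts per stream (union within stream)
  stream <- paste(prescriptions$drug_name, prescriptions$dose_label, sep = "\r")
  day0 <- as.integer(window[1])
  covered <- lapply(split(seq_len(nrow(prescriptions)), stream), function(i) {
    lo <- pmax(as.integer(prescriptions$start_date[i]), day0)
    hi <- pmin(as.integer(e[i]), as.integer(window[2]))
    keep <- hi >= lo
    if (!any(keep)) return(integer())
    unique(unlist(mapply(seq, lo[keep], hi[keep], SIMPLIFY = FALSE)))
  })
  per_stream <- sum(lengths(covered))
  union_days <- length(unique(unlist(covered)))
  overlap <- per_stream - union_days
  as.integer(total - max(0, overlap - 90))
}

#' Medication possession ratio
#'
#' Total prescribed amount during the initial exposure period divided by the
#' period length in days, capped at 100%.
#'
#' @param prescribed_amount_days Days of supply dispensed during the period.
#' @param episode_length_days Length of the period in days (>= 1).
#' @return MPR in `[0, 1]`.
#' @export
mpr <- function(prescribed_amount_days, episode_length_days) {
  if (any(episode_length_days < 1)) {
    stop("episode length must be >= 1 day", call. = FALSE)
  }
  pmin(1, prescribed_amount_days / episode_length_days)
}

#' Exposure metrics for the initial treatment episode
#'
#' Builds the first exposure episode of `class` from `from_date`, truncates
#' it at `censor_date`, and computes the prescribed amount (90-day overlap
#' cap) and MPR over the episode.
#'
#' @inheritParams build_episodes
#' @param censor_date Last usable day of follow-up.
#' @return One-row tibble: `start_date`, `discontinuation_date`,
#'   `episode_length_days`, `prescribed_amount_days`, `mpr`; or a zero-row
#'   tibble when the class was never dispensed on/after `from_date`.
#' @export
exposure_metrics <- function(prescriptions, class, from_date,
                             censor_date = NULL) {
  eps <- build_episodes(prescriptions, class, from_date)
  empty <- tibble::new_tibble(list(
    start_date = as.Date(character()),
    discontinuation_date = as.Date(character()),
    episode_length_days = integer(),
    prescribed_amount_days = integer(), mpr = numeric()), nrow = 0L)
  if (nrow(eps) == 0L) return(empty)
  ep <- eps[1, ]
  disc <- ep$discontinuation_date
  if (!is.null(censor_date)) {
    censor_date <- as.Date(censor_date)
    if (censor_date < ep$start_date) return(empty)
    disc <- min(disc, censor_date)
  }
  len <- as.integer(disc - ep$start_date) + 1L
  rx <- prescriptions[prescriptions$drug_class == class, , drop = FALSE]
  amt <- total_prescribed_amount(rx, window = c(ep$start_date, disc))
  tibble::new_tibble(list(start_date = ep$start_date,
                          discontinuation_date = disc,
                          episode_length_days = len,
                          prescribed_amount_days = amt,
                          mpr = mpr(amt, len)), nrow = 1L)
}
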