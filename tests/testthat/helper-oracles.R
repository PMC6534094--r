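# Brute-force daily-grid oracles: enumerate every calendar day and apply the
# rules exhaustively. Deliberately naive and independent of the interval
# arithmetic used by the package.

# days covered by a prescription, as integer days
.rx_days <- function(start, days_supply) {
  as.integer(start) + seq_len(days_supply) - 1L
}

.month_of_day <- function(day_int) {
  as.integer(format(as.Date(day_int, origin = "1970-01-01"), "%m"))
}

# allowance for a run of uncovered days: 121 if any day falls in Jun-Aug
.oracle_allowance <- function(gap_days) {
  if (any(.month_of_day(gap_days) %in% 6:8)) 121L else 30L
}

# episodes by walking the day grid: a gap of uncovered days longer than its
# allowance ends the episode on the last covered day before the gap
oracle_episodes <- function(prescriptions, class, from_date) {
  rx <- prescriptions[prescriptions$drug_class == class &
                        prescriptions$start_date >= as.Date(from_date), ,
                      drop = FALSE]
  if (nrow(rx) == 0L) {
    return(data.frame(start_date = as.Date(character()),
                      discontinuation_date = as.Date(character())))
  }
  covered <- sort(unique(unlist(
    Map(.rx_days, rx$start_date, rx$days_supply))))
  starts <- covered[1]; ends <- integer()
  for (k in seq_along(covered)[-1]) {
    gap_len <- covered[k] - covered[k - 1] - 1L
    if (gap_len > 0) {
      gap_days <- (covered[k - 1] + 1L):(covered[k] - 1L)
      if (gap_len > .oracle_allowance(gap_days)) {
        ends <- c(ends, covered[k - 1])
        starts <- c(starts, covered[k])
      }
    }
  }
  ends <- c(ends, covered[length(covered)])
  data.frame(start_date = as.Date(starts, origin = "1970-01-01"),
             discontinuation_date = as.Date(ends, origin = "1970-01-01"))
}

# total prescribed amount by tabulating every supplied day: T counts each
# prescription's days (multiplicity within a stream included), O counts
# days covered by more than one distinct drug/dose stream
oracle_total_amount <- function(prescriptions, window) {
  window <- as.Date(window)
  w <- as.integer(window[1]):as.integer(window[2])
  total <- 0L
  stream_days <- list()
  for (i in seq_len(nrow(prescriptions))) {
    days <- .rx_days(prescriptions$start_date[i],
                     prescriptions$days_supply[i])
    days <- days[days %in% w]
    total <- total + length(days)
    key <- paste(prescriptions$drug_name[i], prescriptions$dose_label[i])
    stream_days[[key]] <- union(stream_days[[key]], days)
  }
  day_counts <- table(unlist(stream_days))
  overlap <- sum(pmax(0L, as.integer(day_counts) - 1L))
  as.integer(total - max(0L, overlap - 90L))
}

# random prescription sets spanning up to ~3 years
random_rx_set <- function(n_max = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- sample.int(n_max, 1)
  tibble::tibble(
    patient_id = "X",
    drug_name = sample(c("drugA", "drugB"), n, replace = TRUE),
    drug_class = "stimulant",
    dose_label = sample(c("d1", "d2"), n, replace = TRUE),
    start_date = as.Date("2009-01-01") + sample.int(1000, n, replace = TRUE),
    days_supply = sample.int(120, n, replace = TRUE))
}

# expected generator labels for a simulated regimen
regimen_cohort <- function(reg) {
  switch(reg,
         first_line_guanfacine = "guanfacine",
         nonfirst_line_guanfacine = "guanfacine",
         combined = "guanfacine",
         first_line_stimulant = "first_line_stimulant",
         unmedicated = "unmedicated")
}

regimen_subgroup <- function(reg) {
  switch(reg,
         first_line_guanfacine = "first_line_guanfacine_mono",
         nonfirst_line_guanfacine = "nonfirst_line_guanfacine_mono",
         combined = "combined_pharmacotherapy",
         "none")
}
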