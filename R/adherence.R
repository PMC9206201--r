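# Adherence to daily recording: recorded days inside the prescribed
# window over prescribed days, the 80% high/low split, and >=3-day
# delayed-start / early-end deviations.

#' Start/end deviation of a recorded series
#'
#' Days between the window start and the first in-window record (delayed
#' start) and between the last in-window record and the window end (early
#' end); a deviation of `flag_days` (default 3) or more raises the
#' corresponding flag. A series with no in-window records is flagged
#' `never_started` with both day counts undefined.
#'
#' @param series A [patient_series()].
#' @param flag_days Deviation (in days) at or above which a flag is raised.
#' @return List with `delayed_start_days`, `early_end_days`,
#'   `delayed_start`, `early_end`, `never_started`.
#' @export
start_end_deviation <- function(series, flag_days = 3L) {
  stopifnot(inherits(series, "patient_series"))
  w <- series$window
  d <- series$days$date
  d <- d[d >= w$start & d <= w$end]
  if (!length(d)) {
    return(list(delayed_start_days = NA_integer_, early_end_days = NA_integer_,
                delayed_start = NA, early_end = NA, never_started = TRUE))
  }
  delayed <- as.integer(min(d) - w$start)
  early <- as.integer(w$end - max(d))
  list(delayed_start_days = delayed, early_end_days = early,
       delayed_start = delayed >= flag_days, early_end = early >= flag_days,
       never_started = FALSE)
}

#' Adherence of one patient
#'
#' Adherence is the percentage of prescribed monitoring days with a
#' completed diary entry: `100 * recorded_days / prescribed_days`. Records
#' dated outside the prescribed window do not count towards the numerator;
#' their number is returned in `excluded_out_of_window`. Patients at or
#' above `threshold` (default 80%) are classified `high`, below it `low`.
#'
#' @param series A [patient_series()].
#' @param threshold High/low adherence split in percent (inclusive at the
#'   threshold: exactly 80% is `high`).
#' @param flag_days Passed to [start_end_deviation()].
#' @return One-row data frame with columns `patient_id, recorded_days,
#'   prescribed_days, adherence_pct, group, delayed_start_days,
#'   early_end_days, delayed_start, early_end, excluded_out_of_window`.
#' @export
patient_adherence <- function(series, threshold = 80, flag_days = 3L) {
  stopifnot(inherits(series, "patient_series"))
  w <- series$window
  inside <- series$days$date >= w$start & series$days$date <= w$end
  rec <- sum(inside)
  pct <- 100 * rec / w$prescribed_days
  dev <- start_end_deviation(series, flag_days)
  data.frame(
    patient_id = series$patient_id,
    recorded_days = rec,
    prescribed_days = w$prescribed_days,
    adherence_pct = pct,
    group = if (pct >= threshold) "high" else "low",
    delayed_start_days = dev$delayed_start_days,
    early_end_days = dev$early_end_days,
    delayed_start = dev$delayed_start,
    early_end = dev$early_end,
    excluded_out_of_window = sum(!inside),
    stringsAsFactors = FALSE
  )
}

#' Adherence table for a cohort
#'
#' @param cohort A [diary_cohort()].
#' @inheritParams patient_adherence
#' @return Data frame with one [patient_adherence()] row per patient.
#' @export
cohort_adherence <- function(cohort, threshold = 80, flag_days = 3L) {
  stopifnot(inherits(cohort, "diary_cohort"))
  if (!length(cohort$patients)) stop("empty cohort", call. = FALSE)
  do.call(rbind, c(lapply(cohort$patients, patient_adherence,
                          threshold = threshold, flag_days = flag_days),
                   make.row.names = FALSE))
}

#' Pooled cohort adherence
#'
#' The pooled ratio `100 * (total recorded days) / (total prescribed
#' days)`. This is the cohort "average adherence" in the pooled sense
#' (e.g. 4003 reports over 5654 prescribed days = 70.8%); it differs from
#' the mean of per-patient percentages when prescribed windows differ, so
#' both are computed and labelled distinctly (see
#' [mean_individual_adherence()]).
#'
#' @param cohort A [diary_cohort()] or a [cohort_adherence()] table.
#' @return A percentage in `[0, 100]`.
#' @export
pooled_adherence <- function(cohort) {
  tab <- if (is.data.frame(cohort)) cohort else cohort_adherence(cohort)
  if (!nrow(tab)) stop("empty cohort", call. = FALSE)
  100 * sum(tab$recorded_days) / sum(tab$prescribed_days)
}

#' Mean of per-patient adherence percentages
#'
#' @inheritParams pooled_adherence
#' @return A percentage in `[0, 100]`.
#' @export
mean_individual_adherence <- function(cohort) {
  tab <- if (is.data.frame(cohort)) cohort else cohort_adherence(cohort)
  if (!nrow(tab)) stop("empty cohort", call. = FALSE)
  mean(tab$adherence_pct)
}

#' Partition a cohort by adherence
#'
#' Splits patients at the (inclusive) adherence threshold and reports the
#' group sizes and their percentages of the cohort (one decimal place).
#'
#' @inheritParams cohort_adherence
#' @return List with `high` / `low` (character vectors of patient ids),
#'   `n_high`, `n_low`, `pct_high`, `pct_low`, `threshold`.
#' @export
classify_cohort <- function(cohort, threshold = 80) {
  tab <- if (is.data.frame(cohort)) cohort else cohort_adherence(cohort)
  hi <- tab$adherence_pct >= threshold
  n <- nrow(tab)
  list(
    high = tab$patient_id[hi],
    low = tab$patient_id[!hi],
    n_high = sum(hi),
    n_low = sum(!hi),
    pct_high = round(100 * sum(hi) / n, 1),
    pct_low = round(100 * sum(!hi) / n, 1),
    threshold = threshold
  )
}
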