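#' Score names understood by the pipeline
#' @format Character vector `c("RTSS", "CSMS", "VAS")`.
#' @export
SCORE_NAMES <- c("RTSS", "CSMS", "VAS")

#' Default medication weights for the daily medication score
#'
#' Stepwise drug-class scheme of the combined symptom and medication score:
#' antihistamine = 1, nasal (topical) steroid = 2, systemic steroid = 3;
#' when several classes are taken the same day the maximum applies.
#'
#' @format Named numeric vector.
#' @export
DEFAULT_MED_WEIGHTS <- c(antihistamine = 1, nasal_steroid = 2,
                         systemic_steroid = 3)

# Accept a patient_series, a data frame of days, or a single day given as a
# named list; always return a data frame with the item columns.
as_day_frame <- function(day) {
  if (inherits(day, "patient_series")) return(day$days)
  if (is.data.frame(day)) return(day)
  if (is.list(day)) return(as.data.frame(day, stringsAsFactors = FALSE))
  stop("expected a patient_series, data frame or named list of items",
       call. = FALSE)
}

#' Rhinoconjunctivitis Total Symptom Score (RTSS)
#'
#' Sum of the six symptom grades (four nasal + two ocular, each 0-3),
#' range 0-18.
#'
#' @param day A diary day (named list), a data frame of days, or a
#'   [patient_series()]; vectorised over rows.
#' @return Numeric vector of daily RTSS values.
#' @examples
#' rtss(list(sneezing = 1, rhinorrhea = 2, nasal_pruritus = 0,
#'           nasal_congestion = 1, itchy_eyes = 0, watery_eyes = 1))  # 5
#' @export
rtss <- function(day) {
  days <- as_day_frame(day)
  unname(rowSums(days[DIARY_SYMPTOMS]))
}

#' Daily medication score (dMS)
#'
#' 0 when no medication was taken; otherwise the maximum weight among the
#' drug classes used that day (see [DEFAULT_MED_WEIGHTS]). Range 0-3 under
#' the default weights.
#'
#' @inheritParams rtss
#' @param med_weights Named weights for the three medication flags.
#' @return Numeric vector of daily medication scores.
#' @export
medication_score <- function(day, med_weights = DEFAULT_MED_WEIGHTS) {
  days <- as_day_frame(day)
  stopifnot(all(DIARY_MEDS %in% names(med_weights)))
  parts <- lapply(DIARY_MEDS, function(m) med_weights[[m]] * days[[m]])
  unname(do.call(pmax, c(parts, list(0))))
}

#' Combined Symptom and Medication Score (CSMS)
#'
#' Daily symptom score (mean of the six grades, range 0-3) plus daily
#' medication score (range 0-3), giving a 0-6 score whose unit increment is
#' 1/6 (~0.167): one symptom item rising by one grade moves the score by
#' one sixth.
#'
#' @inheritParams medication_score
#' @return Numeric vector of daily CSMS values, multiples of 1/6.
#' @export
csms <- function(day, med_weights = DEFAULT_MED_WEIGHTS) {
  days <- as_day_frame(day)
  unname(rowSums(days[DIARY_SYMPTOMS]) / 6 +
           medication_score(days, med_weights))
}

#' Daily visual analogue scale value
#'
#' Pass-through of the recorded 0-10 VAS with range validation.
#'
#' @inheritParams rtss
#' @return Numeric vector of daily VAS values.
#' @export
vas_value <- function(day) {
  days <- as_day_frame(day)
  v <- days$vas
  if (any(is.na(v) | v < 0 | v > 10)) {
    stop("vas outside {0,...,10}", call. = FALSE)
  }
  unname(as.numeric(v))
}

#' Unit increment of a daily score
#'
#' The smallest possible nonzero change of the score: 1 for RTSS and VAS,
#' 1/6 for CSMS.
#'
#' @param score_name One of [SCORE_NAMES].
#' @return A positive number.
#' @export
unit_step <- function(score_name) {
  score_name <- match.arg(score_name, SCORE_NAMES)
  c(RTSS = 1, CSMS = 1 / 6, VAS = 1)[[score_name]]
}

#' Compute one daily score for a set of days
#' @inheritParams medication_score
#' @param score_name One of [SCORE_NAMES].
#' @return Numeric vector of daily values.
#' @export
daily_score <- function(day, score_name, med_weights = DEFAULT_MED_WEIGHTS) {
  score_name <- match.arg(score_name, SCORE_NAMES)
  switch(score_name,
         RTSS = rtss(day),
         CSMS = csms(day, med_weights),
         VAS = vas_value(day))
}

#' Score trajectory constructor
#'
#' An ordered per-patient (date, value) series for one score, carrying the
#' score's unit increment `S`. Values must lie on the score's grid (every
#' value an integer multiple of `S`, checked to 1e-9) and dates must be
#' strictly increasing.
#'
#' @param patient_id Scalar identifier.
#' @param score_name One of [SCORE_NAMES].
#' @param dates Vector of dates (strictly increasing).
#' @param values Numeric values, same length as `dates`.
#' @param S Unit increment; defaults to [unit_step()] of `score_name`.
#' @return An object of class `score_trajectory` with fields `patient_id`,
#'   `score_name`, `S`, `dates`, `values`.
#' @export
score_trajectory <- function(patient_id, score_name, dates, values,
                             S = unit_step(score_name)) {
  score_name <- match.arg(score_name, SCORE_NAMES)
  dates <- as.Date(dates)
  values <- as.numeric(values)
  if (length(dates) != length(values)) {
    stop("dates and values must have the same length", call. = FALSE)
  }
  if (length(dates) > 1L && any(diff(dates) <= 0)) {
    stop("trajectory dates must be strictly increasing", call. = FALSE)
  }
  if (!is.numeric(S) || length(S) != 1L || S <= 0) {
    stop("S must be a single positive number", call. = FALSE)
  }
  off_grid <- abs(values / S - round(values / S)) > 1e-9
  if (any(off_grid)) {
    stop("value ", values[off_grid][1L], " is not a multiple of the unit ",
         "step S = ", S, call. = FALSE)
  }
  structure(
    list(patient_id = as.character(patient_id), score_name = score_name,
         S = S, dates = dates, values = values),
    class = "score_trajectory"
  )
}

#' @export
print.score_trajectory <- function(x, ...) {
  cat(sprintf("<score_trajectory %s/%s: T=%d, S=%.3g>\n", x$patient_id,
              x$score_name, length(x$values), x$S))
  invisible(x)
}

#' Number of recorded values in a trajectory
#' @param traj A [score_trajectory()].
#' @return Integer `T`.
#' @export
trajectory_length <- function(traj) {
  stopifnot(inherits(traj, "score_trajectory"))
  length(traj$values)
}

#' Build a patient's score trajectory
#'
#' Applies the daily score to every recorded day of a series, in date
#' order. An empty series yields an empty trajectory (`T = 0`), not an
#' error.
#'
#' @param series A [patient_series()].
#' @inheritParams daily_score
#' @return A [score_trajectory()].
#' @export
build_trajectory <- function(series, score_name,
                             med_weights = DEFAULT_MED_WEIGHTS) {
  stopifnot(inherits(series, "patient_series"))
  score_name <- match.arg(score_name, SCORE_NAMES)
  score_trajectory(series$patient_id, score_name, series$days$date,
                   daily_score(series$days, score_name, med_weights))
}

#' Daily score table for a cohort
#'
#' One row per recorded patient-day with all three daily scores.
#'
#' @param cohort A [diary_cohort()].
#' @inheritParams medication_score
#' @return Data frame with columns `patient_id,date,rtss,csms,vas`.
#' @export
score_table <- function(cohort, med_weights = DEFAULT_MED_WEIGHTS) {
  stopifnot(inherits(cohort, "diary_cohort"))
  rows <- lapply(cohort$patients, function(p) {
    if (!nrow(p$days)) return(NULL)
    data.frame(
      patient_id = p$patient_id,
      date = p$days$date,
      rtss = rtss(p$days),
      csms = csms(p$days, med_weights),
      vas = vas_value(p$days),
      stringsAsFactors = FALSE
    )
  })
  rows <- Filter(Negate(is.null), rows)
  out <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE)) else NULL
  if (is.null(out)) {
    out <- data.frame(patient_id = character(0), date = as.Date(character(0)),
                      rtss = numeric(0), csms = numeric(0), vas = numeric(0))
  }
  out
}
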