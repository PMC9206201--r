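# The four candidate data-quality indices computed on one patient's score
# trajectory. Percent-scale outputs; undefined values are NA (never 0).
#
# Numerical conventions: values lie on a grid of step S, so equality of
# consecutive values is tested with an absolute tolerance of 1e-9 (the
# smallest grid step in use is 1/6); the sample SD uses the n-1
# denominator.

.EQ_TOL <- 1e-9

# Sign of a difference with the grid tolerance: -1, 0, +1.
diff_sign <- function(x) {
  s <- sign(x)
  s[abs(x) <= .EQ_TOL] <- 0
  s
}

#' Consecutive-day value pairs of a trajectory
#'
#' The day-to-day comparisons all four indices are built from. Under the
#' default `"calendar"` mode a pair is formed only when two records fall on
#' adjacent calendar dates, so recording gaps break the pairing; under
#' `"record"` mode successive records are paired regardless of gaps.
#'
#' @param traj A [score_trajectory()].
#' @param mode `"calendar"` (default) or `"record"`.
#' @return Numeric matrix with columns `y1`, `y2`; zero rows when fewer
#'   than two records (or no adjacent records in calendar mode).
#' @export
consecutive_pairs <- function(traj, mode = c("calendar", "record")) {
  mode <- match.arg(mode)
  v <- traj$values
  n <- length(v)
  if (n < 2L) {
    return(matrix(numeric(0), ncol = 2L, dimnames = list(NULL, c("y1", "y2"))))
  }
  keep <- if (mode == "calendar") {
    diff(as.integer(traj$dates)) == 1L
  } else {
    rep(TRUE, n - 1L)
  }
  cbind(y1 = v[-n][keep], y2 = v[-1L][keep])
}

#' Individual variation range in unit steps (rVAR)
#'
#' `(max(y) - min(y)) / S`: the observed range of the trajectory expressed
#' in unit increments of the score. With `plus_one = TRUE` the variant
#' `(max - min + S) / S` (= steps + 1) is used, which avoids a zero range
#' for constant series.
#'
#' @param traj A [score_trajectory()].
#' @param plus_one Use the range-plus-one variant.
#' @return A number >= 0, or `NA` for an empty trajectory.
#' @export
rvar <- function(traj, plus_one = FALSE) {
  v <- traj$values
  if (!length(v)) return(NA_real_)
  r <- (max(v) - min(v)) / traj$S
  if (plus_one) r + 1 else r
}

#' Intravariation index (IVI)
#'
#' Step (1): the percentage of consecutive-day pairs on which the value
#' changed, `pctVar = 100 * sum(I(y_{t+1} != y_t)) / n_pairs`. Step (2):
#' the individual variation range in unit steps, [rvar()]. The index is
#' `pctVar / rVAR`; a constant series (rVAR = 0) yields 0. Undefined (NA)
#' when fewer than two values, or when the pairing mode leaves no pairs.
#'
#' @inheritParams consecutive_pairs
#' @param rvar_plus_one Use the `(max - min + S)/S` range variant.
#' @return A number >= 0, or `NA` when undefined.
#' @export
intravariation_index <- function(traj, mode = c("calendar", "record"),
                                 rvar_plus_one = FALSE) {
  p <- consecutive_pairs(traj, mode)
  if (!nrow(p)) return(NA_real_)
  pct_var <- 100 * mean(abs(p[, 2L] - p[, 1L]) > .EQ_TOL)
  r <- rvar(traj, plus_one = rvar_plus_one)
  if (r == 0) 0 else pct_var / r
}

#' Percentage of zero values
#'
#' `100 * #\{t : y_t = 0\} / T` over the compiled (recorded) days.
#'
#' @param traj A [score_trajectory()].
#' @return A percentage in `[0, 100]`, or `NA` for an empty trajectory.
#' @export
pct_zero_values <- function(traj) {
  v <- traj$values
  if (!length(v)) return(NA_real_)
  100 * mean(abs(v) <= .EQ_TOL)
}

#' Coefficient of variation
#'
#' `100 * SD / mean` with the sample SD (n - 1 denominator). Undefined
#' (NA) for fewer than two values or a zero mean.
#'
#' @param traj A [score_trajectory()].
#' @return A number >= 0, or `NA` when undefined.
#' @export
coefficient_of_variation <- function(traj) {
  v <- traj$values
  if (length(v) < 2L) return(NA_real_)
  m <- mean(v)
  if (m <= .EQ_TOL) return(NA_real_)
  100 * stats::sd(v) / m
}

#' Percentage of changes in trend
#'
#' Each consecutive-day pair is labelled by the sign of its difference:
#' worsening (+), stability (0) or improvement (-). A change in trend is a
#' transition between successive labels, and the index is
#' `100 * changes / (n_pairs - 1)`. Being a function of the sign pattern
#' only, it is insensitive to the score's scale and level. Undefined (NA)
#' with fewer than two pairs.
#'
#' `trend_mode = "nonzero_diff"` instead reports the percentage of pairs
#' with any change (`100 * #\{s_t != 0\} / n_pairs`), an alternative
#' reading that duplicates the IVI numerator; defined from one pair.
#'
#' @inheritParams consecutive_pairs
#' @param trend_mode `"sign_transition"` (default) or `"nonzero_diff"`.
#' @return A percentage in `[0, 100]`, or `NA` when undefined.
#' @export
pct_changes_in_trend <- function(traj, mode = c("calendar", "record"),
                                 trend_mode = c("sign_transition",
                                                "nonzero_diff")) {
  trend_mode <- match.arg(trend_mode)
  p <- consecutive_pairs(traj, mode)
  np <- nrow(p)
  s <- diff_sign(p[, 2L] - p[, 1L])
  if (trend_mode == "nonzero_diff") {
    if (np < 1L) return(NA_real_)
    return(100 * mean(s != 0))
  }
  if (np < 2L) return(NA_real_)
  100 * sum(s[-1L] != s[-np]) / (np - 1L)
}

#' All four quality indices of one trajectory
#'
#' Bundles the four indices with the bookkeeping quantities `T` (recorded
#' values), `n_pairs` (consecutive-day pairs used), `rVAR` and `S`.
#' Undefined indices are NA, never imputed as 0.
#'
#' @inheritParams pct_changes_in_trend
#' @inheritParams intravariation_index
#' @return One-row data frame with columns `patient_id, score_name, T,
#'   n_pairs, ivi, pct_zero, cv, pct_trend_change, rVAR, S`.
#' @export
trajectory_quality <- function(traj, mode = c("calendar", "record"),
                               rvar_plus_one = FALSE,
                               trend_mode = c("sign_transition",
                                              "nonzero_diff")) {
  mode <- match.arg(mode)
  trend_mode <- match.arg(trend_mode)
  data.frame(
    patient_id = traj$patient_id,
    score_name = traj$score_name,
    T = length(traj$values),
    n_pairs = nrow(consecutive_pairs(traj, mode)),
    ivi = intravariation_index(traj, mode, rvar_plus_one),
    pct_zero = pct_zero_values(traj),
    cv = coefficient_of_variation(traj),
    pct_trend_change = pct_changes_in_trend(traj, mode, trend_mode),
    rVAR = rvar(traj, plus_one = rvar_plus_one),
    S = traj$S,
    stringsAsFactors = FALSE
  )
}

#' Quality-index table for a cohort
#'
#' Computes [trajectory_quality()] for every patient and every requested
#' score.
#'
#' @param cohort A [diary_cohort()].
#' @param scores Subset of [SCORE_NAMES].
#' @inheritParams trajectory_quality
#' @inheritParams build_trajectory
#' @return Data frame, one row per patient x score.
#' @export
cohort_quality_indices <- function(cohort, scores = SCORE_NAMES,
                                   mode = c("calendar", "record"),
                                   rvar_plus_one = FALSE,
                                   trend_mode = c("sign_transition",
                                                  "nonzero_diff"),
                                   med_weights = DEFAULT_MED_WEIGHTS) {
  stopifnot(inherits(cohort, "diary_cohort"))
  mode <- match.arg(mode)
  trend_mode <- match.arg(trend_mode)
  scores <- match.arg(scores, SCORE_NAMES, several.ok = TRUE)
  rows <- lapply(cohort$patients, function(p) {
    do.call(rbind, lapply(scores, function(sc) {
      trajectory_quality(build_trajectory(p, sc, med_weights), mode,
                         rvar_plus_one, trend_mode)
    }))
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
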