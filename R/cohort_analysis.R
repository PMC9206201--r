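# Cohort-level statistics: population trajectories, score interrelations,
# index summaries (mean, t-based 95% CI) and the high- vs low-adherence
# Mann-Whitney comparison that is the headline analysis.

INDEX_COLUMNS <- c(ivi = "ivi", pct_zero = "pct_zero", cv = "cv",
                   pct_trend_change = "pct_trend_change")

#' Per-date population mean of a score
#'
#' For each calendar date, the mean score over the patients who recorded
#' that date, with the per-date denominator.
#'
#' @param cohort A [diary_cohort()].
#' @inheritParams daily_score
#' @return Data frame with columns `date`, `mean`, `n`, sorted by date.
#' @export
population_trajectory <- function(cohort, score_name,
                                  med_weights = DEFAULT_MED_WEIGHTS) {
  stopifnot(inherits(cohort, "diary_cohort"))
  if (!length(cohort$patients)) stop("empty cohort", call. = FALSE)
  score_name <- match.arg(score_name, SCORE_NAMES)
  tab <- score_table(cohort, med_weights)
  col <- c(RTSS = "rtss", CSMS = "csms", VAS = "vas")[[score_name]]
  if (!nrow(tab)) {
    return(data.frame(date = as.Date(character(0)), mean = numeric(0),
                      n = integer(0)))
  }
  agg <- stats::aggregate(tab[[col]], by = list(date = tab$date),
                          FUN = function(x) c(mean = mean(x), n = length(x)))
  out <- data.frame(date = agg$date, mean = agg$x[, "mean"],
                    n = as.integer(agg$x[, "n"]))
  out[order(out$date), , drop = FALSE]
}

#' Per-patient mean daily scores
#'
#' Individual averages of RTSS, CSMS and VAS over each patient's recorded
#' days (NA for a patient with no records).
#'
#' @inheritParams population_trajectory
#' @return Data frame with columns `patient_id`, `RTSS`, `CSMS`, `VAS`.
#' @export
patient_mean_scores <- function(cohort, med_weights = DEFAULT_MED_WEIGHTS) {
  stopifnot(inherits(cohort, "diary_cohort"))
  rows <- lapply(cohort$patients, function(p) {
    if (!nrow(p$days)) {
      return(data.frame(patient_id = p$patient_id, RTSS = NA_real_,
                        CSMS = NA_real_, VAS = NA_real_,
                        stringsAsFactors = FALSE))
    }
    data.frame(
      patient_id = p$patient_id,
      RTSS = mean(rtss(p$days)),
      CSMS = mean(csms(p$days, med_weights)),
      VAS = mean(vas_value(p$days)),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Spearman correlations between individual average scores
#'
#' Rank correlation of the per-patient mean scores for the pairs
#' (RTSS, VAS), (CSMS, VAS) and (CSMS, RTSS). P-values use the asymptotic
#' t approximation (ties among patient means are common, so the exact
#' permutation p is not available in general).
#'
#' @inheritParams population_trajectory
#' @return Data frame with columns `score_pair`, `spearman_rho`,
#'   `p_value`, `n`.
#' @export
score_correlations <- function(cohort, med_weights = DEFAULT_MED_WEIGHTS) {
  means <- patient_mean_scores(cohort, med_weights)
  means <- means[stats::complete.cases(means), , drop = FALSE]
  if (nrow(means) < 3L) {
    stop("score correlations need at least 3 patients with recorded days",
         call. = FALSE)
  }
  pairs <- list(c("RTSS", "VAS"), c("CSMS", "VAS"), c("CSMS", "RTSS"))
  rows <- lapply(pairs, function(pr) {
    ct <- suppressWarnings(
      stats::cor.test(means[[pr[1L]]], means[[pr[2L]]],
                      method = "spearman", exact = FALSE)
    )
    data.frame(score_pair = paste(pr, collapse = "_"),
               spearman_rho = unname(ct$estimate),
               p_value = ct$p.value,
               n = nrow(means),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Cohort summary of the quality indices
#'
#' Mean and t-based 95% confidence interval (mean +/- t_{0.975, n-1} * SE)
#' of each index for each score, over the patients for whom the index is
#' defined. Patients with undefined (NA) index values are excluded from
#' the average, never imputed; the exclusion counts are attached as the
#' `"n_excluded"` attribute.
#'
#' @param indices A [cohort_quality_indices()] table.
#' @return Data frame with columns `score_name, index_name, mean,
#'   ci95_low, ci95_high, n_used` (CI is NA when n < 2).
#' @export
summarize_indices <- function(indices) {
  stopifnot(is.data.frame(indices))
  combos <- expand.grid(score_name = unique(indices$score_name),
                        index_name = names(INDEX_COLUMNS),
                        stringsAsFactors = FALSE)
  excl <- integer(0)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sc <- combos$score_name[i]
    ix <- combos$index_name[i]
    x <- indices[indices$score_name == sc, INDEX_COLUMNS[[ix]]]
    excl[[paste(sc, ix, sep = ".")]] <<- sum(is.na(x))
    x <- x[!is.na(x)]
    n <- length(x)
    m <- if (n) mean(x) else NA_real_
    half <- if (n >= 2L) {
      stats::qt(0.975, n - 1L) * stats::sd(x) / sqrt(n)
    } else {
      NA_real_
    }
    data.frame(score_name = sc, index_name = ix, mean = m,
               ci95_low = m - half, ci95_high = m + half, n_used = n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  attr(out, "n_excluded") <- excl
  out
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two samples. The p-value is exact when
#' the combined sample size is at most `exact_max` (default 20) and there
#' are no ties; otherwise the normal approximation with tie correction
#' (and continuity correction) is used. The reported U statistic counts
#' the pairs `(x_i, y_j)` with `x_i > y_j` (plus half-ties), i.e. the
#' Wilcoxon W of the first sample.
#'
#' @param x,y Numeric samples.
#' @param exact_max Largest combined size for the exact null distribution.
#' @return List with `u`, `p_value`, `n_x`, `n_y`, `method`.
#' @export
mann_whitney <- function(x, y, exact_max = 20L) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (!length(x) || !length(y)) {
    stop("mann_whitney requires non-empty samples", call. = FALSE)
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- !ties && (length(x) + length(y)) <= exact_max
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = use_exact,
                       correct = !use_exact)
  )
  list(u = unname(wt$statistic), p_value = wt$p.value,
       n_x = length(x), n_y = length(y),
       method = if (use_exact) "exact" else "normal_approx_tie_corrected")
}

#' Compare quality indices between adherence groups
#'
#' The headline analysis: for each score x index pair, the per-patient
#' index values of the low-adherence group (< threshold) are compared with
#' those of the high-adherence group (>= threshold) by a two-sided
#' Mann-Whitney U test. Group medians and interquartile ranges (25th/75th
#' percentiles, linear interpolation, [stats::quantile()] type 7) are
#' reported; p-values are raw (no multiplicity adjustment). Patients with
#' an undefined index are excluded pairwise.
#'
#' @param indices A [cohort_quality_indices()] table.
#' @param adherence A [cohort_adherence()] table for the same patients.
#' @param threshold Adherence split in percent (inclusive for `high`).
#' @return Data frame with one row per score x index: `score_name,
#'   index_name, n_low, n_high, median_low, q1_low, q3_low, median_high,
#'   q1_high, q3_high, u_statistic, p_value`.
#' @export
compare_by_adherence <- function(indices, adherence, threshold = 80) {
  stopifnot(is.data.frame(indices), is.data.frame(adherence))
  grp <- ifelse(adherence$adherence_pct >= threshold, "high", "low")
  names(grp) <- adherence$patient_id
  if (!any(grp == "low")) stop("adherence group 'low' is empty", call. = FALSE)
  if (!any(grp == "high")) stop("adherence group 'high' is empty", call. = FALSE)
  unknown <- setdiff(indices$patient_id, adherence$patient_id)
  if (length(unknown)) {
    stop("no adherence record for patient(s): ",
         paste(unique(unknown), collapse = ", "), call. = FALSE)
  }
  g <- grp[indices$patient_id]
  combos <- expand.grid(score_name = unique(indices$score_name),
                        index_name = names(INDEX_COLUMNS),
                        stringsAsFactors = FALSE)
  q13 <- function(x) stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sel <- indices$score_name == combos$score_name[i]
    x <- indices[sel & g == "low", INDEX_COLUMNS[[combos$index_name[i]]]]
    y <- indices[sel & g == "high", INDEX_COLUMNS[[combos$index_name[i]]]]
    x <- x[!is.na(x)]
    y <- y[!is.na(y)]
    if (!length(x) || !length(y)) {
      mw <- list(u = NA_real_, p_value = NA_real_)
      qx <- qy <- c(NA_real_, NA_real_)
      mx <- my <- NA_real_
    } else {
      mw <- mann_whitney(x, y)
      qx <- q13(x); qy <- q13(y)
      mx <- stats::median(x); my <- stats::median(y)
    }
    data.frame(
      score_name = combos$score_name[i], index_name = combos$index_name[i],
      n_low = length(x), n_high = length(y),
      median_low = mx, q1_low = qx[1L], q3_low = qx[2L],
      median_high = my, q1_high = qy[1L], q3_high = qy[2L],
      u_statistic = mw$u, p_value = mw$p_value,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
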