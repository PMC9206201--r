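test_that("population trajectory is the per-date mean over recording patients", {
  w <- test_window()
  d1 <- rbind(day_row(date = "2016-05-04", sneezing = 2),
              day_row(date = "2016-05-05", sneezing = 1))
  d2 <- day_row(date = "2016-05-04", sneezing = 2, rhinorrhea = 2)
  cohort <- diary_cohort(list(patient_series("A", w, d1),
                              patient_series("B", w, d2)))
  pop <- population_trajectory(cohort, "RTSS")
  expect_equal(pop$mean, c(3, 1))  # (2+4)/2 on day 1, single patient on day 2
  expect_equal(pop$n, c(2L, 1L))

  single <- diary_cohort(list(patient_series("A", w, d1)))
  expect_equal(population_trajectory(single, "RTSS")$mean, rtss(d1))
})

test_that("population trajectory matches a brute-force group-by mean on synthetic data", {
  sim <- small_sim(n_patients = 8L, seed = 21L)
  tab <- score_table(sim$cohort)
  pop <- population_trajectory(sim$cohort, "CSMS")
  for (i in seq_len(nrow(pop))) {
    sel <- tab$date == pop$date[i]
    expect_equal(pop$mean[i], mean(tab$csms[sel]))
    expect_equal(pop$n[i], sum(sel))
  }
})

test_that("spearman correlations agree with the rank-based oracle and hit the +/-1 bounds", {
  w <- test_window()
  mk <- function(id, grade, vas) {
    patient_series(id, w, day_row(sneezing = grade, vas = vas))
  }
  # identical rankings -> rho = 1 for RTSS vs VAS
  up <- diary_cohort(list(mk("A", 0, 1), mk("B", 1, 2), mk("C", 2, 5),
                          mk("D", 3, 9)))
  rows <- score_correlations(up)
  expect_equal(rows$spearman_rho[rows$score_pair == "RTSS_VAS"], 1)
  # reversed rankings -> rho = -1
  down <- diary_cohort(list(mk("A", 0, 9), mk("B", 1, 5), mk("C", 2, 2),
                            mk("D", 3, 1)))
  rows2 <- score_correlations(down)
  expect_equal(rows2$spearman_rho[rows2$score_pair == "RTSS_VAS"], -1)

  sim <- small_sim(n_patients = 10L, seed = 31L)
  means <- patient_mean_scores(sim$cohort)
  rows3 <- score_correlations(sim$cohort)
  expect_equal(rows3$spearman_rho[rows3$score_pair == "CSMS_RTSS"],
               oracle_spearman_rho(means$CSMS, means$RTSS))
  expect_equal(rows3$spearman_rho[rows3$score_pair == "CSMS_VAS"],
               oracle_spearman_rho(means$CSMS, means$VAS))

  tiny <- diary_cohort(list(mk("A", 0, 1), mk("B", 1, 2)))
  expect_error(score_correlations(tiny), "at least 3")
})

test_that("index summaries use t-based confidence intervals over defined values", {
  idx <- data.frame(
    patient_id = sprintf("P%d", 1:5),
    score_name = "RTSS",
    ivi = c(0, 0, 10, 10, NA),
    pct_zero = c(5, 5, 5, 5, 5),
    cv = c(NA, NA, NA, NA, NA),
    pct_trend_change = c(0, 50, 100, 25, 75),
    stringsAsFactors = FALSE
  )
  s <- summarize_indices(idx)
  row <- s[s$index_name == "ivi", ]
  expect_equal(row$mean, 5)
  expect_equal(row$n_used, 4L)
  half <- stats::qt(0.975, 3) * stats::sd(c(0, 0, 10, 10)) / 2
  expect_equal(row$ci95_low, 5 - half)
  expect_equal(row$ci95_high, 5 + half)

  const <- s[s$index_name == "pct_zero", ]
  expect_equal(const$mean, 5)
  expect_equal(const$ci95_low, 5)  # zero-width CI for identical values
  expect_true(is.na(s[s$index_name == "cv", "mean"]))
  expect_equal(attr(s, "n_excluded")[["RTSS.ivi"]], 1L)
  expect_true(all(s$ci95_low <= s$mean & s$mean <= s$ci95_high, na.rm = TRUE))
})

test_that("mann_whitney agrees with exact enumeration for all group sizes <= 6", {
  set.seed(501)
  for (m in 1:6) {
    for (n in 1:6) {
      vals <- sample(seq(0, 1, length.out = 50), m + n)  # distinct values
      x <- vals[seq_len(m)]
      y <- vals[-seq_len(m)]
      mw <- mann_whitney(x, y)
      expect_equal(mw$u, oracle_u(x, y))
      expect_equal(mw$p_value, oracle_mw_exact_p(x, y), tolerance = 1e-12)
      expect_equal(mw$method, "exact")
    }
  }
  # completely separated groups of 3 vs 3: exact two-sided p = 2/20
  sep <- mann_whitney(c(1, 2, 3), c(10, 11, 12))
  expect_equal(sep$p_value, 0.1)
  expect_equal(sep$u, 0)
})

test_that("mann_whitney falls back to the tie-corrected normal approximation", {
  x <- c(1, 1, 2, 3)
  y <- c(2, 2, 3, 4)
  mw <- mann_whitney(x, y)
  expect_equal(mw$method, "normal_approx_tie_corrected")
  expect_true(mw$p_value > 0 && mw$p_value <= 1)
})

test_that("group comparison reports medians/IQRs and is symmetric in labels", {
  set.seed(502)
  idx <- data.frame(
    patient_id = sprintf("P%02d", 1:12),
    score_name = "VAS",
    ivi = rnorm(12, 5), pct_zero = runif(12, 0, 100),
    cv = rnorm(12, 100, 10), pct_trend_change = runif(12, 0, 100),
    stringsAsFactors = FALSE
  )
  adh <- data.frame(patient_id = idx$patient_id,
                    adherence_pct = c(rep(50, 5), rep(95, 7)),
                    stringsAsFactors = FALSE)
  cmp <- compare_by_adherence(idx, adh)
  expect_equal(nrow(cmp), 4L)
  expect_equal(cmp$n_low[1], 5L)
  expect_equal(cmp$n_high[1], 7L)
  row <- cmp[cmp$index_name == "ivi", ]
  low_vals <- idx$ivi[adh$adherence_pct < 80]
  expect_equal(row$median_low, stats::median(low_vals))
  expect_equal(row$q1_low, unname(stats::quantile(low_vals, 0.25)))

  # swapping the group labels leaves p unchanged
  adh_swap <- adh
  adh_swap$adherence_pct <- ifelse(adh$adherence_pct < 80, 95, 50)
  cmp_swap <- compare_by_adherence(idx, adh_swap)
  expect_equal(cmp$p_value, cmp_swap$p_value)

  adh_all_high <- adh
  adh_all_high$adherence_pct <- 90
  expect_error(compare_by_adherence(idx, adh_all_high), "'low' is empty")
})
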