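test_that("consecutive pairs respect calendar vs record adjacency", {
  t1 <- traj(c(0, 1, 2))
  expect_equal(nrow(consecutive_pairs(t1, "calendar")), 2L)
  expect_equal(nrow(consecutive_pairs(t1, "record")), 2L)

  # records on days 1,2,5,6: calendar 2 pairs, record 3 pairs
  d <- as.Date("2016-05-04") + c(0, 1, 4, 5)
  t2 <- traj(c(0, 1, 2, 3), dates = d)
  expect_equal(nrow(consecutive_pairs(t2, "calendar")), 2L)
  expect_equal(consecutive_pairs(t2, "calendar")[, "y1"], c(0, 2))
  expect_equal(nrow(consecutive_pairs(t2, "record")), 3L)

  expect_equal(nrow(consecutive_pairs(traj(5))), 0L)
})

test_that("intravariation index matches its hand-computed examples", {
  expect_equal(intravariation_index(traj(c(1, 1, 1))), 0)
  expect_equal(intravariation_index(traj(c(0, 1, 0, 1))), 100)
  expect_equal(intravariation_index(traj(c(0, 2, 2, 4, 4))), 12.5)
  # CSMS grid: pctVar 50, rVAR (1/6)/(1/6) = 1
  expect_equal(intravariation_index(traj(c(0, 1 / 6, 1 / 6), score = "CSMS")), 50)
  expect_true(is.na(intravariation_index(traj(3))))
  # rVAR variant: (max-min+S)/S = steps + 1
  expect_equal(rvar(traj(c(0, 2))), 2)
  expect_equal(rvar(traj(c(0, 2)), plus_one = TRUE), 3)
  expect_equal(intravariation_index(traj(c(0, 1, 0, 1)), rvar_plus_one = TRUE), 50)
})

test_that("percentage of zero values and coefficient of variation match hand arithmetic", {
  expect_equal(pct_zero_values(traj(c(0, 0, 1, 2))), 50)
  expect_equal(pct_zero_values(traj(c(0, 0, 0))), 100)
  expect_equal(pct_zero_values(traj(c(1, 2, 3))), 0)

  expect_equal(coefficient_of_variation(traj(c(2, 2, 2))), 0)
  expect_equal(coefficient_of_variation(traj(c(0, 4))), 100 * sqrt(8) / 2)
  # scale invariance
  v <- c(1, 3, 0, 2, 5)
  expect_equal(coefficient_of_variation(traj(3 * v, score = "VAS", S = 1)),
               coefficient_of_variation(traj(v)))
  expect_true(is.na(coefficient_of_variation(traj(c(0, 0)))))
  expect_true(is.na(coefficient_of_variation(traj(7))))
})

test_that("percentage of changes in trend counts sign transitions", {
  expect_equal(pct_changes_in_trend(traj(c(1, 2, 3, 4))), 0)
  expect_equal(pct_changes_in_trend(traj(c(1, 2, 1, 2))), 100)
  expect_equal(pct_changes_in_trend(traj(c(5, 5, 5, 5))), 0)
  expect_true(is.na(pct_changes_in_trend(traj(c(1, 2)))))  # one pair
  # alternative reading: share of non-zero differences
  expect_equal(pct_changes_in_trend(traj(c(1, 2, 2, 3)),
                                    trend_mode = "nonzero_diff"),
               100 * 2 / 3)
})

test_that("trend change is invariant under strictly increasing affine maps; ivi under joint scaling", {
  set.seed(77)
  for (r in 1:25) {
    v <- sample(0:4, 7, replace = TRUE)
    tv <- traj(v)
    expect_equal(pct_changes_in_trend(traj(2.5 * v + 3, S = 0.5)),
                 pct_changes_in_trend(tv))
    expect_equal(intravariation_index(traj(2 * v, S = 2)),
                 intravariation_index(tv))
  }
})

test_that("ivi never exceeds pctVar on integer-grid series with range >= S", {
  set.seed(78)
  for (r in 1:50) {
    v <- sample(0:4, 6, replace = TRUE)
    if (max(v) - min(v) < 1) next
    tv <- traj(v)
    pct_var <- 100 * mean(diff(v) != 0)
    expect_lte(intravariation_index(tv), pct_var + 1e-12)
  }
})

test_that("randomised series agree with the brute-force oracles under record pairing", {
  set.seed(79)
  for (r in 1:60) {
    n <- sample(0:10, 1)
    v <- sample(0:4, n, replace = TRUE)
    # random gaps: oracle is record-adjacent, so use record mode
    gaps <- cumsum(sample(1:3, n, replace = TRUE))
    tv <- traj(v, dates = as.Date("2016-05-04") + gaps)
    expect_equal(intravariation_index(tv, mode = "record"), oracle_ivi(v))
    expect_equal(pct_zero_values(tv), oracle_pct_zero(v))
    expect_equal(coefficient_of_variation(tv), oracle_cv(v))
    expect_equal(pct_changes_in_trend(tv, mode = "record"), oracle_trend(v))
  }
})

test_that("trajectory_quality bundles the standalone indices and degenerate cases", {
  q <- trajectory_quality(traj(numeric(0)))
  expect_equal(q$T, 0L)
  expect_true(all(is.na(c(q$ivi, q$pct_zero, q$cv, q$pct_trend_change, q$rVAR))))

  q0 <- trajectory_quality(traj(c(0, 0, 0, 0)))
  expect_equal(q0$ivi, 0)
  expect_equal(q0$pct_zero, 100)
  expect_true(is.na(q0$cv))
  expect_equal(q0$pct_trend_change, 0)

  set.seed(80)
  v <- sample(0:4, 8, replace = TRUE)
  tv <- traj(v)
  q1 <- trajectory_quality(tv)
  expect_equal(q1$ivi, intravariation_index(tv))
  expect_equal(q1$pct_zero, pct_zero_values(tv))
  expect_equal(q1$cv, coefficient_of_variation(tv))
  expect_equal(q1$pct_trend_change, pct_changes_in_trend(tv))
  expect_equal(q1$n_pairs, nrow(consecutive_pairs(tv)))
  expect_equal(q1$S, 1)
})

test_that("cohort index table covers every patient x score", {
  sim <- small_sim(n_patients = 6L, seed = 3L)
  idx <- cohort_quality_indices(sim$cohort)
  expect_equal(nrow(idx), 6L * 3L)
  expect_setequal(unique(idx$score_name), SCORE_NAMES)
  defined <- !is.na(idx$pct_zero)
  expect_true(all(idx$pct_zero[defined] >= 0 & idx$pct_zero[defined] <= 100))
})
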