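test_that("config validation catches bad probabilities and thresholds", {
  expect_error(synthetic_config(n_patients = 1), ">= 2")
  expect_error(synthetic_config(carry_q = 1.2), "probabilities")
  expect_error(synthetic_config(symptom_thresholds = c(1, 0.5, 2)),
               "increasing")
  cfg <- synthetic_config()
  expect_equal(cfg$n_patients, 101L)
  expect_equal(cfg$window$prescribed_days, 56L)
})

test_that("pollen series is bounded, unimodal in expectation, and seed-stable", {
  cfg <- synthetic_config(seed = 123L)
  set.seed(1)
  p1 <- generate_pollen_series(cfg)
  expect_equal(nrow(p1), 56L)
  expect_true(all(p1$pollen >= 0 & p1$pollen <= cfg$pollen_max))
  set.seed(1)
  p2 <- generate_pollen_series(cfg)
  expect_identical(p1, p2)

  zero <- synthetic_config(pollen_max = 0)
  set.seed(1)
  expect_true(all(generate_pollen_series(zero)$pollen == 0))
})

test_that("generated cohorts are reproducible from the seed, byte for byte", {
  cfg <- synthetic_config(n_patients = 6L, seed = 2024L)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_diary_table(generate_cohort(cfg)$cohort, f1)
  write_diary_table(generate_cohort(cfg)$cohort, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("generated data satisfy the diary invariants and minimal cohorts work", {
  sim <- small_sim(n_patients = 12L, seed = 8L)
  expect_equal(length(sim$cohort), 12L)
  for (p in sim$cohort$patients) {
    g <- as.matrix(p$days[DIARY_SYMPTOMS])
    expect_true(all(g %in% 0:3))
    expect_true(all(as.matrix(p$days[DIARY_MEDS]) %in% 0:1))
    expect_true(all(p$days$vas %in% 0:10))
    expect_false(is.unsorted(p$days$date, strictly = TRUE))
    expect_gte(n_recorded(p), 1L)
  }
  expect_setequal(sim$truth$behavior, intersect(unique(sim$truth$behavior),
                                                c("accurate", "carry_forward")))
  tiny <- generate_cohort(synthetic_config(n_patients = 2L, seed = 1L))
  expect_equal(length(tiny$cohort), 2L)
})

test_that("a null patient (zero sensitivity, zero noise) records all zeros", {
  cfg <- synthetic_config(sensitivity_meanlog = -30, sensitivity_sdlog = 0,
                          burden_noise_sd = 0,
                          symptom_noise_sd = 0, vas_noise_sd = 0,
                          med_intercepts = c(antihistamine = -Inf,
                                             nasal_steroid = -Inf,
                                             systemic_steroid = -Inf),
                          n_patients = 2L, seed = 5L)
  sim <- generate_cohort(cfg)
  p <- sim$cohort$patients[[1L]]
  tr <- build_trajectory(p, "RTSS")
  expect_true(all(tr$values == 0))
  expect_equal(pct_zero_values(tr), 100)
  expect_true(all(p$days$vas == 0))
})

test_that("a forced carry-forward responder (q = 1) shows no trend changes", {
  cfg <- synthetic_config(n_patients = 4L, seed = 9L, carry_q = 1,
                          carry_frac = 1, link_behavior_to_adherence = FALSE,
                          delayed_start_prob = 0, early_end_prob = 0)
  sim <- generate_cohort(cfg)
  expect_true(all(sim$truth$behavior == "carry_forward"))
  for (p in sim$cohort$patients) {
    tr <- build_trajectory(p, "RTSS")
    q <- trajectory_quality(tr, mode = "record")
    if (!is.na(q$pct_trend_change)) expect_equal(q$pct_trend_change, 0)
    expect_equal(length(unique(tr$values)), 1L)  # every entry is a copy
  }
})

test_that("full recording probability with no deviations gives 100% adherence", {
  cfg <- synthetic_config(n_patients = 3L, seed = 10L,
                          adherence_beta_high = c(1e9, 1e-9),
                          adherence_beta_low = c(1e9, 1e-9),
                          delayed_start_prob = 0, early_end_prob = 0)
  sim <- generate_cohort(cfg)
  adh <- cohort_adherence(sim$cohort)
  expect_true(all(adh$adherence_pct == 100))
})

test_that("linking behaviour to adherence raises carry-forward prevalence in the low class", {
  sim <- generate_cohort(synthetic_config(n_patients = 150L, seed = 77L))
  tab <- table(sim$truth$adherence_class, sim$truth$behavior)
  frac <- function(cls) {
    tab[cls, "carry_forward"] / sum(tab[cls, ])
  }
  expect_gt(frac("low"), frac("high"))
})

test_that("the manifest records seed and config for reproducibility", {
  sim <- small_sim(n_patients = 3L, seed = 314L)
  expect_equal(sim$manifest$seed, 314L)
  expect_equal(sim$manifest$n_patients, 3L)
  expect_equal(sim$manifest$window$prescribed_days, 56L)
  d <- withr::local_tempdir()
  paths <- write_simulation(sim, d)
  expect_true(all(file.exists(paths)))
  m <- jsonlite::read_json(paths[["manifest"]])
  expect_equal(m$seed, 314L)
})
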