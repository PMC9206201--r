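# Builders used across the suite. Fixtures are constructed in code; no
# binary data.

day_row <- function(sneezing = 0, rhinorrhea = 0, nasal_pruritus = 0,
                    nasal_congestion = 0, itchy_eyes = 0, watery_eyes = 0,
                    antihistamine = 0, nasal_steroid = 0,
                    systemic_steroid = 0, vas = 0, date = "2016-05-04") {
  data.frame(date = as.Date(date), sneezing = sneezing,
             rhinorrhea = rhinorrhea, nasal_pruritus = nasal_pruritus,
             nasal_congestion = nasal_congestion, itchy_eyes = itchy_eyes,
             watery_eyes = watery_eyes, antihistamine = antihistamine,
             nasal_steroid = nasal_steroid,
             systemic_steroid = systemic_steroid, vas = vas,
             stringsAsFactors = FALSE)
}

# n all-zero diary days on consecutive dates
zero_days <- function(n, start = "2016-05-04") {
  if (n == 0L) return(day_row()[0L, ])
  do.call(rbind, lapply(seq_len(n) - 1L,
                        function(k) day_row(date = as.Date(start) + k)))
}

test_window <- function(start = "2016-05-04", end = "2016-06-28") {
  monitoring_window(start, end)
}

# Trajectory on consecutive dates (calendar mode == record mode)
traj <- function(values, score = "RTSS", dates = NULL,
                 S = unit_step(score)) {
  if (is.null(dates)) {
    dates <- as.Date("2016-05-04") + seq_along(values) - 1L
  }
  score_trajectory("PX", score, dates, values, S)
}

small_sim <- function(n_patients = 5L, seed = 11L, ...) {
  generate_cohort(synthetic_config(n_patients = n_patients, seed = seed, ...))
}
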