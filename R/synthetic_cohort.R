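# Synthetic diary-cohort generator. Emulates a ~100-patient pollen-season
# monitoring campaign: a unimodal noisy exposure curve, ordinal symptom
# grades driven by latent exposure x sensitivity, medication uptake rising
# with symptom burden (with persistence), per-patient Bernoulli recording
# with optional delayed start / early stop, and a carry-forward
# ("insufficient effort") responding style that copies the previous
# recorded questionnaire wholesale. Ground-truth behaviour labels are
# returned so recovery of the adherence/quality association can be tested.

#' Configuration of the synthetic diary cohort
#'
#' Defaults state the emulated study world: 101 patients monitored daily
#' over the 56-day peak grass pollen season (2016-05-04 to 2016-06-28),
#' grass pollen concentrations peaking below 199 grains/m3, roughly 65% of
#' patients in the highly adherent class, and carry-forward responding
#' concentrated among low-adherence patients (prevalence 0.7 vs 0.1) with
#' per-day repetition probability 0.8 when behaviour is linked to
#' adherence.
#'
#' @param n_patients Number of patients (>= 2).
#' @param window_start,window_end Prescribed monitoring window (inclusive).
#' @param pollen_peak_day Day index (1-based) of the seasonal peak.
#' @param pollen_width Gaussian width of the seasonal curve, days.
#' @param pollen_max Maximum pollen concentration, grains/m3.
#' @param pollen_noise_sd SD of the multiplicative log-normal day-to-day
#'   pollen noise.
#' @param sensitivity_meanlog,sensitivity_sdlog Log-normal parameters of
#'   the per-patient sensitivity.
#' @param burden_noise_sd SD of the shared daily noise on the latent
#'   symptom burden.
#' @param symptom_thresholds Increasing cutpoints mapping latent burden to
#'   grades 1, 2, 3.
#' @param symptom_noise_sd SD of the per-item noise added before
#'   thresholding.
#' @param med_intercepts Named logistic intercepts for the three
#'   medication classes (more negative = rarer).
#' @param med_slope Logistic slope on the latent burden.
#' @param med_persistence Logit bonus when the same drug was taken the
#'   previous day.
#' @param vas_scale Saturation rate of the monotone burden -> VAS map.
#' @param vas_noise_sd SD of the VAS reporting noise (before rounding).
#' @param frac_high_adherence Probability of the highly adherent latent
#'   class.
#' @param adherence_beta_high,adherence_beta_low Beta(a, b) parameters of
#'   the daily recording probability in the two classes.
#' @param delayed_start_prob,early_end_prob Probability of a >= 3-day
#'   delayed start / early stop.
#' @param deviation_extra_mean Poisson mean of deviation days beyond 3.
#' @param carry_frac Carry-forward prevalence when behaviour is not linked
#'   to adherence.
#' @param carry_frac_low,carry_frac_high Carry-forward prevalence in the
#'   low/high latent adherence class when linked.
#' @param carry_q Per-day probability that a carry-forward responder copies
#'   the previous recorded questionnaire.
#' @param link_behavior_to_adherence Couple responding style to the latent
#'   adherence class.
#' @param seed Integer seed; all randomness flows through one generator.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 101L,
                             window_start = "2016-05-04",
                             window_end = "2016-06-28",
                             pollen_peak_day = 28,
                             pollen_width = 12,
                             pollen_max = 199,
                             pollen_noise_sd = 0.35,
                             sensitivity_meanlog = 0,
                             sensitivity_sdlog = 0.5,
                             burden_noise_sd = 0.15,
                             symptom_thresholds = c(0.25, 0.55, 0.85),
                             symptom_noise_sd = 0.3,
                             med_intercepts = c(antihistamine = -2.5,
                                                nasal_steroid = -3.5,
                                                systemic_steroid = -6),
                             med_slope = 3,
                             med_persistence = 1.5,
                             vas_scale = 1.1,
                             vas_noise_sd = 1,
                             frac_high_adherence = 0.65,
                             adherence_beta_high = c(28, 2),
                             adherence_beta_low = c(8, 5),
                             delayed_start_prob = 0.09,
                             early_end_prob = 0.12,
                             deviation_extra_mean = 2,
                             carry_frac = 0.3,
                             carry_frac_low = 0.7,
                             carry_frac_high = 0.1,
                             carry_q = 0.8,
                             link_behavior_to_adherence = TRUE,
                             seed = 20160504L) {
  cfg <- as.list(environment())
  cfg$n_patients <- as.integer(cfg$n_patients)
  if (cfg$n_patients < 2L) stop("n_patients must be >= 2", call. = FALSE)
  if (cfg$pollen_max < 0) stop("pollen_max must be >= 0", call. = FALSE)
  probs <- c(frac_high_adherence, delayed_start_prob, early_end_prob,
             carry_frac, carry_frac_low, carry_frac_high, carry_q)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(diff(symptom_thresholds) <= 0) || length(symptom_thresholds) != 3L) {
    stop("symptom_thresholds must be 3 increasing cutpoints", call. = FALSE)
  }
  cfg$window <- monitoring_window(window_start, window_end)
  structure(cfg, class = "synthetic_config")
}

#' Daily pollen exposure series
#'
#' A scaled Gaussian seasonal kernel with multiplicative log-normal
#' day-to-day noise, capped at `pollen_max` so the stated concentration
#' bound holds. Uses the current RNG state; seed via [set.seed()] or use
#' [generate_cohort()], which seeds once from the config.
#'
#' @param config A [synthetic_config()].
#' @return Data frame with columns `date`, `pollen` (grains/m3), one row
#'   per prescribed day.
#' @export
generate_pollen_series <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$window$prescribed_days
  d <- seq_len(n)
  base <- config$pollen_max *
    exp(-0.5 * ((d - config$pollen_peak_day) / config$pollen_width)^2)
  noise <- exp(stats::rnorm(n, 0, config$pollen_noise_sd))
  data.frame(
    date = seq(config$window$start, by = "day", length.out = n),
    pollen = pmin(base * noise, config$pollen_max)
  )
}

#' Generate one synthetic patient
#'
#' Draws the patient's accurate (pre-behaviour) daily questionnaire over
#' the full window from the latent burden model, then applies the
#' recording process (Bernoulli daily recording, optional delayed start /
#' early stop) and, for carry-forward responders, per-day copying of the
#' previous recorded questionnaire. Uses the current RNG state;
#' [generate_cohort()] seeds once for the whole cohort.
#'
#' @param config A [synthetic_config()].
#' @param pollen Pollen series from [generate_pollen_series()] covering
#'   the window.
#' @param patient_id Identifier for the generated patient.
#' @return List with `series` (a [patient_series()]) and `truth` (one-row
#'   ground-truth data frame).
#' @export
generate_patient <- function(config, pollen, patient_id) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- nrow(pollen)
  w <- config$window

  sens <- stats::rlnorm(1, config$sensitivity_meanlog, config$sensitivity_sdlog)
  high_class <- stats::runif(1) < config$frac_high_adherence
  ab <- if (high_class) config$adherence_beta_high else config$adherence_beta_low
  p_rec <- stats::rbeta(1, ab[1L], ab[2L])
  carry_p <- if (config$link_behavior_to_adherence) {
    if (high_class) config$carry_frac_high else config$carry_frac_low
  } else {
    config$carry_frac
  }
  behavior <- if (stats::runif(1) < carry_p) "carry_forward" else "accurate"

  rel <- if (config$pollen_max > 0) pollen$pollen / config$pollen_max else 0
  burden <- sens * rel + stats::rnorm(n, 0, config$burden_noise_sd)

  grades <- vapply(DIARY_SYMPTOMS, function(sym) {
    x <- burden + stats::rnorm(n, 0, config$symptom_noise_sd)
    findInterval(x, config$symptom_thresholds)
  }, integer(n))
  if (n == 1L) grades <- matrix(grades, nrow = 1L,
                                dimnames = list(NULL, DIARY_SYMPTOMS))

  meds <- matrix(0L, n, length(DIARY_MEDS),
                 dimnames = list(NULL, DIARY_MEDS))
  prev <- stats::setNames(rep(0L, length(DIARY_MEDS)), DIARY_MEDS)
  for (d in seq_len(n)) {
    for (m in DIARY_MEDS) {
      z <- config$med_intercepts[[m]] + config$med_slope * burden[d] +
        config$med_persistence * prev[[m]]
      meds[d, m] <- as.integer(stats::runif(1) < stats::plogis(z))
    }
    prev <- meds[d, ]
  }

  vas_raw <- 10 * (1 - exp(-config$vas_scale * pmax(burden, 0))) +
    stats::rnorm(n, 0, config$vas_noise_sd)
  vas <- pmin(10L, pmax(0L, as.integer(round(vas_raw))))

  recorded <- stats::runif(n) < p_rec
  delay <- if (stats::runif(1) < config$delayed_start_prob) {
    3L + stats::rpois(1, config$deviation_extra_mean)
  } else 0L
  early <- if (stats::runif(1) < config$early_end_prob) {
    3L + stats::rpois(1, config$deviation_extra_mean)
  } else 0L
  if (delay > 0L) recorded[seq_len(min(delay, n))] <- FALSE
  if (early > 0L) recorded[seq.int(max(1L, n - early + 1L), n)] <- FALSE
  if (!any(recorded)) recorded[sample.int(n, 1L)] <- TRUE

  days <- data.frame(date = pollen$date, grades, meds, vas = vas,
                     stringsAsFactors = FALSE)
  idx <- which(recorded)
  # carry-forward responders copy the previous *recorded* questionnaire
  # wholesale with probability q (chains of copies allowed)
  if (behavior == "carry_forward" && length(idx) > 1L) {
    for (k in 2L:length(idx)) {
      if (stats::runif(1) < config$carry_q) {
        days[idx[k], DIARY_ITEMS] <- days[idx[k - 1L], DIARY_ITEMS]
      }
    }
  }
  days <- days[idx, , drop = FALSE]

  list(
    series = patient_series(patient_id, w, days),
    truth = data.frame(
      patient_id = patient_id,
      behavior = behavior,
      p_record = p_rec,
      sensitivity = sens,
      adherence_class = if (high_class) "high" else "low",
      delayed_start_days = delay,
      early_end_days = early,
      stringsAsFactors = FALSE
    )
  )
}

#' Generate a synthetic diary cohort
#'
#' Seeds the RNG from `config$seed` and draws the pollen season and every
#' patient, so the result (and any file written from it) is reproducible
#' from the config alone.
#'
#' @param config A [synthetic_config()].
#' @return List with `cohort` (a [diary_cohort()]), `truth` (per-patient
#'   ground-truth data frame: behaviour label, recording probability,
#'   sensitivity, latent adherence class, deviations), `pollen` (the
#'   exposure series) and `manifest` (seed, config echo, package version).
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  pollen <- generate_pollen_series(config)
  ids <- sprintf("P%03d", seq_len(config$n_patients))
  drawn <- lapply(ids, function(id) generate_patient(config, pollen, id))
  cohort <- diary_cohort(lapply(drawn, `[[`, "series"))
  truth <- do.call(rbind, c(lapply(drawn, `[[`, "truth"),
                            make.row.names = FALSE))
  cfg_plain <- unclass(config)
  cfg_plain$window <- NULL
  manifest <- list(
    generator = "rhinodiary::generate_cohort",
    package_version = as.character(utils::packageVersion("rhinodiary")),
    seed = config$seed,
    n_patients = config$n_patients,
    window = list(start = format(config$window$start),
                  end = format(config$window$end),
                  prescribed_days = config$window$prescribed_days),
    config = cfg_plain
  )
  list(cohort = cohort, truth = truth, pollen = pollen, manifest = manifest)
}

#' Write a simulated cohort to disk
#'
#' Emits the diary table, the per-patient window table, the ground-truth
#' table, the pollen series and a JSON manifest into `dir`.
#'
#' @param sim Result of [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @return Named character vector of the files written, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    diary = file.path(dir, "diary.csv"),
    windows = file.path(dir, "windows.csv"),
    truth = file.path(dir, "ground_truth.csv"),
    pollen = file.path(dir, "pollen.csv"),
    manifest = file.path(dir, "manifest.json")
  )
  write_diary_table(sim$cohort, paths[["diary"]])
  write_window_table(sim$cohort, paths[["windows"]])
  utils::write.csv(sim$truth, paths[["truth"]], row.names = FALSE)
  utils::write.csv(sim$pollen, paths[["pollen"]], row.names = FALSE)
  jsonlite::write_json(sim$manifest, paths[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(paths)
}
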