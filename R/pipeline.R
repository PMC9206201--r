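# Pipeline orchestration: read -> score -> adherence -> indices -> cohort
# analysis, with a JSON run log, plus the command-line entry point.

#' Analysis configuration
#'
#' The tunable choices of the pipeline, with defaults reproducing the
#' reference analysis: 80% adherence threshold (inclusive), calendar-day
#' pairing, Methods-form rVAR, sign-transition trend mode.
#'
#' @param adherence_threshold High/low adherence split in percent.
#' @param pairing `"calendar"` or `"record"` consecutive-pair mode.
#' @param rvar_plus_one Use the `(max - min + S)/S` range variant.
#' @param trend_mode `"sign_transition"` or `"nonzero_diff"`.
#' @param med_weights Medication weights for the CSMS, see
#'   [DEFAULT_MED_WEIGHTS].
#' @param flag_days Start/end deviation flag threshold in days.
#' @param partial Partial-row policy of [read_diary_table()].
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(adherence_threshold = 80,
                            pairing = c("calendar", "record"),
                            rvar_plus_one = FALSE,
                            trend_mode = c("sign_transition", "nonzero_diff"),
                            med_weights = DEFAULT_MED_WEIGHTS,
                            flag_days = 3L,
                            partial = c("error", "drop")) {
  if (!is.numeric(adherence_threshold) || adherence_threshold <= 0 ||
      adherence_threshold > 100) {
    stop("adherence_threshold must lie in (0, 100]", call. = FALSE)
  }
  structure(
    list(
      adherence_threshold = adherence_threshold,
      pairing = match.arg(pairing),
      rvar_plus_one = isTRUE(rvar_plus_one),
      trend_mode = match.arg(trend_mode),
      med_weights = med_weights,
      flag_days = as.integer(flag_days),
      partial = match.arg(partial)
    ),
    class = "analysis_config"
  )
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full diary analysis pipeline
#'
#' Reads the diary table, computes daily scores, adherence, the four
#' quality indices, cohort summaries, the adherence-group comparison, the
#' score correlations and the population trajectories, and writes every
#' table plus a JSON run log (config echo, exclusion counts, software
#' version) to `out_dir`. Any stage error aborts with the stage name.
#'
#' @param diary_path Path to the diary table.
#' @param out_dir Output directory (created if absent).
#' @param window Optional global [monitoring_window()].
#' @param windows Optional per-patient window table or file path.
#' @param config An [analysis_config()].
#' @return Invisibly, a list with all computed tables and the output file
#'   paths.
#' @export
run_pipeline <- function(diary_path, out_dir, window = NULL, windows = NULL,
                         config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  cohort <- with_stage("read", {
    read_diary_table(diary_path, window = window, windows = windows,
                     partial = config$partial)
  })
  scores <- with_stage("score", score_table(cohort, config$med_weights))
  adh <- with_stage("adherence", {
    cohort_adherence(cohort, config$adherence_threshold, config$flag_days)
  })
  idx <- with_stage("indices", {
    cohort_quality_indices(cohort, mode = config$pairing,
                           rvar_plus_one = config$rvar_plus_one,
                           trend_mode = config$trend_mode,
                           med_weights = config$med_weights)
  })
  table2 <- with_stage("summarize", summarize_indices(idx))
  table3 <- with_stage("compare", {
    compare_by_adherence(idx, adh, config$adherence_threshold)
  })
  correlations <- with_stage("correlations", {
    score_correlations(cohort, config$med_weights)
  })
  pop <- with_stage("population_trajectory", {
    do.call(rbind, c(lapply(SCORE_NAMES, function(sc) {
      cbind(score_name = sc,
            population_trajectory(cohort, sc, config$med_weights))
    }), make.row.names = FALSE))
  })

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- c(
    scores = file.path(out_dir, "scores.csv"),
    adherence = file.path(out_dir, "adherence.csv"),
    indices = file.path(out_dir, "indices.csv"),
    table2 = file.path(out_dir, "table2.csv"),
    table3 = file.path(out_dir, "table3.csv"),
    correlations = file.path(out_dir, "correlations.csv"),
    population_trajectory = file.path(out_dir, "population_trajectory.csv"),
    run_log = file.path(out_dir, "run_log.json")
  )
  utils::write.csv(scores, paths[["scores"]], row.names = FALSE)
  utils::write.csv(adh, paths[["adherence"]], row.names = FALSE)
  utils::write.csv(idx, paths[["indices"]], row.names = FALSE)
  utils::write.csv(table2, paths[["table2"]], row.names = FALSE)
  utils::write.csv(table3, paths[["table3"]], row.names = FALSE)
  utils::write.csv(correlations, paths[["correlations"]], row.names = FALSE)
  utils::write.csv(pop, paths[["population_trajectory"]], row.names = FALSE)

  run_log <- list(
    package_version = as.character(utils::packageVersion("rhinodiary")),
    diary_path = diary_path,
    config = unclass(config),
    n_patients = length(cohort),
    n_reports = nrow(scores),
    pooled_adherence_pct = pooled_adherence(adh),
    mean_individual_adherence_pct = mean_individual_adherence(adh),
    n_high = sum(adh$adherence_pct >= config$adherence_threshold),
    n_low = sum(adh$adherence_pct < config$adherence_threshold),
    out_of_window_records = sum(adh$excluded_out_of_window),
    undefined_index_values = as.list(attr(table2, "n_excluded"))
  )
  jsonlite::write_json(run_log, paths[["run_log"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(cohort = cohort, scores = scores, adherence = adh,
                 indices = idx, table2 = table2, table3 = table3,
                 correlations = correlations, population_trajectory = pop,
                 paths = paths))
}

cli_common_opts <- function() {
  list(
    optparse::make_option("--diary", type = "character", default = NULL,
                          help = "Path to the diary table"),
    optparse::make_option("--windows", type = "character", default = NULL,
                          help = "Per-patient window table (patient_id,start,end)"),
    optparse::make_option("--start", type = "character", default = NULL,
                          help = "Global window start (YYYY-MM-DD)"),
    optparse::make_option("--end", type = "character", default = NULL,
                          help = "Global window end (YYYY-MM-DD)"),
    optparse::make_option("--out", type = "character", default = "results",
                          help = "Output directory [default %default]"),
    optparse::make_option("--threshold", type = "double", default = 80,
                          help = "Adherence threshold in percent [default %default]"),
    optparse::make_option("--pairing", type = "character",
                          default = "calendar",
                          help = "Pair mode: calendar|record [default %default]"),
    optparse::make_option("--trend-mode", dest = "trend_mode",
                          type = "character", default = "sign_transition",
                          help = "sign_transition|nonzero_diff [default %default]"),
    optparse::make_option("--rvar-plus-one", dest = "rvar_plus_one",
                          action = "store_true", default = FALSE,
                          help = "Use the (max-min+S)/S range variant")
  )
}

cli_config <- function(opt) {
  analysis_config(adherence_threshold = opt$threshold,
                  pairing = opt$pairing,
                  rvar_plus_one = opt$rvar_plus_one,
                  trend_mode = opt$trend_mode)
}

cli_window <- function(opt) {
  if (!is.null(opt$start) && !is.null(opt$end)) {
    monitoring_window(opt$start, opt$end)
  } else {
    NULL
  }
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic cohort), `run` (full
#' pipeline), and the stage shortcuts `score`, `adherence`, `indices`,
#' `compare`, `report` (all run the pipeline; they are synonyms kept for
#' scripting convenience since every stage's table is cheap to emit).
#' Invoke as e.g.
#' `Rscript -e 'rhinodiary::rhinodiary_cli()' simulate --out sim --seed 1`.
#'
#' @param args Character vector of command-line arguments; defaults to
#'   [commandArgs()] trailing arguments.
#' @return Invisibly, the result of the dispatched command.
#' @export
rhinodiary_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message("usage: rhinodiary <simulate|run|score|adherence|indices|",
            "compare|report> [options]")
    return(invisible(NULL))
  }
  cmd <- args[[1L]]
  rest <- args[-1L]
  if (cmd == "simulate") {
    opts <- list(
      optparse::make_option("--out", type = "character", default = "sim",
                            help = "Output directory [default %default]"),
      optparse::make_option("--seed", type = "integer", default = 20160504L,
                            help = "RNG seed [default %default]"),
      optparse::make_option("--n-patients", dest = "n_patients",
                            type = "integer", default = 101L,
                            help = "Cohort size [default %default]"),
      optparse::make_option("--unlinked", action = "store_true",
                            default = FALSE,
                            help = "Decouple responding style from adherence")
    )
    opt <- optparse::parse_args(optparse::OptionParser(option_list = opts),
                                args = rest)
    cfg <- synthetic_config(n_patients = opt$n_patients, seed = opt$seed,
                            link_behavior_to_adherence = !opt$unlinked)
    sim <- generate_cohort(cfg)
    paths <- write_simulation(sim, opt$out)
    message("wrote ", length(paths), " file(s) to ", opt$out)
    return(invisible(sim))
  }
  if (cmd %in% c("run", "score", "adherence", "indices", "compare",
                 "report")) {
    opt <- optparse::parse_args(
      optparse::OptionParser(option_list = cli_common_opts()), args = rest
    )
    if (is.null(opt$diary)) stop("--diary is required", call. = FALSE)
    res <- run_pipeline(opt$diary, opt$out, window = cli_window(opt),
                        windows = opt$windows, config = cli_config(opt))
    message("pipeline complete; outputs in ", opt$out)
    return(invisible(res))
  }
  stop("unknown subcommand: ", cmd, call. = FALSE)
}
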