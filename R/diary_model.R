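# Column layout of the on-disk diary table. Order is part of the file
# contract; readers reject files whose header deviates from it.

#' Diary item columns
#'
#' Column names of the item-level diary table: six ordinal symptom items
#' (four nasal, two ocular; each graded 0 = none, 1 = mild, 2 = moderate,
#' 3 = severe), three binary medication-intake flags, and a 0-10 visual
#' analogue scale answering "How do you feel in relation to your allergic
#' symptoms today?".
#'
#' @format Character vectors.
#' @name diary-columns
NULL

#' @rdname diary-columns
#' @export
DIARY_SYMPTOMS <- c(
  "sneezing", "rhinorrhea", "nasal_pruritus", "nasal_congestion",
  "itchy_eyes", "watery_eyes"
)

#' @rdname diary-columns
#' @export
DIARY_MEDS <- c("antihistamine", "nasal_steroid", "systemic_steroid")

#' @rdname diary-columns
#' @export
DIARY_COLUMNS <- c("patient_id", "date", DIARY_SYMPTOMS, DIARY_MEDS, "vas")

DIARY_ITEMS <- c(DIARY_SYMPTOMS, DIARY_MEDS, "vas")

#' Prescribed monitoring window
#'
#' A per-patient (or cohort-wide) date range over which daily diary
#' recording is prescribed. Endpoints are inclusive, so a window of
#' 2016-05-04 to 2016-06-28 prescribes 56 daily entries.
#'
#' @param start,end Window endpoints, coercible with [as.Date()].
#' @return An object of class `monitoring_window` with fields `start`,
#'   `end` and `prescribed_days` (inclusive day count).
#' @examples
#' w <- monitoring_window("2016-05-04", "2016-06-28")
#' w$prescribed_days  # 56
#' @export
monitoring_window <- function(start, end) {
  start <- as.Date(start)
  end <- as.Date(end)
  if (is.na(start) || is.na(end)) {
    stop("monitoring window endpoints must be valid dates", call. = FALSE)
  }
  if (start > end) {
    stop("monitoring window start (", format(start), ") is after end (",
         format(end), ")", call. = FALSE)
  }
  structure(
    list(
      start = start,
      end = end,
      prescribed_days = as.integer(end - start) + 1L
    ),
    class = "monitoring_window"
  )
}

#' @export
print.monitoring_window <- function(x, ...) {
  cat(sprintf("<monitoring_window %s .. %s (%d days)>\n",
              format(x$start), format(x$end), x$prescribed_days))
  invisible(x)
}

#' One patient's diary series
#'
#' Bundles a patient identifier, the prescribed [monitoring_window()] and
#' the recorded item-level days (a data frame with a `date` column plus the
#' item columns of [DIARY_COLUMNS]). Days are stored sorted by date;
#' duplicate dates are an error. A missing day is simply an absent row.
#'
#' @param patient_id Scalar identifier (coerced to character).
#' @param window A `monitoring_window`.
#' @param days Data frame of recorded days; may have zero rows.
#' @return An object of class `patient_series`.
#' @export
patient_series <- function(patient_id, window, days) {
  stopifnot(inherits(window, "monitoring_window"))
  patient_id <- as.character(patient_id)
  if (length(patient_id) != 1L || is.na(patient_id) || !nzchar(patient_id)) {
    stop("patient_id must be a single non-empty string", call. = FALSE)
  }
  need <- c("date", DIARY_ITEMS)
  missing_cols <- setdiff(need, names(days))
  if (length(missing_cols)) {
    stop("patient ", patient_id, ": days is missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  days <- days[need]
  days$date <- as.Date(days$date)
  if (nrow(days)) {
    days <- days[order(days$date), , drop = FALSE]
    if (anyDuplicated(days$date)) {
      dup <- days$date[duplicated(days$date)][1L]
      stop("patient ", patient_id, ": duplicate diary entry for ",
           format(dup), call. = FALSE)
    }
    check_diary_values(days, context = paste0("patient ", patient_id))
  }
  rownames(days) <- NULL
  structure(
    list(patient_id = patient_id, window = window, days = days),
    class = "patient_series"
  )
}

#' @export
print.patient_series <- function(x, ...) {
  cat(sprintf("<patient_series %s: %d recorded day(s), window %s .. %s>\n",
              x$patient_id, nrow(x$days), format(x$window$start),
              format(x$window$end)))
  invisible(x)
}

#' Number of recorded days in a series
#' @param series A [patient_series()].
#' @return Integer count of recorded rows.
#' @export
n_recorded <- function(series) {
  stopifnot(inherits(series, "patient_series"))
  nrow(series$days)
}

#' Diary cohort container
#'
#' A named list of [patient_series()] objects, one per patient.
#'
#' @param patients List of `patient_series`; names are taken from the
#'   contained patient ids.
#' @return An object of class `diary_cohort`.
#' @export
diary_cohort <- function(patients = list()) {
  ok <- vapply(patients, inherits, logical(1), what = "patient_series")
  if (length(patients) && !all(ok)) {
    stop("all cohort elements must be patient_series objects", call. = FALSE)
  }
  ids <- vapply(patients, function(p) p$patient_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate patient_id in cohort: ", ids[duplicated(ids)][1L],
         call. = FALSE)
  }
  names(patients) <- ids
  structure(list(patients = patients), class = "diary_cohort")
}

#' @export
length.diary_cohort <- function(x) length(x$patients)

#' @export
print.diary_cohort <- function(x, ...) {
  n_days <- sum(vapply(x$patients, n_recorded, integer(1)))
  cat(sprintf("<diary_cohort: %d patient(s), %d recorded day(s)>\n",
              length(x$patients), n_days))
  invisible(x)
}

#' Patient identifiers of a cohort
#' @param cohort A [diary_cohort()].
#' @return Character vector of patient ids.
#' @export
cohort_ids <- function(cohort) {
  stopifnot(inherits(cohort, "diary_cohort"))
  names(cohort$patients)
}

# Validate item values on a diary day frame. `rows` gives the labels used
# in error messages (file line numbers when reading from disk); the first
# violation aborts, naming the row and the offending field. No clamping.
check_diary_values <- function(days, rows = seq_len(nrow(days)),
                               context = NULL) {
  ctx <- if (is.null(context)) "" else paste0(context, ", ")
  fail <- function(col, i, allowed) {
    stop(ctx, "row ", rows[i], ": field '", col, "' has value '",
         days[[col]][i], "' outside ", allowed, call. = FALSE)
  }
  check_int_range <- function(col, lo, hi) {
    x <- days[[col]]
    if (!is.numeric(x)) x <- suppressWarnings(as.numeric(as.character(x)))
    bad <- is.na(x) | x != as.integer(x) | x < lo | x > hi
    if (any(bad)) {
      fail(col, which(bad)[1L], sprintf("{%d,...,%d}", lo, hi))
    }
    invisible(NULL)
  }
  for (col in DIARY_SYMPTOMS) check_int_range(col, 0L, 3L)
  for (col in DIARY_MEDS) check_int_range(col, 0L, 1L)
  check_int_range("vas", 0L, 10L)
  invisible(days)
}

# Resolve the window specification for read_diary_table(): either a single
# monitoring_window applied to everyone, a data frame / file with columns
# patient_id,start,end, or NULL (an error once patients are known).
resolve_windows <- function(window, windows, ids) {
  if (!is.null(window)) {
    stopifnot(inherits(window, "monitoring_window"))
    out <- lapply(ids, function(i) window)
    names(out) <- ids
    return(out)
  }
  if (is.null(windows)) {
    stop("either a global `window` or a per-patient `windows` table ",
         "must be supplied", call. = FALSE)
  }
  if (is.character(windows) && length(windows) == 1L) {
    if (!file.exists(windows)) {
      stop("window file not found: ", windows, call. = FALSE)
    }
    windows <- utils::read.csv(windows, stringsAsFactors = FALSE)
  }
  need <- c("patient_id", "start", "end")
  if (!all(need %in% names(windows))) {
    stop("windows table must have columns patient_id, start, end",
         call. = FALSE)
  }
  windows$patient_id <- as.character(windows$patient_id)
  if (anyDuplicated(windows$patient_id)) {
    stop("duplicate patient_id in windows table", call. = FALSE)
  }
  absent <- setdiff(ids, windows$patient_id)
  if (length(absent)) {
    stop("no monitoring window for patient(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  out <- lapply(ids, function(i) {
    r <- windows[windows$patient_id == i, ]
    monitoring_window(r$start, r$end)
  })
  names(out) <- ids
  out
}

#' Read an item-level diary table
#'
#' Reads a delimited diary table (columns exactly [DIARY_COLUMNS], dates
#' ISO-8601) into a [diary_cohort()]. Every row is validated against the
#' diary-day invariants; out-of-range grades, malformed dates and duplicate
#' (patient, date) pairs are errors naming the file row and field — values
#' are never silently clamped. The diary-capture app forced complete
#' questionnaires, so a partially blank row indicates corruption and is
#' rejected by default; `partial = "drop"` discards such rows with a
#' warning instead.
#'
#' @param path Path to the diary table.
#' @param window Optional [monitoring_window()] applied to every patient.
#' @param windows Optional per-patient window table (data frame or file
#'   path) with columns `patient_id,start,end`; exactly one of `window` /
#'   `windows` must be given.
#' @param sep Field separator (default comma).
#' @param partial `"error"` (default) or `"drop"` for rows with blank items.
#' @return A [diary_cohort()], rows sorted by date within patient.
#' @export
read_diary_table <- function(path, window = NULL, windows = NULL, sep = ",",
                             partial = c("error", "drop")) {
  partial <- match.arg(partial)
  if (!file.exists(path)) {
    stop("diary table not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                        check.names = FALSE)
  if (!identical(names(df), DIARY_COLUMNS)) {
    stop("diary table header must be exactly: ",
         paste(DIARY_COLUMNS, collapse = ","), call. = FALSE)
  }
  df$patient_id <- as.character(df$patient_id)
  file_row <- seq_len(nrow(df)) + 1L  # +1 for the header line

  incomplete <- !stats::complete.cases(df[DIARY_ITEMS]) |
    is.na(df$patient_id) | !nzchar(df$patient_id) | is.na(df$date)
  if (any(incomplete)) {
    if (partial == "error") {
      i <- which(incomplete)[1L]
      blank <- DIARY_ITEMS[is.na(unlist(df[i, DIARY_ITEMS]))][1L]
      if (is.na(blank)) blank <- "patient_id/date"
      stop("row ", file_row[i], ": incomplete record (field '", blank,
           "' is blank); the questionnaire is all-or-nothing", call. = FALSE)
    }
    warning(sum(incomplete), " incomplete row(s) dropped", call. = FALSE)
    df <- df[!incomplete, , drop = FALSE]
    file_row <- file_row[!incomplete]
  }

  dt <- as.Date(as.character(df$date), format = "%Y-%m-%d")
  bad_date <- is.na(dt)
  if (any(bad_date)) {
    i <- which(bad_date)[1L]
    stop("row ", file_row[i], ": field 'date' has unparseable value '",
         df$date[i], "' (expected YYYY-MM-DD)", call. = FALSE)
  }
  df$date <- dt

  check_diary_values(df, rows = file_row)

  key <- paste(df$patient_id, format(df$date))
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1L]
    stop("row ", file_row[i], ": duplicate entry for patient '",
         df$patient_id[i], "' on ", format(df$date[i]), call. = FALSE)
  }

  ids <- unique(df$patient_id)
  win <- resolve_windows(window, windows, ids)
  patients <- lapply(ids, function(i) {
    patient_series(i, win[[i]], df[df$patient_id == i, , drop = FALSE])
  })
  diary_cohort(patients)
}

#' Write a cohort back to the diary-table format
#'
#' Inverse of [read_diary_table()]: emits one row per recorded day with the
#' exact [DIARY_COLUMNS] header and ISO-8601 dates, so that reading the file
#' back (with the same windows) reproduces the cohort.
#'
#' @param cohort A [diary_cohort()].
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_diary_table <- function(cohort, path, sep = ",") {
  stopifnot(inherits(cohort, "diary_cohort"))
  rows <- lapply(cohort$patients, function(p) {
    if (!nrow(p$days)) return(NULL)
    cbind(
      data.frame(patient_id = p$patient_id, date = format(p$days$date),
                 stringsAsFactors = FALSE),
      p$days[DIARY_ITEMS]
    )
  })
  rows <- Filter(Negate(is.null), rows)
  rows <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE)) else NULL
  if (is.null(rows)) {
    rows <- as.data.frame(
      stats::setNames(rep(list(character(0)), length(DIARY_COLUMNS)),
                      DIARY_COLUMNS)
    )
  }
  utils::write.table(rows, path, sep = sep, row.names = FALSE,
                     col.names = TRUE, qmethod = "double")
  invisible(path)
}

#' Write the per-patient window table
#'
#' @param cohort A [diary_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_window_table <- function(cohort, path) {
  stopifnot(inherits(cohort, "diary_cohort"))
  df <- do.call(rbind, lapply(cohort$patients, function(p) {
    data.frame(patient_id = p$patient_id, start = format(p$window$start),
               end = format(p$window$end), stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
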