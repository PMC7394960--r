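# Reading vendor CSV exports into glucose traces, and writing summary / QC
# CSVs. The generic dialect (columns: participant_id, timestamp ISO-8601,
# glucose_mmol_per_L, event_kind) is the normative format; vendor layouts
# churn between firmware versions, so each vendor dialect is a documented,
# overridable column map with best-effort defaults.

#' Device CSV dialects
#'
#' A dialect names the columns and timestamp format of a CGM export so that
#' [read_cgm_file()] can parse it. Shipped defaults cover the Medtronic iPro2,
#' Abbott FreeStyle Libre and Dexcom G6 export layouts plus the generic
#' (`"other"`) format, which is: one header row and the columns
#' `participant_id`, `timestamp` (ISO-8601), `glucose_mmol_per_L`,
#' `event_kind` (empty, or one of meal / exercise / medication /
#' calibration). Any field can be overridden for local export variants,
#' including `decimal_mark = ","` for locales whose Libre exports use decimal
#' commas.
#'
#' @param name One of `"other"`, `"medtronic_ipro2"`, `"abbott_libre"`,
#'   `"dexcom_g6"`.
#' @param ... Overrides for the dialect fields (`timestamp_col`, `date_col`,
#'   `time_col`, `glucose_col`, `event_col`, `participant_col`,
#'   `timestamp_format`, `decimal_mark`, `units`).
#' @return A list of class `device_dialect`.
#' @export
#' @examples
#' device_dialect("abbott_libre", decimal_mark = ",")
device_dialect <- function(name = c("other", "medtronic_ipro2",
                                    "abbott_libre", "dexcom_g6"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    other = list(
      timestamp_col = "timestamp", date_col = NULL, time_col = NULL,
      glucose_col = "glucose_mmol_per_L", event_col = "event_kind",
      participant_col = "participant_id",
      timestamp_format = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                           "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M"),
      decimal_mark = ".", units = "mmol"
    ),
    medtronic_ipro2 = list(
      timestamp_col = NULL, date_col = "Date", time_col = "Time",
      glucose_col = "Sensor Glucose (mmol/L)", event_col = NULL,
      participant_col = NULL,
      timestamp_format = c("%d/%m/%y %H:%M:%S", "%d/%m/%Y %H:%M:%S",
                           "%d/%m/%Y %H:%M"),
      decimal_mark = ".", units = "mmol"
    ),
    abbott_libre = list(
      timestamp_col = "Time", date_col = NULL, time_col = NULL,
      glucose_col = "Historic Glucose (mmol/L)", event_col = NULL,
      participant_col = NULL,
      timestamp_format = c("%Y/%m/%d %H:%M", "%d-%m-%Y %H:%M"),
      decimal_mark = ".", units = "mmol"
    ),
    dexcom_g6 = list(
      timestamp_col = "Timestamp (YYYY-MM-DDThh:mm:ss)", date_col = NULL,
      time_col = NULL, glucose_col = "Glucose Value (mmol/L)",
      event_col = "Event Type", participant_col = NULL,
      timestamp_format = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"),
      decimal_mark = ".", units = "mmol"
    )
  )
  over <- list(...)
  base[names(over)] <- over
  base$name <- name
  structure(base, class = "device_dialect")
}

#' @noRd
parse_stamp <- function(x, formats) {
  out <- rep(as.POSIXct(NA, tz = GLUCOTRACE_TZ), length(x))
  left <- rep(TRUE, length(x))
  for (f in formats) {
    if (!any(left)) break
    p <- as.POSIXct(x[left], format = f, tz = GLUCOTRACE_TZ)
    ok <- !is.na(p)
    out[which(left)[ok]] <- p[ok]
    left[which(left)[ok]] <- FALSE
  }
  out
}

#' Read a CGM export file into a glucose trace
#'
#' Parses one per-participant CSV under the given [device_dialect()]. Rows
#' without a sensor-glucose value become explicit gaps (no reading is
#' emitted); rows with an event kind become [glucose_trace()] events.
#' Unparseable timestamps are a row-level error reporting the offending line
#' numbers; non-monotone timestamps are a hard error naming the first
#' offending pair.
#'
#' @param path CSV file path.
#' @param dialect A [device_dialect()]; default the generic format.
#' @param units `"mmol"` or `"mgdl"`; mg/dL values are converted to mmol/L by
#'   dividing by 18.016.
#' @param participant_id Override for the participant id (defaults to the
#'   file's id column, or the file name).
#' @return A [glucose_trace()].
#' @export
read_cgm_file <- function(path, dialect = device_dialect("other"),
                          units = NULL, participant_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  units <- units %||% dialect$units
  raw <- readr::read_csv(
    path, col_types = readr::cols(.default = readr::col_character()),
    locale = readr::locale(decimal_mark = dialect$decimal_mark),
    progress = FALSE, show_col_types = FALSE
  )
  if (nrow(raw) == 0) stop("empty CGM file: ", path, call. = FALSE)
  stamp_raw <- if (!is.null(dialect$timestamp_col)) {
    need_col(raw, dialect$timestamp_col, path)
    raw[[dialect$timestamp_col]]
  } else {
    need_col(raw, dialect$date_col, path)
    need_col(raw, dialect$time_col, path)
    paste(raw[[dialect$date_col]], raw[[dialect$time_col]])
  }
  stamps <- parse_stamp(stamp_raw, dialect$timestamp_format)
  bad <- which(is.na(stamps) & !is.na(stamp_raw) & nzchar(stamp_raw))
  if (length(bad)) {
    stop("unparseable timestamp(s) in ", path, " at data line(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  need_col(raw, dialect$glucose_col, path)
  gtxt <- raw[[dialect$glucose_col]]
  if (dialect$decimal_mark != ".") gtxt <- gsub(dialect$decimal_mark, ".",
                                                gtxt, fixed = TRUE)
  glucose <- suppressWarnings(as.numeric(gtxt))
  if (identical(units, "mgdl")) glucose <- glucose / MGDL_PER_MMOL
  kind <- if (!is.null(dialect$event_col) &&
              dialect$event_col %in% names(raw)) {
    tolower(trimws(dplyr::coalesce(raw[[dialect$event_col]], "")))
  } else {
    rep("", nrow(raw))
  }
  is_event <- kind %in% c("meal", "exercise", "medication", "calibration")
  is_reading <- !is.na(glucose) & !is_event
  rt <- stamps[is_reading]
  if (length(rt) >= 2 && any(diff(as.numeric(rt)) <= 0)) {
    k <- which(diff(as.numeric(rt)) <= 0)[1]
    stop("non-monotone timestamps in ", path, ": ", format(rt[k]),
         " followed by ", format(rt[k + 1]), call. = FALSE)
  }
  if (!any(is_reading)) stop("no sensor glucose readings in ", path,
                             call. = FALSE)
  pid <- participant_id %||% {
    if (!is.null(dialect$participant_col) &&
        dialect$participant_col %in% names(raw)) {
      stats::na.omit(raw[[dialect$participant_col]])[1]
    } else {
      sub("\\.[^.]*$", "", basename(path))
    }
  }
  events <- if (any(is_event)) {
    tibble::tibble(time = stamps[is_event], kind = kind[is_event],
                   glucose = glucose[is_event])
  } else {
    NULL
  }
  glucose_trace(rt, glucose[is_reading], participant_id = pid,
                events = events)
}

#' @noRd
need_col <- function(df, col, path) {
  if (is.null(col) || !col %in% names(df)) {
    stop("column '", col, "' not found in ", path, call. = FALSE)
  }
  invisible(TRUE)
}

#' Write a glucose trace in the generic CSV dialect
#'
#' Serialises readings and events to the normative generic format
#' (`participant_id`, `timestamp`, `glucose_mmol_per_L`, `event_kind`);
#' [read_cgm_file()] round-trips glucose values bit-exactly.
#'
#' @param trace A [glucose_trace()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cgm_file <- function(trace, path) {
  fmt_t <- function(t) format(t, "%Y-%m-%dT%H:%M:%S")
  rows <- tibble::tibble(
    participant_id = trace$participant_id,
    timestamp = fmt_t(trace$readings$time),
    glucose_mmol_per_L = sprintf("%.17g", trace$readings$glucose),
    event_kind = "",
    .t = trace$readings$time
  )
  if (nrow(trace$events)) {
    ev <- tibble::tibble(
      participant_id = trace$participant_id,
      timestamp = fmt_t(trace$events$time),
      glucose_mmol_per_L = ifelse(is.na(trace$events$glucose), "",
                                  sprintf("%.17g", trace$events$glucose)),
      event_kind = trace$events$kind,
      .t = trace$events$time
    )
    rows <- dplyr::bind_rows(rows, ev)
  }
  rows <- dplyr::arrange(rows, .data$.t)
  readr::write_csv(rows[, 1:4], path, progress = FALSE)
  invisible(path)
}

#' Write derived summary variables to CSV
#'
#' One row per participant-period in the stable column order
#' (`participant_id, scope, date, n_minutes, n_minutes_imputed, auc_per_min,
#' prop_hypo, prop_normo, prop_hyper, mad, sgvp, gvp, fasting_proxy,
#' tt_peak_meal, auc1h_meal, auc2h_meal, auc1h_exercise, auc2h_exercise,
#' auc1h_medication, auc2h_medication`), missing statistics written as empty
#' fields. With `per_event = TRUE`, per-event rows are appended to a sibling
#' `<path base>_events.csv`.
#'
#' @param records Records tibble from [summarise_trace()] /
#'   [aggregate_summaries()].
#' @param path Output CSV path.
#' @param per_event Also write per-event rows (requires `events`).
#' @param events Per-event tibble from [summarise_trace()].
#' @return `path`, invisibly.
#' @export
write_summary_csv <- function(records, path, per_event = FALSE,
                              events = NULL) {
  if (is.null(records) || nrow(records) == 0) {
    stop("no summary records to write", call. = FALSE)
  }
  cols <- c("participant_id", "scope", "date", "n_minutes",
            "n_minutes_imputed", "auc_per_min", "prop_hypo", "prop_normo",
            "prop_hyper", "mad", "sgvp", "gvp", "fasting_proxy",
            "tt_peak_meal", "auc1h_meal", "auc2h_meal", "auc1h_exercise",
            "auc2h_exercise", "auc1h_medication", "auc2h_medication")
  readr::write_csv(records[, cols], path, na = "", progress = FALSE)
  if (per_event && !is.null(events) && nrow(events)) {
    ev_path <- sub("(\\.[^.]*)?$", "_events\\1", path)
    readr::write_csv(events, ev_path, na = "", progress = FALSE)
  }
  invisible(path)
}

#' Write the per-participant QC report CSV
#'
#' Per-day rows (reading counts, minutes missing/imputed, completeness,
#' per-day outlier counts, imputation outcome) followed, when outliers were
#' flagged, by their timestamps in an `outlier_times` header comment-free
#' sibling column format: one extra row per flagged timestamp with
#' `day_index = NA`.
#'
#' @param report A [qc_report()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_qc_csv <- function(report, path) {
  days <- report$days
  days$outlier_time <- NA_character_
  if (length(report$outliers)) {
    extra <- days[0, ]
    extra[seq_along(report$outliers), "participant_id"] <-
      report$summary$participant_id
    extra$outlier_time <- format(report$outliers, "%Y-%m-%dT%H:%M:%S")
    days <- dplyr::bind_rows(days, extra)
  }
  readr::write_csv(days, path, na = "", progress = FALSE)
  invisible(path)
}
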