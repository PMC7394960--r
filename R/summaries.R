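# Six-domain glucose summary variables, computed on the 1-min grid per day
# period, per night-time and per day-time window, plus across-day means.
#
# Pair-based statistics (AUC, GVP/sGVP) walk consecutive minute pairs.  Two
# exclusion mechanisms apply: `run` breaks (non-contiguous minutes, e.g. the
# two chunks of a night window split by the period boundary) break every
# pairwise statistic, while `section` breaks (imputation boundaries) are
# additionally excluded from the order-sensitive line-length statistics and
# their duration denominators, because the value-to-value transition across
# such a boundary is an artifact of stitching, not physiology.

#' Population-specific glycaemic threshold sets
#'
#' Cutpoints for classifying each minute as hypo-, normo- or hyper-glycaemic.
#' Hypo-glycaemia is strictly below `hypo_below`; hyper-glycaemia is at or
#' above `hyper_at_or_above`; normo-glycaemia is the half-open band between.
#' Defaults: general (non-diabetic, non-pregnant) population 3.3 / 10.0
#' mmol/L; diabetes 3.9 / 10.0; pregnancy 3.5 / 7.8. Custom cutpoints override
#' the population label.
#'
#' @param population `"general"`, `"diabetes"` or `"pregnancy"`.
#' @param hypo,hyper Optional custom cutpoints (mmol/L), both or neither.
#' @return List with `hypo_below`, `hyper_at_or_above`, `label`.
#' @export
#' @examples
#' threshold_set("pregnancy")
threshold_set <- function(population = c("general", "diabetes", "pregnancy"),
                          hypo = NULL, hyper = NULL) {
  population <- match.arg(population)
  ts <- switch(population,
    general = list(hypo_below = 3.3, hyper_at_or_above = 10.0,
                   label = "healthy"),
    diabetes = list(hypo_below = 3.9, hyper_at_or_above = 10.0,
                    label = "diabetic"),
    pregnancy = list(hypo_below = 3.5, hyper_at_or_above = 7.8,
                     label = "pregnant")
  )
  if (!is.null(hypo) || !is.null(hyper)) {
    if (is.null(hypo) || is.null(hyper)) {
      stop("custom thresholds need both hypo and hyper", call. = FALSE)
    }
    ts <- list(hypo_below = hypo, hyper_at_or_above = hyper, label = "custom")
  }
  if (ts$hypo_below >= ts$hyper_at_or_above) {
    stop("hypo cutpoint must be below hyper cutpoint", call. = FALSE)
  }
  ts
}

# Consecutive-pair inclusion masks for a segment.
#' @noRd
segment_pairs <- function(minutes, section = NULL, run = NULL) {
  n <- length(minutes)
  if (n < 2) return(list(dt = numeric(), contiguous = logical(),
                         same_section = logical()))
  dt <- diff(minutes)
  contiguous <- if (is.null(run)) dt > 0 else dt > 0 & diff(run) == 0
  same_section <- if (is.null(section)) {
    rep(TRUE, n - 1)
  } else {
    diff(section) == 0
  }
  list(dt = dt, contiguous = contiguous, same_section = same_section)
}

#' Trapezoidal AUC per minute (time-averaged glucose)
#'
#' Sum of trapezoid areas between adjacent grid minutes divided by the number
#' of minutes spanned, giving the average glucose level per minute (mmol/L).
#' Dividing by the period's duration (1440 for a whole day, 450 / 990 for the
#' default night / day-time windows) makes levels comparable across periods of
#' different lengths. Non-contiguous pairs (run breaks) are excluded from both
#' numerator and denominator; imputation boundaries are retained, as the AUC
#' is not order-sensitive.
#'
#' @param glucose Glucose values (mmol/L) on the 1-min grid.
#' @param minutes Integer minute stamps; default `0, 1, 2, ...`.
#' @param run Optional run ids; pairs spanning different runs are excluded.
#' @return AUC per minute (mmol/L); `NA` if no valid pair exists.
#' @export
#' @examples
#' auc_per_minute(c(4, 6, 5)) # ((4+6)/2 + (6+5)/2) / 2 = 5.25
auc_per_minute <- function(glucose, minutes = NULL, run = NULL) {
  minutes <- minutes %||% (seq_along(glucose) - 1)
  p <- segment_pairs(minutes, run = run)
  use <- p$contiguous
  if (!any(use)) return(NA_real_)
  g <- glucose
  area <- sum(((g[-length(g)] + g[-1]) / 2 * p$dt)[use])
  area / sum(p$dt[use])
}

#' Proportions of time in hypo-, normo- and hyper-glycaemia
#'
#' Classifies each grid minute against a [threshold_set()] and returns the
#' proportion of minutes in each range. Boundary semantics: hypo iff
#' `glucose < hypo_below`, hyper iff `glucose >= hyper_at_or_above`, normo
#' otherwise — a value exactly at the hyper cutpoint is hyper, one exactly at
#' the hypo cutpoint is normo.
#'
#' @param glucose Glucose values (mmol/L), one per minute.
#' @param thresholds A [threshold_set()].
#' @return Named numeric: `prop_hypo`, `prop_normo`, `prop_hyper`; sums to 1.
#' @export
time_in_ranges <- function(glucose, thresholds = threshold_set()) {
  if (length(glucose) == 0) stop("empty segment", call. = FALSE)
  hypo <- glucose < thresholds$hypo_below
  hyper <- glucose >= thresholds$hyper_at_or_above
  c(prop_hypo = mean(hypo),
    prop_normo = mean(!hypo & !hyper),
    prop_hyper = mean(hyper))
}

#' Median absolute deviation about the median
#'
#' Robust overall-variability (dispersion) measure:
#' `median(|SG_i - median(SG)|)`, unscaled. Preferred over SD/CV because
#' one day holds few values (288 at 5-min epochs) and sensor glucose
#' distributions are often skewed. Even-length sets use the midpoint
#' (interpolated) median.
#'
#' @param glucose Glucose values (mmol/L).
#' @return MAD in mmol/L.
#' @export
#' @examples
#' mad_glucose(1:5) # 1
mad_glucose <- function(glucose) {
  if (length(glucose) == 0) stop("empty segment", call. = FALSE)
  stats::median(abs(glucose - stats::median(glucose)))
}

#' Glycaemic variability percentage (GVP)
#'
#' The excess length of the glucose trace, treated as a polyline in
#' (minute, mmol/L) coordinates, over the length of a flat trace of the same
#' duration: `GVP = (L / D - 1) * 100` with
#' `L = sum(sqrt(dSG^2 + dt^2))` and `D` the summed duration of the included
#' pairs. A constant trace has GVP 0; GVP 100 means the stretched-out trace is
#' twice its duration. Pairs that cross a run break or a section (imputation)
#' boundary are excluded from both `L` and `D`.
#'
#' @inheritParams auc_per_minute
#' @param section Optional section ids; pairs spanning different sections are
#'   excluded.
#' @return GVP in percent (non-negative).
#' @export
#' @examples
#' gvp(c(5, 8), minutes = c(0, 4)) # (5/4 - 1) * 100 = 25
gvp <- function(glucose, minutes = NULL, section = NULL, run = NULL) {
  if (length(glucose) < 2) {
    stop("GVP needs at least 2 time-points", call. = FALSE)
  }
  minutes <- minutes %||% (seq_along(glucose) - 1)
  p <- segment_pairs(minutes, section = section, run = run)
  use <- p$contiguous & p$same_section
  if (!any(use)) stop("no within-section transitions in segment",
                      call. = FALSE)
  dg <- diff(glucose)
  L <- sum(sqrt(dg[use]^2 + p$dt[use]^2))
  (L / sum(p$dt[use]) - 1) * 100
}

#' Standardized glycaemic variability percentage (sGVP)
#'
#' [gvp()] computed on the standardized trace `(SG - median(SG)) / MAD(SG)`.
#' Standardization removes overall dispersion (already captured by
#' [mad_glucose()]), leaving a measure of moment-to-moment complexity that is
#' invariant to (i) the spacing of time-points, (ii) affine rescaling of the
#' glucose values, and (iii) the duration of the trace. A constant trace
#' (MAD = 0) has no moment-to-moment variability; its sGVP is defined as 0,
#' with a warning.
#'
#' @inheritParams gvp
#' @return sGVP in percent (non-negative).
#' @export
sgvp <- function(glucose, minutes = NULL, section = NULL, run = NULL) {
  if (length(glucose) < 2) {
    stop("sGVP needs at least 2 time-points", call. = FALSE)
  }
  m <- stats::median(glucose)
  s <- mad_glucose(glucose)
  if (s == 0) {
    warning("constant trace: MAD is 0, sGVP defined as 0", call. = FALSE)
    return(0)
  }
  gvp((glucose - m) / s, minutes = minutes, section = section, run = run)
}

#' Fasting glucose proxy from night-time readings
#'
#' The mean of the 30 lowest consecutive minutes during the night-time window
#' (equivalently, the minimum over all 30-minute sliding windows of the window
#' mean; 30 minutes equates to 6 readings at 5-min native epochs). A proxy for
#' fasting glucose that needs no knowledge of meal times. Windows never span a
#' run break.
#'
#' @param glucose Night-time glucose values (mmol/L) on the 1-min grid.
#' @param run Optional run ids delimiting contiguous chunks.
#' @param window Window length in minutes; default 30.
#' @return Minimum windowed mean (mmol/L).
#' @export
fasting_proxy <- function(glucose, run = NULL, window = 30L) {
  run <- run %||% rep(1L, length(glucose))
  best <- Inf
  for (chunk in split(glucose, run)) {
    if (length(chunk) >= window) {
      best <- min(best, min(zoo::rollmean(chunk, window)))
    }
  }
  if (!is.finite(best)) {
    stop("night-time segment shorter than ", window, " minutes",
         call. = FALSE)
  }
  best
}

#' Minutes from an event to the next glucose peak
#'
#' Finds the nearest time-point after the event whose glucose value is higher
#' than both its nearest *differing* neighbours — the plateau rule: when the
#' peak is a flat run of equal values, the comparison is made against the
#' closest previous and subsequent values that differ, and the peak time is
#' the first minute of the plateau. Returns `NA` when no qualifying peak
#' occurs before the end of the day period.
#'
#' @param glucose Whole-day glucose values on the 1-min grid.
#' @param minutes Integer minute stamps aligned with `glucose`.
#' @param event_minute Event time as an integer minute stamp.
#' @return Minutes from event to peak, or `NA_real_`.
#' @export
#' @examples
#' time_to_peak(c(5, 6, 7, 7, 7, 6), 0:5, 0) # 2
time_to_peak <- function(glucose, minutes, event_minute) {
  r <- rle(glucose)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nr <- length(r$values)
  if (nr < 3) return(NA_real_)
  for (q in 2:(nr - 1)) {
    if (r$values[q] > r$values[q - 1] && r$values[q] > r$values[q + 1]) {
      t_peak <- minutes[starts[q]]
      if (t_peak > event_minute) return(t_peak - event_minute)
    }
  }
  NA_real_
}

#' Post-event 15-minute AUC at a 1-h or 2-h horizon
#'
#' The trapezoidal AUC per minute over the 15-minute window starting 60 or 120
#' minutes after the event (windows `[60, 75]` and `[120, 135]` minutes
#' post-event). All 16 bounding grid minutes must be present within the day's
#' data; otherwise the statistic is missing.
#'
#' @param glucose Whole-day glucose values on the 1-min grid.
#' @param minutes Integer minute stamps aligned with `glucose`.
#' @param event_minute Event time as an integer minute stamp.
#' @param horizon `"1h"` or `"2h"`.
#' @return AUC per minute (mmol/L), or `NA_real_` when the window is not
#'   fully covered.
#' @export
post_event_auc <- function(glucose, minutes, event_minute,
                           horizon = c("1h", "2h")) {
  horizon <- match.arg(horizon)
  off <- if (horizon == "1h") 60L else 120L
  want <- event_minute + off + 0:15
  pos <- match(want, minutes)
  if (anyNA(pos)) return(NA_real_)
  auc_per_minute(glucose[pos], minutes = want)
}

# ---- per-day driver -------------------------------------------------------

# Extract the 1-min rows of one scope within a day period, with run ids for
# contiguity and a closing boundary point appended to each run when the next
# minute exists in the trace (so a whole day integrates over 1440 trapezoids).
#' @noRd
scope_segment <- function(readings, day, scope, night_start, day_start) {
  m <- minute_index(readings$time)
  s <- minute_index(day$start)
  e <- minute_index(day$end)
  inside <- m >= s & m < e
  if (scope == "night") {
    inside <- inside & in_clock_window(readings$time, night_start, day_start)
  } else if (scope == "day_time") {
    inside <- inside & !in_clock_window(readings$time, night_start, day_start)
  }
  idx <- which(inside)
  if (length(idx) == 0) return(NULL)
  mm <- m[idx]
  run <- cumsum(c(1L, as.integer(diff(mm) != 1L)))
  core_n <- length(idx)
  # closing point: first minute after each run, if present in the trace
  closes <- integer()
  for (rid in unique(run)) {
    last_idx <- idx[max(which(run == rid))]
    nxt <- last_idx + 1L
    if (nxt <= nrow(readings) && m[nxt] == m[last_idx] + 1L) {
      closes <- c(closes, nxt)
    }
  }
  seg <- tibble::tibble(
    minute = c(mm, m[closes]),
    glucose = c(readings$glucose[idx], readings$glucose[closes]),
    source = c(readings$source[idx], readings$source[closes]),
    section = c(readings$section[idx], readings$section[closes]),
    run = c(run, run[vapply(closes, function(ci) {
      max(which(idx == ci - 1L))
    }, integer(1))]),
    core = c(rep(TRUE, core_n), rep(FALSE, length(closes)))
  )
  dplyr::arrange(seg, .data$minute)
}

#' Derive the summary variables for one participant
#'
#' Computes, for every included (complete) day period and for its night-time
#' and day-time windows, the six-domain summary variables: AUC per minute,
#' proportions of time in hypo-/normo-/hyper-glycaemia, MAD, sGVP (with the
#' unstandardized GVP as a diagnostic), the night-time fasting glucose proxy,
#' and per-event-kind statistics (time to peak for meals; 1-h and 2-h
#' post-event AUCs for meals, exercise and medication, averaged within each
#' day). Pair statistics exclude transitions across imputation boundaries.
#'
#' @param trace A resampled [glucose_trace()] (see [resample_to_1min()]).
#' @param days Day tibble from [segment_days()], refreshed after any
#'   imputation; only complete days are summarised.
#' @param thresholds A [threshold_set()].
#' @param save_events Also return one row per event.
#' @return List: `records` (per-day/per-scope tibble in the stable column
#'   order), `events` (per-event tibble or `NULL`).
#' @export
summarise_trace <- function(trace, days, thresholds = threshold_set(),
                            save_events = FALSE) {
  stopifnot(inherits(trace, "glucose_trace"))
  if (!trace$resampled) trace <- resample_to_1min(trace)
  ns <- attr(days, "night_start") %||% clock_minutes("23:00")
  ds <- attr(days, "day_start") %||% clock_minutes("06:30")
  readings <- trace$readings
  included <- days[days$complete, ]
  rows <- list()
  event_rows <- list()
  for (i in seq_len(nrow(included))) {
    day <- included[i, ]
    ev_day <- day_event_stats(trace, day, readings, save_events)
    for (scope in c("whole_day", "night", "day_time")) {
      seg <- scope_segment(readings, day, scope, ns, ds)
      if (is.null(seg)) next
      core <- seg[seg$core, ]
      fp <- if (scope == "night") {
        tryCatch(fasting_proxy(core$glucose, run = core$run),
                 error = function(e) NA_real_)
      } else {
        NA_real_
      }
      tir <- time_in_ranges(core$glucose, thresholds)
      sg <- standardized_for_gvp(seg, core)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        participant_id = trace$participant_id,
        scope = scope,
        date = as.Date(day$start),
        day_index = day$day_index,
        n_minutes = nrow(core),
        n_minutes_imputed = sum(core$section > 1L |
                                  startsWith(core$source, "imputed")),
        auc_per_min = auc_per_minute(seg$glucose, seg$minute, run = seg$run),
        prop_hypo = tir[["prop_hypo"]],
        prop_normo = tir[["prop_normo"]],
        prop_hyper = tir[["prop_hyper"]],
        mad = mad_glucose(core$glucose),
        sgvp = sg$sgvp,
        gvp = sg$gvp,
        fasting_proxy = fp,
        tt_peak_meal = if (scope == "whole_day") ev_day$tt_peak_meal
                       else NA_real_,
        auc1h_meal = if (scope == "whole_day") ev_day$auc1h_meal
                     else NA_real_,
        auc2h_meal = if (scope == "whole_day") ev_day$auc2h_meal
                     else NA_real_,
        auc1h_exercise = if (scope == "whole_day") ev_day$auc1h_exercise
                         else NA_real_,
        auc2h_exercise = if (scope == "whole_day") ev_day$auc2h_exercise
                         else NA_real_,
        auc1h_medication = if (scope == "whole_day") ev_day$auc1h_medication
                           else NA_real_,
        auc2h_medication = if (scope == "whole_day") ev_day$auc2h_medication
                           else NA_real_
      )
    }
    if (save_events && !is.null(ev_day$per_event)) {
      event_rows[[length(event_rows) + 1L]] <- ev_day$per_event
    }
  }
  list(
    records = if (length(rows)) dplyr::bind_rows(rows) else empty_records(),
    events = if (length(event_rows)) dplyr::bind_rows(event_rows) else NULL
  )
}

#' @noRd
standardized_for_gvp <- function(seg, core) {
  med <- stats::median(core$glucose)
  s <- mad_glucose(core$glucose)
  g <- tryCatch(
    gvp(seg$glucose, seg$minute, section = seg$section, run = seg$run),
    error = function(e) NA_real_
  )
  sgv <- if (s == 0) {
    0
  } else {
    tryCatch(
      gvp((seg$glucose - med) / s, seg$minute,
          section = seg$section, run = seg$run),
      error = function(e) NA_real_
    )
  }
  list(gvp = g, sgvp = sgv)
}

#' @noRd
day_event_stats <- function(trace, day, readings, save_events) {
  out <- list(tt_peak_meal = NA_real_, auc1h_meal = NA_real_,
              auc2h_meal = NA_real_, auc1h_exercise = NA_real_,
              auc2h_exercise = NA_real_, auc1h_medication = NA_real_,
              auc2h_medication = NA_real_, per_event = NULL)
  ev <- trace$events
  ev <- ev[ev$time >= day$start & ev$time < day$end &
             ev$kind %in% c("meal", "exercise", "medication"), ]
  if (nrow(ev) == 0) return(out)
  m <- minute_index(readings$time)
  s <- minute_index(day$start); e <- minute_index(day$end)
  inside <- which(m >= s & m <= e)  # closing boundary point allowed
  g <- readings$glucose[inside]
  mm <- m[inside]
  per <- lapply(seq_len(nrow(ev)), function(k) {
    em <- minute_index(ev$time[k])
    tibble::tibble(
      participant_id = trace$participant_id,
      day_index = day$day_index,
      event_time = minute_floor(ev$time[k]),
      kind = ev$kind[k],
      tt_peak = if (ev$kind[k] == "meal") {
        time_to_peak(g, mm, em)
      } else {
        NA_real_
      },
      auc1h = post_event_auc(g, mm, em, "1h"),
      auc2h = post_event_auc(g, mm, em, "2h")
    )
  })
  per <- dplyr::bind_rows(per)
  mean_or_na <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  for (kind in c("meal", "exercise", "medication")) {
    rows <- per[per$kind == kind, ]
    if (nrow(rows) == 0) next
    out[[paste0("auc1h_", kind)]] <- mean_or_na(rows$auc1h)
    out[[paste0("auc2h_", kind)]] <- mean_or_na(rows$auc2h)
    if (kind == "meal") out$tt_peak_meal <- mean_or_na(rows$tt_peak)
  }
  if (save_events) out$per_event <- per
  out
}

#' @noRd
empty_records <- function() {
  tibble::tibble(
    participant_id = character(), scope = character(),
    date = as.Date(character()), day_index = integer(),
    n_minutes = integer(), n_minutes_imputed = integer(),
    auc_per_min = numeric(), prop_hypo = numeric(), prop_normo = numeric(),
    prop_hyper = numeric(), mad = numeric(), sgvp = numeric(),
    gvp = numeric(), fasting_proxy = numeric(), tt_peak_meal = numeric(),
    auc1h_meal = numeric(), auc2h_meal = numeric(),
    auc1h_exercise = numeric(), auc2h_exercise = numeric(),
    auc1h_medication = numeric(), auc2h_medication = numeric()
  )
}

#' Across-day means of the summary variables
#'
#' Appends, for each scope, one row holding the unweighted mean of every
#' summary variable across the included days (scope labels `whole_day_mean`,
#' `night_mean`, `day_time_mean`), giving one overall value per variable per
#' participant. Event statistics are averaged within day first (see
#' [summarise_trace()]) and then across days with missing days dropped.
#'
#' @param records Per-day records from [summarise_trace()].
#' @return `records` with the across-day mean rows appended.
#' @export
aggregate_summaries <- function(records) {
  if (nrow(records) == 0) return(records)
  num_cols <- setdiff(names(records)[vapply(records, is.numeric, logical(1))],
                      "day_index")
  means <- lapply(c("whole_day", "night", "day_time"), function(sc) {
    sub <- records[records$scope == sc, ]
    if (nrow(sub) == 0) return(NULL)
    row <- sub[1, ]
    row$scope <- paste0(sc, "_mean")
    row$date <- as.Date(NA)
    row$day_index <- NA_integer_
    for (cl in num_cols) {
      v <- sub[[cl]]
      row[[cl]] <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }
    row
  })
  dplyr::bind_rows(records, dplyr::bind_rows(means))
}
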