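#' Construct a glucose trace
#'
#' A `glucose_trace` is the in-memory container for one participant-instance of
#' CGM data: a time-ordered sequence of sensor glucose readings (mmol/L) at the
#' device-native epoch spacing, plus any annotated events (meals, exercise,
#' medication, capillary calibration readings).
#'
#' Each reading carries a provenance `source` (one of `"observed"`,
#' `"interpolated"`, `"imputed_approximal_left"`, `"imputed_approximal_right"`,
#' `"imputed_otherday"`) and a `section` id. Sections delimit contiguous runs of
#' provenance-homogeneous data: transitions *between* sections (e.g. from
#' observed data into an imputed span, or between the two halves of an
#' approximally imputed gap) are excluded from order-sensitive statistics such
#' as the standardized glycaemic variability percentage and from Poincare
#' pairs. Missing data are represented by absent rows, never by sentinel
#' values.
#'
#' @param times Reading timestamps (`POSIXct` or coercible); strictly
#'   increasing after truncation to minutes.
#' @param glucose Sensor glucose values in mmol/L; positive and finite. `NA`
#'   values are dropped, i.e. treated as explicit gaps.
#' @param participant_id Opaque participant/instance identifier.
#' @param epoch_minutes Device-native spacing in minutes (positive integer).
#'   If `NULL`, inferred as the modal difference between consecutive readings.
#' @param events Optional tibble with columns `time`, `kind` (one of `"meal"`,
#'   `"exercise"`, `"medication"`, `"calibration"`) and optionally `glucose`
#'   (capillary value for calibration rows).
#' @param source Per-reading provenance; defaults to `"observed"`.
#'
#' @return An object of class `glucose_trace`: a list with elements `readings`
#'   (tibble: `time`, `glucose`, `source`, `section`), `events`,
#'   `participant_id`, `epoch_minutes`, `outliers` (flagged timestamps) and
#'   `resampled` (logical).
#' @export
#' @examples
#' t0 <- as.POSIXct("2024-03-01 23:00:00", tz = "UTC")
#' tr <- glucose_trace(t0 + 300 * (0:11), 5 + 0.1 * sin(0:11), "p1")
#' tr
glucose_trace <- function(times, glucose, participant_id = "unknown",
                          epoch_minutes = NULL, events = NULL,
                          source = "observed") {
  times <- as_wallclock(times)
  stopifnot(length(times) == length(glucose))
  keep <- !is.na(glucose)
  times <- times[keep]
  glucose <- as.numeric(glucose[keep])
  if (length(source) > 1) source <- source[keep]
  if (any(!is.finite(glucose) | glucose <= 0)) {
    stop("glucose values must be finite and positive (mmol/L)", call. = FALSE)
  }
  ord <- order(times)
  times <- times[ord]
  glucose <- glucose[ord]
  if (length(source) > 1) source <- source[ord]
  if (anyDuplicated(times)) {
    stop("duplicate timestamps in trace", call. = FALSE)
  }
  if (is.null(epoch_minutes)) {
    epoch_minutes <- infer_epoch(times)
  }
  epoch_minutes <- as.integer(epoch_minutes)
  stopifnot(epoch_minutes >= 1, 1440L %% epoch_minutes == 0L)
  readings <- tibble::tibble(
    time = times,
    glucose = glucose,
    source = rep_len(source, length(times)),
    section = 1L
  )
  events <- normalize_events(events)
  structure(
    list(
      readings = readings,
      events = events,
      participant_id = as.character(participant_id),
      epoch_minutes = epoch_minutes,
      outliers = as_wallclock(as.POSIXct(character(), tz = GLUCOTRACE_TZ)),
      resampled = FALSE
    ),
    class = "glucose_trace"
  )
}

#' @noRd
infer_epoch <- function(times) {
  if (length(times) < 2) return(5L)
  d <- round(diff(as.numeric(times)) / 60)
  d <- d[d >= 1]
  if (length(d) == 0) return(1L)
  as.integer(names(sort(table(d), decreasing = TRUE))[1])
}

#' @noRd
normalize_events <- function(events) {
  kinds <- c("meal", "exercise", "medication", "calibration")
  if (is.null(events) || nrow(events) == 0) {
    return(tibble::tibble(
      time = as_wallclock(as.POSIXct(character(), tz = GLUCOTRACE_TZ)),
      kind = character(),
      glucose = numeric()
    ))
  }
  stopifnot(all(c("time", "kind") %in% names(events)))
  kind <- tolower(as.character(events$kind))
  if (!all(kind %in% kinds)) {
    stop("event kind must be one of: ", paste(kinds, collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(
    time = as_wallclock(events$time),
    kind = kind,
    glucose = if ("glucose" %in% names(events)) {
      as.numeric(events$glucose)
    } else {
      NA_real_
    }
  )
}

#' @export
print.glucose_trace <- function(x, ...) {
  n <- nrow(x$readings)
  cat("<glucose_trace> participant ", x$participant_id, "\n", sep = "")
  cat("  ", n, " readings at ", x$epoch_minutes, "-min native epochs",
      if (x$resampled) " (resampled to 1-min grid)", "\n", sep = "")
  if (n > 0) {
    cat("  span: ", format(x$readings$time[1]), " to ",
        format(x$readings$time[n]), "\n", sep = "")
  }
  cat("  events: ", nrow(x$events), "; flagged outliers: ",
      length(x$outliers), "\n", sep = "")
  invisible(x)
}

#' Linear interpolation between two sensor glucose readings
#'
#' Estimates the glucose value at time `t_prime` lying between two adjacent
#' readings by assuming a straight line between them:
#' `SG' = (1 - w) * SG1 + w * SG2` with `w = (t' - t1) / (t2 - t1)`.
#'
#' @param t1,t2 Times of the bracketing readings (`POSIXct` or numeric, same
#'   units); `t1 < t2`.
#' @param sg1,sg2 Glucose values (mmol/L) at `t1` and `t2`.
#' @param t_prime Time(s) at which to interpolate; must lie in `[t1, t2]`.
#' @return Interpolated glucose value(s); always within
#'   `[min(sg1, sg2), max(sg1, sg2)]`.
#' @export
#' @examples
#' linear_interpolate(0, 5.0, 5, 8.0, 2) # 6.2
linear_interpolate <- function(t1, sg1, t2, sg2, t_prime) {
  t1 <- as.numeric(t1); t2 <- as.numeric(t2); t_prime <- as.numeric(t_prime)
  if (t1 >= t2) {
    stop("degenerate interval: t1 must be strictly before t2", call. = FALSE)
  }
  if (any(t_prime < t1 | t_prime > t2)) {
    stop("t_prime outside [t1, t2]: refusing to extrapolate", call. = FALSE)
  }
  w <- (t_prime - t1) / (t2 - t1)
  (1 - w) * sg1 + w * sg2
}

#' Resample a glucose trace to a one-minute grid
#'
#' Truncates reading timestamps to whole minutes and fills every minute between
#' native-epoch-adjacent readings by linear interpolation
#' (see [linear_interpolate()]). Gaps longer than the native epoch are left
#' missing: bridging them is imputation, a separate and flagged quality-control
#' step, never a silent side effect of resampling. Original readings keep their
#' values and provenance at their truncated minute; inserted points carry
#' `source = "interpolated"` and inherit the section of the left bracketing
#' reading. Resampling is idempotent.
#'
#' @param trace A [glucose_trace()].
#' @return A `glucose_trace` with one reading per minute inside each contiguous
#'   span, and `resampled = TRUE`.
#' @export
resample_to_1min <- function(trace) {
  stopifnot(inherits(trace, "glucose_trace"))
  r <- trace$readings
  if (nrow(r) < 2) {
    stop("resampling needs at least 2 readings", call. = FALSE)
  }
  m <- minute_index(r$time)
  keep <- !duplicated(m)
  r <- r[keep, ]
  m <- m[keep]
  dm <- diff(m)
  bridge <- dm >= 1 & dm <= trace$epoch_minutes
  # span = maximal run of bridgeable adjacent pairs
  span_id <- cumsum(c(TRUE, !bridge))
  out <- vector("list", max(span_id))
  for (s in seq_len(max(span_id))) {
    idx <- which(span_id == s)
    ms <- m[idx]
    if (length(idx) == 1) {
      out[[s]] <- tibble::tibble(
        minute = ms, glucose = r$glucose[idx],
        source = r$source[idx], section = r$section[idx]
      )
      next
    }
    grid <- seq(ms[1], ms[length(ms)])
    g <- stats::approx(ms, r$glucose[idx], xout = grid)$y
    left <- findInterval(grid, ms)
    src <- rep("interpolated", length(grid))
    on_native <- grid %in% ms
    src[on_native] <- r$source[idx][match(grid[on_native], ms)]
    out[[s]] <- tibble::tibble(
      minute = grid, glucose = g,
      source = src, section = r$section[idx][left]
    )
  }
  res <- dplyr::bind_rows(out)
  trace$readings <- tibble::tibble(
    time = as.POSIXct(res$minute * 60, origin = "1970-01-01",
                      tz = GLUCOTRACE_TZ),
    glucose = res$glucose,
    source = res$source,
    section = res$section
  )
  trace$resampled <- TRUE
  trace
}

#' Segment a trace into consecutive 24-hour day periods
#'
#' Builds the analysis windows used by every downstream summary: consecutive
#' non-overlapping 24-h periods anchored at a configurable start time, each
#' split by wall clock into a night-time window `[night_start, day_start)` and
#' a day-time window covering the remainder. All intervals are half-open, so a
#' reading at a boundary belongs to exactly one period. By default periods
#' start at the night-time start (23:00), following the convention that a
#' "day" of CGM data runs from bedtime to bedtime.
#'
#' @param trace A [glucose_trace()].
#' @param night_start,day_start Clock times `"HH:MM"`; defaults 23:00 and
#'   06:30.
#' @param day_period_start Start of each 24-h period: a clock time `"HH:MM"`,
#'   or `"firstvalid"` to anchor at the participant's first reading (truncated
#'   to the minute). Default: `night_start`.
#' @return A tibble of day periods with columns `day_index`, `start`, `end`,
#'   `n_expected`, `n_readings`, `complete`, `minutes_missing`,
#'   `minutes_imputed`, plus attributes `night_start`/`day_start` (minutes
#'   after midnight) and `epoch_minutes`. Partial leading/trailing periods are
#'   emitted flagged incomplete.
#' @export
segment_days <- function(trace, night_start = "23:00", day_start = "06:30",
                         day_period_start = NULL) {
  stopifnot(inherits(trace, "glucose_trace"))
  ns <- clock_minutes(night_start)
  ds <- clock_minutes(day_start)
  if (ns == ds) stop("night_start and day_start must differ", call. = FALSE)
  r <- trace$readings
  if (nrow(r) == 0) stop("empty trace", call. = FALSE)
  t_first <- minute_floor(r$time[1])
  t_last <- minute_floor(r$time[nrow(r)])
  anchor <- day_period_start %||% ns
  if (identical(anchor, "firstvalid")) {
    start0 <- t_first
  } else {
    am <- clock_minutes(anchor)
    # latest occurrence of the anchor clock time at or before the first reading
    midnight <- t_first - as.difftime(minute_of_day(t_first), units = "mins")
    start0 <- minutes_after(midnight, am)
    if (start0 > t_first) start0 <- minutes_after(start0, -1440)
  }
  starts <- start0
  while (minutes_after(starts[length(starts)], 1440) <= t_last) {
    starts <- c(starts, minutes_after(starts[length(starts)], 1440))
  }
  ends <- minutes_after(starts, 1440)
  n_expected <- 1440L %/% trace$epoch_minutes
  rt <- minute_floor(r$time)
  n_readings <- vapply(seq_along(starts), function(i) {
    sum(rt >= starts[i] & rt < ends[i])
  }, integer(1))
  days <- tibble::tibble(
    day_index = seq_along(starts),
    start = as_wallclock(starts),
    end = as_wallclock(ends),
    n_expected = n_expected,
    n_readings = n_readings,
    complete = n_readings == n_expected,
    minutes_missing = (n_expected - n_readings) * trace$epoch_minutes,
    minutes_imputed = 0L
  )
  attr(days, "night_start") <- ns
  attr(days, "day_start") <- ds
  attr(days, "epoch_minutes") <- trace$epoch_minutes
  days
}
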