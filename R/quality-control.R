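# Quality control: outlier flagging on adjacent differences, complete-day
# determination, and the two imputation schemes (approximal, other-day).
# All completeness arithmetic happens on the device-native epoch grid so that
# the "288 readings per 5-min day" contract stays meaningful; resampling to
# the 1-min grid happens after imputation.

#' Flag outlier time-points on adjacent differences
#'
#' Sensor glucose distributions are often skewed, but the distribution of
#' differences between adjacent readings is closer to normal and — unlike the
#' SD of the values themselves — rescales with the sampling resolution. The
#' threshold is therefore `d = k * SD` of the participant's adjacent-difference
#' distribution (population SD). A time-point is flagged iff its value deviates
#' by more than `d` from **both** its previous and its next reading. Flags are
#' annotations for the researcher's review; no values are ever removed.
#' Detection runs on device-native readings, before resampling.
#'
#' @param trace A [glucose_trace()] with at least 3 native readings.
#' @param k Positive threshold multiplier; default 5.
#' @return `POSIXct` vector of flagged timestamps (possibly empty).
#' @export
detect_outliers <- function(trace, k = 5) {
  stopifnot(inherits(trace, "glucose_trace"), k > 0)
  g <- trace$readings$glucose
  n <- length(g)
  empty <- trace$readings$time[0]
  if (n < 3) return(empty)
  d <- diff(g)
  if (length(d) < 3) return(empty)  # SD of < 3 differences is meaningless
  thr <- k * sd_pop(d)
  i <- 2:(n - 1)
  hit <- abs(g[i] - g[i - 1]) > thr & abs(g[i] - g[i + 1]) > thr
  trace$readings$time[i][hit]
}

#' @rdname detect_outliers
#' @return `flag_outliers()` returns the trace with `$outliers` set.
#' @export
flag_outliers <- function(trace, k = 5) {
  trace$outliers <- detect_outliers(trace, k)
  trace
}

#' Keep only complete day periods
#'
#' A day is complete when it holds a glucose value at every expected
#' device-native epoch: `1440 / epoch_minutes` readings (e.g. 288 for 5-min
#' epochs). Imputed readings count, so a successfully imputed day passes.
#'
#' @param days Day-period tibble from [segment_days()].
#' @param trace The trace whose readings determine completeness (native grid,
#'   after any imputation).
#' @return The subset of `days` that are complete, with refreshed counts.
#' @export
complete_day_filter <- function(days, trace) {
  days <- refresh_day_counts(days, trace)
  days[days$complete, ]
}

#' @noRd
refresh_day_counts <- function(days, trace) {
  rt <- minute_floor(trace$readings$time)
  imput <- startsWith(trace$readings$source, "imputed")
  for (i in seq_len(nrow(days))) {
    inside <- rt >= days$start[i] & rt < days$end[i]
    days$n_readings[i] <- sum(inside)
    days$minutes_imputed[i] <-
      as.integer(sum(inside & imput) * trace$epoch_minutes)
    days$minutes_missing[i] <-
      (days$n_expected[i] - days$n_readings[i]) * trace$epoch_minutes
    days$complete[i] <- days$n_readings[i] == days$n_expected[i]
  }
  days
}

# The expected native-epoch grid of one day period, phase-aligned with the
# trace's readings. Returns times plus a presence/observed mask.
#' @noRd
native_day_grid <- function(trace, day) {
  e <- trace$epoch_minutes
  rt <- minute_index(minute_floor(trace$readings$time))
  s <- minute_index(day$start)
  phase <- if (length(rt)) (rt[1] - s) %% e else 0L
  grid <- s + phase + e * (0:(1440L %/% e - 1L))
  pos <- match(grid, rt)
  list(
    minute = grid,
    pos = pos,                       # row index into trace$readings, NA if gap
    present = !is.na(pos),
    observed = !is.na(pos) & trace$readings$source[pmax(pos, 1L)] == "observed"
  )
}

#' @noRd
gap_runs <- function(present) {
  r <- rle(present)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tibble::tibble(i = starts[!r$values], j = ends[!r$values])
}

#' @noRd
next_section <- function(trace) max(trace$readings$section) + 1L

#' @noRd
insert_readings <- function(trace, minutes, glucose, source, section) {
  add <- tibble::tibble(
    time = as.POSIXct(minutes * 60, origin = "1970-01-01", tz = GLUCOTRACE_TZ),
    glucose = glucose, source = source, section = section
  )
  r <- dplyr::arrange(dplyr::bind_rows(trace$readings, add), .data$time)
  trace$readings <- r
  trace
}

#' Approximal imputation of a day's missing spans
#'
#' Fills each missing span of an eligible day from the data immediately
#' flanking it within the same day: the gap is split in half, the left half is
#' replaced by the block of readings directly before the gap and the right
#' half by the block directly after, both in forward time order. For a gap at
#' native-grid indices `i..j`, the left half ends at
#' `k = i + floor((j - i + 1) / 2) - 1` and receives indices `2i-k-1 .. i-1`;
#' the right half (from `k + 1`) receives `j+1 .. 2j-k`. The floor in `k`
#' means an odd-length gap gives the extra point to the right half; a
#' length-1 gap is filled entirely from its right neighbour. A day is
#' eligible only if it has
#' at most 6 h missing in total and every gap is strictly shorter than 2 h;
#' the flanking blocks must consist of observed readings inside the same day.
#'
#' Imputed points are flagged `imputed_approximal_left` /
#' `imputed_approximal_right` and each half opens a new section, so that
#' transitions into, out of, and between the halves are excluded from
#' order-sensitive statistics. Observed readings are never altered.
#'
#' @param trace A native-epoch [glucose_trace()].
#' @param day One row of the [segment_days()] tibble.
#' @return A list: `trace` (imputed or unchanged), `imputed` (logical),
#'   `minutes_imputed`, `reason` (`NA` on success, otherwise why the day was
#'   left alone).
#' @export
approximal_impute <- function(trace, day) {
  stopifnot(inherits(trace, "glucose_trace"))
  e <- trace$epoch_minutes
  grid <- native_day_grid(trace, day)
  gaps <- gap_runs(grid$present)
  if (nrow(gaps) == 0) {
    return(list(trace = trace, imputed = FALSE, minutes_imputed = 0L,
                reason = "no_missing_data"))
  }
  gap_min <- (gaps$j - gaps$i + 1L) * e
  if (sum(gap_min) > 360L) {
    return(list(trace = trace, imputed = FALSE, minutes_imputed = 0L,
                reason = "over_6h_missing"))
  }
  if (any(gap_min >= 120L)) {
    return(list(trace = trace, imputed = FALSE, minutes_imputed = 0L,
                reason = "gap_2h_or_longer"))
  }
  n <- length(grid$minute)
  plan <- vector("list", nrow(gaps))
  for (gi in seq_len(nrow(gaps))) {
    i <- gaps$i[gi]; j <- gaps$j[gi]
    k <- i + floor((j - i + 1) / 2) - 1
    left_to <- if (k >= i) i:k else integer()
    left_from <- if (k >= i) (2 * i - k - 1):(i - 1) else integer()
    right_to <- if (j >= k + 1) (k + 1):j else integer()
    right_from <- if (j >= k + 1) (j + 1):(2 * j - k) else integer()
    src <- c(left_from, right_from)
    if (length(src) && (min(src) < 1 || max(src) > n ||
                        !all(grid$observed[src]))) {
      return(list(trace = trace, imputed = FALSE, minutes_imputed = 0L,
                  reason = "insufficient_flanking_data"))
    }
    # capture donor values now: insertions below renumber trace rows
    plan[[gi]] <- list(
      left_to = left_to,
      left_vals = trace$readings$glucose[grid$pos[left_from]],
      right_to = right_to,
      right_vals = trace$readings$glucose[grid$pos[right_from]]
    )
  }
  for (p in plan) {
    if (length(p$left_to)) {
      trace <- insert_readings(trace, grid$minute[p$left_to], p$left_vals,
                               "imputed_approximal_left", next_section(trace))
    }
    if (length(p$right_to)) {
      trace <- insert_readings(trace, grid$minute[p$right_to], p$right_vals,
                               "imputed_approximal_right", next_section(trace))
    }
  }
  list(trace = trace, imputed = TRUE,
       minutes_imputed = as.integer(sum(gap_min)), reason = NA_character_)
}

#' Other-day imputation of a day's missing spans
#'
#' Fills each missing span with time-matched data from another day of the same
#' participant: among all other segmented days where the same clock-time span
#' is completely observed, one donor day is selected uniformly at random (one
#' independent draw per gap) and its values are copied in. Donor spans must be
#' observed data — imputations are never imputed from. Eligibility requires at
#' most 6 h missing in the day. Imputed points are flagged `imputed_otherday`
#' and open a new section.
#'
#' @param trace A native-epoch [glucose_trace()].
#' @param day One row of the [segment_days()] tibble.
#' @param days The full day-period tibble (donor candidates).
#' @param rng_seed Optional integer; when given, donor draws use this seed via
#'   a local RNG state (reproducible and side-effect free). When `NULL`, the
#'   current RNG stream is used (the pipeline seeds it once per run).
#' @return Same shape as [approximal_impute()].
#' @export
otherday_impute <- function(trace, day, days, rng_seed = NULL) {
  stopifnot(inherits(trace, "glucose_trace"))
  e <- trace$epoch_minutes
  grid <- native_day_grid(trace, day)
  gaps <- gap_runs(grid$present)
  if (nrow(gaps) == 0) {
    return(list(trace = trace, imputed = FALSE, minutes_imputed = 0L,
                reason = "no_missing_data"))
  }
  gap_min <- (gaps$j - gaps$i + 1L) * e
  if (sum(gap_min) > 360L) {
    return(list(trace = trace, imputed = FALSE, minutes_imputed = 0L,
                reason = "over_6h_missing"))
  }
  rt <- minute_index(minute_floor(trace$readings$time))
  obs <- trace$readings$source == "observed"
  others <- days$day_index[days$day_index != day$day_index]
  draw_all <- function() {
    plan <- vector("list", nrow(gaps))
    for (gi in seq_len(nrow(gaps))) {
      i <- gaps$i[gi]; j <- gaps$j[gi]
      span <- grid$minute[i:j]
      donors <- others[vapply(others, function(d) {
        shift <- (d - day$day_index) * 1440L
        pos <- match(span + shift, rt)
        all(!is.na(pos)) && all(obs[pos])
      }, logical(1))]
      if (length(donors) == 0) return(NULL)
      pick <- donors[sample.int(length(donors), 1L)]
      shift <- (pick - day$day_index) * 1440L
      plan[[gi]] <- list(to = span,
                         glucose = trace$readings$glucose[match(span + shift, rt)])
    }
    plan
  }
  plan <- if (is.null(rng_seed)) draw_all() else {
    withr::with_seed(as.integer(rng_seed), draw_all())
  }
  if (is.null(plan)) {
    return(list(trace = trace, imputed = FALSE, minutes_imputed = 0L,
                reason = "no_eligible_donor_day"))
  }
  for (p in plan) {
    trace <- insert_readings(trace, p$to, p$glucose, "imputed_otherday",
                             next_section(trace))
  }
  list(trace = trace, imputed = TRUE,
       minutes_imputed = as.integer(sum(gap_min)), reason = NA_character_)
}

#' Apply the selected missing-data approach to every day
#'
#' Runs [approximal_impute()] or [otherday_impute()] over each incomplete day
#' (complete days and fully-empty days are untouched), then refreshes the day
#' table's completeness counts. `method = "none"` is the complete-days
#' approach: nothing is filled and incomplete days simply fail
#' [complete_day_filter()].
#'
#' @param trace Native-epoch [glucose_trace()].
#' @param days Tibble from [segment_days()].
#' @param method `"none"`, `"approximal"` or `"otherday"`.
#' @param seed Integer seed for other-day donor draws.
#' @return List: `trace`, `days` (refreshed, with an `impute_reason` column),
#'   `n_days_imputed`.
#' @export
impute_missing <- function(trace, days, method = c("none", "approximal",
                                                   "otherday"), seed = 0L) {
  method <- match.arg(method)
  days$impute_reason <- NA_character_
  n_imp <- 0L
  if (method != "none") {
    if (method == "otherday") {
      seed <- as.integer(seed) %% .Machine$integer.max
    }
    for (i in seq_len(nrow(days))) {
      if (days$complete[i] || days$n_readings[i] == 0L) next
      res <- switch(
        method,
        approximal = approximal_impute(trace, days[i, ]),
        otherday = otherday_impute(trace, days[i, ], days,
                                   rng_seed = seed + days$day_index[i])
      )
      trace <- res$trace
      days$impute_reason[i] <- res$reason
      if (res$imputed) n_imp <- n_imp + 1L
    }
  }
  days2 <- refresh_day_counts(days, trace)
  days2$impute_reason <- days$impute_reason
  list(trace = trace, days = days2, n_days_imputed = n_imp)
}

#' Per-participant quality-control report
#'
#' @param trace Trace after outlier flagging and (optional) imputation.
#' @param days Refreshed day tibble.
#' @return List with `summary` (one-row tibble of counts), `days` (per-day QC
#'   rows including per-day outlier counts) and `outliers` (timestamps).
#' @export
qc_report <- function(trace, days) {
  ot <- trace$outliers
  n_out_day <- vapply(seq_len(nrow(days)), function(i) {
    sum(ot >= days$start[i] & ot < days$end[i])
  }, integer(1))
  day_rows <- tibble::tibble(
    participant_id = trace$participant_id,
    day_index = days$day_index,
    start = days$start,
    n_expected = days$n_expected,
    n_readings = days$n_readings,
    minutes_missing = days$minutes_missing,
    minutes_imputed = days$minutes_imputed,
    complete = days$complete,
    n_outliers = n_out_day,
    impute_reason = if ("impute_reason" %in% names(days)) {
      days$impute_reason
    } else {
      NA_character_
    }
  )
  list(
    summary = tibble::tibble(
      participant_id = trace$participant_id,
      n_outliers = length(ot),
      n_days_total = nrow(days),
      n_days_complete = sum(days$complete),
      n_days_imputed = sum(days$minutes_imputed > 0 & days$complete)
    ),
    days = day_rows,
    outliers = ot
  )
}
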