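# Synthetic CGM fixture generator. Emulates the structure of real sensor
# exports — a circadian baseline with a night-time nadir, meal excursions with
# matching meal events, missing spans, and isolated spike artifacts — with
# planted ground truth returned alongside for test assertions.

#' Generate a synthetic CGM fixture
#'
#' Builds a reproducible synthetic glucose trace in the generic dialect. The
#' underlying model is a circadian sinusoid (baseline 5.2 mmol/L, amplitude
#' 0.5, nadir around 04:00) plus small Gaussian sensor noise (SD 0.05
#' mmol/L), optionally with:
#' \describe{
#'   \item{`smooth`}{baseline + noise only; no gaps, no artifacts.}
#'   \item{`meals`}{three daily meal excursions (07:30, 12:30, 18:30; gamma-
#'     shaped bump, peak +2 mmol/L about 45 min after the meal) with matching
#'     meal events recorded.}
#'   \item{`gappy`}{`meals`, plus one 90-minute missing span per day from the
#'     second day on (03:00–04:30) — short enough for approximal imputation
#'     (< 2 h) and leaving day 1 complete as an other-day donor.}
#'   \item{`spiky`}{`smooth`, plus one isolated spike artifact per day at a
#'     random interior epoch, placed 10 adjacent-difference SDs above the
#'     larger of its two neighbours.}
#' }
#' Readings start at 23:00 (the default day-period start) and cover `n_days`
#' full periods plus the closing boundary reading.
#'
#' @param profile `"smooth"`, `"meals"`, `"gappy"` or `"spiky"`.
#' @param n_days Number of 24-h day periods (>= 1).
#' @param epoch_minutes Native epoch spacing: 1, 5 or 15.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments.
#' @param dir Optional directory; when given, writes
#'   `<participant_id>.csv` (generic dialect) and
#'   `<participant_id>_truth.json` there.
#' @param participant_id Identifier; default derives from profile and seed.
#' @return List: `trace` (a [glucose_trace()]), `truth` (planted ground truth:
#'   `gap_spans`, `spike_times`, `meal_times`, `day_true_auc` — per-day
#'   time-average of the pre-gap trace), and when `dir` is given `csv_path` /
#'   `truth_path`.
#' @export
#' @examples
#' fx <- generate_fixture("meals", n_days = 2, epoch_minutes = 5, seed = 1)
#' fx$trace
generate_fixture <- function(profile = c("smooth", "meals", "gappy", "spiky"),
                             n_days = 1, epoch_minutes = 5, seed = 0,
                             dir = NULL, participant_id = NULL) {
  profile <- match.arg(profile)
  stopifnot(n_days >= 1, epoch_minutes %in% c(1L, 5L, 15L))
  n_days <- as.integer(n_days)
  epoch_minutes <- as.integer(epoch_minutes)
  participant_id <- participant_id %||%
    sprintf("%s_%dd_%dmin_s%d", profile, n_days, epoch_minutes, seed)
  t0 <- as.POSIXct("2024-03-01 23:00:00", tz = GLUCOTRACE_TZ)
  n <- as.integer(n_days * 1440 / epoch_minutes) + 1L  # + closing boundary
  offs <- epoch_minutes * (0:(n - 1L))                 # minutes since t0
  times <- minutes_after(t0, offs)
  clock <- (minute_of_day(t0) + offs) %% 1440
  with_meals <- profile %in% c("meals", "gappy")
  meal_clock <- c(450, 750, 1110)  # 07:30, 12:30, 18:30
  build <- function() {
    g <- 5.2 + 0.5 * sin(2 * pi * (clock - 600) / 1440)
    if (with_meals) {
      for (d in 0:(n_days - 1)) {
        for (mc in meal_clock) {
          meal_off <- (mc - minute_of_day(t0)) %% 1440 + d * 1440
          dt <- offs - meal_off
          bump <- ifelse(dt > 0, 2.0 * (dt / 45) * exp(1 - dt / 45), 0)
          g <- g + bump
        }
      }
    }
    g + stats::rnorm(n, sd = 0.05)
  }
  res <- withr::with_seed(as.integer(seed), {
    g <- build()
    day_idx <- pmin(offs %/% 1440L, n_days - 1L)
    day_true_auc <- vapply(0:(n_days - 1), function(d) {
      sel <- offs >= d * 1440 & offs <= (d + 1) * 1440
      auc_per_minute(g[sel], offs[sel])
    }, numeric(1))
    spike_times <- times[0]
    if (profile == "spiky") {
      amp <- 10 * sd_pop(diff(g))
      # one spike per day at a random interior epoch, away from day edges
      per_day <- 1440L %/% epoch_minutes
      spike_at <- vapply(0:(n_days - 1), function(d) {
        d * per_day + sample(3:(per_day - 3), 1L)
      }, integer(1)) + 1L
      # the spike sits 10 diff-SDs above the larger of its two neighbours,
      # so its deviation from both exceeds the flagging threshold by design
      g[spike_at] <- pmax(g[spike_at - 1L], g[spike_at + 1L]) + amp
      spike_times <- times[spike_at]
    }
    gap_spans <- tibble::tibble(day = integer(), start = times[0],
                                end = times[0])
    keep <- rep(TRUE, n)
    if (profile == "gappy" && n_days >= 2) {
      for (d in 1:(n_days - 1)) {
        gs <- (240 - minute_of_day(t0)) %% 1440 + d * 1440  # 03:00
        drop <- offs >= gs & offs < gs + 90
        keep[drop] <- FALSE
        gap_spans <- dplyr::bind_rows(gap_spans, tibble::tibble(
          day = d + 1L, start = minutes_after(t0, gs),
          end = minutes_after(t0, gs + 90)
        ))
      }
    }
    list(g = g, keep = keep, day_true_auc = day_true_auc,
         spike_times = spike_times, gap_spans = gap_spans)
  })
  events <- if (with_meals) {
    mt <- sort(unlist(lapply(0:(n_days - 1), function(d) {
      (meal_clock - minute_of_day(t0)) %% 1440 + d * 1440
    })))
    tibble::tibble(time = minutes_after(t0, mt), kind = "meal")
  } else {
    NULL
  }
  trace <- glucose_trace(times[res$keep], res$g[res$keep],
                         participant_id = participant_id,
                         epoch_minutes = epoch_minutes, events = events)
  truth <- list(
    gap_spans = res$gap_spans,
    spike_times = res$spike_times,
    meal_times = if (is.null(events)) times[0] else events$time,
    day_true_auc = res$day_true_auc
  )
  out <- list(trace = trace, truth = truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    out$csv_path <- file.path(dir, paste0(participant_id, ".csv"))
    write_cgm_file(trace, out$csv_path)
    out$truth_path <- file.path(dir, paste0(participant_id, "_truth.json"))
    jsonlite::write_json(
      list(
        gap_spans = within(as.data.frame(truth$gap_spans), {
          start <- format(start, "%Y-%m-%dT%H:%M:%S")
          end <- format(end, "%Y-%m-%dT%H:%M:%S")
        }),
        spike_times = format(truth$spike_times, "%Y-%m-%dT%H:%M:%S"),
        meal_times = format(truth$meal_times, "%Y-%m-%dT%H:%M:%S"),
        day_true_auc = truth$day_true_auc
      ),
      out$truth_path, auto_unbox = TRUE, digits = NA
    )
  }
  out
}
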