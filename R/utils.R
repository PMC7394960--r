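# Internal helpers shared across modules. All timestamps are naive local
# wall-clock times held as POSIXct in UTC; no DST arithmetic is ever applied,
# so one day period is always exactly 1440 grid minutes.

GLUCOTRACE_TZ <- "UTC"
MGDL_PER_MMOL <- 18.016

#' @noRd
as_wallclock <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- GLUCOTRACE_TZ
    return(x)
  }
  as.POSIXct(x, tz = GLUCOTRACE_TZ)
}

# Truncate (never round) timestamps to whole minutes.
#' @noRd
minute_floor <- function(t) {
  as.POSIXct(floor(as.numeric(t) / 60) * 60,
             origin = "1970-01-01", tz = GLUCOTRACE_TZ)
}

# Integer minute index since the epoch; the unit of all grid arithmetic.
#' @noRd
minute_index <- function(t) {
  as.integer(floor(as.numeric(t) / 60))
}

#' @noRd
minutes_after <- function(t, m) {
  t + as.difftime(m, units = "mins")
}

# Parse "HH:MM" into minutes after midnight.
#' @noRd
clock_minutes <- function(x) {
  if (is.numeric(x)) {
    stopifnot(x >= 0, x < 1440)
    return(as.integer(x))
  }
  m <- regmatches(x, regexec("^([01]?[0-9]|2[0-3]):([0-5][0-9])$", x))[[1]]
  if (length(m) != 3) {
    stop("malformed clock time '", x, "'; expected HH:MM", call. = FALSE)
  }
  as.integer(m[2]) * 60L + as.integer(m[3])
}

#' @noRd
minute_of_day <- function(t) {
  minute_index(t) %% 1440L
}

# Membership in the half-open wall-clock window [from, to), wrapping midnight
# when from >= to.
#' @noRd
in_clock_window <- function(t, from, to) {
  m <- minute_of_day(t)
  if (from < to) m >= from & m < to else m >= from | m < to
}

# Population SD (denominator n), the convention used for the outlier threshold.
#' @noRd
sd_pop <- function(x) {
  n <- length(x)
  if (n == 0) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
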