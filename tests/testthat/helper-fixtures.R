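# Shared fixture builders and independent oracles.

T0 <- as.POSIXct("2024-03-01 23:00:00", tz = "UTC")

# Trace from offsets (minutes after T0) and values.
make_trace <- function(offsets_min, glucose, epoch = NULL, id = "t",
                       events = NULL) {
  glucose_trace(T0 + 60 * offsets_min, glucose, participant_id = id,
                epoch_minutes = epoch, events = events)
}

# A complete 1-min-epoch day (1440 readings starting 23:00) from a value
# vector, plus the closing boundary reading when `close = TRUE`.
make_day_trace <- function(values, close = FALSE, id = "t") {
  n <- 1440L + as.integer(close)
  stopifnot(length(values) >= n)
  make_trace(0:(n - 1L), values[1:n], epoch = 1L, id = id)
}

# Brute-force sliding-window fasting-proxy oracle.
oracle_fasting <- function(x, window = 30L) {
  min(vapply(1:(length(x) - window + 1L),
             function(i) mean(x[i:(i + window - 1L)]), numeric(1)))
}

# Brute-force trapezoid AUC per minute over a contiguous 1-min segment.
oracle_auc <- function(x) {
  sum((x[-length(x)] + x[-1]) / 2) / (length(x) - 1)
}

# Brute-force outlier scan: population-SD threshold on adjacent differences.
oracle_outliers <- function(g, k = 5) {
  d <- diff(g)
  thr <- k * sqrt(mean((d - mean(d))^2))
  i <- 2:(length(g) - 1)
  i[abs(g[i] - g[i - 1]) > thr & abs(g[i] - g[i + 1]) > thr]
}

# A smooth circadian day of values on the 1-min grid (no noise).
smooth_day <- function(n = 1441, baseline = 5.2, amp = 0.5) {
  clock <- (23 * 60 + 0:(n - 1)) %% 1440
  baseline + amp * sin(2 * pi * (clock - 600) / 1440)
}
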