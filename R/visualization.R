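# Trace and Poincare plots for manual QC review. The data behind each plot is
# exposed as a pure function of the trace so marker sets and pair sets are
# unit-testable without comparing rendered pixels.

#' Data behind a sensor glucose trace plot
#'
#' @param trace A [glucose_trace()].
#' @return List: `readings`, `events` (non-calibration), `calibration`
#'   (capillary readings with values), `outliers` (flagged readings),
#'   `imputed_spans` (one row per contiguous imputed span) and
#'   `marker_counts` (named counts by marker kind).
#' @export
trace_plot_data <- function(trace) {
  r <- trace$readings
  ev <- trace$events
  cal <- ev[ev$kind == "calibration", ]
  ev <- ev[ev$kind != "calibration", ]
  out_rows <- r[r$time %in% trace$outliers, ]
  imput <- startsWith(r$source, "imputed")
  spans <- if (any(imput)) {
    m <- minute_index(r$time)
    im <- which(imput)
    brk <- cumsum(c(1L, as.integer(diff(m[im]) > 60 |
                                     diff(r$section[im]) != 0)))
    dplyr::summarise(
      dplyr::group_by(tibble::tibble(t = r$time[im], s = r$source[im],
                                     g = brk), .data$g),
      start = min(.data$t), end = max(.data$t), source = .data$s[1],
      .groups = "drop"
    )[, c("start", "end", "source")]
  } else {
    tibble::tibble(start = r$time[0], end = r$time[0], source = character())
  }
  counts <- c(table(ev$kind), outlier = nrow(out_rows),
              calibration = nrow(cal))
  list(readings = r, events = ev, calibration = cal, outliers = out_rows,
       imputed_spans = spans, marker_counts = counts)
}

#' Plot a sensor glucose trace
#'
#' Time on x, glucose (mmol/L) on y; event markers by kind as vertical lines,
#' capillary calibration readings overlaid as points, flagged outliers
#' highlighted, and imputed spans shaded.
#'
#' @param trace A [glucose_trace()].
#' @param file Optional output path (`.png`, `.pdf` or `.svg`); when given the
#'   plot is saved there.
#' @param show_events,show_outliers,show_imputed Toggle the marker layers.
#' @param width,height Device size in inches.
#' @return The ggplot object, invisibly, with the [trace_plot_data()] attached
#'   as attribute `"plot_data"`.
#' @export
plot_trace <- function(trace, file = NULL, show_events = TRUE,
                       show_outliers = TRUE, show_imputed = TRUE,
                       width = 10, height = 4) {
  pd <- trace_plot_data(trace)
  if (nrow(pd$readings) == 0) {
    warning("empty trace: no plot produced", call. = FALSE)
    return(invisible(NULL))
  }
  p <- ggplot2::ggplot(pd$readings,
                       ggplot2::aes(x = .data$time, y = .data$glucose)) +
    ggplot2::geom_line(colour = "grey30", linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "Sensor glucose (mmol/L)",
                  title = trace$participant_id) +
    ggplot2::theme_minimal()
  if (show_imputed && nrow(pd$imputed_spans)) {
    p <- p + ggplot2::geom_rect(
      data = pd$imputed_spans,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "steelblue", alpha = 0.15
    )
  }
  if (show_events && nrow(pd$events)) {
    p <- p + ggplot2::geom_vline(
      data = pd$events,
      ggplot2::aes(xintercept = .data$time, colour = .data$kind),
      linetype = "dashed", alpha = 0.7
    )
  }
  if (show_events && nrow(pd$calibration)) {
    p <- p + ggplot2::geom_point(
      data = pd$calibration[!is.na(pd$calibration$glucose), ],
      ggplot2::aes(x = .data$time, y = .data$glucose),
      shape = 4, size = 2, colour = "purple"
    )
  }
  if (show_outliers && nrow(pd$outliers)) {
    p <- p + ggplot2::geom_point(
      data = pd$outliers,
      ggplot2::aes(x = .data$time, y = .data$glucose),
      shape = 21, size = 2.5, colour = "red", fill = NA
    )
  }
  attr(p, "plot_data") <- pd
  if (!is.null(file)) save_plot_file(p, file, width, height)
  invisible(p)
}

#' Lag-1 pairs behind a Poincare plot
#'
#' Pairs `(SG_t, SG_{t+1})` over consecutive minutes of the resampled grid,
#' within contiguous spans only: no pair is formed across a gap or an
#' imputation-section boundary.
#'
#' @param trace A [glucose_trace()]; resampled first if necessary.
#' @return Tibble with columns `x` (value at t) and `y` (value at t+1).
#' @export
poincare_pairs <- function(trace) {
  if (!trace$resampled) trace <- resample_to_1min(trace)
  r <- trace$readings
  if (nrow(r) < 2) return(tibble::tibble(x = numeric(), y = numeric()))
  m <- minute_index(r$time)
  ok <- diff(m) == 1L & diff(r$section) == 0L
  tibble::tibble(x = r$glucose[-nrow(r)][ok], y = r$glucose[-1][ok])
}

#' Poincare plot of lag-1 glucose stability
#'
#' Scatter of each minute's glucose against the next minute's, with the
#' ascending diagonal for reference. Slowly varying traces hug the diagonal;
#' erratic (possibly erroneous) traces spread away from it.
#'
#' @inheritParams plot_trace
#' @return The ggplot object, invisibly, with the pair tibble attached as
#'   attribute `"plot_data"`.
#' @export
plot_poincare <- function(trace, file = NULL, width = 5, height = 5) {
  pairs <- poincare_pairs(trace)
  if (nrow(pairs) == 0) {
    warning("fewer than 2 grid readings: no Poincare plot produced",
            call. = FALSE)
    return(invisible(NULL))
  }
  p <- ggplot2::ggplot(pairs, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.2, size = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "SG(t) (mmol/L)", y = "SG(t+1) (mmol/L)",
                  title = trace$participant_id) +
    ggplot2::theme_minimal()
  attr(p, "plot_data") <- pairs
  if (!is.null(file)) save_plot_file(p, file, width, height)
  invisible(p)
}

#' @noRd
save_plot_file <- function(p, file, width, height) {
  tryCatch(
    suppressMessages(ggplot2::ggsave(file, p, width = width, height = height,
                                     dpi = 100)),
    error = function(e) {
      warning("could not render plot to ", file, ": ", conditionMessage(e),
              call. = FALSE)
    }
  )
  invisible(file)
}
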