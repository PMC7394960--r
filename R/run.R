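# End-to-end pipeline: one input directory of per-participant CGM files, one
# output directory receiving <id>_summary.csv, <id>_qc.csv and plot files.
# Mirrors the command-line surface in exec/glucotrace.

#' Run configuration
#'
#' Bundles and validates every pipeline option. The two imputation approaches
#' are mutually exclusive per run; to compare all three missing-data
#' approaches (as recommended), run the pipeline three times.
#'
#' @param indir Directory of per-participant CGM CSV files.
#' @param outdir Output directory (created if absent).
#' @param device Device dialect name (see [device_dialect()]).
#' @param nightstart,daystart Clock times `"HH:MM"`; defaults 23:00 / 06:30.
#' @param dayperiodstart `"HH:MM"`, `"firstvalid"`, or `NULL` (= nightstart).
#' @param population `"general"`, `"pregnancy"` or `"diabetes"`.
#' @param hypo,hyper Optional custom thresholds (mmol/L, both or neither);
#'   mutually exclusive with a non-general `population`.
#' @param impute `"none"` (complete days, the default), `"approximal"` or
#'   `"otherday"`.
#' @param outlier_k Outlier threshold multiplier (> 0); default 5.
#' @param save_events Also write per-event summary rows.
#' @param seed Integer seed for other-day donor draws; default 0.
#' @param units `"mmol"` or `"mgdl"` (input conversion).
#' @param plots Render trace/Poincare plots (PNG) per participant.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(indir, outdir, device = "other",
                       nightstart = "23:00", daystart = "06:30",
                       dayperiodstart = NULL,
                       population = c("general", "pregnancy", "diabetes"),
                       hypo = NULL, hyper = NULL,
                       impute = c("none", "approximal", "otherday"),
                       outlier_k = 5, save_events = FALSE, seed = 0,
                       units = c("mmol", "mgdl"), plots = TRUE) {
  population <- match.arg(population)
  impute <- match.arg(impute)
  units <- match.arg(units)
  if (!dir.exists(indir)) stop("input directory not found: ", indir,
                               call. = FALSE)
  if ((!is.null(hypo) || !is.null(hyper)) && population != "general") {
    stop("custom thresholds and a population flag are mutually exclusive",
         call. = FALSE)
  }
  stopifnot(outlier_k > 0)
  clock_minutes(nightstart); clock_minutes(daystart)
  if (!is.null(dayperiodstart) && !identical(dayperiodstart, "firstvalid")) {
    clock_minutes(dayperiodstart)
  }
  structure(list(
    indir = indir, outdir = outdir, device = device,
    nightstart = nightstart, daystart = daystart,
    dayperiodstart = dayperiodstart, population = population,
    hypo = hypo, hyper = hyper, impute = impute, outlier_k = outlier_k,
    save_events = isTRUE(save_events), seed = as.integer(seed),
    units = units, plots = isTRUE(plots)
  ), class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' The YAML keys mirror the [run_config()] arguments.
#'
#' @param path YAML file path.
#' @param ... Overrides applied after the file is read.
#' @return A [run_config()].
#' @export
read_run_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  over <- list(...)
  vals[names(over)] <- over
  do.call(run_config, vals)
}

#' Process one participant's CGM file
#'
#' The per-file pipeline: read, outlier flagging, day segmentation, the
#' selected missing-data approach, completeness filtering, resampling to the
#' 1-min grid, six-domain summaries with across-day means, and the QC report.
#'
#' @param path CGM file path.
#' @param config A [run_config()].
#' @return List: `records`, `events`, `qc`, `trace` (resampled), `days`,
#'   `included` (tibble of included days), or `NULL` with a message when the
#'   participant has no included days.
#' @export
process_cgm_file <- function(path, config) {
  trace <- read_cgm_file(path, device_dialect(config$device),
                         units = config$units)
  trace <- flag_outliers(trace, k = config$outlier_k)
  days <- segment_days(trace, config$nightstart, config$daystart,
                       config$dayperiodstart)
  imp <- impute_missing(trace, days, method = config$impute,
                        seed = config$seed)
  trace <- imp$trace
  days <- imp$days
  qc <- qc_report(trace, days)
  included <- days[days$complete, ]
  resampled <- resample_to_1min(trace)
  if (nrow(included) == 0) {
    return(list(records = NULL, events = NULL, qc = qc, trace = resampled,
                days = days, included = included))
  }
  thr <- threshold_set(
    switch(config$population, pregnancy = "pregnancy",
           diabetes = "diabetes", "general"),
    hypo = config$hypo, hyper = config$hyper
  )
  summ <- summarise_trace(resampled, days, thresholds = thr,
                          save_events = config$save_events)
  records <- aggregate_summaries(summ$records)
  list(records = records, events = summ$events, qc = qc, trace = resampled,
       days = days, included = included)
}

#' Run the full pipeline over a directory of CGM files
#'
#' For every parseable file in `config$indir`: quality control, the selected
#' missing-data approach, summary derivation, and CSV/plot output into
#' `config$outdir` (`<id>_summary.csv`, `<id>_qc.csv`, `<id>_trace.png`,
#' `<id>_poincare.png`). Per-file parse failures are logged and skipped.
#' Identical config + inputs + seed give byte-identical summary CSVs.
#'
#' @param config A [run_config()], or the first argument to one (`indir`)
#'   with the remaining [run_config()] arguments in `...`.
#' @param ... Passed to [run_config()] when `config` is a path.
#' @return Invisibly, a tibble log with one row per input file:
#'   `file`, `participant_id`, `status`
#'   (`processed` / `no_included_days` / `parse_error`), `n_days_included`,
#'   `detail` (machine-readable reason or error message).
#' @export
run_glucotrace <- function(config, ...) {
  if (!inherits(config, "run_config")) config <- run_config(config, ...)
  files <- list.files(config$indir, pattern = "\\.csv$", full.names = TRUE)
  files <- files[!grepl("_truth\\.json$|_summary\\.csv$|_qc\\.csv$",
                        files)]
  if (length(files) == 0) {
    stop("no CSV files in input directory: ", config$indir, call. = FALSE)
  }
  if (!dir.exists(config$outdir)) dir.create(config$outdir, recursive = TRUE)
  set.seed(config$seed)
  log <- vector("list", length(files))
  for (i in seq_along(files)) {
    f <- files[i]
    res <- tryCatch(process_cgm_file(f, config), error = function(e) e)
    if (inherits(res, "error")) {
      message("skipping ", basename(f), ": ", conditionMessage(res))
      log[[i]] <- tibble::tibble(
        file = basename(f), participant_id = NA_character_,
        status = "parse_error", n_days_included = 0L,
        detail = conditionMessage(res)
      )
      next
    }
    pid <- res$qc$summary$participant_id
    write_qc_csv(res$qc, file.path(config$outdir, paste0(pid, "_qc.csv")))
    if (is.null(res$records)) {
      reasons <- stats::na.omit(res$days$impute_reason)
      log[[i]] <- tibble::tibble(
        file = basename(f), participant_id = pid,
        status = "no_included_days", n_days_included = 0L,
        detail = paste(unique(c("incomplete_days", reasons)), collapse = ";")
      )
      next
    }
    write_summary_csv(res$records,
                      file.path(config$outdir, paste0(pid, "_summary.csv")),
                      per_event = config$save_events, events = res$events)
    if (config$plots) {
      plot_trace(res$trace,
                 file.path(config$outdir, paste0(pid, "_trace.png")))
      plot_poincare(res$trace,
                    file.path(config$outdir, paste0(pid, "_poincare.png")))
    }
    log[[i]] <- tibble::tibble(
      file = basename(f), participant_id = pid, status = "processed",
      n_days_included = nrow(res$included),
      detail = NA_character_
    )
  }
  log <- dplyr::bind_rows(log)
  readr::write_csv(log, file.path(config$outdir, "run_log.csv"), na = "",
                   progress = FALSE)
  if (!any(log$status == "processed")) {
    warning("no participant could be processed", call. = FALSE)
  }
  invisible(log)
}
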