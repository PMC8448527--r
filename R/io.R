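# Trace, event and truth serialisation. CSV dialect: comma-separated,
# UTF-8, header row, '.' decimal.

#' Write a fluorescence trace as CSV
#'
#' Columns `time_s` (frame start time, s) and `f_over_f0`. When the trace
#' carries simulation ground truth (see [render_trace()]), a JSON sidecar
#' `<path>.json` is written with the true open counts, stationary P_O,
#' true NP_O and generator parameters.
#'
#' @param trace a [fluorescence_trace()].
#' @param path output CSV path.
#' @param sidecar write the truth sidecar when available (default TRUE).
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path, sidecar = TRUE) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  df <- data.frame(time_s = trace_times(trace), f_over_f0 = trace$values)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (sidecar && !is.null(trace$truth)) {
    tr <- trace$truth
    side <- list(
      open_counts = tr$open_counts,
      stationary_po = tr$stationary_po,
      true_npo = tr$true_npo,
      true_dwell_times = as.list(tr$true_dwell_times),
      params = unclass(tr$params),
      render = if (!is.null(trace$render)) unclass(trace$render))
    jsonlite::write_json(side, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a fluorescence trace from CSV
#'
#' Expects columns `time_s` and `f_over_f0` (or a single-column file of
#' F/F0 values plus an explicit `frame_rate`). The frame rate is inferred
#' from the median time step when a time column is present.
#'
#' @param path CSV path.
#' @param frame_rate frames/s; required when the file has no time column.
#' @return a [fluorescence_trace()].
#' @export
read_trace_csv <- function(path, frame_rate = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  if ("f_over_f0" %in% names(df) && "time_s" %in% names(df)) {
    dt <- stats::median(diff(df$time_s))
    if (!is.finite(dt) || dt <= 0) {
      if (is.null(frame_rate))
        stop("cannot infer frame rate from time column", call. = FALSE)
    } else frame_rate <- 1 / dt
    v <- df$f_over_f0
  } else {
    if (is.null(frame_rate))
      stop("no time column: frame_rate must be supplied", call. = FALSE)
    v <- df[[1]]
  }
  fluorescence_trace(v, frame_rate = frame_rate)
}

#' Write detected events as CSV
#'
#' Columns `start_s`, `peak_s`, `end_s`, `amplitude`, `auc` (times are
#' frame start times in seconds).
#'
#' @param events a [detect_events()] result.
#' @param trace the trace the events came from (for the frame rate).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, trace, path) {
  stopifnot(is.data.frame(events), inherits(trace, "fluorescence_trace"))
  fr <- trace$frame_rate
  df <- data.frame(start_s = (events$start_frame - 1) / fr,
                   peak_s = (events$peak_frame - 1) / fr,
                   end_s = (events$end_frame - 1) / fr,
                   amplitude = events$peak_amplitude,
                   auc = events$auc)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
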