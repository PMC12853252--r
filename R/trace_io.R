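# Sample-trace interchange format.
#
# The single ingestion format is a 9-column CSV at 1 kHz, one row per
# millisecond: time_ms, xl, yl, pl, vl, xr, yr, pr, vr.  Real recordings
# (e.g. EyeLink ASC sample exports) can be converted to this schema with any
# table tool; conversion itself is out of scope.  Trial events travel in a
# separate TSV with the `session_design` trial-table columns plus `onset_ms`
# (block time of scene onset).

#' Write / read a sample trace as CSV
#'
#' @param trace a `sample_trace`.
#' @param path CSV path.
#' @return `path` invisibly (writer); a `sample_trace` (reader).
#' @export
write_trace_csv <- function(trace, path) {
  df <- data.frame(time_ms = trace$time_ms,
                   xl = trace$xl, yl = trace$yl, pl = trace$pl,
                   vl = as.integer(trace$vl),
                   xr = trace$xr, yr = trace$yr, pr = trace$pr,
                   vr = as.integer(trace$vr))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @param events optional trial-event table (data frame or TSV path) with the
#'   trial-table columns and `onset_ms`.
#' @param fs_hz sampling rate of the recording.
#' @export
read_trace_csv <- function(path, events = NULL, fs_hz = 1000) {
  df <- utils::read.csv(path)
  need <- c("time_ms", "xl", "yl", "pl", "vl", "xr", "yr", "pr", "vr")
  if (!all(need %in% names(df)))
    stop("trace CSV must have columns: ", paste(need, collapse = ", "))
  if (is.character(events)) events <- utils::read.delim(events)
  structure(list(fs_hz = fs_hz, time_ms = df$time_ms,
                 xl = df$xl, yl = df$yl, pl = df$pl, vl = as.logical(df$vl),
                 xr = df$xr, yr = df$yr, pr = df$pr, vr = as.logical(df$vr),
                 events = events, ground_truth = NULL),
            class = "sample_trace")
}

#' Write ground truth as a JSON sidecar
#'
#' @param trace a simulated `sample_trace`.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(trace, path) {
  gt <- trace$ground_truth
  gt$params <- unclass(gt$params)
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "columns")
  invisible(path)
}
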