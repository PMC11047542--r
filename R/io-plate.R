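#' @include AllClasses.R
NULL

PLATE_COLUMNS <- c("time_s", "well", "sample", "conc_uM", "replicate", "signal")

#' Read a plate-reader time series from long-format CSV
#'
#' The expected layout is one row per (time point, well) with the header
#' `time_s, well, sample, conc_uM, replicate, signal` (comma-separated,
#' UTF-8, dot decimal). Times are deduplicated and sorted; wells are ordered
#' by (sample, concentration, replicate). Plate readers that log a cycle
#' index instead of seconds are handled by `time = "cycles"`, which maps
#' cycle `i` to `i * cycle_s` seconds.
#'
#' @param path CSV file path.
#' @param kind `"fluorescence"` (RFU) or `"absorbance"` (AU).
#' @param time `"seconds"` (default) when `time_s` already holds seconds, or
#'   `"cycles"` when it holds 0-based cycle indices.
#' @param cycle_s seconds per cycle, used only for `time = "cycles"`.
#' @return A \linkS4class{PlateTimeSeries}.
#' @seealso [writePlateTimeSeries()]
#' @export
readPlateTimeSeries <- function(path, kind = c("fluorescence", "absorbance"),
                                time = c("seconds", "cycles"), cycle_s = 60) {
  kind <- match.arg(kind)
  time <- match.arg(time)
  if (!file.exists(path)) format_error(sprintf("no such file: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(PLATE_COLUMNS, names(df))
  if (length(missing_cols)) {
    format_error(sprintf("plate CSV lacks column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  if (time == "cycles") df$time_s <- df$time_s * cycle_s
  times <- sort(unique(df$time_s))
  wells <- unique(df[c("well", "sample", "conc_uM", "replicate")])
  sig <- matrix(NA_real_, nrow = length(times), ncol = nrow(wells))
  for (j in seq_len(nrow(wells))) {
    rows <- df[df$well == wells$well[j], ]
    if (nrow(rows) != length(times) ||
        !all(sort(rows$time_s) == times)) {
      validation_error(sprintf(
        "well '%s' is ragged: expected %d time points, found %d",
        wells$well[j], length(times), nrow(rows)))
    }
    sig[, j] <- rows$signal[order(rows$time_s)]
  }
  PlateTimeSeries(times, wells, sig, kind = kind)
}

#' Write a plate-reader time series to long-format CSV
#'
#' Inverse of [readPlateTimeSeries()]; a write/read round trip reproduces
#' the object exactly at double precision.
#'
#' @param x a \linkS4class{PlateTimeSeries}.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writePlateTimeSeries <- function(x, path) {
  wi <- wellInfo(x)
  sig <- signalMatrix(x)
  t <- plateTimes(x)
  df <- do.call(rbind, lapply(seq_len(nrow(wi)), function(j) {
    data.frame(time_s = t, well = wi$well[j], sample = wi$sample[j],
               conc_uM = wi$conc_uM[j], replicate = wi$replicate[j],
               signal = sig[, j])
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
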