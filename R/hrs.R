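#' @include AllClasses.R
NULL

#' Percent ROS reduction at one time point
#'
#' \deqn{100 (RFU_{control} - RFU_{sample}) / RFU_{control}} at the requested
#' time, where the control is the radical generator alone. No interpolation:
#' the time must be on the measurement grid. The result is invariant under a
#' common rescaling of all fluorescence values.
#'
#' @param tc a \linkS4class{RosTimecourse}.
#' @param sample sample row name.
#' @param atTime time in hours; must match a grid point.
#' @return Percent reduction (100 when the sample signal is fully
#'   suppressed; 0 when it equals the control).
#' @export
percentRosReduction <- function(tc, sample, atTime) {
  idx <- which(abs(tc@times - atTime) < 1e-9)
  if (!length(idx))
    oxi_stop(sprintf("time %g h not on the measurement grid (%s)", atTime,
                     paste(tc@times, collapse = ", ")),
             "oxicap_missing_timepoint_error")
  if (!sample %in% rownames(tc@rfu))
    validation_error(sprintf("sample '%s' not in time course", sample))
  ctrl <- tc@rfu[tc@controlLabel, idx]
  if (!is.finite(ctrl) || ctrl <= 0)
    validation_error("control RFU must be > 0 at the requested time")
  unname(100 * (ctrl - tc@rfu[sample, idx]) / ctrl)
}

#' Reductions for every sample at every time point
#'
#' Full matrix of percent ROS reductions relative to the control, plus a
#' per-sample flag stating whether the reduction is non-decreasing in time
#' (time-dependent scavenging).
#'
#' @param tc a \linkS4class{RosTimecourse} with at least 2 time points.
#' @return list with `reductions` (samples x times matrix, control excluded)
#'   and `monotone` (named logical vector). Both are empty when the time
#'   course contains only the control.
#' @export
timecourseSummary <- function(tc) {
  if (length(tc@times) < 2L)
    validation_error("need >= 2 time points")
  samples <- setdiff(rownames(tc@rfu), tc@controlLabel)
  red <- matrix(NA_real_, length(samples), length(tc@times),
                dimnames = list(samples, as.character(tc@times)))
  for (s in samples) {
    red[s, ] <- vapply(tc@times,
                       function(t) percentRosReduction(tc, s, t), numeric(1))
  }
  monotone <- apply(red, 1L, function(r) all(diff(r) >= 0))
  if (!length(samples)) monotone <- logical()
  list(reductions = red, monotone = monotone)
}
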