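#' @include AllClasses.R
NULL

#' Area under an ORAC fluorescence-decay curve
#'
#' Discrete, reference-normalized area: with `R1 = signal[r1Index]` the
#' fluorescence at the first recorded kinetic time point (immediately after
#' peroxyl-generator addition),
#' \deqn{AUC = R_1/R_1 + R_2/R_1 + \dots + R_n/R_1,}
#' a unit-step rectangular sum whose first term is exactly 1 and whose units
#' are counts of time points (cycles). This is the conventional plate-reader
#' formula and the package default. For irregular time grids an optional
#' trapezoidal mode integrates the normalized signal over real time instead
#' (units: seconds).
#'
#' The AUC is invariant under rescaling of the whole signal.
#'
#' @param signal numeric vector of fluorescence values (RFU).
#' @param r1Index 1-based index of the reference time point (default 1, the
#'   first post-addition reading). Terms before `r1Index` are excluded.
#' @param method `"cycles"` (unit-step sum, default) or `"trapezoid"`.
#' @param times acquisition times in seconds; required for
#'   `method = "trapezoid"`.
#' @return The dimensionless AUC (or seconds for the trapezoid mode).
#' @examples
#' computeAUC(c(5, 5, 5, 5, 5))   # 5: every term is 1
#' computeAUC(c(100, 80, 60))     # 2.4
#' @seealso [computeNetAUC()], [plateAUC()], [fitDoseResponse()]
#' @export
computeAUC <- function(signal, r1Index = 1L, method = c("cycles", "trapezoid"),
                       times = NULL) {
  method <- match.arg(method)
  if (!length(signal)) validation_error("signal must be non-empty")
  if (r1Index < 1L || r1Index > length(signal))
    validation_error("r1Index out of range")
  r1 <- signal[r1Index]
  if (!is.finite(r1) || r1 <= 0)
    oxi_stop(sprintf("degenerate reference: signal[%d] = %g must be > 0",
                     r1Index, r1), "oxicap_degenerate_reference_error")
  y <- signal[r1Index:length(signal)] / r1
  if (method == "cycles") return(sum(y))
  if (is.null(times)) validation_error("trapezoid mode needs 'times'")
  t <- times[r1Index:length(signal)]
  sum(diff(t) * (y[-1L] + y[-length(y)]) / 2)
}

#' Net AUC of an antioxidant well
#'
#' Difference between the antioxidant well's AUC and the blank (no
#' antioxidant) AUC. Negative values are legitimate output and indicate
#' pro-oxidant behavior; they are flagged, not clamped.
#'
#' @param aucAntioxidant,aucBlank AUC values from [computeAUC()].
#' @return The net AUC (possibly negative).
#' @export
computeNetAUC <- function(aucAntioxidant, aucBlank) {
  stopifnot_number(aucAntioxidant, "aucAntioxidant")
  stopifnot_number(aucBlank, "aucBlank")
  aucAntioxidant - aucBlank
}

#' Per-well AUC and net AUC table
#'
#' Computes the AUC of every well on the plate and subtracts the mean AUC of
#' the blank wells. Wells whose net AUC is negative are flagged as
#' pro-oxidant.
#'
#' @param plate a \linkS4class{PlateTimeSeries}.
#' @param blank sample label of the blank (no antioxidant) wells.
#' @param r1Index reference time-point index passed to [computeAUC()].
#' @return data.frame with one row per well: `well`, `sample`, `conc_uM`,
#'   `replicate`, `auc`, `net_auc`, `pro_oxidant`.
#' @export
plateAUC <- function(plate, blank = "BLANK", r1Index = 1L) {
  wi <- wellInfo(plate)
  sig <- signalMatrix(plate)
  if (!any(wi$sample == blank))
    validation_error(sprintf("no blank wells labelled '%s'", blank))
  auc <- vapply(seq_len(ncol(sig)),
                function(j) computeAUC(sig[, j], r1Index), numeric(1))
  blank_auc <- mean(auc[wi$sample == blank])
  net <- auc - blank_auc
  data.frame(well = wi$well, sample = wi$sample, conc_uM = wi$conc_uM,
             replicate = wi$replicate, auc = auc, net_auc = net,
             pro_oxidant = net < 0 & wi$sample != blank,
             row.names = NULL)
}

#' Fit an ORAC dose-response line for one sample
#'
#' Replicate net AUCs are averaged per concentration, then an ordinary
#' least-squares line (with intercept) is fitted through (concentration,
#' mean net AUC). The slope, in net-AUC units per uM, is the sample's ORAC
#' potency and the numerator/denominator of the Trolox equivalent.
#'
#' @param plate a \linkS4class{PlateTimeSeries}.
#' @param sample sample label to fit.
#' @param blank blank sample label.
#' @param r1Index reference time-point index for [computeAUC()].
#' @return A \linkS4class{DoseResponse}.
#' @seealso [troloxEquivalent()]
#' @export
fitDoseResponse <- function(plate, sample, blank = "BLANK", r1Index = 1L) {
  tab <- plateAUC(plate, blank = blank, r1Index = r1Index)
  tab <- tab[tab$sample == sample, , drop = FALSE]
  if (!nrow(tab))
    validation_error(sprintf("no wells for sample '%s'", sample))
  mean_net <- tapply(tab$net_auc, tab$conc_uM, mean)
  concs <- as.numeric(names(mean_net))
  doseResponse(sample, concs, as.numeric(mean_net))
}

#' Trolox equivalent from two dose-response fits
#'
#' Antioxidant capacity relative to the Trolox standard:
#' `TE = slope_sample / slope_Trolox`. Trolox against itself gives exactly 1.
#'
#' @param drSample \linkS4class{DoseResponse} of the sample.
#' @param drTrolox \linkS4class{DoseResponse} of the Trolox standard.
#' @return data.frame with columns `sample` and `te`.
#' @export
troloxEquivalent <- function(drSample, drTrolox) {
  if (abs(drSlope(drTrolox)) < 1e-12)
    oxi_stop("Trolox slope is zero: Trolox equivalent undefined",
             "oxicap_undefined_te_error")
  data.frame(sample = sampleName(drSample),
             te = drSlope(drSample) / drSlope(drTrolox))
}
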