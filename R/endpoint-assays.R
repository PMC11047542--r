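#' @include AllClasses.R
NULL

#' DPPH radical-scavenging percentage
#'
#' \deqn{Scavenging\% = 100 (Abs_{control} - Abs_{sample}) / Abs_{control}}
#' Scale-invariant in the pair of absorbances. Negative values (sample more
#' absorbing than the control) are reported as-is for diagnostic value.
#'
#' @param absControl control (DPPH without antioxidant) absorbance, AU; > 0.
#' @param absSample sample absorbance, AU (vectorized).
#' @return Scavenging percentage(s).
#' @examples
#' dpphScavenging(1.0, 0.5)  # 50
#' @export
dpphScavenging <- function(absControl, absSample) {
  stopifnot_number(absControl, "absControl")
  if (absControl <= 0)
    oxi_stop("degenerate control: absControl must be > 0",
             "oxicap_degenerate_control_error")
  100 * (absControl - absSample) / absControl
}

#' Scavenging percentages for a DPPH dose series
#'
#' @param series an \linkS4class{EndpointSeries} with `assay = "dpph"`.
#' @return data.frame with columns `conc_uM` and `scavenging`, ordered by
#'   increasing concentration.
#' @export
scavengingTable <- function(series) {
  ord <- order(series@concentrations)
  data.frame(conc_uM = series@concentrations[ord],
             scavenging = dpphScavenging(series@absControl,
                                         series@absorbances[ord]))
}

#' Estimate the IC50 of a DPPH dose series
#'
#' The IC50 is the concentration scavenging 50% of the initial radicals. It
#' is found by linear interpolation in concentration between the two
#' measured points bracketing 50% -- deliberately not a 4-parameter logistic
#' fit, which a sparse endpoint series cannot support. When the maximum
#' observed scavenging stays below 50% the result is "not reached" (common
#' for weak scavengers); a series crossing 50% more than once is ambiguous
#' and raises an error listing all crossings.
#'
#' @param series an \linkS4class{EndpointSeries} with `assay = "dpph"`.
#' @return An \linkS4class{IC50Estimate}.
#' @examples
#' s <- EndpointSeries("x", c(50, 70), c(0.6, 0.4), absControl = 1,
#'                     assay = "dpph")
#' ic50Value(estimateIC50(s))  # 60
#' @export
estimateIC50 <- function(series) {
  tab <- scavengingTable(series)
  if (nrow(tab) < 2L)
    oxi_stop("need >= 2 concentrations to estimate an IC50",
             "oxicap_insufficient_design_error")
  s <- tab$scavenging
  n <- nrow(tab)
  up <- which(s[-n] < 50 & s[-1L] >= 50)
  down <- which(s[-n] >= 50 & s[-1L] < 50)
  crossings <- sort(c(up, down))
  if (length(crossings) > 1L) {
    oxi_stop(sprintf(
      "series crosses 50%% more than once (between concentrations: %s)",
      paste(sprintf("%g-%g uM", tab$conc_uM[crossings],
                    tab$conc_uM[crossings + 1L]), collapse = ", ")),
      "oxicap_ambiguous_ic50_error")
  }
  if (max(s) < 50) {
    return(IC50Estimate(series@sample, NA_real_, FALSE,
                        data.frame(conc = numeric(), scavenging = numeric())))
  }
  if (!length(up)) {
    oxi_stop("scavenging already >= 50% at the lowest tested concentration",
             "oxicap_below_range_error")
  }
  i <- up
  frac <- (50 - s[i]) / (s[i + 1L] - s[i])
  ic50 <- tab$conc_uM[i] + frac * (tab$conc_uM[i + 1L] - tab$conc_uM[i])
  IC50Estimate(series@sample, ic50, TRUE,
               data.frame(conc = tab$conc_uM[c(i, i + 1L)],
                          scavenging = s[c(i, i + 1L)]))
}

#' FRAP relative reducing power
#'
#' \deqn{Relative\ reducing\ power\ \% =
#'   100 (Abs_{sample} - Abs_{min}) / (Abs_{max} - Abs_{min})}
#' with `absMin` the assay floor (control) and `absMax` the highest standard
#' (Trolox) absorbance, conventionally taken at the highest common tested
#' concentration. Values above 100% are legitimate (a sample out-reducing the
#' top standard). Adding a constant to all three absorbances leaves the
#' result unchanged.
#'
#' @param absSample sample absorbance(s), AU (vectorized).
#' @param absMin,absMax range absorbances, AU, with `absMax > absMin`.
#' @return Relative reducing power percentage(s).
#' @export
relativeReducingPower <- function(absSample, absMin, absMax) {
  stopifnot_number(absMin, "absMin")
  stopifnot_number(absMax, "absMax")
  if (absMax <= absMin)
    oxi_stop("degenerate range: absMax must exceed absMin",
             "oxicap_degenerate_range_error")
  100 * (absSample - absMin) / (absMax - absMin)
}

#' Fit a FRAP calibration line from a standard series
#'
#' OLS line of replicate-averaged absorbance against concentration for the
#' calibration standard (Trolox).
#'
#' @param series an \linkS4class{EndpointSeries} with `assay = "frap"`.
#' @return A \linkS4class{DoseResponse} (absorbance per uM).
#' @export
frapCalibration <- function(series) {
  doseResponse(series@sample, series@concentrations, series@absorbances)
}

#' Trolox-equivalent concentrations from a FRAP calibration
#'
#' Inverts the calibration line at every measured absorbance:
#' `TE_c = (Abs_c - intercept) / slope`, expressing each sample concentration
#' as the Trolox concentration producing the same absorbance.
#'
#' @param series an \linkS4class{EndpointSeries} with `assay = "frap"`.
#' @param troloxCalibration a \linkS4class{DoseResponse} from
#'   [frapCalibration()]; its slope must be positive.
#' @return data.frame with columns `conc_uM` and `te_uM`.
#' @export
frapTE <- function(series, troloxCalibration) {
  if (drSlope(troloxCalibration) <= 0)
    oxi_stop("invalid calibration: slope must be positive",
             "oxicap_invalid_calibration_error")
  data.frame(conc_uM = series@concentrations,
             te_uM = (series@absorbances - drIntercept(troloxCalibration)) /
                     drSlope(troloxCalibration))
}
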