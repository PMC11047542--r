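#' @include utils.R AllGenerics.R
NULL

## ---------------------------------------------------------------------------
## PlateTimeSeries
## ---------------------------------------------------------------------------

#' Plate-reader kinetic time series
#'
#' Container for per-well fluorescence or absorbance kinetics, built on
#' \linkS4class{SummarizedExperiment}: the `"signal"` assay holds a
#' (time point x well) matrix, `rowData` carries the acquisition times in
#' seconds (`time_s`, strictly increasing), and `colData` annotates each well
#' with `well`, `sample`, `conc_uM` (final antioxidant concentration, >= 0)
#' and `replicate` (>= 1). The assay kind (`"fluorescence"` or
#' `"absorbance"`) is stored in `metadata(x)$kind`.
#'
#' Wells are always ordered by (sample, concentration, replicate).
#'
#' @param times numeric vector of acquisition times in seconds, strictly
#'   increasing.
#' @param wells data.frame with columns `well`, `sample`, `conc_uM`,
#'   `replicate` (one row per well).
#' @param signal numeric matrix, `length(times)` rows by `nrow(wells)`
#'   columns, in RFU (fluorescence) or AU (absorbance).
#' @param kind `"fluorescence"` or `"absorbance"`.
#' @return A `PlateTimeSeries` object.
#' @seealso [readPlateTimeSeries()], [simulateOracPlate()], [plateAUC()]
#' @examples
#' p <- PlateTimeSeries(
#'   times  = c(0, 60, 120),
#'   wells  = data.frame(well = c("A1", "A2"), sample = c("Trolox", "BLANK"),
#'                       conc_uM = c(10, 0), replicate = c(1L, 1L)),
#'   signal = cbind(c(100, 90, 80), c(100, 60, 30)))
#' plateTimes(p)
#' wellInfo(p)
#' @aliases PlateTimeSeries-class
#' @export
PlateTimeSeries <- function(times, wells, signal,
                            kind = c("fluorescence", "absorbance")) {
  kind <- match.arg(kind)
  wells <- as.data.frame(wells)
  signal <- as.matrix(signal)
  required <- c("well", "sample", "conc_uM", "replicate")
  missing_cols <- setdiff(required, names(wells))
  if (length(missing_cols)) {
    format_error(sprintf("well table lacks column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  if (nrow(signal) != length(times)) {
    validation_error("signal must have one row per time point")
  }
  if (ncol(signal) != nrow(wells)) {
    validation_error("signal must have one column per well")
  }
  ord <- order(wells$sample, wells$conc_uM, wells$replicate)
  wells <- wells[ord, c(required, setdiff(names(wells), required)),
                 drop = FALSE]
  signal <- signal[, ord, drop = FALSE]
  colnames(signal) <- wells$well
  se <- SummarizedExperiment::SummarizedExperiment(
    assays  = list(signal = signal),
    rowData = S4Vectors::DataFrame(time_s = as.numeric(times)),
    colData = S4Vectors::DataFrame(wells, row.names = wells$well),
    metadata = list(kind = kind))
  methods::new("PlateTimeSeries", se)
}

#' @rdname PlateTimeSeries
#' @export
setClass("PlateTimeSeries", contains = "SummarizedExperiment")

setValidity("PlateTimeSeries", function(object) {
  msgs <- character()
  if (!"signal" %in% SummarizedExperiment::assayNames(object))
    msgs <- c(msgs, "assay 'signal' is required")
  t <- SummarizedExperiment::rowData(object)$time_s
  if (is.null(t) || !is.numeric(t)) {
    msgs <- c(msgs, "rowData must carry numeric 'time_s'")
  } else if (any(!is.finite(t)) || any(diff(t) <= 0)) {
    msgs <- c(msgs, "times must be finite and strictly increasing")
  }
  cd <- SummarizedExperiment::colData(object)
  for (col in c("well", "sample", "conc_uM", "replicate")) {
    if (!col %in% names(cd)) msgs <- c(msgs, sprintf("colData lacks '%s'", col))
  }
  if ("conc_uM" %in% names(cd) &&
      (any(!is.finite(cd$conc_uM)) || any(cd$conc_uM < 0)))
    msgs <- c(msgs, "concentrations must be finite and non-negative")
  if ("replicate" %in% names(cd) && any(cd$replicate < 1))
    msgs <- c(msgs, "replicate indices must be >= 1")
  kind <- S4Vectors::metadata(object)$kind
  if (is.null(kind) || !kind %in% c("fluorescence", "absorbance"))
    msgs <- c(msgs, "metadata 'kind' must be 'fluorescence' or 'absorbance'")
  if (length(msgs)) msgs else TRUE
})

#' @rdname oxicap-accessors
#' @export
setMethod("plateTimes", "PlateTimeSeries", function(x)
  SummarizedExperiment::rowData(x)$time_s)

#' @rdname oxicap-accessors
#' @export
setMethod("wellInfo", "PlateTimeSeries", function(x)
  as.data.frame(SummarizedExperiment::colData(x)))

#' @rdname oxicap-accessors
#' @export
setMethod("signalMatrix", "PlateTimeSeries", function(x)
  SummarizedExperiment::assay(x, "signal"))

#' @rdname oxicap-accessors
#' @export
setMethod("plateKind", "PlateTimeSeries", function(x)
  S4Vectors::metadata(x)$kind)

setMethod("show", "PlateTimeSeries", function(object) {
  cd <- wellInfo(object)
  cat(sprintf("PlateTimeSeries (%s): %d time points x %d wells\n",
              plateKind(object), nrow(object), ncol(object)))
  cat(sprintf("  samples: %s\n",
              paste(unique(cd$sample), collapse = ", ")))
  t <- plateTimes(object)
  cat(sprintf("  time range: %g .. %g s\n", t[1], t[length(t)]))
})

## ---------------------------------------------------------------------------
## Geometry
## ---------------------------------------------------------------------------

#' Molecular geometry
#'
#' Cartesian coordinates of a molecule: element symbols and an (n x 3) matrix
#' of positions in Angstrom, plus a free-text title (conventionally the
#' molecule name, carried on the XYZ comment line).
#'
#' @param elements character vector of element symbols.
#' @param coords numeric matrix with one (x, y, z) row per atom, in Angstrom.
#' @param title molecule name or comment.
#' @return A `Geometry` object.
#' @seealso [readXYZ()], [findOHBonds()], [makeGeometryFixture()]
#' @examples
#' g <- Geometry(c("O", "H"), rbind(c(0, 0, 0), c(0.9741, 0, 0)), "hydroxyl")
#' nAtoms(g)
#' @aliases Geometry-class
#' @export
Geometry <- function(elements, coords, title = "") {
  methods::new("Geometry", elements = as.character(elements),
               coords = matrix(as.numeric(coords), ncol = 3,
                               dimnames = list(NULL, c("x", "y", "z"))),
               title = as.character(title))
}

#' @rdname Geometry
#' @export
setClass("Geometry",
         representation(elements = "character", coords = "matrix",
                        title = "character"))

setValidity("Geometry", function(object) {
  msgs <- character()
  n <- length(object@elements)
  if (n < 1L) msgs <- c(msgs, "a geometry needs at least one atom")
  if (!is.numeric(object@coords) || ncol(object@coords) != 3 ||
      nrow(object@coords) != n)
    msgs <- c(msgs, "coords must be an (n x 3) numeric matrix")
  else if (any(!is.finite(object@coords)))
    msgs <- c(msgs, "coordinates must be finite")
  bad <- setdiff(unique(object@elements), PERIODIC_TABLE)
  if (length(bad))
    msgs <- c(msgs, sprintf("unknown element symbol(s): %s",
                            paste(bad, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' @rdname oxicap-accessors
#' @export
setMethod("nAtoms", "Geometry", function(x) length(x@elements))

#' @rdname oxicap-accessors
#' @export
setMethod("atomElements", "Geometry", function(x) x@elements)

#' @rdname oxicap-accessors
#' @export
setMethod("atomCoords", "Geometry", function(x) x@coords)

#' @rdname oxicap-accessors
#' @export
setMethod("moleculeName", "Geometry", function(x) x@title)

setMethod("show", "Geometry", function(object) {
  cat(sprintf("Geometry '%s': %d atoms (%s)\n", object@title,
              nAtoms(object),
              paste(names(sort(-table(object@elements))), collapse = ", ")))
})

## ---------------------------------------------------------------------------
## ThermoSummary
## ---------------------------------------------------------------------------

#' Quantum-chemistry thermochemistry summary
#'
#' Condensed output of an electronic-structure run for one molecule: frontier
#' orbital energies in eV and enthalpies in Hartree for the neutral molecule,
#' its H-abstraction radicals (one per labelled O-H site) and, optionally,
#' the radical cation, plus optional Mulliken atomic charges. Raw program
#' logs are deliberately not parsed here; a separate conversion step is
#' expected to produce the JSON consumed by [readThermoSummary()].
#'
#' @param molecule molecule name.
#' @param eHomo,eLumo frontier orbital energies in eV (`NA` if unknown);
#'   when both are present `eLumo > eHomo` is enforced.
#' @param hNeutral enthalpy of the neutral molecule, Hartree (`NA` allowed).
#' @param hRadicals named numeric vector of radical enthalpies (Hartree), one
#'   per abstraction site label such as `"O7-H8"`.
#' @param hCation enthalpy of the radical cation, Hartree; `NA` marks the
#'   ionization potential as unavailable.
#' @param charges numeric vector of Mulliken charges in atom order
#'   (length 0 when not supplied).
#' @return A `ThermoSummary` object.
#' @seealso [readThermoSummary()], [computeBDE()], [computeIP()], [chargeAudit()]
#' @examples
#' ThermoSummary("Trolox", eHomo = -5.294, eLumo = -0.655)
#' @aliases ThermoSummary-class
#' @export
ThermoSummary <- function(molecule, eHomo = NA_real_, eLumo = NA_real_,
                          hNeutral = NA_real_, hRadicals = numeric(),
                          hCation = NA_real_, charges = numeric()) {
  methods::new("ThermoSummary", molecule = as.character(molecule),
               eHomo = as.numeric(eHomo), eLumo = as.numeric(eLumo),
               hNeutral = as.numeric(hNeutral),
               hRadicals = vapply(hRadicals, as.numeric, numeric(1)),
               hCation = as.numeric(hCation),
               charges = as.numeric(charges))
}

#' @rdname ThermoSummary
#' @export
setClass("ThermoSummary",
         representation(molecule = "character", eHomo = "numeric",
                        eLumo = "numeric", hNeutral = "numeric",
                        hRadicals = "numeric", hCation = "numeric",
                        charges = "numeric"))

setValidity("ThermoSummary", function(object) {
  msgs <- character()
  if (!is.na(object@eHomo) && !is.na(object@eLumo) &&
      object@eLumo <= object@eHomo)
    msgs <- c(msgs, "E_LUMO must exceed E_HOMO")
  for (h in list(object@hNeutral, object@hCation)) {
    if (!is.na(h) && !is.finite(h)) msgs <- c(msgs, "enthalpies must be finite")
  }
  if (length(object@hRadicals) && any(!is.finite(object@hRadicals)))
    msgs <- c(msgs, "radical enthalpies must be finite")
  if (length(msgs)) msgs else TRUE
})

#' @rdname oxicap-accessors
#' @export
setMethod("moleculeName", "ThermoSummary", function(x) x@molecule)

#' @rdname oxicap-accessors
#' @export
setMethod("orbitalEnergies", "ThermoSummary", function(x)
  c(e_homo = x@eHomo, e_lumo = x@eLumo))

#' @rdname oxicap-accessors
#' @export
setMethod("hasCationEnthalpy", "ThermoSummary", function(x) !is.na(x@hCation))

setMethod("show", "ThermoSummary", function(object) {
  cat(sprintf("ThermoSummary '%s'\n", object@molecule))
  cat(sprintf("  E_HOMO = %s eV, E_LUMO = %s eV\n",
              format(object@eHomo), format(object@eLumo)))
  cat(sprintf("  radical sites: %d; cation enthalpy: %s; charges: %d\n",
              length(object@hRadicals),
              if (hasCationEnthalpy(object)) "yes" else "no (IP unavailable)",
              length(object@charges)))
})

## ---------------------------------------------------------------------------
## MassDistribution
## ---------------------------------------------------------------------------

#' Polymer molar-mass distribution
#'
#' Discrete distribution of polymer species: a mass (Da) and a non-negative
#' count (number of chains) per species. The basis for number- and
#' weight-average molar masses via [distributionMoments()].
#'
#' @param mass numeric vector of species masses in Da (> 0).
#' @param count numeric vector of species counts (>= 0, at least one > 0).
#' @param label distribution label (e.g. sample name).
#' @return A `MassDistribution` object.
#' @seealso [distributionMoments()], [simulateScission()], [readMassDistribution()]
#' @examples
#' MassDistribution(c(100, 300), c(5, 5), "two species")
#' @aliases MassDistribution-class
#' @export
MassDistribution <- function(mass, count, label = "") {
  methods::new("MassDistribution", mass = as.numeric(mass),
               count = as.numeric(count), label = as.character(label))
}

#' @rdname MassDistribution
#' @export
setClass("MassDistribution",
         representation(mass = "numeric", count = "numeric",
                        label = "character"))

setValidity("MassDistribution", function(object) {
  msgs <- character()
  if (length(object@mass) != length(object@count))
    msgs <- c(msgs, "mass and count must have equal length")
  if (any(!is.finite(object@mass)) || any(object@mass <= 0))
    msgs <- c(msgs, "masses must be finite and positive")
  if (any(!is.finite(object@count)) || any(object@count < 0))
    msgs <- c(msgs, "counts must be finite and non-negative")
  if (!any(object@count > 0))
    msgs <- c(msgs, "at least one species must have count > 0")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "MassDistribution", function(object) {
  cat(sprintf("MassDistribution '%s': %d species, total count %g\n",
              object@label, length(object@mass), sum(object@count)))
})

## ---------------------------------------------------------------------------
## DoseResponse
## ---------------------------------------------------------------------------

#' Dose-response line
#'
#' Mean response per concentration together with the ordinary-least-squares
#' line (with intercept) fitted through the points. For ORAC the response is
#' the mean net AUC at each antioxidant concentration; for FRAP it is the
#' replicate-averaged endpoint absorbance of the calibration standard.
#'
#' @param sample sample name.
#' @param concentrations numeric vector of concentrations (uM), >= 2 points.
#' @param responses numeric vector of mean responses, same length.
#' @return A `DoseResponse` with slots `slope` (per uM), `intercept` and
#'   `rSquared` filled in by the OLS fit.
#' @seealso [fitDoseResponse()], [troloxEquivalent()], [frapTE()]
#' @examples
#' dr <- doseResponse("x", c(1, 2, 4), c(2, 4, 8))
#' drSlope(dr)      # 2
#' drRSquared(dr)   # 1
#' @aliases DoseResponse-class
#' @export
doseResponse <- function(sample, concentrations, responses) {
  concentrations <- as.numeric(concentrations)
  responses <- as.numeric(responses)
  if (length(concentrations) != length(responses))
    validation_error("concentrations and responses must have equal length")
  if (length(unique(concentrations)) < 2L)
    oxi_stop("need >= 2 distinct concentrations to fit a dose-response line",
             "oxicap_insufficient_design_error")
  if (stats::var(concentrations) == 0)
    oxi_stop("zero variance in concentrations: singular fit",
             "oxicap_singular_fit_error")
  fit <- stats::lm(responses ~ concentrations)
  tss <- sum((responses - mean(responses))^2)
  r2 <- if (tss == 0) 1 else 1 - sum(stats::residuals(fit)^2) / tss
  methods::new("DoseResponse", sample = as.character(sample),
               concentrations = concentrations, responses = responses,
               slope = unname(stats::coef(fit)[2L]),
               intercept = unname(stats::coef(fit)[1L]),
               rSquared = r2)
}

#' @rdname doseResponse
#' @export
setClass("DoseResponse",
         representation(sample = "character", concentrations = "numeric",
                        responses = "numeric", slope = "numeric",
                        intercept = "numeric", rSquared = "numeric"))

setValidity("DoseResponse", function(object) {
  if (length(object@concentrations) != length(object@responses))
    return("concentrations and responses must have equal length")
  if (length(object@concentrations) < 2L)
    return("a dose-response needs at least two points")
  TRUE
})

#' @rdname oxicap-accessors
#' @export
setMethod("drSlope", "DoseResponse", function(x) x@slope)

#' @rdname oxicap-accessors
#' @export
setMethod("drIntercept", "DoseResponse", function(x) x@intercept)

#' @rdname oxicap-accessors
#' @export
setMethod("drRSquared", "DoseResponse", function(x) x@rSquared)

#' @rdname oxicap-accessors
#' @export
setMethod("sampleName", "DoseResponse", function(x) x@sample)

setMethod("show", "DoseResponse", function(object) {
  cat(sprintf(
    "DoseResponse '%s': %d concentrations, slope %.4g/uM, intercept %.4g, R^2 %.4f\n",
    object@sample, length(object@concentrations), object@slope,
    object@intercept, object@rSquared))
})

## ---------------------------------------------------------------------------
## EndpointSeries
## ---------------------------------------------------------------------------

#' Endpoint absorbance dose series
#'
#' Replicate-averaged endpoint absorbances for one sample over a
#' concentration series, plus the reference absorbances the assay formulas
#' need: `absControl` (radical solution without antioxidant; DPPH), and
#' `absMin`/`absMax` (assay floor and the top standard absorbance; FRAP).
#'
#' @param sample sample name.
#' @param concentrations numeric vector, uM.
#' @param absorbances numeric vector of mean absorbances (AU), same length.
#' @param absControl control absorbance (AU); required > 0 for `assay = "dpph"`.
#' @param absMin,absMax FRAP range absorbances; required `absMax > absMin`
#'   for `assay = "frap"`.
#' @param assay `"dpph"` or `"frap"`.
#' @return An `EndpointSeries` object.
#' @seealso [estimateIC50()], [relativeReducingPower()], [frapTE()],
#'   [simulateEndpointAssay()]
#' @aliases EndpointSeries-class
#' @export
EndpointSeries <- function(sample, concentrations, absorbances,
                           absControl = NA_real_, absMin = NA_real_,
                           absMax = NA_real_, assay = c("dpph", "frap")) {
  assay <- match.arg(assay)
  methods::new("EndpointSeries", sample = as.character(sample),
               concentrations = as.numeric(concentrations),
               absorbances = as.numeric(absorbances),
               absControl = as.numeric(absControl),
               absMin = as.numeric(absMin), absMax = as.numeric(absMax),
               assay = assay)
}

#' @rdname EndpointSeries
#' @export
setClass("EndpointSeries",
         representation(sample = "character", concentrations = "numeric",
                        absorbances = "numeric", absControl = "numeric",
                        absMin = "numeric", absMax = "numeric",
                        assay = "character"))

setValidity("EndpointSeries", function(object) {
  msgs <- character()
  if (length(object@concentrations) != length(object@absorbances))
    msgs <- c(msgs, "concentrations and absorbances must have equal length")
  if (object@assay == "dpph" &&
      (is.na(object@absControl) || object@absControl <= 0))
    msgs <- c(msgs, "DPPH series needs absControl > 0")
  if (object@assay == "frap" &&
      (is.na(object@absMin) || is.na(object@absMax) ||
       object@absMax <= object@absMin))
    msgs <- c(msgs, "FRAP series needs absMax > absMin")
  if (length(msgs)) msgs else TRUE
})

#' @rdname oxicap-accessors
#' @export
setMethod("sampleName", "EndpointSeries", function(x) x@sample)

setMethod("show", "EndpointSeries", function(object) {
  cat(sprintf("EndpointSeries '%s' (%s): %d concentrations [%g .. %g uM]\n",
              object@sample, object@assay, length(object@concentrations),
              min(object@concentrations), max(object@concentrations)))
})

## ---------------------------------------------------------------------------
## IC50Estimate
## ---------------------------------------------------------------------------

#' IC50 estimate from a scavenging dose series
#'
#' Result of [estimateIC50()]: the concentration scavenging 50% of the
#' radical, found by linear interpolation between the two measured points
#' bracketing 50%, or "not reached" when the maximum observed scavenging
#' stays below 50%.
#'
#' @aliases IC50Estimate-class
#' @seealso [estimateIC50()]
#' @export
setClass("IC50Estimate",
         representation(sample = "character", ic50 = "numeric",
                        reached = "logical", bracket = "data.frame"))

IC50Estimate <- function(sample, ic50, reached, bracket) {
  methods::new("IC50Estimate", sample = as.character(sample),
               ic50 = as.numeric(ic50), reached = reached, bracket = bracket)
}

setValidity("IC50Estimate", function(object) {
  if (object@reached) {
    b <- object@bracket
    if (nrow(b) != 2L) return("a reached IC50 must carry two bracketing points")
    if (!(b$scavenging[1L] < 50 && b$scavenging[2L] >= 50))
      return("bracketing points must straddle 50% (lower < 50 <= upper)")
  }
  TRUE
})

#' @rdname oxicap-accessors
#' @export
setMethod("sampleName", "IC50Estimate", function(x) x@sample)

#' @rdname oxicap-accessors
#' @export
setMethod("ic50Value", "IC50Estimate", function(x) x@ic50)

#' @rdname oxicap-accessors
#' @export
setMethod("ic50Reached", "IC50Estimate", function(x) x@reached)

setMethod("show", "IC50Estimate", function(object) {
  if (object@reached) {
    cat(sprintf("IC50Estimate '%s': %.4g uM (bracket %g-%g uM)\n",
                object@sample, object@ic50, object@bracket$conc[1L],
                object@bracket$conc[2L]))
  } else {
    cat(sprintf("IC50Estimate '%s': not reached (max scavenging < 50%%)\n",
                object@sample))
  }
})

## ---------------------------------------------------------------------------
## RosTimecourse
## ---------------------------------------------------------------------------

#' ROS fluorescence time course
#'
#' Replicate-averaged DCFH-DA fluorescence (RFU) of several samples over a
#' shared time grid in hours, with a designated no-antioxidant control
#' (radical generator alone). Optional replicate standard deviations are
#' carried alongside for reporting.
#'
#' @param times numeric vector of measurement times in hours.
#' @param rfu numeric matrix (samples x times) with sample row names.
#' @param controlLabel row name of the control.
#' @param rfuSd optional matrix of replicate SDs, same shape as `rfu`.
#' @return A `RosTimecourse` object.
#' @seealso [percentRosReduction()], [timecourseSummary()], [simulateHRS()]
#' @aliases RosTimecourse-class
#' @export
rosTimecourse <- function(times, rfu, controlLabel,
                          rfuSd = matrix(numeric(), 0, 0)) {
  methods::new("RosTimecourse", times = as.numeric(times),
               rfu = as.matrix(rfu), controlLabel = as.character(controlLabel),
               rfuSd = as.matrix(rfuSd))
}

#' @rdname rosTimecourse
#' @export
setClass("RosTimecourse",
         representation(times = "numeric", rfu = "matrix",
                        controlLabel = "character", rfuSd = "matrix"))

setValidity("RosTimecourse", function(object) {
  msgs <- character()
  if (ncol(object@rfu) != length(object@times))
    msgs <- c(msgs, "rfu must have one column per time point")
  if (is.null(rownames(object@rfu)))
    msgs <- c(msgs, "rfu must carry sample row names")
  else if (!object@controlLabel %in% rownames(object@rfu))
    msgs <- c(msgs, sprintf("control '%s' not among samples",
                            object@controlLabel))
  if (length(object@rfuSd) && !identical(dim(object@rfuSd), dim(object@rfu)))
    msgs <- c(msgs, "rfuSd must match the shape of rfu")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "RosTimecourse", function(object) {
  cat(sprintf("RosTimecourse: %d samples x %d times (control '%s')\n",
              nrow(object@rfu), length(object@times), object@controlLabel))
})

## ---------------------------------------------------------------------------
## PolymerStats
## ---------------------------------------------------------------------------

#' Polymer molar-mass statistics
#'
#' Number-average (`mn`) and weight-average (`mw`) molar masses in Da and
#' their ratio (`dispersity`, the polydispersity index), plus pass-through
#' chromatography metadata: peak retention volume `vp` (mL) and intrinsic
#' viscosity `iv` (carried verbatim, no unit conversion).
#'
#' @param mn,mw number- and weight-average molar mass, Da.
#' @param vp,iv optional pass-through metadata.
#' @param label sample label.
#' @return A `PolymerStats` object. The constructor warns (does not fail)
#'   when `mw < mn`, which can arise from printed rounding.
#' @seealso [distributionMoments()], [dispersityFromMwMn()], [degradationReport()]
#' @aliases PolymerStats-class
#' @export
polymerStats <- function(mn, mw, vp = NA_real_, iv = NA_real_, label = "") {
  stopifnot_number(mn, "mn")
  stopifnot_number(mw, "mw")
  if (mn <= 0) validation_error("mn must be positive")
  if (mw < mn) warning("mw < mn (dispersity < 1): check for rounded inputs")
  methods::new("PolymerStats", mn = as.numeric(mn), mw = as.numeric(mw),
               dispersity = mw / mn, vp = as.numeric(vp), iv = as.numeric(iv),
               label = as.character(label))
}

#' @rdname polymerStats
#' @export
setClass("PolymerStats",
         representation(mn = "numeric", mw = "numeric", dispersity = "numeric",
                        vp = "numeric", iv = "numeric", label = "character"))

setValidity("PolymerStats", function(object) {
  if (!is_number(object@mn) || object@mn <= 0) return("mn must be positive")
  if (!is_number(object@mw) || object@mw <= 0) return("mw must be positive")
  TRUE
})

setMethod("show", "PolymerStats", function(object) {
  cat(sprintf("PolymerStats '%s': Mn %.6g Da, Mw %.6g Da, dispersity %.4g\n",
              object@label, object@mn, object@mw, object@dispersity))
})

## ---------------------------------------------------------------------------
## BondReport
## ---------------------------------------------------------------------------

#' O-H bond report
#'
#' Hydroxyl bonds detected in a geometry: one row per O-H pair within the
#' distance cutoff (`o_index`, `h_index`, `length` in Angstrom) and their
#' arithmetic mean length, used to rank molecules by hydrogen-donating
#' propensity (a longer average O-H bond is easier to break homolytically).
#'
#' @aliases BondReport-class
#' @seealso [findOHBonds()], [averageOHRanking()]
#' @export
setClass("BondReport",
         representation(molecule = "character", bonds = "data.frame",
                        averageLength = "numeric"))

BondReport <- function(molecule, bonds) {
  avg <- if (nrow(bonds)) mean(bonds$length) else NA_real_
  methods::new("BondReport", molecule = as.character(molecule), bonds = bonds,
               averageLength = avg)
}

setValidity("BondReport", function(object) {
  b <- object@bonds
  if (nrow(b) && (any(b$length <= 0.5) || any(b$length >= 1.2)))
    return("O-H bond lengths must lie in (0.5, 1.2) Angstrom")
  if (nrow(b) && abs(object@averageLength - mean(b$length)) > 1e-12)
    return("averageLength must equal the mean of the listed lengths")
  TRUE
})

#' @rdname oxicap-accessors
#' @export
setMethod("moleculeName", "BondReport", function(x) x@molecule)

setMethod("show", "BondReport", function(object) {
  cat(sprintf("BondReport '%s': %d O-H bond(s), average length %s A\n",
              object@molecule, nrow(object@bonds),
              format(object@averageLength, digits = 6)))
})

#' Bonds listed in a bond report
#'
#' @param report a \linkS4class{BondReport}.
#' @return data.frame with columns `o_index`, `h_index`, `length`.
#' @export
bondTable <- function(report) report@bonds

#' Average O-H bond length of a report
#'
#' @param report a \linkS4class{BondReport}.
#' @return Mean bond length in Angstrom (`NA` for an empty report).
#' @export
averageBondLength <- function(report) report@averageLength
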