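#' @include utils.R
NULL

#' Accessor generics
#'
#' Small accessor generics for the package's S4 containers. Each is
#' documented with the class it belongs to.
#'
#' @param x an oxicap S4 object.
#' @return The slot value; see the class documentation for details.
#' @name oxicap-accessors
#' @keywords internal
NULL

#' @rdname oxicap-accessors
#' @export
setGeneric("plateTimes", function(x) standardGeneric("plateTimes"))

#' @rdname oxicap-accessors
#' @export
setGeneric("wellInfo", function(x) standardGeneric("wellInfo"))

#' @rdname oxicap-accessors
#' @export
setGeneric("signalMatrix", function(x) standardGeneric("signalMatrix"))

#' @rdname oxicap-accessors
#' @export
setGeneric("plateKind", function(x) standardGeneric("plateKind"))

#' @rdname oxicap-accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname oxicap-accessors
#' @export
setGeneric("atomElements", function(x) standardGeneric("atomElements"))

#' @rdname oxicap-accessors
#' @export
setGeneric("atomCoords", function(x) standardGeneric("atomCoords"))

#' @rdname oxicap-accessors
#' @export
setGeneric("moleculeName", function(x) standardGeneric("moleculeName"))

#' @rdname oxicap-accessors
#' @export
setGeneric("orbitalEnergies", function(x) standardGeneric("orbitalEnergies"))

#' @rdname oxicap-accessors
#' @export
setGeneric("hasCationEnthalpy", function(x) standardGeneric("hasCationEnthalpy"))

#' @rdname oxicap-accessors
#' @export
setGeneric("drSlope", function(x) standardGeneric("drSlope"))

#' @rdname oxicap-accessors
#' @export
setGeneric("drIntercept", function(x) standardGeneric("drIntercept"))

#' @rdname oxicap-accessors
#' @export
setGeneric("drRSquared", function(x) standardGeneric("drRSquared"))

#' @rdname oxicap-accessors
#' @export
setGeneric("sampleName", function(x) standardGeneric("sampleName"))

#' @rdname oxicap-accessors
#' @export
setGeneric("ic50Value", function(x) standardGeneric("ic50Value"))

#' @rdname oxicap-accessors
#' @export
setGeneric("ic50Reached", function(x) standardGeneric("ic50Reached"))
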