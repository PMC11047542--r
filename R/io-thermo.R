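#' @include AllClasses.R
NULL

THERMO_KEYS <- c("molecule", "E_HOMO", "E_LUMO", "H_neutral", "H_radicals",
                 "H_cation", "charges")

#' Read a thermochemistry summary from JSON
#'
#' Consumes the condensed JSON summary of a quantum-chemistry run (keys
#' `molecule`, `E_HOMO`, `E_LUMO` in eV; `H_neutral`, `H_radicals` -- a
#' site-label to Hartree map -- and optional `H_cation` in Hartree; optional
#' `charges`, Mulliken charges in atom order). Unknown keys are ignored with
#' a warning. A missing `H_cation` simply flags the ionization potential as
#' unavailable.
#'
#' @param path JSON file path.
#' @return A \linkS4class{ThermoSummary}.
#' @seealso [writeThermoSummary()], [computeBDE()], [computeIP()]
#' @export
readThermoSummary <- function(path) {
  if (!file.exists(path)) format_error(sprintf("no such file: %s", path))
  raw <- jsonlite::fromJSON(path)
  unknown <- setdiff(names(raw), THERMO_KEYS)
  if (length(unknown)) {
    warning(sprintf("ignoring unknown key(s) in %s: %s", basename(path),
                    paste(unknown, collapse = ", ")))
  }
  num_or_na <- function(key) {
    v <- raw[[key]]
    if (is.null(v)) return(NA_real_)
    if (!is.numeric(v) || length(v) != 1L)
      format_error(sprintf("'%s' must be a single number", key))
    v
  }
  radicals <- raw[["H_radicals"]]
  if (!is.null(radicals)) {
    radicals <- unlist(radicals)
    if (!is.numeric(radicals))
      format_error("'H_radicals' must map site labels to numbers")
  } else {
    radicals <- numeric()
  }
  charges <- raw[["charges"]]
  if (!is.null(charges) && !is.numeric(charges))
    format_error("'charges' must be numeric")
  e_homo <- num_or_na("E_HOMO")
  e_lumo <- num_or_na("E_LUMO")
  if (!is.na(e_homo) && !is.na(e_lumo) && e_lumo <= e_homo)
    validation_error(sprintf("E_LUMO (%g) must exceed E_HOMO (%g)",
                             e_lumo, e_homo))
  ThermoSummary(molecule = if (is.null(raw$molecule)) "" else raw$molecule,
                eHomo = e_homo, eLumo = e_lumo,
                hNeutral = num_or_na("H_neutral"), hRadicals = radicals,
                hCation = num_or_na("H_cation"),
                charges = if (is.null(charges)) numeric() else charges)
}

#' Write a thermochemistry summary to JSON
#'
#' @param x a \linkS4class{ThermoSummary}.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeThermoSummary <- function(x, path) {
  out <- list(molecule = x@molecule)
  add <- function(out, key, v) {
    if (length(v) && !all(is.na(v))) out[[key]] <- v
    out
  }
  out <- add(out, "E_HOMO", x@eHomo)
  out <- add(out, "E_LUMO", x@eLumo)
  out <- add(out, "H_neutral", x@hNeutral)
  if (length(x@hRadicals)) out$H_radicals <- as.list(x@hRadicals)
  out <- add(out, "H_cation", x@hCation)
  if (length(x@charges)) out$charges <- x@charges
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
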