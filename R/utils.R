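## Internal helpers shared across modules.

## Classed conditions so callers (and tests) can distinguish failure modes.
oxi_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "oxicap_error")))
}

format_error     <- function(msg) oxi_stop(msg, "oxicap_format_error")
validation_error <- function(msg) oxi_stop(msg, "oxicap_validation_error")

#' Truncate numbers at a fixed number of decimal places
#'
#' Drops (rather than rounds away) all digits beyond `digits`, moving toward
#' zero. Printed tables in the quantum-chemistry literature are frequently
#' truncated at the displayed precision instead of rounded; this helper
#' reproduces that display convention when reporting descriptor tables, while
#' all internal computation keeps full double precision.
#'
#' A guard digit absorbs binary floating-point representation error so that,
#' e.g., `truncateDigits(0.9821, 4)` returns `0.9821` and not `0.9820`.
#'
#' @param x numeric vector.
#' @param digits integer, number of decimal places to keep.
#' @return numeric vector truncated toward zero at `digits` decimals.
#' @examples
#' truncateDigits(2.3195, 2)   # 2.31
#' truncateDigits(-1.999, 2)   # -1.99
#' @export
truncateDigits <- function(x, digits) {
  scale <- 10^digits
  trunc(round(x * scale, 6)) / scale
}

## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
## Keeps the simulators pure functions of (config, seed).
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    validation_error("'seed' must be a single finite number")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## Scalar checks used by validity methods and argument guards.
is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stopifnot_number <- function(x, what) {
  if (!is_number(x)) validation_error(sprintf("'%s' must be a single finite number", what))
  invisible(x)
}

## IUPAC element symbols (through oganesson); used by Geometry validity.
PERIODIC_TABLE <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn",
  "Fr", "Ra", "Ac", "Th", "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf",
  "Es", "Fm", "Md", "No", "Lr", "Rf", "Db", "Sg", "Bh", "Hs", "Mt", "Ds",
  "Rg", "Cn", "Nh", "Fl", "Mc", "Lv", "Ts", "Og")

## Energy conversion constants (CODATA).
HARTREE_TO_KJ_MOL <- 2625.4996
EV_PER_HARTREE    <- 27.211386
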