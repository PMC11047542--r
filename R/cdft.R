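#' @include AllClasses.R
NULL

#' Koopmans-type conceptual-DFT reactivity descriptors
#'
#' From frontier orbital energies (eV), computes the standard global
#' reactivity descriptors:
#' gap \eqn{\Delta E = E_{LUMO} - E_{HOMO}},
#' hardness \eqn{\eta = \Delta E / 2},
#' softness \eqn{\sigma = 1/\eta},
#' electronegativity \eqn{\chi = -(E_{HOMO} + E_{LUMO})/2},
#' chemical potential \eqn{\mu = -\chi}, and
#' electrophilicity \eqn{\omega = \chi^2 / (2\eta)}.
#' All values are kept at full double precision; use [formatDescriptors()]
#' to reproduce a display-truncated literature table.
#'
#' A soft molecule (small gap, large \eqn{\sigma}) is more polarizable and
#' more reactive toward radicals; a low \eqn{\omega} marks a reluctant
#' electron acceptor, i.e. a better electron donor.
#'
#' @param eHomo,eLumo HOMO and LUMO energies in eV (vectorized; each pair
#'   must satisfy `eLumo > eHomo`).
#' @param molecule optional molecule name(s).
#' @return data.frame with columns `molecule`, `e_homo`, `e_lumo`, `gap`,
#'   `eta`, `sigma`, `chi`, `mu`, `omega` (energies in eV, `sigma` in 1/eV).
#' @examples
#' d <- descriptorsFromOrbitals(-5.294, -0.655, "Trolox")
#' round(d$eta, 4)  # 2.3195
#' @seealso [electrophilicityFromRounded()], [formatDescriptors()]
#' @export
descriptorsFromOrbitals <- function(eHomo, eLumo, molecule = NA_character_) {
  if (length(eHomo) != length(eLumo))
    validation_error("eHomo and eLumo must have equal length")
  if (any(!is.finite(eHomo)) || any(!is.finite(eLumo)))
    validation_error("orbital energies must be finite")
  if (any(eLumo <= eHomo))
    oxi_stop("E_LUMO <= E_HOMO gives non-positive hardness",
             "oxicap_nonpositive_hardness_error")
  gap <- eLumo - eHomo
  eta <- gap / 2
  chi <- -(eHomo + eLumo) / 2
  data.frame(molecule = molecule, e_homo = eHomo, e_lumo = eLumo,
             gap = gap, eta = eta, sigma = 1 / eta, chi = chi, mu = -chi,
             omega = chi^2 / (2 * eta), row.names = NULL)
}

#' Electrophilicity recomputed from display-precision inputs
#'
#' \eqn{\omega = \chi^2 / (2\eta)} evaluated from electronegativity and
#' hardness as printed in a descriptor table (i.e. already at display
#' precision), with the result truncated to three decimals -- the display
#' convention such tables use. This reproduces a published \eqn{\omega}
#' column from its own printed \eqn{\chi} and \eqn{\eta}, which
#' full-precision computation generally cannot.
#'
#' @param chi electronegativity, eV (vectorized).
#' @param eta hardness, eV; must be > 0.
#' @return Electrophilicity in eV, truncated to 3 decimals.
#' @examples
#' electrophilicityFromRounded(2.974, 2.31)  # 1.914
#' @export
electrophilicityFromRounded <- function(chi, eta) {
  if (any(!is.finite(eta)) || any(eta <= 0))
    validation_error("eta must be positive")
  truncateDigits(chi^2 / (2 * eta), 3)
}

#' Display-truncated descriptor table
#'
#' Formats a full-precision descriptor table (from
#' [descriptorsFromOrbitals()]) the way quantum-chemistry tables are
#' conventionally printed: values truncated (not rounded) at the displayed
#' precision -- hardness to 2 decimals, softness, electronegativity,
#' chemical potential to 3 -- with softness recomputed from the displayed
#' hardness and electrophilicity recomputed from the displayed
#' electronegativity and hardness (via [electrophilicityFromRounded()]).
#'
#' @param desc data.frame from [descriptorsFromOrbitals()].
#' @return data.frame with columns `molecule`, `e_homo`, `e_lumo`, `eta`,
#'   `sigma`, `chi`, `omega`, `mu` at display precision.
#' @export
formatDescriptors <- function(desc) {
  eta <- truncateDigits(desc$eta, 2)
  chi <- truncateDigits(desc$chi, 3)
  data.frame(molecule = desc$molecule,
             e_homo = desc$e_homo, e_lumo = desc$e_lumo,
             eta = eta,
             sigma = truncateDigits(1 / eta, 3),
             chi = chi,
             omega = electrophilicityFromRounded(chi, eta),
             mu = -chi, row.names = NULL)
}

#' O-H bond dissociation enthalpy
#'
#' Enthalpy cost of homolytic O-H cleavage, the descriptor of the
#' hydrogen-atom-transfer (HAT) mechanism:
#' \deqn{BDE = H(ArO\cdot) + H(H\cdot) - H(ArOH),}
#' converted from Hartree to kJ/mol (1 Hartree = 2625.4996 kJ/mol). A lower
#' BDE marks a better hydrogen donor. The H-atom enthalpy must be supplied
#' explicitly; a common choice is the electronic energy -0.5 Hartree plus a
#' 2.5 RT thermal correction at the run's temperature.
#'
#' @param hNeutral enthalpy of the parent molecule, Hartree.
#' @param hRadical enthalpy of the H-abstraction radical, Hartree.
#' @param hHatom enthalpy of the free hydrogen atom, Hartree.
#' @return BDE in kJ/mol. Translation-invariant in the enthalpy zero point.
#' @seealso [computeIP()], [bdeTable()]
#' @export
computeBDE <- function(hNeutral, hRadical, hHatom) {
  stopifnot_number(hNeutral, "hNeutral")
  stopifnot_number(hRadical, "hRadical")
  stopifnot_number(hHatom, "hHatom")
  (hRadical + hHatom - hNeutral) * HARTREE_TO_KJ_MOL
}

#' Adiabatic ionization potential
#'
#' Descriptor of the single-electron-transfer (SET) mechanism:
#' \deqn{IP = H(ArOH^{\cdot+}) + H(e^-) - H(ArOH)}
#' in kJ/mol. The electron enthalpy defaults to 0 (the ion convention);
#' supply a value to use the electron convention instead.
#'
#' @param hNeutral enthalpy of the neutral molecule, Hartree.
#' @param hCation enthalpy of the radical cation, Hartree.
#' @param hElectron enthalpy of the free electron, Hartree (default 0).
#' @return IP in kJ/mol.
#' @export
computeIP <- function(hNeutral, hCation, hElectron = 0) {
  stopifnot_number(hNeutral, "hNeutral")
  stopifnot_number(hCation, "hCation")
  stopifnot_number(hElectron, "hElectron")
  (hCation + hElectron - hNeutral) * HARTREE_TO_KJ_MOL
}

#' BDE table for every abstraction site of a molecule
#'
#' @param thermo a \linkS4class{ThermoSummary} with `hNeutral` and at least
#'   one radical enthalpy.
#' @param hHatom enthalpy of the free hydrogen atom, Hartree.
#' @return data.frame with columns `site` and `bde` (kJ/mol).
#' @export
bdeTable <- function(thermo, hHatom) {
  if (is.na(thermo@hNeutral) || !length(thermo@hRadicals))
    validation_error("BDE needs the neutral enthalpy and >= 1 radical enthalpy")
  data.frame(site = names(thermo@hRadicals),
             bde = vapply(thermo@hRadicals, computeBDE,
                          numeric(1), hNeutral = thermo@hNeutral,
                          hHatom = hHatom),
             row.names = NULL)
}

#' Detect hydroxyl (O-H) bonds in a geometry
#'
#' Lists every oxygen-hydrogen pair whose Euclidean distance is below the
#' cutoff (default 1.2 Angstrom, comfortably above typical O-H lengths of
#' 0.95-1.0 A and below the next-nearest O...H contacts). An empty report
#' (e.g. a molecule without hydroxyls) is returned with a warning, not an
#' error.
#'
#' @param geom a \linkS4class{Geometry}.
#' @param cutoff O-H distance cutoff in Angstrom.
#' @return A \linkS4class{BondReport}.
#' @examples
#' g <- Geometry(c("O", "H"), rbind(c(0, 0, 0), c(0.9741, 0, 0)), "OH")
#' averageBondLength(findOHBonds(g))  # 0.9741
#' @export
findOHBonds <- function(geom, cutoff = 1.2) {
  o <- which(atomElements(geom) == "O")
  h <- which(atomElements(geom) == "H")
  co <- atomCoords(geom)
  bonds <- data.frame(o_index = integer(), h_index = integer(),
                      length = numeric())
  for (i in o) {
    d <- sqrt(colSums((t(co[h, , drop = FALSE]) - co[i, ])^2))
    hit <- which(d < cutoff)
    if (length(hit)) {
      bonds <- rbind(bonds, data.frame(o_index = i, h_index = h[hit],
                                       length = d[hit]))
    }
  }
  if (!nrow(bonds))
    warning(sprintf("no O-H pair within %g A in '%s'", cutoff,
                    moleculeName(geom)))
  BondReport(moleculeName(geom), bonds)
}

#' Rank molecules by average O-H bond length
#'
#' Orders bond reports by descending average O-H length -- the longer (and
#' therefore weaker) the average hydroxyl bond, the better the expected
#' hydrogen-donating capacity. Averages within `tol` of each other share a
#' rank (reported ties).
#'
#' @param reports list of \linkS4class{BondReport} objects.
#' @param tol tie tolerance in Angstrom (default 1e-4, the display precision
#'   of typical bond-length tables).
#' @return data.frame ordered by descending average length with columns
#'   `molecule`, `average_length`, `rank` (ties share a rank).
#' @export
averageOHRanking <- function(reports, tol = 1e-4) {
  if (!length(reports)) validation_error("need at least one bond report")
  avg <- vapply(reports, averageBondLength, numeric(1))
  mol <- vapply(reports, moleculeName, character(1))
  ord <- order(-avg)
  avg <- avg[ord]
  mol <- mol[ord]
  rank <- integer(length(avg))
  rank[1L] <- 1L
  for (i in seq_along(avg)[-1L]) {
    rank[i] <- if (avg[i - 1L] - avg[i] <= tol) rank[i - 1L] else i
  }
  data.frame(molecule = mol, average_length = avg, rank = rank,
             row.names = NULL)
}

#' Sign audit of Mulliken atomic charges
#'
#' Cross-checks provided Mulliken charges against chemical expectation:
#' hydrogens should carry positive and nitrogen/oxygen negative partial
#' charges. Any violation is flagged; carbons and other elements are counted
#' but not judged (their sign legitimately depends on substituents).
#'
#' @param thermo a \linkS4class{ThermoSummary} carrying `charges` in atom
#'   order.
#' @param geom the matching \linkS4class{Geometry} (same atom count/order).
#' @return list with `skipped` (TRUE when no charges are present), `flags`
#'   (data.frame `index`, `element`, `charge`, `issue`) and
#'   `element_counts` (table of audited elements).
#' @export
chargeAudit <- function(thermo, geom) {
  if (!length(thermo@charges)) {
    message("no Mulliken charges provided: audit skipped")
    return(list(skipped = TRUE, flags = NULL, element_counts = NULL))
  }
  if (length(thermo@charges) != nAtoms(geom))
    oxi_stop(sprintf("charge/geometry mismatch: %d charges vs %d atoms",
                     length(thermo@charges), nAtoms(geom)),
             "oxicap_alignment_error")
  el <- atomElements(geom)
  q <- thermo@charges
  bad_h <- el == "H" & q < 0
  bad_no <- el %in% c("N", "O") & q > 0
  flags <- data.frame(index = which(bad_h | bad_no),
                      element = el[bad_h | bad_no],
                      charge = q[bad_h | bad_no],
                      issue = ifelse(el[bad_h | bad_no] == "H",
                                     "negative hydrogen",
                                     "positive N/O"),
                      row.names = NULL)
  list(skipped = FALSE, flags = flags,
       element_counts = table(el[el %in% c("H", "N", "O")]))
}
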