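#' @include AllClasses.R
NULL

#' Read a molecular geometry in XYZ format
#'
#' Standard XYZ: line 1 the atom count, line 2 a comment (taken as the
#' molecule title), then one `element x y z` line per atom with coordinates
#' in Angstrom. Extended-XYZ extras are not parsed.
#'
#' @param path XYZ file path.
#' @return A \linkS4class{Geometry} with exactly the declared atom count.
#' @seealso [writeXYZ()], [makeGeometryFixture()]
#' @export
readXYZ <- function(path) {
  if (!file.exists(path)) format_error(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!(seq_along(lines) > 2 & !nzchar(trimws(lines)))]
  if (length(lines) < 2L) format_error("XYZ file too short")
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || n < 1L)
    format_error("line 1: expected a positive atom count")
  title <- trimws(lines[2L])
  atom_lines <- lines[-(1:2)]
  if (length(atom_lines) != n) {
    format_error(sprintf("declared %d atoms but found %d atom lines",
                         n, length(atom_lines)))
  }
  elements <- character(n)
  coords <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    fields <- strsplit(trimws(atom_lines[i]), "\\s+")[[1L]]
    if (length(fields) < 4L)
      format_error(sprintf("line %d: expected 'element x y z'", i + 2L))
    xyz <- suppressWarnings(as.numeric(fields[2:4]))
    if (any(is.na(xyz)))
      format_error(sprintf("line %d: unparsable coordinate", i + 2L))
    elements[i] <- fields[1L]
    coords[i, ] <- xyz
  }
  Geometry(elements, coords, title)
}

#' Write a molecular geometry in XYZ format
#'
#' Coordinates are written with six decimal places, so a write/read round
#' trip preserves them to 1e-6 Angstrom.
#'
#' @param geom a \linkS4class{Geometry}.
#' @param path output file path.
#' @param digits decimal places for coordinates.
#' @return `path`, invisibly.
#' @export
writeXYZ <- function(geom, path, digits = 6) {
  co <- atomCoords(geom)
  lines <- c(
    as.character(nAtoms(geom)),
    moleculeName(geom),
    sprintf(paste0("%-3s %.", digits, "f %.", digits, "f %.", digits, "f"),
            atomElements(geom), co[, 1], co[, 2], co[, 3]))
  writeLines(lines, path)
  invisible(path)
}
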