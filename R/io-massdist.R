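#' @include AllClasses.R
NULL

#' Read a polymer mass distribution from CSV
#'
#' Expects the header `mass_da, count`: one species per row with its molar
#' mass in Da and chain count.
#'
#' @param path CSV file path.
#' @param label distribution label (defaults to the file name).
#' @return A \linkS4class{MassDistribution}.
#' @seealso [writeMassDistribution()], [distributionMoments()]
#' @export
readMassDistribution <- function(path, label = basename(path)) {
  if (!file.exists(path)) format_error(sprintf("no such file: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("mass_da", "count"), names(df))
  if (length(missing_cols)) {
    format_error(sprintf("mass-distribution CSV lacks column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  MassDistribution(df$mass_da, df$count, label = label)
}

#' Write a polymer mass distribution to CSV
#'
#' @param x a \linkS4class{MassDistribution}.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeMassDistribution <- function(x, path) {
  utils::write.csv(data.frame(mass_da = x@mass, count = x@count), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
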