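#' @include AllClasses.R
NULL

## Long-format endpoint CSV: sample, conc_uM, replicate, signal.
## Control wells carry the control label (any conc value, conventionally 0).
read_endpoint_csv <- function(path) {
  if (!file.exists(path)) format_error(sprintf("no such file: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("sample", "conc_uM", "replicate", "signal"),
                          names(df))
  if (length(missing_cols)) {
    format_error(sprintf("endpoint CSV lacks column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  df
}

## Replicate-average a long endpoint table into per-sample EndpointSeries.
endpoint_series_from_table <- function(df, control, assay,
                                       troloxLabel = "Trolox") {
  if (!any(df$sample == control))
    validation_error(sprintf("no control rows labelled '%s'", control))
  ctrl_abs <- mean(df$signal[df$sample == control])
  agg <- stats::aggregate(signal ~ sample + conc_uM, df, mean)
  samples <- setdiff(unique(agg$sample), control)
  abs_max <- NA_real_
  if (assay == "frap") {
    if (!troloxLabel %in% samples)
      validation_error(sprintf("no '%s' series to define absMax", troloxLabel))
    abs_max <- max(agg$signal[agg$sample == troloxLabel])
  }
  out <- lapply(samples, function(s) {
    rows <- agg[agg$sample == s, ]
    ord <- order(rows$conc_uM)
    if (assay == "dpph") {
      EndpointSeries(s, rows$conc_uM[ord], rows$signal[ord],
                     absControl = ctrl_abs, assay = "dpph")
    } else {
      EndpointSeries(s, rows$conc_uM[ord], rows$signal[ord],
                     absMin = ctrl_abs, absMax = abs_max, assay = "frap")
    }
  })
  names(out) <- samples
  out
}

read_ros_csv <- function(path, control) {
  if (!file.exists(path)) format_error(sprintf("no such file: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("time_h", "sample", "rfu"), names(df))
  if (length(missing_cols)) {
    format_error(sprintf("time-course CSV lacks column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  agg <- stats::aggregate(rfu ~ sample + time_h, df, mean)
  times <- sort(unique(agg$time_h))
  samples <- unique(agg$sample)
  m <- matrix(NA_real_, length(samples), length(times),
              dimnames = list(samples, as.character(times)))
  for (i in seq_len(nrow(agg))) {
    m[agg$sample[i], as.character(agg$time_h[i])] <- agg$rfu[i]
  }
  rosTimecourse(times, m, control)
}

run_stage <- function(name, expr, report, verbose) {
  result <- tryCatch(expr, error = function(e) {
    message(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    structure(list(error = conditionMessage(e)), failed = TRUE)
  })
  if (verbose) message(sprintf("stage '%s' done", name))
  report[[name]] <- result
  report
}

#' Run the combined antioxidant characterization pipeline
#'
#' Executes every configured assay stage and assembles a combined report:
#' ORAC Trolox equivalents, DPPH IC50s, FRAP relative reducing power and
#' Trolox-equivalent concentrations, hydroxyl-radical-scavenging reductions,
#' polymer degradation verdicts, and conceptual-DFT descriptors, plus a
#' per-assay ranking of the samples. Stages not named in the configuration
#' are reported as `NULL`; a failing stage is recorded with an error marker
#' while the remaining stages still run.
#'
#' The configuration is a named list (or the path of a YAML file holding
#' one) with any subset of the sections:
#' \describe{
#'   \item{orac}{`plate` (long CSV path), `blank`, `trolox` labels.}
#'   \item{dpph}{`endpoints` (long endpoint CSV), `control` label.}
#'   \item{frap}{`endpoints`, `control`, `trolox` labels.}
#'   \item{hrs}{`timecourse` (CSV `time_h, sample, rfu`), `control` label.}
#'   \item{gpc}{`stats` (CSV `sample, mw_da, mn_da` plus optional `vp_ml`,
#'     `iv`), `reference` sample label, optional `retention_threshold`.}
#'   \item{cdft}{`thermo` (vector of thermochemistry JSON paths), optional
#'     `geometries` (XYZ paths), optional `h_hatom`, `h_electron` (Hartree).}
#' }
#'
#' @param config configuration list or YAML file path.
#' @param out optional path of the JSON report to write.
#' @param verbose log per-stage progress to stderr.
#' @return The combined report (a nested list), invisibly when `out` is
#'   given. Stages that failed carry an `error` element; the `failed`
#'   attribute of the report lists them.
#' @export
runPipeline <- function(config, out = NULL, verbose = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) validation_error("config must be a list or YAML path")
  report <- list(parameters = config, orac = NULL, dpph = NULL, frap = NULL,
                 hrs = NULL, gpc = NULL, cdft = NULL, rankings = list())

  if (!is.null(config$orac)) {
    report <- run_stage("orac", {
      cc <- config$orac
      blank <- if (is.null(cc$blank)) "BLANK" else cc$blank
      trolox <- if (is.null(cc$trolox)) "Trolox" else cc$trolox
      plate <- readPlateTimeSeries(cc$plate)
      samples <- setdiff(unique(wellInfo(plate)$sample), blank)
      fits <- lapply(samples, function(s) fitDoseResponse(plate, s, blank))
      names(fits) <- samples
      if (!trolox %in% samples)
        validation_error(sprintf("no '%s' wells for TE normalization", trolox))
      te <- vapply(fits, function(f)
        troloxEquivalent(f, fits[[trolox]])$te, numeric(1))
      list(slopes = lapply(fits, function(f) list(
             slope = drSlope(f), intercept = drIntercept(f),
             r_squared = drRSquared(f))),
           trolox_equivalent = as.list(te))
    }, report, verbose)
  }

  if (!is.null(config$dpph)) {
    report <- run_stage("dpph", {
      cc <- config$dpph
      control <- if (is.null(cc$control)) "CONTROL" else cc$control
      series <- endpoint_series_from_table(read_endpoint_csv(cc$endpoints),
                                           control, "dpph")
      est <- lapply(series, estimateIC50)
      ic50 <- vapply(est, ic50Value, numeric(1))
      list(scavenging = lapply(series, scavengingTable),
           ic50_uM = lapply(est, function(e)
             if (ic50Reached(e)) ic50Value(e) else "not reached"))
    }, report, verbose)
  }

  if (!is.null(config$frap)) {
    report <- run_stage("frap", {
      cc <- config$frap
      control <- if (is.null(cc$control)) "CONTROL" else cc$control
      trolox <- if (is.null(cc$trolox)) "Trolox" else cc$trolox
      series <- endpoint_series_from_table(read_endpoint_csv(cc$endpoints),
                                           control, "frap",
                                           troloxLabel = trolox)
      cal <- frapCalibration(series[[trolox]])
      rrp <- lapply(series, function(s)
        max(relativeReducingPower(s@absorbances, s@absMin, s@absMax)))
      list(calibration = list(slope = drSlope(cal),
                              intercept = drIntercept(cal),
                              r_squared = drRSquared(cal)),
           relative_reducing_power = rrp,
           trolox_equivalent_uM = lapply(series, function(s)
             frapTE(s, cal)))
    }, report, verbose)
  }

  if (!is.null(config$hrs)) {
    report <- run_stage("hrs", {
      cc <- config$hrs
      control <- if (is.null(cc$control)) "CTRL" else cc$control
      tc <- read_ros_csv(cc$timecourse, control)
      summ <- timecourseSummary(tc)
      final <- summ$reductions[, ncol(summ$reductions)]
      list(reductions = as.data.frame(summ$reductions),
           monotone = as.list(summ$monotone),
           final_reduction = as.list(final))
    }, report, verbose)
  }

  if (!is.null(config$gpc)) {
    report <- run_stage("gpc", {
      cc <- config$gpc
      if (is.null(cc$stats)) validation_error("gpc section needs 'stats'")
      df <- utils::read.csv(cc$stats, stringsAsFactors = FALSE)
      missing_cols <- setdiff(c("sample", "mw_da", "mn_da"), names(df))
      if (length(missing_cols))
        format_error(sprintf("gpc stats CSV lacks column(s): %s",
                             paste(missing_cols, collapse = ", ")))
      thr <- if (is.null(cc$retention_threshold)) 0.85
             else cc$retention_threshold
      stats_list <- lapply(seq_len(nrow(df)), function(i)
        polymerStats(df$mn_da[i], df$mw_da[i],
                     vp = if ("vp_ml" %in% names(df)) df$vp_ml[i] else NA,
                     iv = if ("iv" %in% names(df)) df$iv[i] else NA,
                     label = df$sample[i]))
      names(stats_list) <- df$sample
      ref <- if (is.null(cc$reference)) df$sample[1L] else cc$reference
      if (!ref %in% df$sample)
        validation_error(sprintf("reference sample '%s' not in stats", ref))
      verdicts <- lapply(stats_list, function(s)
        degradationReport(stats_list[[ref]], s, retentionThreshold = thr))
      list(dispersity = lapply(stats_list, function(s) s@dispersity),
           degradation = verdicts)
    }, report, verbose)
  }

  if (!is.null(config$cdft)) {
    report <- run_stage("cdft", {
      cc <- config$cdft
      thermo <- lapply(cc$thermo, readThermoSummary)
      names(thermo) <- vapply(thermo, moleculeName, character(1))
      oe <- t(vapply(thermo, orbitalEnergies, numeric(2)))
      desc <- descriptorsFromOrbitals(oe[, "e_homo"], oe[, "e_lumo"],
                                      molecule = rownames(oe))
      result <- list(descriptors = desc,
                     descriptors_displayed = formatDescriptors(desc))
      if (!is.null(cc$h_hatom)) {
        result$bde_kj_mol <- lapply(thermo, function(th)
          if (length(th@hRadicals) && !is.na(th@hNeutral))
            bdeTable(th, cc$h_hatom) else NULL)
      }
      h_e <- if (is.null(cc$h_electron)) 0 else cc$h_electron
      result$ip_kj_mol <- lapply(thermo, function(th)
        if (hasCationEnthalpy(th) && !is.na(th@hNeutral))
          computeIP(th@hNeutral, th@hCation, h_e) else NULL)
      if (!is.null(cc$geometries)) {
        reports <- lapply(cc$geometries, function(p) findOHBonds(readXYZ(p)))
        rk <- averageOHRanking(reports)
        result$oh_bonds <- rk
      }
      result
    }, report, verbose)
  }

  ok <- function(x) !is.null(x) && is.null(x$error)
  rankings <- list()
  if (ok(report$orac)) {
    te <- unlist(report$orac$trolox_equivalent)
    rankings$orac <- names(sort(-te))
  }
  if (ok(report$dpph)) {
    ic50 <- vapply(report$dpph$ic50_uM, function(v)
      if (is.numeric(v)) v else NA_real_, numeric(1))
    rankings$dpph <- names(sort(ic50, na.last = TRUE))
  }
  if (ok(report$frap))
    rankings$frap <- names(sort(-unlist(report$frap$relative_reducing_power)))
  if (ok(report$hrs))
    rankings$hrs <- names(sort(-unlist(report$hrs$final_reduction)))
  if (ok(report$cdft)) {
    d <- report$cdft$descriptors
    rankings$cdft_chi <- d$molecule[order(d$chi)]
    if (!is.null(report$cdft$oh_bonds))
      rankings$oh_length <- report$cdft$oh_bonds$molecule
  }
  report$rankings <- rankings

  failed <- names(Filter(function(x) isTRUE(attr(x, "failed")), report))
  attr(report, "failed") <- failed
  if (!is.null(out)) {
    dir.create(dirname(out), showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         null = "null", force = TRUE)
    return(invisible(report))
  }
  report
}
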