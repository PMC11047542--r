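#' @include AllClasses.R
NULL

#' Configuration for the ORAC plate simulator
#'
#' Parameters of the mechanistic kinetic model behind [simulateOracPlate()].
#' Defaults emulate the standard microplate protocol: 250 cycles at 60 s,
#' final antioxidant concentrations 0.625-20 uM in doubling steps, a 58 nM
#' fluorescein probe, and additive Gaussian read noise at 2% of the initial
#' signal.
#'
#' @param stoichiometry named numeric vector: radicals quenched per
#'   antioxidant molecule, one entry per sample (Trolox classically
#'   quenches 2).
#' @param concentrations final antioxidant concentrations, uM.
#' @param radicalFlux peroxyl-radical generation rate, uM/s.
#' @param kFluor,kAnti pseudo-bimolecular rate constants for radical attack
#'   on fluorescein and antioxidant, 1/(uM s).
#' @param kSink first-order loss of radicals to self-termination/buffer,
#'   1/s; must be > 0 so the radical level stays bounded once probe and
#'   antioxidant are depleted.
#' @param fluoresceinUM probe concentration, uM.
#' @param f0Rfu initial fluorescence reading, RFU.
#' @param cycleS seconds per read cycle.
#' @param nCycles number of read cycles (>= 2).
#' @param replicates wells per (sample, concentration).
#' @param noiseSd additive Gaussian read noise, RFU.
#' @param blankLabel sample label of the no-antioxidant wells.
#' @param seed RNG seed; the simulator is a pure function of
#'   (configuration, seed).
#' @return A validated configuration list of class `oracSimConfig`.
#' @seealso [simulateOracPlate()]
#' @export
oracSimConfig <- function(stoichiometry = c(Trolox = 2),
                          concentrations = c(0.625, 1.25, 2.5, 5, 10, 20),
                          radicalFlux = 0.05, kFluor = 1.33e-4, kAnti = 10,
                          kSink = 0.01, fluoresceinUM = 0.058, f0Rfu = 1000,
                          cycleS = 60, nCycles = 250, replicates = 3,
                          noiseSd = 20, blankLabel = "BLANK", seed = 1) {
  if (is.null(names(stoichiometry)) || any(!nzchar(names(stoichiometry))))
    validation_error("stoichiometry must be a named vector (sample -> n)")
  for (v in c(radicalFlux = radicalFlux, kFluor = kFluor, kAnti = kAnti,
              kSink = kSink, fluoresceinUM = fluoresceinUM, f0Rfu = f0Rfu,
              cycleS = cycleS)) {
    if (!is_number(v) || v <= 0)
      validation_error("all rates and scales must be positive numbers")
  }
  if (any(stoichiometry <= 0))
    validation_error("stoichiometries must be positive")
  if (nCycles < 2) validation_error("nCycles must be >= 2")
  if (any(concentrations < 0)) validation_error("concentrations must be >= 0")
  if (noiseSd < 0) validation_error("noiseSd must be >= 0")
  structure(list(stoichiometry = stoichiometry,
                 concentrations = concentrations, radicalFlux = radicalFlux,
                 kFluor = kFluor, kAnti = kAnti, kSink = kSink,
                 fluoresceinUM = fluoresceinUM, f0Rfu = f0Rfu,
                 cycleS = cycleS, nCycles = nCycles, replicates = replicates,
                 noiseSd = noiseSd, blankLabel = blankLabel, seed = seed),
            class = "oracSimConfig")
}

## Vectorized fixed-step RK4 for the radical quasi-steady-state model:
##   rho = flux / (kAnti*A + kFluor*F + kSink)
##   dF/dt = -kFluor * F * rho
##   dA/dt = -kAnti  * A * rho / n   (each molecule absorbs n radicals)
## Fixed 1 s steps keep the integration bit-reproducible.
orac_integrate <- function(A0, n, cfg, dt = 1) {
  keep <- seq(0, by = cfg$cycleS, length.out = cfg$nCycles)
  nw <- length(A0)
  F <- rep(cfg$fluoresceinUM, nw)
  A <- A0
  out <- matrix(NA_real_, cfg$nCycles, nw)
  deriv <- function(F, A) {
    rho <- cfg$radicalFlux / (cfg$kAnti * A + cfg$kFluor * F + cfg$kSink)
    list(dF = -cfg$kFluor * F * rho, dA = -cfg$kAnti * A * rho / n)
  }
  j <- 1L
  nsteps <- as.integer(keep[cfg$nCycles] / dt)
  for (step in 0:nsteps) {
    t <- step * dt
    if (j <= cfg$nCycles && abs(t - keep[j]) < dt / 2) {
      out[j, ] <- F
      j <- j + 1L
    }
    if (j > cfg$nCycles) break
    k1 <- deriv(F, A)
    k2 <- deriv(F + dt / 2 * k1$dF, pmax(A + dt / 2 * k1$dA, 0))
    k3 <- deriv(F + dt / 2 * k2$dF, pmax(A + dt / 2 * k2$dA, 0))
    k4 <- deriv(F + dt * k3$dF, pmax(A + dt * k3$dA, 0))
    F <- pmax(F + dt / 6 * (k1$dF + 2 * k2$dF + 2 * k3$dF + k4$dF), 0)
    A <- pmax(A + dt / 6 * (k1$dA + 2 * k2$dA + 2 * k3$dA + k4$dA), 0)
  }
  out
}

#' Simulate an ORAC kinetic plate
#'
#' Mechanistic generator of fluorescein-decay curves under a constant
#' peroxyl-radical flux: radicals partition between the probe, the
#' antioxidant and a sink in proportion to their rates, so an antioxidant
#' well shows a lag phase (probe protected while the antioxidant is
#' consumed) followed by blank-like decay. The resulting lag scales as
#' `n * [A] / flux`, making the net-AUC dose-response slope proportional to
#' the stoichiometry `n` -- the property the ORAC module's Trolox
#' equivalents recover. Integration is fixed-step RK4 at 1 s sampled at
#' cycle boundaries; Gaussian read noise is truncated at zero.
#'
#' @param cfg an [oracSimConfig()] configuration.
#' @return A \linkS4class{PlateTimeSeries} containing every (sample,
#'   concentration, replicate) well plus blank wells at concentration 0.
#' @export
simulateOracPlate <- function(cfg) {
  if (!inherits(cfg, "oracSimConfig")) cfg <- do.call(oracSimConfig, cfg)
  samples <- names(cfg$stoichiometry)
  wells <- expand.grid(replicate = seq_len(cfg$replicates),
                       conc_uM = cfg$concentrations, sample = samples,
                       stringsAsFactors = FALSE)
  blanks <- data.frame(replicate = seq_len(cfg$replicates), conc_uM = 0,
                       sample = cfg$blankLabel)
  wells <- rbind(wells[c("sample", "conc_uM", "replicate")],
                 blanks[c("sample", "conc_uM", "replicate")])
  wells$well <- sprintf("W%03d", seq_len(nrow(wells)))
  n <- ifelse(wells$sample == cfg$blankLabel, 1,
              cfg$stoichiometry[wells$sample])
  F <- orac_integrate(wells$conc_uM, n, cfg)
  signal <- F / cfg$fluoresceinUM * cfg$f0Rfu
  times <- seq(0, by = cfg$cycleS, length.out = cfg$nCycles)
  with_seed(cfg$seed, {
    if (cfg$noiseSd > 0) {
      signal <- pmax(signal + matrix(stats::rnorm(length(signal),
                                                  sd = cfg$noiseSd),
                                     nrow(signal)), 0)
    }
    PlateTimeSeries(times, wells, signal, kind = "fluorescence")
  })
}

#' Simulate an endpoint dose series (DPPH or FRAP)
#'
#' DPPH: stoichiometric bleaching of a fixed radical pool,
#' `Abs = Abs0 * max(0, 1 - n [A] / [DPPH]0)`, so the analytic IC50 is
#' `[DPPH]0 / (2 n)`. FRAP: linear chromogen formation,
#' `Abs = absMin + slope * potency * [A]`, with potency 1 reproducing the
#' Trolox calibration line by construction. Replicate readings receive
#' truncated Gaussian noise and are averaged.
#'
#' @param kind `"dpph"` or `"frap"`.
#' @param potencies named numeric vector; for DPPH the stoichiometry `n` of
#'   each sample, for FRAP the potency relative to Trolox (a `"Trolox"`
#'   entry is required to define `absMax`).
#' @param concentrations tested concentrations, uM.
#' @param noiseSd additive absorbance noise, AU.
#' @param seed RNG seed.
#' @param replicates replicate wells averaged per concentration.
#' @param abs0 DPPH control absorbance, AU.
#' @param dpph0 initial DPPH concentration, uM.
#' @param absMin FRAP assay floor absorbance, AU.
#' @param frapSlope FRAP chromogen slope, AU per uM at potency 1.
#' @return Named list of \linkS4class{EndpointSeries}, one per sample.
#' @export
simulateEndpointAssay <- function(kind = c("dpph", "frap"), potencies,
                                  concentrations, noiseSd = 0.018, seed = 1,
                                  replicates = 3, abs0 = 0.9, dpph0 = 300,
                                  absMin = 0.1, frapSlope = 0.02) {
  kind <- match.arg(kind)
  if (is.null(names(potencies)) || any(!nzchar(names(potencies))))
    validation_error("potencies must be a named vector (sample -> value)")
  if (any(potencies <= 0)) validation_error("potencies must be positive")
  if (kind == "frap" && !"Trolox" %in% names(potencies))
    validation_error("FRAP simulation needs a 'Trolox' entry to set absMax")
  with_seed(seed, {
    measure <- function(true_abs) {
      reads <- matrix(stats::rnorm(length(true_abs) * replicates,
                                   mean = rep(true_abs, each = replicates),
                                   sd = noiseSd), nrow = replicates)
      colMeans(pmax(reads, 0))
    }
    if (kind == "dpph") {
      abs_control <- measure(abs0)
      out <- lapply(names(potencies), function(s) {
        true_abs <- abs0 * pmax(0, 1 - potencies[[s]] * concentrations / dpph0)
        EndpointSeries(s, concentrations, measure(true_abs),
                       absControl = abs_control, assay = "dpph")
      })
    } else {
      abs_min <- measure(absMin)
      series_abs <- lapply(names(potencies), function(s)
        measure(absMin + frapSlope * potencies[[s]] * concentrations))
      names(series_abs) <- names(potencies)
      abs_max <- max(series_abs[["Trolox"]])
      out <- lapply(names(potencies), function(s)
        EndpointSeries(s, concentrations, series_abs[[s]],
                       absMin = abs_min, absMax = abs_max, assay = "frap"))
    }
    names(out) <- names(potencies)
    out
  })
}

#' Simulate a hydroxyl-radical-scavenging time course
#'
#' The control (radical generator alone) fluorescence grows saturating in
#' time, `C(t) = R0 + (Rmax - R0)(1 - exp(-g t))`; a scavenger suppresses it
#' exponentially in its rate, `S(t) = C(t) exp(-k t)`, so the noise-free
#' percent reduction is `100 (1 - exp(-k t))` -- monotone in both time and
#' rate. Read noise is multiplicative (constant coefficient of variation, as
#' fluorescence plate readers exhibit; an additive floor would swamp the
#' small early-time signals); replicates are averaged and their SD retained.
#'
#' @param scavengingRates named numeric vector of first-order scavenging
#'   rates, per hour (>= 0).
#' @param times measurement times, hours.
#' @param noiseCv coefficient of variation of a single read.
#' @param seed RNG seed.
#' @param replicates replicate wells averaged per reading.
#' @param baselineRfu,maxRfu control fluorescence at time 0 and saturation.
#' @param growthPerH control saturation rate, per hour.
#' @param controlLabel label of the control row.
#' @return A \linkS4class{RosTimecourse} (replicate means, SDs in `rfuSd`).
#' @export
simulateHRS <- function(scavengingRates, times = c(0, 0.5, 1, 2, 4, 8),
                        noiseCv = 0.02, seed = 1, replicates = 3,
                        baselineRfu = 50, maxRfu = 1000, growthPerH = 0.5,
                        controlLabel = "CTRL") {
  if (is.null(names(scavengingRates)) || any(!nzchar(names(scavengingRates))))
    validation_error("scavengingRates must be a named vector (sample -> k)")
  if (any(scavengingRates < 0)) validation_error("rates must be >= 0")
  ctrl_true <- baselineRfu + (maxRfu - baselineRfu) *
    (1 - exp(-growthPerH * times))
  true_rfu <- rbind(ctrl_true,
                    t(vapply(scavengingRates,
                             function(k) ctrl_true * exp(-k * times),
                             numeric(length(times)))))
  rownames(true_rfu) <- c(controlLabel, names(scavengingRates))
  with_seed(seed, {
    reads <- array(stats::rnorm(length(true_rfu) * replicates, mean = 1,
                                sd = noiseCv),
                   dim = c(dim(true_rfu), replicates))
    reads <- pmax(sweep(reads, c(1, 2), true_rfu, `*`), 0)
    m <- apply(reads, c(1, 2), mean)
    s <- apply(reads, c(1, 2), stats::sd)
    dimnames(m) <- dimnames(s) <- dimnames(true_rfu)
    rosTimecourse(times, m, controlLabel, rfuSd = s)
  })
}

#' Configuration for the random-scission simulator
#'
#' @param nChains number of polymer chains.
#' @param chainLength monomers per chain (>= 1).
#' @param monomerMass monomer molar mass, Da.
#' @param scissionProb probability `p` in [0, 1] that any inter-monomer bond
#'   is cleaved.
#' @param seed RNG seed.
#' @return A validated configuration list of class `scissionConfig`.
#' @seealso [simulateScission()]
#' @export
scissionConfig <- function(nChains = 10000, chainLength = 4000,
                           monomerMass = 400, scissionProb = 0.01, seed = 1) {
  if (nChains < 1) validation_error("nChains must be >= 1")
  if (chainLength < 1) validation_error("chainLength must be >= 1")
  if (!is_number(monomerMass) || monomerMass <= 0)
    validation_error("monomerMass must be positive")
  if (!is_number(scissionProb) || scissionProb < 0 || scissionProb > 1)
    validation_error("scissionProb must lie in [0, 1]")
  structure(list(nChains = as.integer(nChains),
                 chainLength = as.integer(chainLength),
                 monomerMass = monomerMass, scissionProb = scissionProb,
                 seed = seed),
            class = "scissionConfig")
}

#' Simulate ROS-driven random chain scission
#'
#' Each inter-monomer bond of every chain breaks independently with
#' probability `p (1 - protection)`, emulating hydroxyl-radical hydrogen
#' abstraction followed by beta-scission; an antioxidant's protection factor
#' scales the effective scission probability down. Fragment lengths are
#' tallied into a mass distribution. Total monomer mass is conserved
#' exactly, and in the heavy-scission limit the dispersity approaches the
#' most-probable-distribution value `2 - p`.
#'
#' @param cfg a [scissionConfig()] configuration.
#' @param protection scavenging efficiency in [0, 1]; 1 suppresses all
#'   scission.
#' @return A \linkS4class{MassDistribution} of fragment masses.
#' @export
simulateScission <- function(cfg, protection = 0) {
  if (!inherits(cfg, "scissionConfig")) cfg <- do.call(scissionConfig, cfg)
  if (!is_number(protection) || protection < 0 || protection > 1)
    validation_error("protection must lie in [0, 1]")
  p_eff <- cfg$scissionProb * (1 - protection)
  L <- cfg$chainLength
  counts <- numeric(L)
  with_seed(cfg$seed, {
    if (p_eff == 0 || L == 1L) {
      counts[L] <- cfg$nChains
    } else {
      for (i in seq_len(cfg$nChains)) {
        k <- stats::rbinom(1L, L - 1L, p_eff)
        if (k == 0L) {
          counts[L] <- counts[L] + 1
        } else {
          cuts <- sort(sample.int(L - 1L, k))
          counts <- counts + tabulate(diff(c(0L, cuts, L)), nbins = L)
        }
      }
    }
  })
  keep <- counts > 0
  MassDistribution(mass = (seq_len(L) * cfg$monomerMass)[keep],
                   count = counts[keep],
                   label = sprintf("scission p=%g protection=%g",
                                   cfg$scissionProb, protection))
}

#' Build a geometry fixture (optionally writing XYZ)
#'
#' Convenience constructor for small test geometries from an atom table;
#' writes a standard XYZ file when `path` is given, which [readXYZ()]
#' round-trips.
#'
#' @param atoms data.frame with columns `element`, `x`, `y`, `z` (Angstrom).
#' @param title molecule name for the XYZ comment line.
#' @param path optional output XYZ path.
#' @return A \linkS4class{Geometry}.
#' @export
makeGeometryFixture <- function(atoms, title = "fixture", path = NULL) {
  g <- Geometry(atoms$element, cbind(atoms$x, atoms$y, atoms$z), title)
  if (!is.null(path)) writeXYZ(g, path)
  g
}

#' Synthetic hydroxyl-bearing geometry with prescribed O-H lengths
#'
#' Builds a minimal synthetic surrogate geometry carrying one isolated O-H
#' pair per requested bond length (pairs are spaced 10 Angstrom apart so no
#' spurious contacts fall under the detection cutoff). Useful for carrying
#' published bond-length tables through [findOHBonds()] without the full
#' optimized structures, which are rarely published.
#'
#' @param molecule molecule name.
#' @param lengths numeric vector of O-H bond lengths, Angstrom.
#' @return A \linkS4class{Geometry} with `2 * length(lengths)` atoms.
#' @export
syntheticOHGeometry <- function(molecule, lengths) {
  if (!length(lengths) || any(!is.finite(lengths)) || any(lengths <= 0))
    validation_error("lengths must be positive numbers")
  n <- length(lengths)
  atoms <- data.frame(
    element = rep(c("O", "H"), n),
    x = as.vector(rbind(0, lengths)),
    y = rep((seq_len(n) - 1) * 10, each = 2),
    z = 0)
  makeGeometryFixture(atoms, title = molecule)
}
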