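---
title: "Models and methods behind oxicap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind oxicap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxicap)
```

`oxicap` implements the computations behind a standard panel of acellular
antioxidant assays — ORAC, DPPH, FRAP and hydroxyl-radical scavenging —
together with polymer molar-mass statistics for hyaluronic-acid (HA)
protection studies and Koopmans-type conceptual-DFT reactivity descriptors.
This vignette documents the models, the tunable parameters and the
numerical conventions, and states explicitly what the synthetic-data
generators do and do not emulate.

## ORAC kinetics

The oxygen radical absorbance capacity assay reads fluorescein fluorescence
once per cycle while an azo initiator (AAPH) generates peroxyl radicals at a
near-constant flux. The area under the decay curve is the discrete,
reference-normalized sum

$$\mathrm{AUC} = \frac{R_1}{R_1} + \frac{R_2}{R_1} + \dots + \frac{R_n}{R_1},$$

with $R_1$ the first reading of the kinetic run (the first post-addition
time point, index 1 by default). This is deliberately a unit-step
rectangular sum in cycle units, not a trapezoid in real time: it is the
formula plate-reader protocols use, and it keeps the AUC scale-invariant in
the signal. A trapezoidal mode over real time is available
(`computeAUC(..., method = "trapezoid")`) for irregular grids.

Net AUC is the blank-corrected area, `netAUC = AUC_antioxidant -
AUC_blank`; negative values are reported with a pro-oxidant flag rather
than clamped. Replicate net AUCs are averaged per concentration *before*
fitting (matching the usual per-concentration calibration plot), and the
dose-response line is ordinary least squares *with* intercept — a
through-origin fit is not assumed because real plates show small
concentration-independent offsets. The Trolox equivalent is the slope
ratio `TE = slope_sample / slope_Trolox`, exactly 1 for Trolox against
itself.

### The kinetic simulator

`simulateOracPlate()` integrates a quasi-steady-state radical partitioning
model. With radical level
$\rho = \Phi / (k_A A + k_F F + k_s)$ for flux $\Phi$,

$$\frac{dF}{dt} = -k_F F \rho, \qquad
  \frac{dA}{dt} = -\frac{k_A A \rho}{n},$$

where $n$ is the antioxidant's stoichiometry (radicals quenched per
molecule; 2 for the classical chromanol). While $k_A A$ dominates, nearly
the whole flux discharges into the antioxidant, which therefore depletes
at $\Phi / n$: the lag time is $n A_0 / \Phi$ and the net-AUC slope in
cycle units is analytically $n / (\Phi \, \Delta t_{cycle})$. This closed
form is the parameter-recovery oracle used by the tests: the fitted slope
must land within 10% of it, and two samples with stoichiometries 2 and 1
must recover a TE ratio of 2.

Defaults: flux 0.05 µM/s, $k_A = 10$, $k_F = 1.33\times10^{-4}$
µM⁻¹s⁻¹, sink $k_s = 0.01$ s⁻¹, 58 nM probe, 250 cycles of 60 s,
concentrations 0.625–20 µM in doubling steps, 3 replicates. The rate
constants are chosen so that (i) the probe is a trace reporter (its radical
consumption is negligible against the sink), (ii) the depletion regime
holds across the tested concentrations, and (iii) the blank decays on a
\~25-cycle scale, well inside the run. The sink must be positive so the
radical level stays bounded once probe and antioxidant are exhausted.
Integration is fixed-step RK4 at 1 s sampled at cycle boundaries —
adaptive steppers would introduce tolerance-dependent nondeterminism into
what must be a pure function of (configuration, seed).

## DPPH endpoint analysis

Scavenging is the normalized decolorization
`100 (Abs_control - Abs_sample) / Abs_control`; negative values are
reported as-is. The IC50 — the concentration scavenging 50% of the initial
radicals — is found by **linear interpolation in concentration** between
the two measured points bracketing 50%. A four-parameter logistic fit is
deliberately excluded: a sparse endpoint series of 4–7 points cannot
constrain one, and the interpolation estimate is reproducible without
starting values. A series whose maximum stays below 50% yields "not
reached" (the usual outcome for weak or sterically hindered scavengers);
multiple 50% crossings raise an ambiguity error listing all crossings, and
a series already above 50% at its lowest point errors rather than
extrapolates.

The simulator uses stoichiometric bleaching of a fixed radical pool,
`Abs = Abs0 · max(0, 1 - n[A]/[DPPH]0)`, whose analytic IC50 is
`[DPPH]0 / (2n)` — with the default 300 µM pool and $n = 2$, 75 µM. The
recovery test requires the interpolated estimate within 3%.

## FRAP endpoint analysis

Relative reducing power is the range-normalized absorbance
`100 (Abs - Abs_min) / (Abs_max - Abs_min)`, affine-invariant in the three
absorbances. `Abs_min` is the assay floor (control) and `Abs_max` the top
standard (Trolox) absorbance, taken at the highest common tested
concentration — the natural convention when the protocol leaves the
reference concentration unstated; both are configurable. Values above 100%
are legitimate and preserved. Trolox-equivalent concentrations invert the
OLS calibration line, `TE_c = (Abs_c - intercept)/slope`. The simulated
potency-recovery check estimates the potency as the regression slope of
`TE` on concentration rather than averaging per-concentration ratios: at
the lowest doses the per-point ratio is dominated by read noise, while the
slope pools the whole series.

## Hydroxyl-radical scavenging time courses

Percent ROS reduction at a grid time is
`100 (RFU_control - RFU_sample) / RFU_control`; times off the measurement
grid are an error, never interpolated, and no background subtraction is
applied beyond what the input carries. `timecourseSummary()` adds a
per-sample monotonicity flag (reduction non-decreasing in time). Replicates
(3 by default) are averaged before the reduction is computed; their SD is
carried alongside.

The simulator grows the control saturatingly,
$C(t) = R_0 + (R_{max} - R_0)(1 - e^{-g t})$, and suppresses a scavenger's
signal as $S(t) = C(t)\,e^{-k t}$, so the noise-free reduction is the
closed form $100(1 - e^{-kt})$, monotone in both $t$ and $k$. Read noise
is **multiplicative** (constant CV, 2% by default): fluorescence readers
show approximately constant relative error, and an additive noise floor
sized to the saturated signal would overwhelm the small early-time control
signal and make the reduction statistic meaningless at $t \lesssim 1$ h.
The recovery test requires simulated reductions within 5 percentage points
of the closed form.

## Polymer mass statistics

From a discrete species distribution, `distributionMoments()` computes

$$M_n = \frac{\sum n_i M_i}{\sum n_i}, \qquad
  M_w = \frac{\sum n_i M_i^2}{\sum n_i M_i}, \qquad
  D = M_w / M_n \ge 1 .$$

Chromatogram deconvolution is out of scope — detector calibration is
instrument-specific — so the module consumes either explicit distributions
or `(Mw, Mn)` pairs as chromatography software reports them. Printed pairs
can violate $M_w \ge M_n$ by rounding, so `dispersityFromMwMn()` warns
instead of failing. Peak retention volume and intrinsic viscosity are
pass-through metadata (no Mark–Houwink conversion is attempted, and IV
units are carried verbatim). `degradationReport()` reduces a before/after
pair to an Mw-retention ratio with a protected/degraded verdict at a
configurable threshold, default 0.85 — comfortably between the \~0.96
retention of a protected polymer and the \~0.19 of a peroxide-degraded one.

The scission simulator breaks each inter-monomer bond independently with
probability $p(1 - \text{protection})$, conserving total monomer mass
exactly. For heavy scission the fragment-length law approaches the most
probable (geometric) distribution, whose dispersity is $2 - p$; the
recovery test runs 10,000 chains of 4,000 monomers at $p = 0.01$ and
requires dispersity within 0.02 of 1.99. These sizes keep the whole
recovery suite in the low seconds while the sampling error of the
dispersity stays an order of magnitude below the tolerance.

## Conceptual-DFT descriptors

From frontier orbital energies (eV), Koopmans-type definitions give
hardness $\eta = (E_{LUMO} - E_{HOMO})/2$, softness $\sigma = 1/\eta$,
electronegativity $\chi = -(E_{HOMO}+E_{LUMO})/2$, chemical potential
$\mu = -\chi$ and electrophilicity $\omega = \chi^2/(2\eta)$. All
computation keeps full double precision; the identities
$\sigma\eta = 1$, $\mu = -\chi$, $\Delta E = 2\eta$, $\omega \ge 0$ are
property-tested over random orbital energies.

**Display truncation.** Published descriptor tables in this literature are
written by *truncating* values at the displayed precision, not rounding
(a truncated 2.3195 prints as 2.31), and their softness and
electrophilicity columns are computed from the already-displayed hardness
and electronegativity. `formatDescriptors()` reproduces exactly this
convention (hardness truncated to 2 decimals, the rest to 3, $\sigma$ and
$\omega$ recomputed from the displayed values), with
`electrophilicityFromRounded()` exposed separately for feeding printed
$\chi$, $\eta$ pairs. `truncateDigits()` carries a guard digit so binary
representation error cannot flip the last displayed digit.

Bond dissociation enthalpies and ionization potentials convert enthalpy
differences with 1 Hartree = 2625.4996 kJ/mol (eV conversions use
27.211386 eV/Hartree). The electron enthalpy defaults to 0 — the ion
convention — and is overridable; the hydrogen-atom enthalpy has **no
default** and must be supplied (a common choice is −0.5 Hartree electronic
energy plus a 2.5 RT thermal correction), because silently assuming one
would make BDEs misleadingly comparable across incompatible thermochemistry
conventions. Both quantities are translation-invariant in the enthalpy
zero point, which the tests assert.

O–H bonds are detected as O–H pairs within 1.2 Å (typical hydroxyl bonds
are 0.95–1.0 Å; the next O···H contacts are far above the cutoff), and
molecules are ranked by descending average O–H length — a longer average
hydroxyl bond is weaker and marks a more willing hydrogen donor. Averages
within 1e-4 Å (the display precision of bond-length tables) are reported
as tied. The Mulliken charge audit is a sign check only — hydrogens
positive, N/O negative — since computing populations is a quantum-chemistry
task, not an analysis one.

## Synthetic data: what it does and does not show

The generators reproduce the *statistical structure* the analyses assume:
lag-phase kinetics with additive truncated read noise, stoichiometric
endpoint bleaching, linear chromogen formation, saturating ROS time
courses with constant-CV noise, and memoryless random scission. They are
pure functions of (configuration, seed), which the tests verify
bit-for-bit.

They deliberately do **not** model: the real radical chain chemistry of
AAPH or Cu/Fenton systems, DCFH-DA photochemistry and autoxidation,
solvent and pH effects on endpoint assays, detector saturation or drift,
or non-random (enzymatic) polymer cleavage. Passing recovery tests
therefore demonstrates that the analysis code inverts its own model
assumptions correctly at realistic noise levels — not that those
assumptions hold for any particular instrument or chemistry. Noise
magnitudes (2% of the initial signal) are a documented convention, not a
fitted value.

## Numerical conventions and degenerate inputs

* Classed error conditions (`oxicap_format_error`,
  `oxicap_validation_error` and operation-specific subclasses) separate
  malformed files from scientifically degenerate inputs (zero reference
  fluorescence, non-positive control absorbance, inverted FRAP range,
  empty distributions, non-positive hardness).
* Times are seconds internally; cycle-index plates convert at read time.
* Dose–response fits require two distinct concentrations; zero
  concentration variance is a singular-fit error rather than an `NA`
  slope.
* A Trolox slope within 1e-12 of zero makes the TE undefined (error), not
  infinite.
* Readers order wells by (sample, concentration, replicate) and never
  otherwise reorder; all writer/reader pairs round-trip losslessly at the
  declared precision (6 decimals for XYZ coordinates, full double
  precision for CSV/JSON).

## Known limitations

* IC50 values depend on the bracketing pair; with very sparse series the
  linear-interpolation error is bounded only by the concentration spacing.
* The ORAC AUC in cycle units is comparable across runs only at equal
  cycle time; use the trapezoid mode to compare across acquisition
  schedules.
* `formatDescriptors()` matches tables produced under the truncation
  convention; tables rounded conventionally will differ by one unit in the
  last digit roughly half the time.
* GPC statistics are taken at face value from the instrument; no
  correction for column calibration or dn/dc is attempted.
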