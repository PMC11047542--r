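test_that("simulators are pure functions of (config, seed)", {
  cfg <- oracSimConfig(stoichiometry = c(Trolox = 2), nCycles = 20,
                       concentrations = c(1, 10), replicates = 2, seed = 8)
  p1 <- simulateOracPlate(cfg)
  p2 <- simulateOracPlate(cfg)
  expect_identical(signalMatrix(p1), signalMatrix(p2))

  e1 <- simulateEndpointAssay("dpph", c(A = 1), c(10, 20), seed = 5)
  e2 <- simulateEndpointAssay("dpph", c(A = 1), c(10, 20), seed = 5)
  expect_identical(e1$A@absorbances, e2$A@absorbances)

  t1 <- simulateHRS(c(A = 0.3), seed = 5)
  t2 <- simulateHRS(c(A = 0.3), seed = 5)
  expect_identical(t1@rfu, t2@rfu)

  s1 <- simulateScission(scissionConfig(50, 100, 400, 0.05, seed = 5))
  s2 <- simulateScission(scissionConfig(50, 100, 400, 0.05, seed = 5))
  expect_identical(s1@count, s2@count)
})

test_that("a zero-concentration antioxidant well decays like the blank", {
  cfg <- oracSimConfig(stoichiometry = c(S = 2), concentrations = c(0, 10),
                       nCycles = 50, replicates = 1, noiseSd = 0, seed = 1)
  p <- simulateOracPlate(cfg)
  wi <- wellInfo(p)
  sig <- signalMatrix(p)
  zero_well <- sig[, wi$sample == "S" & wi$conc_uM == 0]
  blank <- sig[, wi$sample == "BLANK"]
  expect_equal(zero_well, blank, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("net AUC slope scales with stoichiometry (2:1 recovery)", {
  cfg <- oracSimConfig(stoichiometry = c(n2 = 2, n1 = 1), seed = 1)
  p <- simulateOracPlate(cfg)
  s2 <- drSlope(fitDoseResponse(p, "n2"))
  s1 <- drSlope(fitDoseResponse(p, "n1"))
  expect_lt(abs(s2 / s1 - 2), 0.2)
})

test_that("DPPH simulation respects its endpoints", {
  es <- simulateEndpointAssay("dpph", c(A = 2), c(0, 150), abs0 = 0.9,
                              dpph0 = 300, noiseSd = 0, seed = 1)
  expect_equal(es$A@absorbances[1], 0.9)   # [A] = 0 -> control absorbance
  expect_equal(es$A@absorbances[2], 0)     # n*[A] = [DPPH]0 -> full bleach
})

test_that("FRAP potency 1 reproduces the calibration line by construction", {
  es <- simulateEndpointAssay("frap", c(Trolox = 1), c(1, 5, 10),
                              noiseSd = 0, seed = 1, absMin = 0.1,
                              frapSlope = 0.02)
  cal <- frapCalibration(es$Trolox)
  expect_equal(drSlope(cal), 0.02, tolerance = 1e-9)
  expect_equal(drIntercept(cal), 0.1, tolerance = 1e-9)
})

test_that("HRS simulation: k = 0 tracks the control; closed-form reduction at 8 h", {
  tc <- simulateHRS(c(inert = 0), seed = 2)
  s <- timecourseSummary(tc)
  # individual points fluctuate with the read noise; their mean sits at 0
  expect_lt(abs(mean(s$reductions["inert", ])), 3)
  expect_true(all(abs(s$reductions["inert", ]) < 8))

  k <- -log(0.14) / 8  # exp(-8k) = 0.14
  tc2 <- simulateHRS(c(A = k), seed = 2)
  expect_lt(abs(percentRosReduction(tc2, "A", 8) - 86), 3)
})

test_that("scission conserves monomer mass exactly and degenerates correctly", {
  cfg <- scissionConfig(200, 150, 400, 0.02, seed = 6)
  md <- simulateScission(cfg)
  expect_equal(sum(md@mass * md@count), 200 * 150 * 400)

  intact <- simulateScission(scissionConfig(50, 100, 400, 0, seed = 1))
  expect_equal(length(intact@mass), 1L)
  expect_equal(distributionMoments(intact)@dispersity, 1)

  shielded <- simulateScission(scissionConfig(50, 100, 400, 0.5, seed = 1),
                               protection = 1)
  expect_equal(shielded@mass, intact@mass)
  expect_equal(shielded@count, intact@count)
})

test_that("Mn decreases as the effective scission probability grows", {
  mn <- vapply(c(0.001, 0.005, 0.02, 0.08), function(p)
    distributionMoments(
      simulateScission(scissionConfig(300, 400, 400, p, seed = 7)))@mn,
    numeric(1))
  expect_true(all(diff(mn) < 0))
})

test_that("geometry fixtures write valid XYZ that round-trips", {
  f <- withr::local_tempfile(fileext = ".xyz")
  g <- makeGeometryFixture(
    data.frame(element = c("O", "H"), x = c(0, 0.9741), y = 0, z = 0),
    title = "surrogate", path = f)
  g2 <- readXYZ(f)
  expect_equal(atomCoords(g2), atomCoords(g), tolerance = 1e-9)
  one <- makeGeometryFixture(data.frame(element = "He", x = 0, y = 0, z = 0))
  expect_equal(nAtoms(one), 1L)
  expect_error(makeGeometryFixture(
    data.frame(element = "Xx", x = 0, y = 0, z = 0)))
})
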