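test_that("DPPH scavenging percentage and its scale invariance", {
  expect_equal(dpphScavenging(1.0, 0.5), 50)
  expect_equal(dpphScavenging(1.0, 1.0), 0)
  expect_equal(dpphScavenging(0.8, 0.4), 50)
  expect_equal(dpphScavenging(0.5, 0.6), -20)  # reported, not clamped
  expect_error(dpphScavenging(0, 0.5),
               class = "oxicap_degenerate_control_error")
  set.seed(31)
  for (i in 1:20) {
    ac <- runif(1, 0.2, 2); as_ <- runif(1, 0, 2); k <- runif(1, 0.1, 10)
    expect_equal(dpphScavenging(k * ac, k * as_), dpphScavenging(ac, as_),
                 tolerance = 1e-12)
  }
})

test_that("IC50 interpolation brackets 50% and reports 'not reached'", {
  s <- EndpointSeries("x", c(50, 70), c(0.6, 0.4), absControl = 1,
                      assay = "dpph")
  est <- estimateIC50(s)
  expect_true(ic50Reached(est))
  expect_equal(ic50Value(est), 60)
  expect_true(est@bracket$scavenging[1] < 50 && est@bracket$scavenging[2] >= 50)

  weak <- EndpointSeries("RvD1-like", c(20, 40, 80), c(0.98, 0.97, 0.95),
                         absControl = 1, assay = "dpph")
  est2 <- estimateIC50(weak)
  expect_false(ic50Reached(est2))
  expect_true(is.na(ic50Value(est2)))

  wob <- EndpointSeries("w", c(10, 20, 30, 40), c(0.4, 0.6, 0.3, 0.7),
                        absControl = 1, assay = "dpph")
  expect_error(estimateIC50(wob), class = "oxicap_ambiguous_ic50_error")
})

test_that("IC50 on a strictly increasing curve lies inside its bracket", {
  set.seed(32)
  for (i in 1:20) {
    conc <- sort(runif(6, 1, 100))
    scav <- sort(runif(6, 0, 100))
    if (max(scav) < 50 || min(scav) >= 50) next
    s <- EndpointSeries("r", conc, 1 - scav / 100, absControl = 1,
                        assay = "dpph")
    est <- estimateIC50(s)
    expect_true(ic50Value(est) >= est@bracket$conc[1])
    expect_true(ic50Value(est) <= est@bracket$conc[2])
  }
})

test_that("IC50 recovery on the stoichiometric model matches [DPPH]0/(2n)", {
  es <- simulateEndpointAssay("dpph", potencies = c(AA = 2),
                              concentrations = c(20, 40, 60, 80),
                              dpph0 = 300, seed = 1)
  est <- estimateIC50(es$AA)
  expect_true(ic50Reached(est))
  expect_lt(abs(ic50Value(est) - 75), 2)  # analytic IC50 = 300/(2*2)
})

test_that("relative reducing power spans 0-100 over its range and is affine-invariant", {
  expect_equal(relativeReducingPower(0.9, 0.1, 0.9), 100)
  expect_equal(relativeReducingPower(0.1, 0.1, 0.9), 0)
  expect_equal(relativeReducingPower(0.5, 0.1, 0.9), 50)
  expect_equal(relativeReducingPower(1.2, 0.1, 0.9), 137.5)  # >100 allowed
  expect_error(relativeReducingPower(0.5, 0.9, 0.1),
               class = "oxicap_degenerate_range_error")
  set.seed(33)
  for (i in 1:20) {
    a <- runif(3); a[3] <- a[2] + runif(1, 0.1, 1); d <- rnorm(1)
    expect_equal(relativeReducingPower(a[1] + d, a[2] + d, a[3] + d),
                 relativeReducingPower(a[1], a[2], a[3]), tolerance = 1e-9)
  }
})

test_that("FRAP TE inverts the calibration line", {
  cal <- doseResponse("Trolox", c(1, 5, 10), 0.1 + 0.02 * c(1, 5, 10))
  s <- EndpointSeries("x", c(10, 3), c(0.1 + 0.02 * 10, 0.1),
                      absMin = 0.1, absMax = 0.5, assay = "frap")
  te <- frapTE(s, cal)
  expect_equal(te$te_uM, c(10, 0), tolerance = 1e-9)
  bad <- doseResponse("down", c(1, 2), c(2, 1))
  expect_error(frapTE(s, bad), class = "oxicap_invalid_calibration_error")
})

test_that("FRAP potency recovery: TE slope reproduces the simulated potency ratio", {
  es <- simulateEndpointAssay("frap", potencies = c(Trolox = 1, S = 0.5),
                              concentrations = c(0.3125, 0.625, 1.25, 2.5,
                                                 5, 10, 20),
                              seed = 7)
  cal <- frapCalibration(es$Trolox)
  te <- frapTE(es$S, cal)
  ratio <- unname(coef(lm(te_uM ~ conc_uM, te))[2])
  expect_lt(abs(ratio - 0.5), 0.05)
})
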