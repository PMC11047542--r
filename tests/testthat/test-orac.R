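test_that("computeAUC matches the reference-normalized unit-step sum", {
  expect_equal(computeAUC(c(5, 5, 5, 5, 5)), 5)        # every term 1
  expect_equal(computeAUC(c(100, 80, 60)), 2.4)        # 1 + 0.8 + 0.6
  expect_equal(computeAUC(c(100, 0, 0)), 1)            # full quench after t0
  # terms before the reference index are excluded; first term is exactly 1
  expect_equal(computeAUC(c(7, 100, 50), r1Index = 2), 1.5)
  expect_error(computeAUC(c(0, 1, 2)),
               class = "oxicap_degenerate_reference_error")
})

test_that("computeAUC is invariant under signal rescaling", {
  set.seed(21)
  for (i in 1:20) {
    sig <- abs(rnorm(50, 100, 30)) + 1
    c0 <- runif(1, 0.1, 50)
    expect_equal(computeAUC(sig * c0), computeAUC(sig), tolerance = 1e-12)
  }
})

test_that("trapezoid mode integrates the normalized signal over real time", {
  # constant normalized signal over 120 s -> area 120
  expect_equal(computeAUC(c(5, 5, 5), method = "trapezoid",
                          times = c(0, 60, 120)), 120)
})

test_that("net AUC is a plain difference, flagged when negative", {
  expect_equal(computeNetAUC(80, 50), 30)
  expect_equal(computeNetAUC(17.3, 17.3), 0)
  expect_equal(computeNetAUC(40, 50), -10)
  p <- tiny_plate()
  tab <- plateAUC(p, blank = "BLANK")
  expect_equal(tab$net_auc[tab$sample == "Trolox"],
               computeAUC(c(100, 90, 80)) - computeAUC(c(100, 60, 30)))
  expect_false(any(tab$pro_oxidant))
})

test_that("dose-response fit recovers exact linear responses", {
  dr <- doseResponse("x", c(1, 2, 5, 10), 2 * c(1, 2, 5, 10))
  expect_equal(drSlope(dr), 2)
  expect_equal(drIntercept(dr), 0)
  expect_equal(drRSquared(dr), 1)
  flat <- doseResponse("flat", c(1, 2, 5), c(3, 3, 3))
  expect_equal(drSlope(flat), 0)
  expect_error(doseResponse("bad", c(2, 2), c(1, 2)),
               class = "oxicap_insufficient_design_error")
})

test_that("fitted slope on a simulated plate matches the kinetic model's analytic slope", {
  # In the depletion regime the lag is n*[A]/flux seconds, so the net-AUC
  # slope (in cycles per uM) is n / (flux * cycle_s).
  cfg <- oracSimConfig(stoichiometry = c(Trolox = 2), seed = 1)
  plate <- simulateOracPlate(cfg)
  dr <- fitDoseResponse(plate, "Trolox", blank = "BLANK")
  analytic <- 2 / (cfg$radicalFlux * cfg$cycleS)
  expect_lt(abs(drSlope(dr) - analytic) / analytic, 0.10)
  expect_gt(drRSquared(dr), 0.99)
})

test_that("net AUC is monotone in concentration under the kinetic model", {
  for (n in c(1, 2)) {
    cfg <- oracSimConfig(stoichiometry = setNames(n, "S"), noiseSd = 0,
                         nCycles = 120, replicates = 1, seed = 1)
    tab <- plateAUC(simulateOracPlate(cfg), blank = "BLANK")
    tab <- tab[tab$sample == "S", ]
    expect_false(is.unsorted(tab$net_auc[order(tab$conc_uM)]))
  }
})

test_that("Trolox equivalent is the slope ratio and 1 against itself", {
  a <- doseResponse("a", c(1, 2, 3), c(10.85, 21.70, 32.55))
  b <- doseResponse("Trolox", c(1, 2, 3), c(5, 10, 15))
  expect_equal(troloxEquivalent(a, b)$te, 2.17)
  expect_equal(troloxEquivalent(b, b)$te, 1)
  flat <- doseResponse("flat", c(1, 2), c(1, 1))
  expect_error(troloxEquivalent(a, flat), class = "oxicap_undefined_te_error")
})
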