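test_that("descriptors from orbital energies obey their defining identities", {
  d <- descriptorsFromOrbitals(-5.294, -0.655, "Trolox")
  expect_equal(d$eta, 2.3195)
  expect_equal(d$chi, 2.9745)
  expect_equal(d$mu, -2.9745)
  sym <- descriptorsFromOrbitals(-3, 3)
  expect_equal(sym$chi, 0)
  expect_equal(sym$mu, 0)
  expect_equal(sym$omega, 0)
  expect_equal(descriptorsFromOrbitals(-5.690, -0.553)$chi, 3.1215,
               tolerance = 1e-9)
  expect_error(descriptorsFromOrbitals(-1, -2),
               class = "oxicap_nonpositive_hardness_error")
})

test_that("descriptor identities hold on random orbital energies", {
  set.seed(51)
  eh <- runif(200, -9, -2)
  el <- eh + runif(200, 0.5, 6)
  d <- descriptorsFromOrbitals(eh, el)
  expect_equal(d$sigma * d$eta, rep(1, 200), tolerance = 1e-12)
  expect_equal(d$mu, -d$chi)
  expect_equal(d$gap, 2 * d$eta)
  expect_true(all(d$omega >= 0))
})

test_that("display-precision electrophilicity reproduces tabulated values", {
  expect_equal(electrophilicityFromRounded(2.974, 2.31), 1.914)
  expect_equal(electrophilicityFromRounded(3.938, 2.61), 2.970)
  expect_equal(electrophilicityFromRounded(0, 1.7), 0)
  expect_error(electrophilicityFromRounded(1, 0),
               class = "oxicap_validation_error")
})

test_that("displayed descriptor table matches the published one for all five molecules", {
  tab <- orbital_table()
  d <- descriptorsFromOrbitals(tab$e_homo, tab$e_lumo, tab$molecule)
  disp <- formatDescriptors(d)
  expect_equal(disp$eta, tab$eta)
  expect_equal(disp$sigma, tab$sigma)
  expect_equal(disp$mu, -disp$chi)
  expect_true(all(abs(disp$chi - tab$chi) <= 0.005))
  # omega inherits the small discrepancy of the published chi column, so it
  # agrees at tolerance here; the exact 3-dp reproduction goes through
  # electrophilicityFromRounded on the printed chi and eta
  expect_true(all(abs(disp$omega - tab$omega) <= 0.005))
  # electronegativity ranking: Trolox < A2 < A1 < RvD1 < ascorbic acid
  expect_equal(d$molecule[order(d$chi)],
               c("Trolox", "Analogue 2", "Analogue 1", "RvD1",
                 "Ascorbic acid"))
  # the RvD1-family member with an aliphatic acid tail is the weakest electrophile
  expect_equal(d$molecule[which.min(d$omega)], "Analogue 1")
})

test_that("BDE and IP apply the Hartree -> kJ/mol conversion and are translation-invariant", {
  expect_equal(computeBDE(0, 0.07, 0.03), 0.1 * 2625.4996)
  expect_equal(computeBDE(1.5, 1.0, 0.5), 0)
  expect_equal(computeIP(0, 0.296664, 0), 778.9, tolerance = 0.2)
  expect_equal(computeIP(5, 5, 0), 0)
  set.seed(52)
  for (i in 1:10) {
    h0 <- rnorm(1); hr <- rnorm(1); shift <- rnorm(1, sd = 100)
    expect_equal(computeBDE(h0 + shift, hr + shift, -0.5),
                 computeBDE(h0, hr, -0.5), tolerance = 1e-6)
    expect_equal(computeIP(h0 + shift, hr + shift),
                 computeIP(h0, hr), tolerance = 1e-6)
  }
  th <- ThermoSummary("m", hNeutral = -100,
                      hRadicals = c(a = -99.9, b = -99.8))
  bt <- bdeTable(th, hHatom = -0.49)
  expect_equal(bt$site, c("a", "b"))
  expect_equal(bt$bde, c(-0.39, -0.29) * 2625.4996, tolerance = 1e-6)
})

test_that("O-H bond detection matches a brute-force all-pairs oracle", {
  g <- Geometry(c("O", "H"), rbind(c(0, 0, 0), c(0.9741, 0, 0)), "forced")
  rep1 <- findOHBonds(g)
  expect_equal(nrow(bondTable(rep1)), 1L)
  expect_equal(bondTable(rep1)$length, 0.9741)

  expect_warning(
    rep0 <- findOHBonds(Geometry(c("C", "H", "H", "H", "H"),
                                 rbind(c(0, 0, 0), c(1.09, 0, 0),
                                       c(-1.09, 0, 0), c(0, 1.09, 0),
                                       c(0, -1.09, 0)), "methane")),
    "no O-H pair")
  expect_equal(nrow(bondTable(rep0)), 0L)
  expect_true(is.na(averageBondLength(rep0)))

  set.seed(53)
  for (i in 1:10) {
    n <- 12
    el <- sample(c("O", "H", "C"), n, TRUE)
    co <- matrix(runif(3 * n, 0, 4), ncol = 3)
    rep <- suppressWarnings(findOHBonds(Geometry(el, co, "rand"), cutoff = 1.1))
    # oracle: double loop over all (O, H) pairs
    hits <- 0L
    for (a in which(el == "O")) for (b in which(el == "H")) {
      if (sqrt(sum((co[a, ] - co[b, ])^2)) < 1.1) hits <- hits + 1L
    }
    expect_equal(nrow(bondTable(rep)), hits)
  }
})

test_that("average O-H lengths and ranking reproduce the published ordering", {
  tab <- oh_length_table()
  reports <- lapply(split(tab, tab$molecule), function(df)
    findOHBonds(syntheticOHGeometry(df$molecule[1], df$length_a)))
  avg <- vapply(reports, averageBondLength, numeric(1))
  expect_equal(truncateDigits(avg[["Trolox"]], 4), 0.9781)
  expect_equal(truncateDigits(avg[["Ascorbic acid"]], 4), 0.9789)
  expect_equal(truncateDigits(avg[["Analogue 1"]], 4), 0.9801)
  expect_equal(truncateDigits(avg[["RvD1"]], 4), 0.9856)
  expect_equal(truncateDigits(avg[["Analogue 2"]], 4), 0.9856)

  rk <- averageOHRanking(reports)
  expect_equal(rk$molecule[3:5],
               c("Analogue 1", "Ascorbic acid", "Trolox"))
  expect_setequal(rk$molecule[1:2], c("RvD1", "Analogue 2"))
  expect_equal(rk$rank, c(1, 1, 3, 4, 5))  # RvD1 and Analogue 2 tie
})

test_that("ranking handles singletons and exact ties", {
  r1 <- averageOHRanking(list(findOHBonds(syntheticOHGeometry("a", 0.98))))
  expect_equal(nrow(r1), 1L)
  twin <- lapply(c("a", "b"), function(m)
    findOHBonds(syntheticOHGeometry(m, 0.98)))
  expect_equal(averageOHRanking(twin)$rank, c(1, 1))
})

test_that("charge audit flags sign anomalies and enforces alignment", {
  g <- syntheticOHGeometry("m", c(0.98, 0.99))  # O H O H
  ok <- ThermoSummary("m", charges = c(-0.5, 0.3, -0.4, 0.2))
  audit <- chargeAudit(ok, g)
  expect_false(audit$skipped)
  expect_equal(nrow(audit$flags), 0L)

  bad <- ThermoSummary("m", charges = c(0.1, 0.3, -0.4, -0.2))
  audit2 <- chargeAudit(bad, g)
  expect_equal(nrow(audit2$flags), 2L)
  expect_setequal(audit2$flags$issue, c("positive N/O", "negative hydrogen"))

  expect_error(chargeAudit(ThermoSummary("m", charges = c(1, 2)), g),
               class = "oxicap_alignment_error")
  expect_message(audit3 <- chargeAudit(ThermoSummary("m"), g), "skipped")
  expect_true(audit3$skipped)
})

test_that("truncateDigits drops digits toward zero with a float guard", {
  expect_equal(truncateDigits(2.3195, 2), 2.31)
  expect_equal(truncateDigits(2.97085, 3), 2.970)
  expect_equal(truncateDigits(0.9821, 4), 0.9821)
  expect_equal(truncateDigits(-1.999, 2), -1.99)
})
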