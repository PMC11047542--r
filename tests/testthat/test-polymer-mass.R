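test_that("distribution moments match forced arithmetic", {
  single <- distributionMoments(MassDistribution(5000, 10))
  expect_equal(single@mn, 5000)
  expect_equal(single@mw, 5000)
  expect_equal(single@dispersity, 1)

  two <- distributionMoments(MassDistribution(c(100, 300), c(1, 1)))
  expect_equal(two@mn, 200)
  expect_equal(two@mw, 250)
  expect_equal(two@dispersity, 1.25)

  empty <- MassDistribution(c(100, 200), c(1, 0))
  empty@count <- c(0, 0)  # bypass constructor validity to hit the guard
  expect_error(distributionMoments(empty),
               class = "oxicap_empty_distribution_error")
})

test_that("moments agree with a brute-force summation oracle", {
  set.seed(41)
  for (i in 1:5) {
    m <- runif(1000, 100, 1e6)
    n <- rpois(1000, 5)
    n[1] <- n[1] + 1  # ensure non-empty
    ps <- distributionMoments(MassDistribution(m, n))
    # oracle: explicit loop accumulation, independent of the vectorized path
    s0 <- s1 <- s2 <- 0
    for (j in seq_along(m)) {
      s0 <- s0 + n[j]
      s1 <- s1 + n[j] * m[j]
      s2 <- s2 + n[j] * m[j]^2
    }
    expect_equal(ps@mn, s1 / s0, tolerance = 1e-9)
    expect_equal(ps@mw, s2 / s1, tolerance = 1e-9)
    expect_gte(ps@dispersity, 1)
  }
})

test_that("dispersity is >= 1 and merging a distribution with itself changes nothing", {
  set.seed(42)
  for (i in 1:20) {
    m <- runif(50, 200, 5e5)
    n <- runif(50, 0, 10)
    n[n < 0.1] <- 1
    ps <- distributionMoments(MassDistribution(m, n))
    expect_gte(ps@dispersity, 1 - 1e-12)
    doubled <- distributionMoments(MassDistribution(c(m, m), c(n, n)))
    expect_equal(doubled@mn, ps@mn, tolerance = 1e-12)
    expect_equal(doubled@mw, ps@mw, tolerance = 1e-12)
  }
})

test_that("dispersity from printed Mw/Mn reproduces tabulated indices", {
  expect_equal(round(dispersityFromMwMn(1160000, 1052000), 3), 1.103)
  expect_equal(round(dispersityFromMwMn(217211, 131579), 3), 1.651)
  expect_equal(dispersityFromMwMn(5e5, 5e5), 1)
  expect_warning(dispersityFromMwMn(99, 100), "mw < mn")
  expect_error(dispersityFromMwMn(100, 0), class = "oxicap_validation_error")
})

test_that("degradation report computes retention and a verdict", {
  native <- polymerStats(1052000, 1160000, label = "HA")
  protected <- polymerStats(1031000, 1113000, label = "HA+scavenger")
  degraded <- polymerStats(131579, 217211, label = "HA+H2O2")

  r1 <- degradationReport(native, protected)
  expect_equal(round(r1$retention, 3), 0.959)
  expect_equal(r1$verdict, "protected")

  r2 <- degradationReport(native, degraded)
  expect_equal(round(r2$retention, 3), 0.187)
  expect_equal(r2$verdict, "degraded")

  r3 <- degradationReport(native, native)
  expect_equal(r3$retention, 1)
  expect_equal(r3$dispersity_change, 0)
})
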