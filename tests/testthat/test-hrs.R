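ros_fixture <- function() {
  rosTimecourse(
    times = c(0, 4, 8),
    rfu = rbind(CTRL = c(100, 100, 100), S = c(100, 50, 14)),
    controlLabel = "CTRL")
}

test_that("percent ROS reduction is the normalized control difference", {
  tc <- ros_fixture()
  expect_equal(percentRosReduction(tc, "S", 8), 86)
  expect_equal(percentRosReduction(tc, "S", 0), 0)    # equals control
  tc0 <- rosTimecourse(c(0, 8), rbind(CTRL = c(50, 100), Z = c(50, 0)), "CTRL")
  expect_equal(percentRosReduction(tc0, "Z", 8), 100) # fully suppressed
  expect_error(percentRosReduction(tc, "S", 3),
               class = "oxicap_missing_timepoint_error")
})

test_that("reduction is invariant under common RFU rescaling", {
  tc <- ros_fixture()
  tc2 <- rosTimecourse(tc@times, tc@rfu * 7.3, "CTRL")
  expect_equal(percentRosReduction(tc2, "S", 4), percentRosReduction(tc, "S", 4))
})

test_that("time-course summary reports the reduction matrix and monotonicity", {
  tc <- ros_fixture()
  s <- timecourseSummary(tc)
  expect_equal(dim(s$reductions), c(1L, 3L))
  expect_true(s$monotone[["S"]])

  # constant control, linearly rising sample -> strictly decreasing reduction
  tc2 <- rosTimecourse(c(0, 1, 2), rbind(CTRL = c(90, 90, 90),
                                         R = c(10, 40, 70)), "CTRL")
  s2 <- timecourseSummary(tc2)
  expect_true(all(diff(s2$reductions["R", ]) < 0))
  expect_false(s2$monotone[["R"]])

  only_ctrl <- rosTimecourse(c(0, 1), rbind(CTRL = c(1, 2)), "CTRL")
  s3 <- timecourseSummary(only_ctrl)
  expect_equal(nrow(s3$reductions), 0L)
  expect_length(s3$monotone, 0L)
})

test_that("simulated reductions track the closed form 100(1 - exp(-k t))", {
  k <- 0.5
  tc <- simulateHRS(c(S = k), seed = 3)
  s <- timecourseSummary(tc)
  expected <- 100 * (1 - exp(-k * tc@times))
  expect_true(all(abs(s$reductions["S", ] - expected) <= 5))
})

test_that("a larger scavenging rate gives a larger reduction at every time", {
  tc <- simulateHRS(c(slow = 0.1, mid = 0.5, fast = 1.5), seed = 9)
  s <- timecourseSummary(tc)
  later <- tc@times > 0  # at t = 0 all reductions are ~0
  expect_true(all(s$reductions["fast", later] > s$reductions["mid", later]))
  expect_true(all(s$reductions["mid", later] > s$reductions["slow", later]))
})
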