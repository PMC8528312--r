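test_that("mutation draws follow the frameshift fraction and uniform positions", {
  p <- protectionParams(0.1, 0.3, 0.5, nReps = 1e5, seed = 11)
  set.seed(11)
  d <- drawMutation(p, 1e5)
  expect_equal(mean(d$type == "frameshift"), 0.3, tolerance = 0.02)
  expect_true(all(d$position >= 0 & d$position < 1000))
  set.seed(12)
  expect_true(all(drawMutation(protectionParams(0.1, 1, 1), 100)$type == "frameshift"))
  set.seed(12)
  expect_true(all(drawMutation(protectionParams(0.1, 0, 1), 100)$type == "substitution"))
})

test_that("discrete LOF draws match the Bernoulli closed form", {
  set.seed(3)
  expect_false(any(lofDiscrete(rep(0L, 1000), 0.5)))
  expect_true(all(lofDiscrete(rep(5L, 1000), 1)))
  rate <- mean(lofDiscrete(rep(10L, 1e5), 0.1))
  expect_equal(rate, 1 - 0.9^10, tolerance = 0.01)
})

test_that("continuous impact is the closed form and monotone", {
  expect_identical(impactContinuous(0, 0.3), 0)
  expect_equal(impactContinuous(1, 0.1), 0.1)
  n <- 0:50
  expect_true(all(diff(impactContinuous(n, 0.2)) >= 0))
  expect_true(all(impactContinuous(5, seq(0, 1, 0.1)) ==
                  cummax(impactContinuous(5, seq(0, 1, 0.1)))))
})

test_that("degenerate overlap fractions give the forced protection values", {
  r0 <- simulateProtection(protectionParams(0.1, 0.3, 0, nReps = 2e4, seed = 5))
  expect_identical(r0@protection, 0)
  r1 <- simulateProtection(protectionParams(0.5, 1, 1, nReps = 5e3, seed = 5))
  expect_identical(r1@protection, 1)
})

test_that("the simulator is reproducible and respects result invariants", {
  p <- protectionParams(0.3, 0.3, 0.6, nReps = 2e4, seed = 77)
  a <- simulateProtection(p); b <- simulateProtection(p)
  expect_identical(a@protection, b@protection)
  expect_identical(a@nPurged, b@nPurged)
  expect_equal(a@protection, a@nPurged / a@nUpstreamLof)
  expect_true(a@ci95[1] <= a@protection && a@protection <= a@ci95[2])
})

test_that("Monte-Carlo agrees with the exact expectation over a parameter grid", {
  for (Pe in c(0.1, 0.3, 0.5)) {
    for (fs in c(0.1, 0.3, 0.7)) {
      for (ov in c(0.2, 0.6, 1)) {
        p <- protectionParams(Pe, fs, ov, nReps = 2e4,
                              seed = round(1e3 * (Pe + 10 * fs + 100 * ov)))
        r <- simulateProtection(p)
        exact <- protectionExact(p)
        se <- sqrt(exact * (1 - exact) / r@nUpstreamLof)
        expect_lt(abs(r@protection - exact), 3 * se + 1e-9)
      }
    }
  }
})

test_that("the exact expectation matches an independently coded enumeration", {
  for (Pe in c(0.1, 0.5)) {
    for (fs in c(0.1, 0.7)) {
      for (ov in c(0, 0.4, 1)) {
        p <- protectionParams(Pe, fs, ov, upstreamLenNt = 60,
                              downstreamLenNt = 90, nReps = 10)
        expect_equal(protectionExact(p),
                     oracleProtectionDiscrete(Pe, fs, ov, 60, 90),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("protection responds to parameters as the overlap model predicts", {
  exact <- function(Pe, fs, ov, mode = "riboverlap")
    protectionExact(protectionParams(Pe, fs, ov, overlapMode = mode, nReps = 10))
  # increasing in overlap fraction
  ovs <- seq(0.1, 1, 0.1)
  expect_true(all(diff(vapply(ovs, function(o) exact(0.1, 0.3, o), 1)) > 0))
  # increasing in frameshift fraction
  fss <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  expect_true(all(diff(vapply(fss, function(f) exact(0.1, f, 0.6), 1)) > 0))
  # decreasing in Pe
  pes <- c(0.1, 0.3, 0.5, 0.7)
  expect_true(all(diff(vapply(pes, function(pe) exact(pe, 0.3, 0.6), 1)) < 0))
  # a true protein overlap protects at least as much as a riboverlap
  for (ov in c(0.3, 0.7, 1))
    expect_gte(exact(0.3, 0.3, ov, "protein_overlap"),
               exact(0.3, 0.3, ov, "riboverlap"))
})

test_that("the parameter grid runs to completion and is tidy", {
  g <- protectionGrid(PeValues = c(0.1, 0.5), fsValues = c(0.1, 0.7),
                      overlapValues = c(0, 0.5, 1), nReps = 2000, seed = 9)
  expect_identical(nrow(g), 12L)
  expect_true(all(g$protection[g$overlap_fraction == 0] == 0))
  expect_true(all(g$protection >= 0 & g$protection <= 1, na.rm = TRUE))
  g2 <- protectionGrid(PeValues = c(0.1, 0.5), fsValues = c(0.1, 0.7),
                       overlapValues = c(0, 0.5, 1), nReps = 2000, seed = 9)
  expect_identical(g, g2)
})

test_that("both continuous-model protection metrics are available", {
  p <- protectionParams(0.1, 0.7, 1, lofModel = "continuous_deterministic",
                        nReps = 10)
  thr <- protectionExact(p, "threshold")
  dot <- protectionExact(p, "dot")
  expect_true(thr >= 0 && thr <= 1)
  expect_true(dot >= 0 && dot <= 1)
  r <- simulateProtection(protectionParams(0.1, 0.7, 1,
                                           lofModel = "continuous_deterministic",
                                           nReps = 2e4, seed = 8))
  se <- sqrt(thr * (1 - thr) / r@nUpstreamLof)
  expect_lt(abs(r@protection - thr), 3 * se + 1e-9)
})
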