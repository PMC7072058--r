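test_that("expected counts are the volume-weighted pure-count sums", {
  pure <- PureSuspensionCounts(1000, nPiD100 = 510)
  expect_equal(expectedCounts(pure, 100), c(viable = 1000, dead = 0))
  expect_equal(expectedCounts(pure, 80), c(viable = 800, dead = 102))

  # brute-force re-computation on random inputs
  set.seed(10)
  for (i in 1:50) {
    v <- runif(4, 0, 1e6); P <- runif(1, 0, 100)
    pure <- PureSuspensionCounts(v[1], v[2], v[3], v[4])
    got <- expectedCounts(pure, P)
    expect_equal(got[["viable"]], v[1] * P / 100 + v[2] * (100 - P) / 100)
    expect_equal(got[["dead"]], v[3] * P / 100 + v[4] * (100 - P) / 100)
  }
})

test_that("expected ratios normalize, round correctly and hit endpoints", {
  r <- expectedRatio(800, 102)
  expect_equal(r@ratioViable, 100 * 800 / 902)
  expect_equal(reportedRatio(r)[["viable"]], 89)
  expect_equal(reportedRatio(expectedRatio(500, 255))[["viable"]], 66)
  z <- expectedRatio(0, 42)
  expect_equal(z@ratioViable, 0)
  expect_equal(z@ratioDead, 100)
  expect_error(expectedRatio(0, 0), "undefined")

  # normalization and monotonicity properties
  set.seed(11)
  prev <- -1
  for (P in seq(0, 100, by = 5)) {
    r <- expectedRatio(expectedCounts(PureSuspensionCounts(1200,
                                                           nPiD100 = 700), P))
    expect_equal(r@ratioViable + r@ratioDead, 100)
    expect_gt(r@ratioViable, prev)
    prev <- r@ratioViable
  }
})

test_that("yield factor reproduces the calibration expected-ratio rows", {
  # independent oracle: grid search over r in (0, 1], step 0.001
  gridFit <- function(P, R) {
    grid <- seq(0.001, 1, by = 0.001)
    sse <- vapply(grid, function(r)
      sum((100 * P / (P + r * (100 - P)) - R)^2), numeric(1))
    grid[which.min(sse)]
  }
  P <- c(80, 60, 50, 40, 20)

  rowPbs <- c(89, 75, 66, 57, 33)
  rHat <- fitYieldFactor(P, rowPbs)
  expect_equal(rHat, gridFit(P, rowPbs), tolerance = 2e-3)
  expect_equal(rHat, 0.51, tolerance = 0.01)
  # the fitted factor reproduces every reported integer
  expect_equal(round(100 * P / (P + rHat * (100 - P))), rowPbs)

  rowFiltered <- c(81, 61, 51, 41, 21)
  rHat2 <- fitYieldFactor(P, rowFiltered)
  expect_equal(rHat2, gridFit(P, rowFiltered), tolerance = 2e-3)
  expect_equal(rHat2, 0.96, tolerance = 0.01)
  expect_equal(round(100 * P / (P + rHat2 * (100 - P))), rowFiltered)

  # identity mixture: measured ratio equals the volumetric ratio
  expect_equal(fitYieldFactor(P, P), 1.0)
  expect_error(fitYieldFactor(c(0, 100), c(0, 100)), "non-endpoint")
})

test_that("yield factor recovers the generator's r from simulated labels", {
  P <- c(80, 60, 40, 20)
  for (r in c(0.3, 0.5, 0.75, 1.0)) {
    ratios <- vapply(P, function(p) {
      ev <- simulateMixture(mixtureSpec(p, rYield = r, sslLevel = 0,
                                        nEvents = 20000),
                            seed = round(1000 * r) + p, nSamples = 8)
      lab <- eventData(ev)$label
      100 * mean(lab == "viable")
    }, numeric(1))
    expect_lt(abs(fitYieldFactor(P, ratios) - r), 0.02)
  }
})

test_that("accuracy evaluation summarizes replicates against expectation", {
  perfect <- evaluateAccuracy(c(89, 89, 89), 89)
  expect_equal(perfect$deviation, 0)
  expect_true(perfect$pass)

  noisy <- evaluateAccuracy(c(60, 80, 100), 60)
  expect_equal(noisy$mean, 80)
  expect_equal(noisy$sd, 20)
  expect_false(noisy$pass)

  expect_error(evaluateAccuracy(89, 89), "replicates")
})

test_that("particle-load QC trips above the limit with power-of-ten advice", {
  expect_true(qcParticleLoad(5e5)$pass)
  expect_equal(qcParticleLoad(5e5)$recommendedDilution, 1)
  expect_true(qcParticleLoad(1e6)$pass)           # boundary is inclusive
  expect_false(qcParticleLoad(1e6 + 1)$pass)
  expect_equal(qcParticleLoad(3e7)$recommendedDilution, 100)
  expect_equal(qcParticleLoad(9.9e6)$recommendedDilution, 10)
  expect_error(qcParticleLoad(-1), "totalConcentration")
})
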