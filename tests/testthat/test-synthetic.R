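test_that("simulation is seeded, empty-safe and validates its specs", {
  expect_equal(nEvents(simulatePopulation(populationSpec("viable"), 0)), 0)

  a <- extractFeatures(simulateMixture(mixtureSpec(60, nEvents = 500),
                                       seed = 42))
  b <- extractFeatures(simulateMixture(mixtureSpec(60, nEvents = 500),
                                       seed = 42))
  expect_identical(featureTable(a), featureTable(b))
  c2 <- extractFeatures(simulateMixture(mixtureSpec(60, nEvents = 500),
                                        seed = 43))
  expect_false(identical(featureTable(a), featureTable(c2)))

  expect_error(populationSpec("viable", greenPositiveFraction = 1.2),
               "fractions")
  expect_error(populationSpec("dead", buddingFraction = 0.5),
               "viable populations only")
  expect_error(mixtureSpec(60, pDead = 50), "must equal 100")
  expect_error(mixtureSpec(50, rYield = 0), "rYield")
})

test_that("ground-truth composition converges to the specified fractions", {
  # P 60/40 at r_yield 1, no background: expect 60 % viable among cells
  spec <- mixtureSpec(60, medium = "unfiltered_SSL", rYield = 1,
                      sslLevel = 0, nEvents = 1e5)
  ev <- simulateMixture(spec, seed = 7, nSamples = 8)
  lab <- eventData(ev)$label
  p <- mean(lab == "viable")
  sigma <- sqrt(0.6 * 0.4 / 1e5)
  expect_lt(abs(p - 0.60), 3 * sigma)

  # all-viable endpoint with no background
  ev100 <- simulateMixture(mixtureSpec(100, sslLevel = 0, nEvents = 2000),
                           seed = 1, nSamples = 8)
  expect_true(all(eventData(ev100)$label == "viable"))

  # yield factor shifts the event-based composition per the mixture model:
  # 80/20 at r_yield 0.51 gives 88.7 % viable events
  spec2 <- mixtureSpec(80, medium = "PBS", rYield = 0.51, sslLevel = 0,
                       nEvents = 1e5)
  ev2 <- simulateMixture(spec2, seed = 8, nSamples = 8)
  p2 <- mean(eventData(ev2)$label == "viable")
  expected <- 80 / (80 + 0.51 * 20)
  expect_lt(abs(p2 - expected), 3 * sqrt(expected * (1 - expected) / 1e5))
})

test_that("pure simulated populations classify as themselves", {
  gates <- sharedGates()
  v <- extractFeatures(simulatePopulation(
    populationSpec("viable", buddingFraction = 0.15), 10000, seed = 77))
  res <- classifyEvents(v, gates)
  expect_gte(classCounts(res)[["viable"]] / 10000, 0.99)

  d <- extractFeatures(simulatePopulation(populationSpec("dead"), 10000,
                                          seed = 78))
  resd <- classifyEvents(d, gates)
  expect_gte(classCounts(resd)[["dead"]] / 10000, 0.99)
})

test_that("SSL particles never read as viable (FDA specificity)", {
  gates <- sharedGates()
  s <- extractFeatures(simulatePopulation(populationSpec("ssl_particle"),
                                          20000, seed = 79))
  res <- classifyEvents(s, gates)
  expect_equal(classCounts(res)[["viable"]], 0)
  # green totals of particles stay far below the viable gate
  expect_lt(max(log10(pmax(featureTable(s)$FL_GREEN_total, 1))),
            min(gates@viableGate[, 1]))
})

test_that("instrument limit passes compliant samples and thins overloads", {
  ev <- simulateMixture(mixtureSpec(50, nEvents = 2000), seed = 21)
  below <- applyInstrumentLimit(ev, totalConcentration = 5e5, limit = 1e6)
  expect_false(below$overload)
  expect_identical(below$events@traces, ev@traces)

  above <- applyInstrumentLimit(ev, totalConcentration = 2e6, limit = 1e6,
                                seed = 1)
  expect_true(above$overload)
  expect_lt(nEvents(above$events), nEvents(ev))
})

test_that("overloaded acquisition biases the measured viable ratio", {
  gates <- sharedGates()
  spec <- mixtureSpec(50, medium = "unfiltered_SSL", rYield = 1,
                      nEvents = 4000)
  errBelow <- errAbove <- numeric(20)
  for (k in 1:20) {
    ev <- simulateMixture(spec, seed = 3000 + k)
    ok <- classifyEvents(extractFeatures(ev), gates)
    thin <- applyInstrumentLimit(ev, totalConcentration = 4e6, limit = 1e6,
                                 seed = 5000 + k)
    bad <- classifyEvents(extractFeatures(thin$events), gates)
    errBelow[k] <- abs(viabilityPercent(ok) - 50)
    errAbove[k] <- abs(viabilityPercent(bad) - 50)
  }
  expect_gt(mean(errAbove), mean(errBelow))
})
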