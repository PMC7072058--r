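test_that("gates fitted on separated references are disjoint and reusable", {
  gates <- sharedGates()
  expect_s4_class(gates, "GateSet")
  # disjointness is part of the class validity, checked on construction
  expect_true(validObject(gates))

  # same-population references cannot be separated
  d <- extractFeatures(simulatePopulation(populationSpec("dead"), 2000,
                                          seed = 1))
  b <- extractFeatures(simulatePopulation(populationSpec("ssl_particle"),
                                          2000, seed = 2))
  expect_error(fitGates(d, d, b), "overlap")
  expect_error(fitGates(d[1:50], d, b), "at least 100 events")
})

test_that("gates fitted on one seed classify events from another seed", {
  gates <- referenceGates(seed = 101, nRef = 4000)
  ev <- simulateMixture(mixtureSpec(50, medium = "filtered_SSL",
                                    nEvents = 20000), seed = 202)
  feats <- extractFeatures(ev)
  res <- classifyEvents(feats, gates)
  truth <- eventData(ev)$label
  agree <- mean(eventLabels(res) == truth)
  expect_gte(agree, 0.97)
})

test_that("classification recovers mixture viability and is a partition", {
  gates <- sharedGates()
  # pure endpoints
  v <- extractFeatures(simulatePopulation(
    populationSpec("viable", buddingFraction = 0.15), 3000, seed = 31))
  expect_equal(viabilityPercent(classifyEvents(v, gates)), 100,
               tolerance = 0.005)
  d <- extractFeatures(simulatePopulation(populationSpec("dead"), 3000,
                                          seed = 32))
  expect_equal(viabilityPercent(classifyEvents(d, gates)), 0,
               tolerance = 0.005)

  # 60/40, r_yield 1, unfiltered background, 10 seeds
  spec <- mixtureSpec(60, medium = "unfiltered_SSL", rYield = 1,
                      nEvents = 50000)
  vias <- vapply(1:10, function(k) {
    ev <- simulateMixture(spec, seed = 600 + k)
    res <- classifyEvents(extractFeatures(ev), gates)
    expect_equal(sum(classCounts(res)), nEvents(ev))  # partition
    viabilityPercent(res)
  }, numeric(1))
  expect_lt(max(abs(vias - 60)), 2)
})

test_that("viability recovery holds across the mixing-ratio grid", {
  gates <- sharedGates()
  for (P in c(20, 40, 50, 60, 80)) {
    ev <- simulateMixture(mixtureSpec(P, medium = "PBS", rYield = 1,
                                      nEvents = 50000), seed = 900 + P)
    via <- viabilityPercent(classifyEvents(extractFeatures(ev), gates))
    expect_lt(abs(via - P), 3)
  }
})

test_that("morphology split recovers the budding fraction", {
  gates <- sharedGates()
  # constructed extremes
  singles <- extractFeatures(simulatePopulation(
    populationSpec("viable", buddingFraction = 0), 2000, seed = 51))
  m0 <- classifyMorphology(singles, gates)
  expect_lte(m0$budding / 2000, 0.04)   # residual equal-error rate
  doublets <- extractFeatures(simulatePopulation(
    populationSpec("viable", buddingFraction = 1), 2000, seed = 52))
  m1 <- classifyMorphology(doublets, gates)
  expect_gte(m1$budding / 2000, 0.96)
  expect_true(is.infinite(classifyMorphology(doublets[
    m1$morphology == "budding"], gates)$buddingRatio))

  # parameter recovery at budding fraction 0.3, 10 seeds
  fracs <- vapply(1:10, function(k) {
    ev <- simulatePopulation(populationSpec("viable", buddingFraction = 0.3),
                             5000, seed = 700 + k)
    m <- classifyMorphology(extractFeatures(ev), gates)
    m$budding / (m$single + m$budding)
  }, numeric(1))
  expect_lt(max(abs(fracs - 0.30)), 0.03)
})

test_that("saturated green events stay viable and are flagged", {
  gates <- sharedGates()
  # drive the green channel into saturation via a bright doublet spec
  spec <- populationSpec("viable", buddingFraction = 1,
                         ampMeanlog = c(FSC = log(800), SSC = log(500),
                                        FL_GREEN = log(3500), FL_RED = NA))
  ev <- simulatePopulation(spec, 2000, seed = 61)
  feats <- extractFeatures(ev)
  f <- featureTable(feats)
  expect_gt(sum(f$FL_GREEN_saturated), 0)
  res <- classifyEvents(feats, gates)
  # every saturated event inside the cell windows is kept viable
  inWin <- f$FSC_length_um >= gates@sizeWindow[1] &
    f$FSC_length_um <= gates@sizeWindow[2] &
    f$SSC_total >= gates@shapeWindow[1] &
    f$SSC_total <= gates@shapeWindow[2]
  sat <- f$FL_GREEN_saturated & inWin
  expect_gt(sum(sat), 0)
  expect_true(all(eventLabels(res)[sat] == "viable"))
  expect_gte(classCounts(res)[["viable"]] / 2000, 0.9)
  expect_gt(qcFlags(res)$saturationFraction, 0)
})

test_that("count to concentration conversion is linear", {
  expect_equal(countsToConcentration(500, 100), 5000)
  expect_equal(countsToConcentration(500, 100, 1000), 5e6)
  expect_equal(countsToConcentration(0, 100, 1000), 0)
  expect_equal(countsToConcentration(123, 50, 7),
               7 * countsToConcentration(123, 50, 1))
  expect_error(countsToConcentration(10, 0), "analyzedVolumeUl")
  expect_error(countsToConcentration(10, 100, 0.5), "dilutionFactor")
})
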