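test_that("analytic pulses yield exact total, maximum and length", {
  # all-zero trace
  z <- featureTable(extractFeatures(rectEventSet(rep(0, 16))))
  expect_equal(z$FSC_total, 0)
  expect_equal(z$FSC_max, 0)
  expect_equal(z$FSC_length_um, 0)
  expect_false(z$FSC_saturated)

  # rectangular pulse: height 100 over 5 samples, spacing 1 um
  r <- featureTable(extractFeatures(rectEventSet(c(0, rep(100, 5), 0)),
                                    baseline = 0, lengthThreshold = 10))
  for (ch in cytoChannels()) {
    expect_equal(r[[paste0(ch, "_total")]], 500)
    expect_equal(r[[paste0(ch, "_max")]], 100)
    expect_equal(r[[paste0(ch, "_length_um")]], 5)
  }

  # baseline subtraction only affects the total
  rb <- featureTable(extractFeatures(rectEventSet(c(0, rep(100, 5), 0)),
                                     baseline = 20))
  expect_equal(rb$SSC_total, 5 * 80)
  expect_equal(rb$SSC_max, 100)
})

test_that("features match a brute-force oracle on Gaussian and random traces", {
  # discretized Gaussian pulse, amplitude 200, sigma = 3 samples
  x <- seq_len(31)
  g <- 200 * exp(-((x - 16)^2) / (2 * 9))
  ev <- rectEventSet(g)
  got <- featureTable(extractFeatures(ev, baseline = 2, lengthThreshold = 10))
  want <- bruteForceFeatures(ev, baseline = 2, threshold = 10)
  expect_equal(got$FSC_total, want$FSC$total)
  expect_equal(got$FSC_max, want$FSC$max)
  expect_equal(got$FSC_length_um, want$FSC$length)

  # 1000 random traces
  ev <- randomTraceSet(1000, nSamples = 16, seed = 99)
  got <- featureTable(extractFeatures(ev, baseline = 5, lengthThreshold = 50))
  want <- bruteForceFeatures(ev, baseline = 5, threshold = 50)
  for (ch in cytoChannels()) {
    expect_equal(got[[paste0(ch, "_total")]], want[[ch]]$total)
    expect_equal(got[[paste0(ch, "_max")]], want[[ch]]$max)
    expect_equal(got[[paste0(ch, "_length_um")]], want[[ch]]$length)
  }
})

test_that("extraction is deterministic and total is monotone", {
  ev <- randomTraceSet(50, seed = 3)
  a <- featureTable(extractFeatures(ev))
  b <- featureTable(extractFeatures(ev))
  expect_identical(a, b)

  # pointwise increase never decreases the total
  bumped <- ev
  bumped@traces <- lapply(ev@traces, function(m) pmin(m + 37, adcMax(ev)))
  fb <- featureTable(extractFeatures(bumped))
  for (ch in cytoChannels())
    expect_true(all(fb[[paste0(ch, "_total")]] >=
                      a[[paste0(ch, "_total")]]))
})

test_that("parameter and structural errors are rejected", {
  ev <- rectEventSet(rep(1, 8))
  expect_error(extractFeatures(ev, baseline = -1), "baseline")
  expect_error(extractFeatures(ev, lengthThreshold = -5), "lengthThreshold")
  # empty traces are rejected at construction time
  expect_error(rectEventSet(matrix(numeric(0), 1, 0)),
               "at least one sample")
})

test_that("saturation requires a run of ceiling samples", {
  adc <- 1000
  below <- rectEventSet(rep(999, 10), adcMax = adc)
  expect_false(detectSaturation(below, "FL_GREEN"))

  runs <- rectEventSet(c(0, adc, adc, adc, 0, 0), adcMax = adc)
  expect_true(detectSaturation(runs, "FL_GREEN", minRun = 2))
  expect_true(detectSaturation(runs, "FL_GREEN", minRun = 3))
  expect_false(detectSaturation(runs, "FL_GREEN", minRun = 4))

  isolated <- rectEventSet(c(adc, 0, adc, 0, adc, 0), adcMax = adc)
  expect_false(detectSaturation(isolated, "FL_GREEN", minRun = 2))
  expect_true(detectSaturation(isolated, "FL_GREEN", minRun = 1))

  expect_error(detectSaturation(runs, "FL_BLUE"), "unknown channel")
  expect_error(detectSaturation(runs, "FSC", minRun = 0), "minRun")

  # the flag propagates into the feature table and implies max == adcMax
  f <- featureTable(extractFeatures(runs))
  expect_true(f$FSC_saturated)
  expect_equal(f$FSC_max, adc)
})
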