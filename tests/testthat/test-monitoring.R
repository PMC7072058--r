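makeTs <- function(df, D = 0.07, V = 1, feed = NA_real_) {
  ProcessTimeSeries(df, workingVolume = V, dilutionRate = D,
                    feedParticleConc = feed)
}

test_that("per-timepoint series compute ratios and flag zero denominators", {
  ts <- makeTs(data.frame(
    time_h = c(0, 10, 20),
    viable_per_ml = c(3000, 0, 1000),
    dead_per_ml = c(1000, 0, 0),
    background_per_ml = c(4000, 5000, 0)))
  v <- viabilitySeries(ts)
  expect_equal(v$value, c(75, NA, 100))
  s <- sslFractionSeries(ts)
  expect_equal(s$value, c(50, 100, 0))
  expect_true(all(v$value >= 0 & v$value <= 100, na.rm = TRUE))

  ts2 <- makeTs(data.frame(
    time_h = 0:1, viable_per_ml = c(800, 0), dead_per_ml = c(200, 0),
    background_per_ml = c(0, 0), single_per_ml = c(600, 0),
    budding_per_ml = c(200, 10)))
  b <- buddingSeries(ts2)
  expect_equal(b$value, c(200 / 600, NA))
})

test_that("feed rate follows D times working volume", {
  expect_equal(feedRate(0.02, 1), 20)
  expect_equal(feedRate(0.07, 1), 70)
  expect_equal(feedRate(0, 5), 0)
  expect_error(feedRate(0.02, 0), "workingVolume")
})

test_that("washout and wash-in dynamics match the closed forms", {
  expect_equal(washoutCurve(1e7, D = 0.02, mu = 0, t = 0), 1e7)
  # one half-life at mu = 0
  expect_equal(washoutCurve(1e7, D = 0.02, mu = 0, t = log(2) / 0.02), 5e6)
  # steady state when mu = D
  tgrid <- seq(0, 200, by = 25)
  expect_equal(washoutCurve(4e6, D = 0.05, mu = 0.05, t = tgrid),
               rep(4e6, length(tgrid)))
  # background reaches the feed level
  D <- 0.02
  cEnd <- backgroundWashin(C0 = 1e4, CFeed = 8e5, D = D, t = 10 / D)
  expect_lt(abs(cEnd - 8e5) / 8e5, 0.001)
  expect_error(washoutCurve(1, 0.1, 0, -1), "non-negative")
})

test_that("specific productivity reduces to D*c/X at steady state", {
  ts <- makeTs(data.frame(
    time_h = seq(0, 40, by = 10),
    viable_per_ml = rep(2e8, 5), dead_per_ml = 0, background_per_ml = 0,
    dw_g_l = rep(4, 5), etoh_g_l = rep(10, 5)), D = 0.02)
  q <- specificProductivity(ts, "total_dw")
  expect_equal(q$q, rep(0.02 * 10 / 4, 5))

  # viable basis with equal unit masses: q_viable = q_total / viability
  # at 50 % viability the viable-basis rate doubles
  dw <- 2e8 * 15 * 1e-9 * 2        # dry weight of viable + dead cells
  ts50 <- makeTs(data.frame(
    time_h = seq(0, 40, by = 10),
    viable_per_ml = rep(2e8, 5), dead_per_ml = rep(2e8, 5),
    background_per_ml = 0, dw_g_l = rep(dw, 5), etoh_g_l = rep(10, 5)),
    D = 0.02)
  qt <- specificProductivity(ts50, "total_dw")$q
  qv <- specificProductivity(ts50, "viable_dw")$q
  expect_equal(qv, 2 * qt)
  expect_true(all(qv >= qt))
})

test_that("falling viability at constant titer raises only the viable-basis q", {
  # synthetic production phase: titer and dry weight constant, viable
  # cell count declining
  ts <- makeTs(data.frame(
    time_h = seq(0, 90, by = 10),
    viable_per_ml = 2e8 * exp(-0.03 * seq(0, 90, by = 10)),
    dead_per_ml = 1e7, background_per_ml = 1e6,
    dw_g_l = 5, etoh_g_l = 12), D = 0.07)
  qv <- specificProductivity(ts, "viable_dw")$q
  qt <- specificProductivity(ts, "total_dw")$q
  expect_true(all(diff(qv) > 0))
  expect_equal(diff(qt), rep(0, 9))
  # normalized output is invariant to the per-cell mass assumption
  n15 <- specificProductivity(ts, "viable_dw", cellDryMassPg = 15,
                              normalize = TRUE)$q
  n30 <- specificProductivity(ts, "viable_dw", cellDryMassPg = 30,
                              normalize = TRUE)$q
  expect_equal(n15, n30)
})

test_that("nutrient-pulse alerts fire once per sustained excursion", {
  t <- 0:30
  expect_length(nutrientPulseRule(t, rep(90, 31), 50, 5), 0)

  # step to 30 % for 10 h: one alert, at the first qualifying time
  v <- c(rep(90, 10), rep(30, 10), rep(90, 11))
  a <- nutrientPulseRule(t, v, 50, 5)
  expect_equal(a, t[10 + 1] + 5)

  # brief dips below min_duration never alert; brute-force scan agrees
  set.seed(5)
  for (k in 1:20) {
    v <- ifelse(runif(31) < 0.25, 30, 90)
    got <- nutrientPulseRule(t, v, 50, 4)
    # oracle: scan runs of below-threshold samples
    r <- rle(v < 50)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    want <- numeric(0)
    for (i in which(r$values)) {
      dur <- t[starts[i]:ends[i]] - t[starts[i]]
      hit <- which(dur >= 4)
      if (length(hit)) want <- c(want, t[starts[i] + hit[1] - 1])
    }
    expect_equal(got, want)
    expect_identical(got, nutrientPulseRule(t, v, 50, 4))  # idempotent
  }
  expect_error(nutrientPulseRule(t, rep(1, 31), 0, 1), "threshold")
})

test_that("process CSV round-trips through the documented schema", {
  df <- data.frame(time_h = c(0, 5.5, 12), viable_per_ml = c(1e6, 8e5, 6e5),
                   dead_per_ml = c(1e4, 2e4, 3e4),
                   background_per_ml = c(5e5, 6e5, 7e5),
                   dw_g_l = c(3, 2.5, 2), etoh_g_l = c(0, 5, 9),
                   sugar_g_l = c(90, 50, 20), phase = c("I", "II", "II"))
  path <- withr::local_tempfile(fileext = ".csv")
  writeProcessCsv(makeTs(df), path)
  back <- readProcessCsv(path, dilutionRate = 0.07)
  expect_equal(back@samples$viable_per_ml, df$viable_per_ml)
  expect_equal(back@samples$phase, df$phase)
  expect_error(readProcessCsv(withr::local_tempfile()), "not found")
  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(time_h = 1), bad, row.names = FALSE)
  expect_error(readProcessCsv(bad), "missing columns")
})
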