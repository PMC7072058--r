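#' Fit gates from simulated reference measurements
#'
#' Convenience wrapper reproducing the bench calibration workflow:
#' simulate pure viable, pure dead and cell-free medium reference
#' measurements plus singlet/doublet morphology references, extract
#' features and fit the gate set.
#'
#' @param seed master seed; sub-seeds for the individual references are
#'   derived from it.
#' @param nRef events per reference measurement (default 6000).
#' @param buddingFraction budding fraction of the viable reference.
#' @param quantile hull quantile passed to \code{\link{fitGates}}.
#' @param ... trace geometry passed to \code{\link{simulatePopulation}}.
#'
#' @return A \code{\link{GateSet-class}} with morphology boundary.
#' @export
referenceGates <- function(seed = 1, nRef = 6000, buddingFraction = 0.15,
                           quantile = 0.99, ...) {
  feats <- function(spec, k, n = nRef)
    extractFeatures(simulatePopulation(spec, n, seed = .subSeed(seed, k), ...))
  fitGates(
    pureViable = feats(populationSpec("viable",
                                      buddingFraction = buddingFraction), 1),
    pureDead = feats(populationSpec("dead"), 2),
    mediumBlank = feats(populationSpec("ssl_particle"), 3),
    quantile = quantile,
    singletRef = feats(populationSpec("viable", buddingFraction = 0), 4,
                       n = max(2000, nRef %/% 2)),
    doubletRef = feats(populationSpec("viable", buddingFraction = 1), 5,
                       n = max(2000, nRef %/% 2)))
}

#' Simulate and classify one mixture measurement
#'
#' Runs the full measurement chain on a simulated sample: particle-load
#' QC, instrument throughput limiting, feature extraction and
#' three-population classification.
#'
#' @param spec a \code{\link{mixtureSpec}}.
#' @param gates a \code{\link{GateSet-class}}.
#' @param seed RNG seed for the measurement.
#' @param limit instrument particle limit (events/mL).
#' @param ... trace geometry passed to \code{\link{simulateMixture}}.
#'
#' @return List with \code{result}
#'   (\code{\link{ClassificationResult-class}}), \code{qc}
#'   (\code{\link{qcParticleLoad}} verdict), \code{features} and
#'   \code{truth} (ground-truth labels).
#' @export
measureMixture <- function(spec, gates, seed = NULL, limit = 1e6, ...) {
  events <- simulateMixture(spec, seed = seed, ...)
  totalConc <- mixtureConcentrations(spec)[["total"]]
  qc <- qcParticleLoad(totalConc, limit)
  lim <- applyInstrumentLimit(events, totalConc, limit,
                              seed = if (is.null(seed)) NULL
                              else .subSeed(seed, 97))
  feats <- extractFeatures(lim$events)
  res <- classifyEvents(feats, gates, overload = lim$overload)
  list(result = res, qc = qc, features = feats,
       truth = eventData(lim$events))
}

#' Full synthetic calibration sweep over the mixture design
#'
#' Reproduces the calibration study end to end on simulated data: for
#' each background medium, gates are fitted on simulated pure-population
#' references; each volumetric mixing ratio is then measured in
#' technical replicates, classified, and compared with the
#' expected-ratio model built from the pure-suspension counts (viable
#' cell concentration and yield-reduced dead cell concentration).
#'
#' @param seed master seed; every replicate uses a sub-seed derived from
#'   it.
#' @param pViable volumetric viable percentages of the design.
#' @param media background media to sweep.
#' @param replicates technical replicates per design point.
#' @param nEvents events acquired per replicate.
#' @param nRef events per gate-fitting reference.
#' @param tolerance accuracy tolerance in percentage points.
#' @param limit instrument particle limit (events/mL).
#'
#' @return data.frame with one row per design point: medium, mixing
#'   ratio, yield factor, expected viable percentage, replicate mean and
#'   SD of the measured viability, absolute deviation, overload flag and
#'   accuracy pass flag.
#' @export
runCalibrationSweep <- function(seed = 1,
                                pViable = c(100, 80, 60, 50, 40, 20, 0),
                                media = c("PBS", "filtered_SSL",
                                          "unfiltered_SSL"),
                                replicates = 3, nEvents = 20000,
                                nRef = 6000, tolerance = 10, limit = 1e6) {
  rows <- list()
  for (mi in seq_along(media)) {
    medium <- media[mi]
    gates <- referenceGates(seed = .subSeed(seed, 1000 + mi), nRef = nRef)
    rYield <- mediumPreset(medium)$rYield
    for (P in pViable) {
      spec <- mixtureSpec(P, medium = medium, nEvents = nEvents)
      pure <- PureSuspensionCounts(nFdaV100 = spec$cellConcentration,
                                   nPiD100 = rYield * spec$cellConcentration)
      expected <- if (P == 0) 0 else if (P == 100) 100 else
        expectedRatio(expectedCounts(pure, P))@ratioViable
      meas <- vapply(seq_len(replicates), function(r) {
        m <- measureMixture(spec, gates,
                            seed = .subSeed(seed, mi * 10000 + P * 10 + r),
                            limit = limit)
        viabilityPercent(m$result)
      }, numeric(1))
      acc <- evaluateAccuracy(meas, expected, tolerance = tolerance)
      rows[[length(rows) + 1]] <- data.frame(
        medium = medium, p_viable = P, r_yield = rYield,
        expected = expected, mean_measured = acc$mean,
        sd_measured = acc$sd, deviation = acc$deviation,
        total_conc = mixtureConcentrations(spec)[["total"]],
        overload = mixtureConcentrations(spec)[["total"]] > limit,
        pass = acc$pass)
    }
  }
  do.call(rbind, rows)
}
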