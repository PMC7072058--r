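#' Set of pulse-shape cytometry events
#'
#' Container for the raw per-particle signal traces recorded by a
#' pulse-shape ("scanning") flow cytometer. Each event carries one trace
#' per detector channel; within a set all traces share a common sampling
#' window so that each channel is stored as an events x samples matrix.
#' Shorter instrument traces are right-padded with zeros when read from
#' disk, which leaves all derived features unchanged.
#'
#' @slot eventId integer vector of unique event identifiers.
#' @slot traces named list with one numeric matrix per canonical channel
#'   (\code{\link{cytoChannels}}); rows are events, columns sample points.
#' @slot sampleSpacing numeric(1), micrometers of flow path per sample
#'   point (set by flow speed and sampling rate).
#' @slot adcMax numeric(1), detector ceiling in arbitrary units; samples
#'   at this value indicate analog-to-digital saturation.
#' @slot eventData data.frame of per-event annotation (e.g. ground-truth
#'   \code{label} and \code{morphology} for simulated events); zero rows
#'   when absent.
#'
#' @seealso \code{\link{extractFeatures}}, \code{\link{simulateMixture}},
#'   \code{\link{readPulseCsv}}
#' @export
setClass("PulseEventSet",
  slots = c(
    eventId = "integer",
    traces = "list",
    sampleSpacing = "numeric",
    adcMax = "numeric",
    eventData = "data.frame"
  )
)

setValidity("PulseEventSet", function(object) {
  msg <- character()
  chans <- cytoChannels()
  if (!identical(sort(names(object@traces)), sort(chans)))
    msg <- c(msg, sprintf("traces must contain exactly the channels: %s",
                          paste(chans, collapse = ", ")))
  n <- length(object@eventId)
  if (anyDuplicated(object@eventId))
    msg <- c(msg, "event ids must be unique")
  for (ch in intersect(names(object@traces), chans)) {
    m <- object@traces[[ch]]
    if (!is.matrix(m) || !is.numeric(m))
      msg <- c(msg, sprintf("trace slot for %s must be a numeric matrix", ch))
    else {
      if (nrow(m) != n)
        msg <- c(msg, sprintf("%s trace matrix has %d rows for %d events",
                              ch, nrow(m), n))
      if (n > 0 && ncol(m) < 1)
        msg <- c(msg, sprintf("%s traces must have at least one sample", ch))
      if (any(m < 0)) msg <- c(msg, sprintf("%s contains negative samples", ch))
      if (any(m > object@adcMax + 1e-9))
        msg <- c(msg, sprintf("%s contains samples above adc_max", ch))
    }
  }
  if (length(object@sampleSpacing) != 1L || object@sampleSpacing <= 0)
    msg <- c(msg, "sampleSpacing must be a single positive number")
  if (length(object@adcMax) != 1L || object@adcMax <= 0)
    msg <- c(msg, "adcMax must be a single positive number")
  if (nrow(object@eventData) > 0 && nrow(object@eventData) != n)
    msg <- c(msg, "eventData must have one row per event (or none)")
  if (length(msg)) msg else TRUE
})

#' Per-event derived feature table
#'
#' Scalar features extracted from each event's traces: per channel the
#' baseline-corrected \code{total} (area), the \code{max}imum, the sample
#' \code{length} (above-threshold extent in micrometers) and a
#' \code{saturated} flag, plus optional population and morphology labels.
#'
#' @slot features data.frame with columns \code{event_id},
#'   \code{<CH>_total}, \code{<CH>_max}, \code{<CH>_length_um},
#'   \code{<CH>_saturated} for each canonical channel, and \code{label},
#'   \code{morphology}.
#' @slot sampleSpacing numeric(1), micrometers per sample (carried over
#'   from the source events).
#' @slot adcMax numeric(1), detector ceiling in arbitrary units.
#'
#' @seealso \code{\link{extractFeatures}}, \code{\link{classifyEvents}}
#' @export
setClass("EventFeatureTable",
  slots = c(
    features = "data.frame",
    sampleSpacing = "numeric",
    adcMax = "numeric"
  )
)

.featureColumns <- function() {
  per <- unlist(lapply(cytoChannels(), function(ch)
    paste0(ch, c("_total", "_max", "_length_um", "_saturated"))))
  c("event_id", per, "label", "morphology")
}

setValidity("EventFeatureTable", function(object) {
  msg <- character()
  need <- .featureColumns()
  missing <- setdiff(need, names(object@features))
  if (length(missing))
    msg <- c(msg, sprintf("missing feature columns: %s",
                          paste(missing, collapse = ", ")))
  else {
    f <- object@features
    if (anyDuplicated(f$event_id)) msg <- c(msg, "event ids must be unique")
    if (!all(f$label %in% .POPULATION_LABELS))
      msg <- c(msg, "label must be one of viable/dead/background/unclassified")
    if (!all(f$morphology %in% .MORPHOLOGY_LABELS))
      msg <- c(msg, "morphology must be one of single/budding/n/a")
    for (ch in cytoChannels()) {
      if (any(f[[paste0(ch, "_total")]] < 0))
        msg <- c(msg, sprintf("%s_total must be non-negative", ch))
      if (any(f[[paste0(ch, "_max")]] > object@adcMax + 1e-9))
        msg <- c(msg, sprintf("%s_max cannot exceed adc_max", ch))
      sat <- f[[paste0(ch, "_saturated")]]
      if (any(sat & abs(f[[paste0(ch, "_max")]] - object@adcMax) > 1e-6))
        msg <- c(msg, sprintf("saturated %s events must have max = adc_max", ch))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Gate set for three-population classification and morphology split
#'
#' Geometric classification rules fitted from reference (pure-population)
#' measurements: convex polygons in (log10 green total, log10 red total)
#' fluorescence space for the viable, dead and background populations;
#' cell size and shape windows over FSC sample length and SSC total; and
#' a straight-line discriminant in (FSC length, SSC total) space that
#' separates single from budding cells.
#'
#' @slot viableGate,deadGate,backgroundGate two-column numeric matrices of
#'   polygon vertices in (log10 FL_GREEN total, log10 FL_RED total).
#' @slot sizeWindow numeric(2), FSC length window in micrometers.
#' @slot shapeWindow numeric(2), SSC total window in arbitrary units.
#' @slot morphologyBoundary numeric(3) coefficients \code{c(a, b, c)} of
#'   the line \code{a*log10(length) + b*log10(ssc_total) + c = 0};
#'   events with positive score are called budding. \code{NA} when no morphology
#'   references were supplied.
#' @slot quantile numeric(1), central mass enclosed by the fluorescence
#'   hulls at fit time.
#'
#' @seealso \code{\link{fitGates}}, \code{\link{classifyEvents}},
#'   \code{\link{writeGates}}
#' @export
setClass("GateSet",
  slots = c(
    viableGate = "matrix",
    deadGate = "matrix",
    backgroundGate = "matrix",
    sizeWindow = "numeric",
    shapeWindow = "numeric",
    morphologyBoundary = "numeric",
    quantile = "numeric"
  )
)

setValidity("GateSet", function(object) {
  msg <- character()
  for (nm in c("viableGate", "deadGate", "backgroundGate")) {
    g <- slot(object, nm)
    if (ncol(g) != 2 || nrow(g) < 3)
      msg <- c(msg, sprintf("%s must be a polygon (>= 3 x 2 matrix)", nm))
  }
  if (length(object@sizeWindow) != 2 || diff(object@sizeWindow) < 0)
    msg <- c(msg, "sizeWindow must be an increasing length-2 interval")
  if (length(object@shapeWindow) != 2 || diff(object@shapeWindow) < 0)
    msg <- c(msg, "shapeWindow must be an increasing length-2 interval")
  if (length(object@morphologyBoundary) != 3)
    msg <- c(msg, "morphologyBoundary must have 3 coefficients")
  if (length(msg) == 0 &&
      .polygonOverlapFraction(object@viableGate, object@deadGate) > 0 &&
      .polygonsIntersect(object@viableGate, object@deadGate))
    msg <- c(msg, "viable and dead gates must be disjoint")
  if (length(msg)) msg else TRUE
})

#' Result of three-population event classification
#'
#' @slot counts named integer vector over viable, dead, background and
#'   unclassified; always sums to the number of classified events.
#' @slot concentrations named numeric vector (events per mL,
#'   dilution-corrected); \code{NA} when no analyzed volume was given.
#' @slot viabilityPercent numeric(1), \code{100 * viable / (viable +
#'   dead)}; \code{NA} when no cells were found.
#' @slot flags list with \code{overload} (logical) and
#'   \code{saturationFraction} (fraction of viable events with saturated
#'   green fluorescence).
#' @slot eventLabels character vector of per-event assignments, in input
#'   order.
#'
#' @seealso \code{\link{classifyEvents}}
#' @export
setClass("ClassificationResult",
  slots = c(
    counts = "integer",
    concentrations = "numeric",
    viabilityPercent = "numeric",
    flags = "list",
    eventLabels = "character"
  )
)

setValidity("ClassificationResult", function(object) {
  msg <- character()
  if (!identical(sort(names(object@counts)), sort(.POPULATION_LABELS)))
    msg <- c(msg, "counts must be named over the four population labels")
  else if (sum(object@counts) != length(object@eventLabels))
    msg <- c(msg, "counts must sum to the number of classified events")
  if (length(msg)) msg else TRUE
})

#' Pure-suspension reference counts for mixture calibration
#'
#' Event concentrations measured on the two reference suspensions used to
#' build defined viable/dead mixtures: FDA-positive (green) and
#' PI-positive (red) counts in the 100 % viable and 100 % dead
#' suspensions. The cross-staining terms default to zero.
#'
#' @slot nFdaV100 FDA-positive events/mL in the 100 % viable suspension.
#' @slot nFdaD100 FDA-positive events/mL in the 100 % dead suspension.
#' @slot nPiV100 PI-positive events/mL in the 100 % viable suspension.
#' @slot nPiD100 PI-positive events/mL in the 100 % dead suspension.
#'
#' @seealso \code{\link{expectedCounts}}, \code{\link{expectedRatio}}
#' @export
setClass("PureSuspensionCounts",
  slots = c(nFdaV100 = "numeric", nFdaD100 = "numeric",
            nPiV100 = "numeric", nPiD100 = "numeric")
)

setValidity("PureSuspensionCounts", function(object) {
  v <- c(object@nFdaV100, object@nFdaD100, object@nPiV100, object@nPiD100)
  if (length(v) != 4 || any(!is.finite(v)) || any(v < 0))
    "all four counts must be single finite non-negative numbers"
  else TRUE
})

#' One point of the mixture calibration design
#'
#' A volumetric mixing ratio of viable and dead cell suspensions together
#' with the medium background it is measured in and scale factors for
#' biomass (optical density) and added spent sulfite liquor.
#'
#' @slot pViable volumetric percentage of the viable suspension.
#' @slot pDead volumetric percentage of the dead suspension
#'   (\code{pViable + pDead == 100}).
#' @slot medium one of \code{"PBS"}, \code{"filtered_SSL"},
#'   \code{"unfiltered_SSL"}.
#' @slot odScale biomass scale factor (0.5, 1 or 2 in the standard design).
#' @slot sslScale particle-background scale factor.
#'
#' @export
setClass("MixtureDesignPoint",
  slots = c(pViable = "numeric", pDead = "numeric", medium = "character",
            odScale = "numeric", sslScale = "numeric")
)

setValidity("MixtureDesignPoint", function(object) {
  msg <- character()
  if (abs(object@pViable + object@pDead - 100) > 1e-9)
    msg <- c(msg, "pViable + pDead must equal 100")
  if (object@pViable < 0 || object@pDead < 0)
    msg <- c(msg, "mixing percentages must be non-negative")
  if (!object@medium %in% c("PBS", "filtered_SSL", "unfiltered_SSL"))
    msg <- c(msg, "medium must be PBS, filtered_SSL or unfiltered_SSL")
  if (object@odScale <= 0 || object@sslScale < 0)
    msg <- c(msg, "odScale must be positive and sslScale non-negative")
  if (length(msg)) msg else TRUE
})

#' Expected counts and ratios for a viable/dead mixture
#'
#' @slot nExpViable expected FDA-positive events/mL in the mixture.
#' @slot nExpDead expected PI-positive events/mL in the mixture.
#' @slot ratioViable expected viable percentage (full precision).
#' @slot ratioDead expected dead percentage; sums with \code{ratioViable}
#'   to 100.
#'
#' @seealso \code{\link{expectedRatio}}, \code{\link{reportedRatio}}
#' @export
setClass("ExpectedRatioResult",
  slots = c(nExpViable = "numeric", nExpDead = "numeric",
            ratioViable = "numeric", ratioDead = "numeric")
)

setValidity("ExpectedRatioResult", function(object) {
  if (abs(object@ratioViable + object@ratioDead - 100) > 1e-6)
    "ratioViable + ratioDead must equal 100" else TRUE
})

#' Time series of bioprocess samples
#'
#' Ordered per-timepoint classification counts and process metadata for a
#' continuous cultivation (chemostat or retentostat).
#'
#' @slot samples data.frame with columns \code{time_h},
#'   \code{viable_per_ml}, \code{dead_per_ml}, \code{background_per_ml},
#'   optional \code{single_per_ml}, \code{budding_per_ml}, \code{dw_g_l},
#'   \code{etoh_g_l}, \code{sugar_g_l}, and \code{phase}.
#' @slot workingVolume reactor working volume in liters.
#' @slot dilutionRate dilution rate D in 1/h.
#' @slot feedParticleConc particle concentration of the feed medium in
#'   events/mL (for background wash-in checks).
#'
#' @seealso \code{\link{viabilitySeries}},
#'   \code{\link{specificProductivity}}, \code{\link{readProcessCsv}}
#' @export
setClass("ProcessTimeSeries",
  slots = c(samples = "data.frame", workingVolume = "numeric",
            dilutionRate = "numeric", feedParticleConc = "numeric")
)

setValidity("ProcessTimeSeries", function(object) {
  msg <- character()
  s <- object@samples
  need <- c("time_h", "viable_per_ml", "dead_per_ml", "background_per_ml")
  missing <- setdiff(need, names(s))
  if (length(missing))
    msg <- c(msg, sprintf("missing columns: %s", paste(missing, collapse = ", ")))
  else {
    if (any(s$time_h < 0)) msg <- c(msg, "times must be non-negative")
    if (is.unsorted(s$time_h, strictly = TRUE))
      msg <- c(msg, "times must be strictly increasing")
  }
  if (object@workingVolume <= 0) msg <- c(msg, "workingVolume must be positive")
  if (object@dilutionRate < 0) msg <- c(msg, "dilutionRate must be non-negative")
  if (length(msg)) msg else TRUE
})
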