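# Constructors, accessors and show methods for the core classes.

#' Construct a PulseEventSet
#'
#' @param traces named list of numeric events x samples matrices, one per
#'   canonical channel (\code{\link{cytoChannels}}).
#' @param eventId integer event identifiers (default sequential).
#' @param sampleSpacing micrometers per sample point (default 0.5).
#' @param adcMax detector ceiling in a.u. (default 4095, a 12-bit ADC).
#' @param eventData optional data.frame of per-event annotation.
#'
#' @return A validated \code{\link{PulseEventSet-class}} object.
#' @export
#' @examples
#' tr <- matrix(c(0, 50, 100, 50, 0), nrow = 1)
#' ev <- PulseEventSet(setNames(rep(list(tr), 4), cytoChannels()))
#' nEvents(ev)
PulseEventSet <- function(traces, eventId = NULL, sampleSpacing = 0.5,
                          adcMax = 4095, eventData = NULL) {
  n <- if (length(traces)) nrow(traces[[1]]) else 0L
  if (is.null(eventId)) eventId <- seq_len(n)
  if (is.null(eventData)) eventData <- data.frame()
  new("PulseEventSet", eventId = as.integer(eventId), traces = traces,
      sampleSpacing = sampleSpacing, adcMax = adcMax,
      eventData = eventData)
}

#' @rdname PulseEventSet-class
#' @export
setMethod("nEvents", "PulseEventSet", function(x) length(x@eventId))

#' @rdname PulseEventSet-class
#' @export
setMethod("sampleSpacing", "PulseEventSet", function(x) x@sampleSpacing)

#' @rdname PulseEventSet-class
#' @export
setMethod("adcMax", "PulseEventSet", function(x) x@adcMax)

#' @rdname PulseEventSet-class
#' @export
setMethod("eventData", "PulseEventSet", function(x) x@eventData)

#' @rdname PulseEventSet-class
#' @param i index vector of events to keep.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "PulseEventSet", function(x, i, j, ..., drop = FALSE) {
  tr <- lapply(x@traces, function(m) m[i, , drop = FALSE])
  ed <- if (nrow(x@eventData)) x@eventData[i, , drop = FALSE] else x@eventData
  rownames(ed) <- NULL
  PulseEventSet(tr, eventId = x@eventId[i], sampleSpacing = x@sampleSpacing,
                adcMax = x@adcMax, eventData = ed)
})

setMethod("show", "PulseEventSet", function(object) {
  ns <- if (length(object@traces)) ncol(object@traces[[1]]) else 0L
  cat(sprintf("PulseEventSet: %d events x %d samples (%.2g um/sample, adc max %g)\n",
              nEvents(object), ns, object@sampleSpacing, object@adcMax))
  if (nrow(object@eventData) && "label" %in% names(object@eventData)) {
    tab <- table(object@eventData$label)
    cat("  ground truth:", paste(sprintf("%s=%d", names(tab), tab),
                                 collapse = ", "), "\n")
  }
})

#' Construct an EventFeatureTable
#'
#' Usually produced by \code{\link{extractFeatures}}; the constructor is
#' exposed for I/O round-trips and tests.
#'
#' @param features data.frame with the full feature column set (see
#'   \code{\link{EventFeatureTable-class}}); absent \code{label} /
#'   \code{morphology} columns are filled with \code{"unclassified"} /
#'   \code{"n/a"}.
#' @param sampleSpacing,adcMax acquisition metadata carried with the table.
#'
#' @return A validated \code{EventFeatureTable}.
#' @export
EventFeatureTable <- function(features, sampleSpacing = 0.5, adcMax = 4095) {
  if (!"label" %in% names(features)) features$label <- "unclassified"
  if (!"morphology" %in% names(features)) features$morphology <- "n/a"
  features <- as.data.frame(features)[, .featureColumns(), drop = FALSE]
  rownames(features) <- NULL
  new("EventFeatureTable", features = features,
      sampleSpacing = sampleSpacing, adcMax = adcMax)
}

#' @rdname EventFeatureTable-class
#' @param x an \code{EventFeatureTable}.
#' @export
setMethod("nEvents", "EventFeatureTable", function(x) nrow(x@features))

#' @rdname EventFeatureTable-class
#' @export
setMethod("featureTable", "EventFeatureTable", function(x) x@features)

#' @rdname EventFeatureTable-class
#' @export
setMethod("eventLabels", "EventFeatureTable", function(x) x@features$label)

#' @rdname EventFeatureTable-class
#' @export
setMethod("sampleSpacing", "EventFeatureTable", function(x) x@sampleSpacing)

#' @rdname EventFeatureTable-class
#' @export
setMethod("adcMax", "EventFeatureTable", function(x) x@adcMax)

#' @rdname EventFeatureTable-class
#' @param i row index of events to keep.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "EventFeatureTable", function(x, i, j, ..., drop = FALSE) {
  EventFeatureTable(x@features[i, , drop = FALSE],
                    sampleSpacing = x@sampleSpacing, adcMax = x@adcMax)
})

setMethod("show", "EventFeatureTable", function(object) {
  cat(sprintf("EventFeatureTable: %d events\n", nEvents(object)))
  tab <- table(object@features$label)
  cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
})

setMethod("show", "GateSet", function(object) {
  cat("GateSet\n")
  cat(sprintf("  viable gate: %d vertices; dead gate: %d; background: %d\n",
              nrow(object@viableGate), nrow(object@deadGate),
              nrow(object@backgroundGate)))
  cat(sprintf("  size window: [%.2f, %.2f] um; shape window: [%.0f, %.0f] a.u.\n",
              object@sizeWindow[1], object@sizeWindow[2],
              object@shapeWindow[1], object@shapeWindow[2]))
  if (all(is.finite(object@morphologyBoundary)))
    cat(sprintf("  morphology boundary: %.3g*log10(len) + %.3g*log10(ssc) + %.3g > 0 => budding\n",
                object@morphologyBoundary[1], object@morphologyBoundary[2],
                object@morphologyBoundary[3]))
  else cat("  morphology boundary: not fitted\n")
})

#' @rdname ClassificationResult-class
#' @param x a \code{ClassificationResult}.
#' @export
setMethod("classCounts", "ClassificationResult", function(x) x@counts)

#' @rdname ClassificationResult-class
#' @export
setMethod("concentrations", "ClassificationResult", function(x) x@concentrations)

#' @rdname ClassificationResult-class
#' @export
setMethod("viabilityPercent", "ClassificationResult", function(x) x@viabilityPercent)

#' @rdname ClassificationResult-class
#' @export
setMethod("qcFlags", "ClassificationResult", function(x) x@flags)

#' @rdname ClassificationResult-class
#' @export
setMethod("eventLabels", "ClassificationResult", function(x) x@eventLabels)

setMethod("show", "ClassificationResult", function(object) {
  cat("ClassificationResult\n  counts:",
      paste(sprintf("%s=%d", names(object@counts), object@counts),
            collapse = ", "), "\n")
  cat(sprintf("  viability: %s %%\n",
              ifelse(is.na(object@viabilityPercent), "NA",
                     sprintf("%.1f", object@viabilityPercent))))
  cat(sprintf("  flags: overload=%s, green saturation fraction=%.3f\n",
              object@flags$overload, object@flags$saturationFraction))
})

#' Construct pure-suspension reference counts
#'
#' @param nFdaV100,nFdaD100,nPiV100,nPiD100 events/mL; see
#'   \code{\link{PureSuspensionCounts-class}}. Cross-staining terms
#'   (\code{nFdaD100}, \code{nPiV100}) default to 0.
#' @return A \code{PureSuspensionCounts} object.
#' @export
#' @examples
#' PureSuspensionCounts(nFdaV100 = 1000, nPiD100 = 510)
PureSuspensionCounts <- function(nFdaV100, nFdaD100 = 0, nPiV100 = 0,
                                 nPiD100 = 0) {
  new("PureSuspensionCounts", nFdaV100 = nFdaV100, nFdaD100 = nFdaD100,
      nPiV100 = nPiV100, nPiD100 = nPiD100)
}

setMethod("show", "PureSuspensionCounts", function(object) {
  cat(sprintf(paste0("PureSuspensionCounts (events/mL)\n  FDA+: V100%%=%g, ",
                     "D100%%=%g\n  PI+:  V100%%=%g, D100%%=%g\n"),
              object@nFdaV100, object@nFdaD100, object@nPiV100,
              object@nPiD100))
})

#' Construct a mixture design point
#'
#' @param pViable volumetric percentage of viable suspension.
#' @param pDead volumetric percentage of dead suspension (defaults to the
#'   complement of \code{pViable}).
#' @param medium background medium identifier.
#' @param odScale,sslScale biomass and particle scale factors.
#' @return A \code{MixtureDesignPoint}.
#' @export
MixtureDesignPoint <- function(pViable, pDead = 100 - pViable,
                               medium = "PBS", odScale = 1, sslScale = 1) {
  new("MixtureDesignPoint", pViable = pViable, pDead = pDead,
      medium = medium, odScale = odScale, sslScale = sslScale)
}

setMethod("show", "MixtureDesignPoint", function(object) {
  cat(sprintf("MixtureDesignPoint: V%g/D%g in %s (OD x%g, SSL x%g)\n",
              object@pViable, object@pDead, object@medium, object@odScale,
              object@sslScale))
})

setMethod("show", "ExpectedRatioResult", function(object) {
  cat(sprintf(paste0("ExpectedRatioResult: N_viable=%g, N_dead=%g events/mL\n",
                     "  expected ratio V/D: %.2f / %.2f %% (reported %d/%d)\n"),
              object@nExpViable, object@nExpDead, object@ratioViable,
              object@ratioDead, round(object@ratioViable),
              round(object@ratioDead)))
})

#' Construct a process time series
#'
#' @param samples data.frame of timepoints; see
#'   \code{\link{ProcessTimeSeries-class}} for the column schema.
#' @param workingVolume reactor working volume (L), default 1.
#' @param dilutionRate dilution rate D (1/h).
#' @param feedParticleConc particle concentration of the feed (events/mL).
#' @return A validated \code{ProcessTimeSeries}.
#' @export
ProcessTimeSeries <- function(samples, workingVolume = 1, dilutionRate = 0,
                              feedParticleConc = NA_real_) {
  samples <- as.data.frame(samples)
  if (!"phase" %in% names(samples)) samples$phase <- NA_character_
  new("ProcessTimeSeries", samples = samples, workingVolume = workingVolume,
      dilutionRate = dilutionRate, feedParticleConc = feedParticleConc)
}

setMethod("show", "ProcessTimeSeries", function(object) {
  s <- object@samples
  cat(sprintf("ProcessTimeSeries: %d samples, %.1f-%.1f h, D=%.3g 1/h, V=%g L\n",
              nrow(s), min(s$time_h), max(s$time_h), object@dilutionRate,
              object@workingVolume))
})
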