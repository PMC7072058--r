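#' Extract scalar pulse features per channel
#'
#' Reduces each event's sampled signal trace to the scalar features used
#' for gating: the baseline-corrected \emph{total} (sum of samples above
#' baseline), the \emph{maximum}, the \emph{sample length} (number of
#' samples above a threshold converted to micrometers via the sample
#' spacing) and a \emph{saturation} flag (a run of at least
#' \code{minSaturationRun} consecutive samples at the detector ceiling).
#'
#' Sample length counts every above-threshold sample, not only the
#' longest run, so it is monotone under pointwise signal increase and
#' equals the pulse extent for the unimodal pulses typical of single
#' particles.
#'
#' @param events a \code{\link{PulseEventSet-class}}.
#' @param baseline baseline level subtracted before summation (a.u.,
#'   default 0; instruments usually pre-subtract the baseline).
#' @param lengthThreshold signal threshold defining the pulse extent
#'   (a.u., default 10, just above the noise floor).
#' @param minSaturationRun minimum number of consecutive ceiling-valued
#'   samples that counts as saturation (default 2, so isolated ADC spikes
#'   are ignored).
#'
#' @return An \code{\link{EventFeatureTable-class}} with one row per event.
#' @export
#' @examples
#' tr <- matrix(c(0, 100, 100, 100, 0), nrow = 1)
#' ev <- PulseEventSet(setNames(rep(list(tr), 4), cytoChannels()),
#'                     sampleSpacing = 1)
#' featureTable(extractFeatures(ev))[, c("FSC_total", "FSC_length_um")]
extractFeatures <- function(events, baseline = 0, lengthThreshold = 10,
                            minSaturationRun = 2) {
  stopifnot(is(events, "PulseEventSet"))
  .assertScalarNumeric(baseline, "baseline", min = 0)
  .assertScalarNumeric(lengthThreshold, "lengthThreshold", min = 0)
  if (length(events@traces[[1]]) && ncol(events@traces[[1]]) < 1)
    stop("events contain empty traces")
  n <- nEvents(events)
  out <- data.frame(event_id = events@eventId)
  for (ch in cytoChannels()) {
    m <- events@traces[[ch]]
    if (n > 0 && ncol(m) == 0) stop("events contain empty traces")
    out[[paste0(ch, "_total")]] <- rowSums(pmax(m - baseline, 0))
    out[[paste0(ch, "_max")]] <-
      if (n) as.numeric(do.call(pmax, asplit(m, 2))) else numeric(0)
    out[[paste0(ch, "_length_um")]] <-
      rowSums(m > lengthThreshold) * events@sampleSpacing
    out[[paste0(ch, "_saturated")]] <-
      .saturatedRows(m, events@adcMax, minSaturationRun)
  }
  lab <- if (nrow(events@eventData) && "label" %in% names(events@eventData))
    as.character(events@eventData$label) else rep("unclassified", n)
  morph <- if (nrow(events@eventData) && "morphology" %in% names(events@eventData))
    as.character(events@eventData$morphology) else rep("n/a", n)
  out$label <- lab
  out$morphology <- morph
  EventFeatureTable(out, sampleSpacing = events@sampleSpacing,
                    adcMax = events@adcMax)
}

# Rows of m containing >= minRun consecutive samples at the ceiling.
.saturatedRows <- function(m, adcMax, minRun) {
  if (nrow(m) == 0) return(logical(0))
  at <- m >= adcMax - 1e-9
  if (minRun > ncol(m)) return(rep(FALSE, nrow(m)))
  hit <- rep(FALSE, nrow(m))
  for (start in seq_len(ncol(m) - minRun + 1)) {
    run <- at[, start, drop = TRUE]
    k <- 1
    while (k < minRun && any(run)) {
      run <- run & at[, start + k, drop = TRUE]
      k <- k + 1
    }
    hit <- hit | run
  }
  hit
}

#' Detect ADC saturation in one channel
#'
#' An event is saturated when its trace holds the detector ceiling
#' (\code{adcMax}) for at least \code{minRun} consecutive samples.
#' Saturation of the green fluorescence channel is expected for strongly
#' stained budding-cell agglomerates and marks a loss of quantitative
#' signal, not an invalid event.
#'
#' @param events a \code{\link{PulseEventSet-class}}.
#' @param channel one of \code{\link{cytoChannels}()}.
#' @param minRun minimum run length of ceiling-valued samples (default 2).
#'
#' @return Logical vector, one flag per event.
#' @export
detectSaturation <- function(events, channel, minRun = 2) {
  stopifnot(is(events, "PulseEventSet"))
  if (!channel %in% cytoChannels())
    stop(sprintf("unknown channel '%s'; expected one of %s", channel,
                 paste(cytoChannels(), collapse = ", ")))
  if (!is.numeric(minRun) || length(minRun) != 1 || minRun < 1)
    stop("minRun must be a single integer >= 1")
  .saturatedRows(events@traces[[channel]], events@adcMax, as.integer(minRun))
}
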