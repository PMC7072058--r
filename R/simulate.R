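#' Population specification for the event simulator
#'
#' Describes one particle population as log-normal distributions over
#' pulse width (size) and per-channel pulse amplitude, plus staining
#' fractions. Defaults emulate the three populations seen when FDA/PI
#' stained yeast is measured in spent-sulfite-liquor media:
#' \describe{
#'   \item{viable}{green-positive, red-negative cells around 5 um, a
#'     configurable fraction of which are budding mother-daughter doublets.}
#'   \item{dead}{red-positive, green-negative cells, slightly smaller and
#'     dimmer in scatter (membrane-compromised, partially disintegrated).}
#'   \item{ssl_particle}{lignosulfonate medium particles with a broad
#'     size/scatter range overlapping and exceeding the cells, no green
#'     fluorescence, and stochastic partial red fluorescence from PI
#'     adsorbing to particles.}
#' }
#' The three populations are constructed to separate in fluorescence
#' space while overlapping in scatter, so classification must combine
#' fluorescence with size and shape.
#'
#' @param kind one of \code{"viable"}, \code{"dead"}, \code{"ssl_particle"}.
#' @param concentration suspension concentration in events/mL (used by
#'   mixture simulation to weight populations).
#' @param sizeMeanlog,sizeSdlog log-normal parameters of the pulse width
#'   in micrometers.
#' @param ampMeanlog,ampSdlog named numeric vectors (per canonical
#'   channel) of log-normal pulse-amplitude parameters in a.u.
#' @param greenPositiveFraction,redPositiveFraction probability that an
#'   event draws its fluorescence amplitude from the positive (stained)
#'   distribution rather than the background distribution.
#' @param buddingFraction fraction of events emitted as two-lobed doublet
#'   pulses (viable cells only).
#' @param negAmpMeanlog,negAmpSdlog log-normal parameters of the
#'   unstained background fluorescence amplitude.
#' @param greenRedBleed fraction of the green trace added to the red
#'   trace (spectral spillover; default 0, matching acquisition software
#'   without spillover compensation).
#'
#' @return A list of class \code{"PopulationSpec"}.
#' @export
#' @examples
#' populationSpec("viable", concentration = 4e5)
populationSpec <- function(kind = c("viable", "dead", "ssl_particle"),
                           concentration = 4e5,
                           sizeMeanlog = NULL, sizeSdlog = NULL,
                           ampMeanlog = NULL, ampSdlog = NULL,
                           greenPositiveFraction = NULL,
                           redPositiveFraction = NULL,
                           buddingFraction = 0,
                           negAmpMeanlog = log(4), negAmpSdlog = 0.5,
                           greenRedBleed = 0) {
  kind <- match.arg(kind)
  def <- switch(kind,
    viable = list(sizeMeanlog = log(5), sizeSdlog = 0.18,
                  ampMeanlog = c(FSC = log(800), SSC = log(500),
                                 FL_GREEN = log(1500), FL_RED = NA),
                  ampSdlog = c(FSC = 0.25, SSC = 0.3,
                               FL_GREEN = 0.35, FL_RED = 0.5),
                  greenPositiveFraction = 1, redPositiveFraction = 0),
    dead = list(sizeMeanlog = log(4.2), sizeSdlog = 0.2,
                ampMeanlog = c(FSC = log(600), SSC = log(400),
                               FL_GREEN = NA, FL_RED = log(1200)),
                ampSdlog = c(FSC = 0.25, SSC = 0.3,
                             FL_GREEN = 0.5, FL_RED = 0.35),
                greenPositiveFraction = 0, redPositiveFraction = 1),
    ssl_particle = list(sizeMeanlog = log(3.5), sizeSdlog = 0.8,
                        ampMeanlog = c(FSC = log(400), SSC = log(300),
                                       FL_GREEN = NA, FL_RED = log(60)),
                        ampSdlog = c(FSC = 0.8, SSC = 0.8,
                                     FL_GREEN = 0.5, FL_RED = 0.7),
                        greenPositiveFraction = 0, redPositiveFraction = 0.3))
  spec <- list(kind = kind, concentration = concentration,
    sizeMeanlog = sizeMeanlog %||% def$sizeMeanlog,
    sizeSdlog = sizeSdlog %||% def$sizeSdlog,
    ampMeanlog = ampMeanlog %||% def$ampMeanlog,
    ampSdlog = ampSdlog %||% def$ampSdlog,
    greenPositiveFraction = greenPositiveFraction %||% def$greenPositiveFraction,
    redPositiveFraction = redPositiveFraction %||% def$redPositiveFraction,
    buddingFraction = buddingFraction,
    negAmpMeanlog = negAmpMeanlog, negAmpSdlog = negAmpSdlog,
    greenRedBleed = greenRedBleed)
  class(spec) <- "PopulationSpec"
  .validatePopulationSpec(spec)
  spec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.validatePopulationSpec <- function(spec) {
  fr <- c(spec$greenPositiveFraction, spec$redPositiveFraction,
          spec$buddingFraction)
  if (any(!is.finite(fr)) || any(fr < 0) || any(fr > 1))
    stop("staining and budding fractions must lie in [0, 1]")
  if (!is.finite(spec$concentration) || spec$concentration < 0)
    stop("concentration must be non-negative")
  if (spec$kind != "viable" && spec$buddingFraction > 0)
    stop("buddingFraction applies to viable populations only")
  invisible(spec)
}

#' Simulate pulse-shape events for one population
#'
#' Draws events with unimodal Gaussian-profile traces. Pulse width sets
#' the Gaussian sigma; scatter amplitudes scale with relative particle
#' size so large medium particles reach and exceed cell-like scatter.
#' Budding events are emitted as two overlapping Gaussian lobes with
#' elevated side scatter and green fluorescence (which may saturate the
#' ADC). Unstained channels carry a low background amplitude; traces
#' additionally carry truncated-Gaussian detector noise.
#'
#' @param spec a \code{\link{populationSpec}}.
#' @param nEvents number of events to draw (>= 0).
#' @param seed RNG seed; a fixed seed reproduces the events exactly.
#' @param nSamples samples per trace (default 64).
#' @param sampleSpacing micrometers per sample (default 0.5).
#' @param adcMax detector ceiling in a.u. (default 4095); traces are
#'   clipped here, producing genuine saturation plateaus.
#' @param noiseSd standard deviation of the additive detector noise.
#'
#' @return A \code{\link{PulseEventSet-class}} with ground-truth
#'   \code{label} and \code{morphology} columns in \code{eventData}.
#' @export
#' @examples
#' ev <- simulatePopulation(populationSpec("viable"), 100, seed = 1)
#' table(eventData(ev)$morphology)
simulatePopulation <- function(spec, nEvents, seed = NULL, nSamples = 64,
                               sampleSpacing = 0.5, adcMax = 4095,
                               noiseSd = 2) {
  .validatePopulationSpec(spec)
  if (!is.numeric(nEvents) || length(nEvents) != 1 || nEvents < 0)
    stop("nEvents must be a single non-negative integer")
  nEvents <- as.integer(nEvents)
  .withSeed(seed, .simulatePopulationImpl(spec, nEvents, nSamples,
                                          sampleSpacing, adcMax, noiseSd))
}

.simulatePopulationImpl <- function(spec, n, nSamples, sampleSpacing,
                                    adcMax, noiseSd) {
  chans <- cytoChannels()
  if (n == 0) {
    tr <- setNames(rep(list(matrix(numeric(0), 0, nSamples)), 4), chans)
    return(PulseEventSet(tr, sampleSpacing = sampleSpacing, adcMax = adcMax,
                         eventData = data.frame(label = character(0),
                                                morphology = character(0))))
  }
  width <- rlnorm(n, spec$sizeMeanlog, spec$sizeSdlog)
  sigma <- pmin(pmax(width / (4 * sampleSpacing), 0.6), nSamples / 6)
  center <- nSamples / 2 + rnorm(n, 0, 1.5)
  budding <- runif(n) < spec$buddingFraction
  relSize <- width / exp(spec$sizeMeanlog)

  amp <- list()
  for (ch in c("FSC", "SSC"))
    amp[[ch]] <- rlnorm(n, spec$ampMeanlog[[ch]], spec$ampSdlog[[ch]]) * relSize
  greenPos <- runif(n) < spec$greenPositiveFraction
  redPos <- runif(n) < spec$redPositiveFraction
  neg <- function(n) rlnorm(n, spec$negAmpMeanlog, spec$negAmpSdlog)
  amp$FL_GREEN <- ifelse(greenPos,
    rlnorm(n, spec$ampMeanlog[["FL_GREEN"]], spec$ampSdlog[["FL_GREEN"]]),
    neg(n))
  amp$FL_RED <- ifelse(redPos,
    rlnorm(n, spec$ampMeanlog[["FL_RED"]], spec$ampSdlog[["FL_RED"]]),
    neg(n))
  # budding doublets: brighter side scatter and green fluorescence
  amp$SSC[budding] <- amp$SSC[budding] * 3.0
  amp$FL_GREEN[budding] <- amp$FL_GREEN[budding] * 1.8

  # budding doublets: two overlapping lobes, centered in the window
  off <- 5 * sigma
  center[budding] <- center[budding] - off[budding] / 2
  J <- matrix(seq_len(nSamples), n, nSamples, byrow = TRUE)
  shape <- exp(-((J - center)^2) / (2 * sigma^2))
  if (any(budding)) {
    lobe2 <- exp(-((J - center - off)^2) / (2 * sigma^2)) * 0.95
    shape[budding, ] <- shape[budding, , drop = FALSE] +
      lobe2[budding, , drop = FALSE]
  }
  traces <- setNames(vector("list", 4), chans)
  for (ch in chans) {
    tr <- shape * amp[[ch]] +
      pmax(matrix(rnorm(n * nSamples, 0, noiseSd), n, nSamples), 0)
    traces[[ch]] <- pmin(tr, adcMax)
  }
  if (spec$greenRedBleed > 0)
    traces$FL_RED <- pmin(traces$FL_RED +
                            spec$greenRedBleed * traces$FL_GREEN, adcMax)
  label <- switch(spec$kind, viable = "viable", dead = "dead",
                  ssl_particle = "background")
  morph <- if (spec$kind == "viable")
    ifelse(budding, "budding", "single") else rep("n/a", n)
  PulseEventSet(traces, sampleSpacing = sampleSpacing, adcMax = adcMax,
                eventData = data.frame(label = rep(label, n),
                                       morphology = morph))
}

#' Medium background presets
#'
#' Base spent-sulfite-liquor particle concentration and the dead-cell
#' event-yield factor associated with each calibration medium. Unfiltered
#' SSL carries roughly 20 times the particle load of filtered SSL;
#' measurement-ready suspensions stay below the instrument's particle
#' limit. Yield factors reproduce the expected-ratio behaviour of
#' microwave-killed reference suspensions in the corresponding media
#' (partial disintegration reduces the countable dead-cell yield).
#'
#' @param medium \code{"PBS"}, \code{"filtered_SSL"} or
#'   \code{"unfiltered_SSL"}.
#' @return List with \code{sslConcentration} (events/mL) and
#'   \code{rYield}.
#' @export
mediumPreset <- function(medium = c("PBS", "filtered_SSL", "unfiltered_SSL")) {
  medium <- match.arg(medium)
  switch(medium,
    PBS = list(sslConcentration = 5e3, rYield = 0.51),
    filtered_SSL = list(sslConcentration = 2.5e4, rYield = 0.96),
    unfiltered_SSL = list(sslConcentration = 5e5, rYield = 1.0))
}

#' Mixture simulation specification
#'
#' Defines a volumetric mixture of a viable and a dead cell suspension in
#' a particle-carrying medium. Event counts follow the event
#' concentrations: the viable suspension contributes in proportion to its
#' volume fraction, the dead suspension in proportion to its volume
#' fraction times the yield factor \code{rYield} (dead suspensions
#' prepared by harsh microwave treatment lose countable events to
#' partial cell disintegration), and the medium contributes its particle
#' background independently of the mixing ratio.
#'
#' @param pViable,pDead volumetric percentages; must sum to 100.
#' @param medium background medium; sets the default particle
#'   concentration and yield factor via \code{\link{mediumPreset}}.
#' @param rYield dead:viable event-yield factor in (0, 1]; default from
#'   the medium preset.
#' @param sslLevel particle-background multiplier (0, 0.5, 1 or 2 in the
#'   standard design; any non-negative value accepted).
#' @param odScale biomass multiplier (optical-density variation).
#' @param nEvents total events to draw per simulated measurement.
#' @param buddingFraction budding fraction of the viable population.
#' @param cellConcentration viable-suspension concentration at OD scale 1
#'   (events/mL, default 4e5 for a measurement-ready dilution).
#' @param viableSpec,deadSpec,sslSpec optional population overrides.
#'
#' @return A list of class \code{"MixtureSpec"}.
#' @export
#' @examples
#' mixtureSpec(60, medium = "unfiltered_SSL", nEvents = 1000)
mixtureSpec <- function(pViable, pDead = 100 - pViable, medium = "PBS",
                        rYield = NULL, sslLevel = 1, odScale = 1,
                        nEvents = 20000, buddingFraction = 0.15,
                        cellConcentration = 4e5,
                        viableSpec = NULL, deadSpec = NULL, sslSpec = NULL) {
  if (abs(pViable + pDead - 100) > 1e-9)
    stop("pViable + pDead must equal 100")
  if (pViable < 0 || pDead < 0) stop("mixing percentages must be >= 0")
  preset <- mediumPreset(medium)
  rYield <- rYield %||% preset$rYield
  if (!is.finite(rYield) || rYield <= 0 || rYield > 1)
    stop("rYield must lie in (0, 1]")
  if (sslLevel < 0 || odScale <= 0)
    stop("sslLevel must be >= 0 and odScale > 0")
  structure(list(
    pViable = pViable, pDead = pDead, medium = medium, rYield = rYield,
    sslLevel = sslLevel, odScale = odScale, nEvents = nEvents,
    buddingFraction = buddingFraction,
    cellConcentration = cellConcentration,
    sslConcentration = preset$sslConcentration,
    viableSpec = viableSpec, deadSpec = deadSpec, sslSpec = sslSpec),
    class = "MixtureSpec")
}

#' Event concentrations implied by a mixture specification
#'
#' @param spec a \code{\link{mixtureSpec}}.
#' @return Named numeric vector with \code{viable}, \code{dead},
#'   \code{background} and \code{total} event concentrations (events/mL).
#' @export
mixtureConcentrations <- function(spec) {
  stopifnot(inherits(spec, "MixtureSpec"))
  cV <- spec$cellConcentration * spec$odScale * spec$pViable / 100
  cD <- spec$cellConcentration * spec$odScale * spec$rYield * spec$pDead / 100
  cS <- spec$sslConcentration * spec$sslLevel
  c(viable = cV, dead = cD, background = cS, total = cV + cD + cS)
}

#' Simulate a stained viable/dead mixture measurement
#'
#' Draws \code{nEvents} events from the three populations with
#' multinomial weights proportional to their event concentrations, then
#' shuffles them into acquisition order. Ground-truth population and
#' morphology labels are stored in \code{eventData}.
#'
#' @param spec a \code{\link{mixtureSpec}}.
#' @param seed RNG seed; fixed seed gives identical output.
#' @param nSamples,sampleSpacing,adcMax,noiseSd trace geometry, as in
#'   \code{\link{simulatePopulation}}.
#'
#' @return A \code{\link{PulseEventSet-class}} with ground truth labels.
#' @export
#' @examples
#' ev <- simulateMixture(mixtureSpec(60, nEvents = 500), seed = 1)
#' prop.table(table(eventData(ev)$label))
simulateMixture <- function(spec, seed = NULL, nSamples = 64,
                            sampleSpacing = 0.5, adcMax = 4095,
                            noiseSd = 2) {
  stopifnot(inherits(spec, "MixtureSpec"))
  .withSeed(seed, {
    conc <- mixtureConcentrations(spec)
    if (conc[["total"]] <= 0) stop("mixture has zero total concentration")
    counts <- as.vector(rmultinom(1, spec$nEvents, conc[1:3]))
    vs <- spec$viableSpec %||%
      populationSpec("viable", concentration = conc[["viable"]],
                     buddingFraction = spec$buddingFraction)
    ds <- spec$deadSpec %||%
      populationSpec("dead", concentration = conc[["dead"]])
    ss <- spec$sslSpec %||%
      populationSpec("ssl_particle", concentration = conc[["background"]])
    parts <- mapply(function(s, k)
      .simulatePopulationImpl(s, k, nSamples, sampleSpacing, adcMax, noiseSd),
      list(vs, ds, ss), counts, SIMPLIFY = FALSE)
    combined <- .rbindEventSets(parts)
    ord <- sample.int(nEvents(combined))
    out <- combined[ord]
    out@eventId <- seq_len(nEvents(out))
    validObject(out)
    out
  })
}

# Concatenate event sets sharing geometry; event ids are renumbered.
.rbindEventSets <- function(sets) {
  chans <- cytoChannels()
  tr <- setNames(lapply(chans, function(ch)
    do.call(rbind, lapply(sets, function(s) s@traces[[ch]]))), chans)
  ed <- do.call(rbind, lapply(sets, function(s) s@eventData))
  rownames(ed) <- NULL
  PulseEventSet(tr, sampleSpacing = sets[[1]]@sampleSpacing,
                adcMax = sets[[1]]@adcMax, eventData = ed)
}

#' Emulate instrument throughput limiting at high particle loads
#'
#' Above its particle-concentration limit the acquisition software
#' reduces data intake, which biases the recorded population. This is
#' modeled as non-uniform thinning: each event is retained with a
#' probability proportional to its forward-scatter signal mass, so
#' larger/brighter particles are preferentially kept and measured ratios
#' become inaccurate. At or below the limit the events pass unchanged.
#'
#' @param events a \code{\link{PulseEventSet-class}}.
#' @param totalConcentration sample concentration in events/mL.
#' @param limit instrument particle limit (default 1e6 events/mL).
#' @param seed RNG seed for the thinning draw.
#'
#' @return List with \code{events} (possibly thinned), \code{overload}
#'   (logical flag) and \code{keptFraction}.
#' @export
applyInstrumentLimit <- function(events, totalConcentration, limit = 1e6,
                                 seed = NULL) {
  stopifnot(is(events, "PulseEventSet"))
  .assertScalarNumeric(totalConcentration, "totalConcentration", min = 0)
  .assertScalarNumeric(limit, "limit", min = 0, strict = TRUE)
  if (totalConcentration <= limit)
    return(list(events = events, overload = FALSE, keptFraction = 1))
  .withSeed(seed, {
    f <- limit / totalConcentration
    w <- rowSums(events@traces$FSC)
    p <- pmin(1, f * w / mean(w))
    keep <- runif(nEvents(events)) < p
    list(events = events[keep], overload = TRUE,
         keptFraction = mean(keep))
  })
}
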