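#' Expected viable and dead counts of a defined mixture
#'
#' Linear mixing of the pure-suspension reference counts: the expected
#' FDA-positive (viable) count of a mixture is the volume-weighted sum of
#' the FDA-positive counts of the two pure suspensions, and likewise for
#' the PI-positive (dead) count:
#' \deqn{N_{exp,viable} = N_{FDA,V100} P_{viable}/100 +
#'       N_{FDA,D100} P_{dead}/100}
#' \deqn{N_{exp,dead} = N_{PI,V100} P_{viable}/100 +
#'       N_{PI,D100} P_{dead}/100}
#'
#' @param pure a \code{\link{PureSuspensionCounts}}.
#' @param point a \code{\link{MixtureDesignPoint}}, or a numeric viable
#'   percentage.
#'
#' @return Named numeric vector \code{c(viable = ..., dead = ...)} in
#'   events/mL.
#' @export
#' @examples
#' expectedCounts(PureSuspensionCounts(1000, nPiD100 = 510), 80)
expectedCounts <- function(pure, point) {
  stopifnot(is(pure, "PureSuspensionCounts"))
  if (is.numeric(point)) point <- MixtureDesignPoint(point)
  stopifnot(is(point, "MixtureDesignPoint"))
  pv <- point@pViable / 100
  pd <- point@pDead / 100
  c(viable = pure@nFdaV100 * pv + pure@nFdaD100 * pd,
    dead = pure@nPiV100 * pv + pure@nPiD100 * pd)
}

#' Expected viable/dead ratio from expected counts
#'
#' \deqn{Ratio_{V,exp} = 100 N_{exp,viable} /
#'       (N_{exp,viable} + N_{exp,dead})}
#' and \eqn{Ratio_{D,exp} = 100 - Ratio_{V,exp}}. Full precision is kept
#' internally; rounding to integer percent happens only at the reporting
#' layer (\code{\link{reportedRatio}}).
#'
#' @param nExpViable,nExpDead expected counts in events/mL; alternatively
#'   pass the named vector returned by \code{\link{expectedCounts}} as
#'   the first argument.
#'
#' @return An \code{\link{ExpectedRatioResult-class}}.
#' @export
#' @examples
#' expectedRatio(800, 102)   # ~88.7 % viable, reported as 89
expectedRatio <- function(nExpViable, nExpDead = NULL) {
  if (is.null(nExpDead) && length(nExpViable) == 2) {
    nExpDead <- nExpViable[["dead"]]
    nExpViable <- nExpViable[["viable"]]
  }
  .assertScalarNumeric(nExpViable, "nExpViable", min = 0)
  .assertScalarNumeric(nExpDead, "nExpDead", min = 0)
  tot <- nExpViable + nExpDead
  if (tot <= 0)
    stop("expected ratio undefined: both expected counts are zero")
  rv <- 100 * nExpViable / tot
  new("ExpectedRatioResult", nExpViable = nExpViable, nExpDead = nExpDead,
      ratioViable = rv, ratioDead = 100 - rv)
}

#' Integer-percent report of an expected ratio
#'
#' @param x an \code{\link{ExpectedRatioResult-class}}.
#' @return Named integer vector \code{c(viable = ..., dead = ...)}.
#' @export
reportedRatio <- function(x) {
  stopifnot(is(x, "ExpectedRatioResult"))
  c(viable = as.integer(round(x@ratioViable)),
    dead = as.integer(round(x@ratioDead)))
}

#' Fit the dead-suspension event-yield factor from an expected-ratio row
#'
#' Dead reference suspensions prepared by harsh (microwave) killing lose
#' countable events to partial cell disintegration, so the event-based
#' expected viable ratio of a volumetric mixture exceeds the volumetric
#' ratio. Under zero cross-staining the relation is
#' \deqn{Ratio_V(P) = 100 P / (P + r (100 - P))}
#' with \eqn{r} the dead:viable event-yield factor. This fits \eqn{r} by
#' least squares over the supplied (P, ratio) pairs.
#'
#' @param pViable numeric vector of volumetric viable percentages
#'   (non-endpoint points, i.e. strictly between 0 and 100, are required
#'   for identifiability).
#' @param ratioViable corresponding expected viable percentages.
#'
#' @return Fitted \code{r} in (0, 1].
#' @export
#' @examples
#' fitYieldFactor(c(80, 60, 50, 40, 20), c(89, 75, 66, 57, 33))  # ~0.51
fitYieldFactor <- function(pViable, ratioViable) {
  if (length(pViable) != length(ratioViable))
    stop("pViable and ratioViable must have equal length")
  inner <- pViable > 0 & pViable < 100
  if (sum(inner) < 2)
    stop("need at least 2 non-endpoint design points to fit the yield factor")
  P <- pViable[inner]; R <- ratioViable[inner]
  sse <- function(r) sum((100 * P / (P + r * (100 - P)) - R)^2)
  opt <- optimize(sse, interval = c(1e-4, 1))
  # the optimum can sit on the closed upper bound r = 1
  if (sse(1) <= opt$objective) 1 else opt$minimum
}

#' Accuracy of measured versus expected viability
#'
#' Summarizes technical replicates of a measured viable percentage
#' against the expected value: mean, standard deviation, absolute
#' deviation of the mean from expectation, and a pass flag requiring
#' both the deviation and the SD to stay within \code{tolerance}
#' percentage points (default 10).
#'
#' @param measured numeric vector of replicate viable percentages
#'   (length >= 2).
#' @param expected expected viable percentage, or an
#'   \code{\link{ExpectedRatioResult-class}}.
#' @param tolerance acceptance tolerance in percentage points.
#'
#' @return List with \code{mean}, \code{sd}, \code{deviation},
#'   \code{expected}, \code{tolerance} and \code{pass}.
#' @export
#' @examples
#' evaluateAccuracy(c(88.1, 90.2, 89.4), 89)
evaluateAccuracy <- function(measured, expected, tolerance = 10) {
  if (length(measured) < 2)
    stop("need at least 2 technical replicates")
  if (is(expected, "ExpectedRatioResult")) expected <- expected@ratioViable
  .assertScalarNumeric(expected, "expected", min = 0)
  .assertScalarNumeric(tolerance, "tolerance", min = 0)
  m <- mean(measured); s <- sd(measured)
  dev <- abs(m - expected)
  list(mean = m, sd = s, deviation = dev, expected = expected,
       tolerance = tolerance, pass = dev <= tolerance && s <= tolerance)
}

#' Particle-load quality control
#'
#' The method cannot cope with particle concentrations above the
#' instrument limit (default 1e6 particles/mL): acquisition is throttled
#' and results become inaccurate. Samples must therefore be checked in a
#' preliminary measurement and diluted before analysis. Concentrations
#' at or below the limit pass; above it the smallest power-of-ten
#' dilution bringing the sample under the limit is recommended, matching
#' serial-dilution practice.
#'
#' @param totalConcentration total particle concentration in events/mL.
#' @param limit instrument particle limit in events/mL (default 1e6).
#'
#' @return List with \code{pass}, \code{recommendedDilution} (1 when
#'   passing), \code{totalConcentration} and \code{limit}.
#' @export
#' @examples
#' qcParticleLoad(3e7)   # fail, dilute 100x
qcParticleLoad <- function(totalConcentration, limit = 1e6) {
  .assertScalarNumeric(totalConcentration, "totalConcentration", min = 0)
  .assertScalarNumeric(limit, "limit", min = 0, strict = TRUE)
  pass <- totalConcentration <= limit
  dil <- if (pass) 1 else 10^ceiling(log10(totalConcentration / limit))
  list(pass = pass, recommendedDilution = dil,
       totalConcentration = totalConcentration, limit = limit)
}
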