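#' Per-timepoint viability, budding and particle-background series
#'
#' \code{viabilitySeries}: \code{100 * viable / (viable + dead)} per
#' timepoint. \code{sslFractionSeries}: percentage of medium (SSL)
#' particles in the total particle count,
#' \code{100 * background / (viable + dead + background)}.
#' \code{buddingSeries}: budding-to-single cell ratio, an indicator of
#' physiological budding activity. Timepoints with a zero denominator
#' are flagged missing (\code{NA}), never reported as zero.
#'
#' @param ts a \code{\link{ProcessTimeSeries-class}}.
#' @return data.frame with \code{time_h} and \code{value}.
#' @export
viabilitySeries <- function(ts) {
  s <- .samples(ts)
  denom <- s$viable_per_ml + s$dead_per_ml
  data.frame(time_h = s$time_h,
             value = ifelse(denom > 0, 100 * s$viable_per_ml / denom,
                            NA_real_))
}

#' @rdname viabilitySeries
#' @export
sslFractionSeries <- function(ts) {
  s <- .samples(ts)
  denom <- s$viable_per_ml + s$dead_per_ml + s$background_per_ml
  data.frame(time_h = s$time_h,
             value = ifelse(denom > 0, 100 * s$background_per_ml / denom,
                            NA_real_))
}

#' @rdname viabilitySeries
#' @export
buddingSeries <- function(ts) {
  s <- .samples(ts)
  if (!all(c("single_per_ml", "budding_per_ml") %in% names(s)))
    stop("time series has no single/budding morphology columns")
  data.frame(time_h = s$time_h,
             value = ifelse(s$single_per_ml > 0,
                            s$budding_per_ml / s$single_per_ml, NA_real_))
}

.samples <- function(ts) {
  stopifnot(is(ts, "ProcessTimeSeries"))
  ts@samples
}

#' Feed rate of a continuous cultivation
#'
#' \code{F = D * V * 1000} in mL/h; e.g. D = 0.02 1/h in a 1 L working
#' volume gives 20 mL/h, and D = 0.07 1/h gives 70 mL/h.
#'
#' @param D dilution rate in 1/h (>= 0).
#' @param workingVolume reactor working volume in liters (> 0).
#' @return Feed rate in mL/h.
#' @export
#' @examples
#' feedRate(0.07, 1)
feedRate <- function(D, workingVolume) {
  .assertScalarNumeric(D, "D", min = 0)
  .assertScalarNumeric(workingVolume, "workingVolume", min = 0, strict = TRUE)
  D * workingVolume * 1000
}

#' Chemostat washout and background wash-in dynamics
#'
#' \code{washoutCurve}: biomass growing at rate \code{mu} under dilution
#' \code{D} follows \eqn{X(t) = X_0 e^{(\mu - D) t}}; non-growing
#' components (\code{mu = 0}) wash out with half-life \eqn{\ln 2 / D}.
#' \code{backgroundWashin}: a passive feed component (e.g. SSL
#' particles) relaxes toward its feed concentration,
#' \eqn{C(t) = C_{feed} + (C_0 - C_{feed}) e^{-D t}}.
#'
#' @param X0 initial concentration.
#' @param D dilution rate (1/h).
#' @param mu specific growth rate (1/h).
#' @param t time in hours (vectorized, >= 0).
#' @return Concentration at \code{t}, same units as the input.
#' @export
#' @examples
#' washoutCurve(1e7, D = 0.02, mu = 0, t = log(2) / 0.02)  # one half-life
washoutCurve <- function(X0, D, mu = 0, t) {
  if (any(t < 0)) stop("t must be non-negative")
  X0 * exp((mu - D) * t)
}

#' @rdname washoutCurve
#' @param C0 initial background concentration.
#' @param CFeed background concentration of the feed medium.
#' @export
backgroundWashin <- function(C0, CFeed, D, t) {
  if (any(t < 0)) stop("t must be non-negative")
  CFeed + (C0 - CFeed) * exp(-D * t)
}

#' Specific ethanol productivity on a total or viable biomass basis
#'
#' The volumetric production rate of a continuously harvested solute is
#' \eqn{r(t) = D c(t) + dc/dt} (at steady state simply \eqn{D c});
#' \eqn{dc/dt} is taken by central finite differences (one-sided at the
#' boundaries). The specific rate divides by the biomass of the chosen
#' basis: total gravimetric dry weight, or viable-cell dry weight
#' reconstructed as viable count times a per-cell dry mass (default
#' 15 pg/cell, an order-of-magnitude literature value for budding
#' yeast). Comparing the two bases separates population-level from
#' per-viable-cell productivity: with constant titer and falling
#' viability, the viable-basis rate rises while the total-basis rate
#' does not. Normalized output is invariant to the per-cell mass.
#'
#' @param ts a \code{\link{ProcessTimeSeries-class}} with \code{etoh_g_l}
#'   and, depending on basis, \code{dw_g_l} or \code{viable_per_ml}.
#' @param basis \code{"total_dw"} or \code{"viable_dw"}.
#' @param cellDryMassPg per-cell dry mass in picograms (viable basis).
#' @param normalize divide the series by its maximum (the common way to
#'   plot relative productivity trends).
#'
#' @return data.frame with \code{time_h} and \code{q} (g ethanol per g
#'   biomass per hour; unitless if normalized). Timepoints without
#'   biomass are \code{NA}.
#' @export
specificProductivity <- function(ts, basis = c("total_dw", "viable_dw"),
                                 cellDryMassPg = 15, normalize = FALSE) {
  basis <- match.arg(basis)
  s <- .samples(ts)
  if (!"etoh_g_l" %in% names(s) || sum(is.finite(s$etoh_g_l)) < 2)
    stop("need ethanol concentrations at >= 2 timepoints")
  c_etoh <- s$etoh_g_l
  dcdt <- .finiteDiff(s$time_h, c_etoh)
  r <- ts@dilutionRate * c_etoh + dcdt
  X <- if (basis == "total_dw") {
    if (!"dw_g_l" %in% names(s)) stop("no dry weight column for total_dw basis")
    s$dw_g_l
  } else {
    # cells/mL * pg/cell -> g/L: 1e-12 g/pg * 1e3 mL/L = 1e-9
    s$viable_per_ml * cellDryMassPg * 1e-9
  }
  q <- ifelse(is.finite(X) & X > 0, r / X, NA_real_)
  if (normalize) {
    mx <- max(q, na.rm = TRUE)
    if (is.finite(mx) && mx > 0) q <- q / mx
  }
  data.frame(time_h = s$time_h, q = q)
}

# Central differences inside, one-sided at the boundaries.
.finiteDiff <- function(t, y) {
  n <- length(t)
  if (n < 2) return(rep(NA_real_, n))
  d <- numeric(n)
  d[1] <- (y[2] - y[1]) / (t[2] - t[1])
  d[n] <- (y[n] - y[n - 1]) / (t[n] - t[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    d[i] <- (y[i + 1] - y[i - 1]) / (t[i + 1] - t[i - 1])
  }
  d
}

#' Low-viability nutrient-pulse alerts
#'
#' Flags timepoints at which viability has stayed below a threshold for
#' at least a minimum duration, the trigger used to pulse essential
#' nutrients into the reactor. Each sustained excursion below the
#' threshold produces at most one alert, at the first timepoint where
#' the duration condition is met; brief dips shorter than
#' \code{minDurationH} produce none. Missing viability values end an
#' excursion.
#'
#' @param time_h sample times in hours (strictly increasing).
#' @param viability viable percentages (0-100, NA allowed).
#' @param threshold alert threshold in percent, in (0, 100).
#' @param minDurationH minimum below-threshold duration in hours.
#'
#' @return Numeric vector of alert times (possibly empty).
#' @export
#' @examples
#' nutrientPulseRule(0:20, c(rep(90, 8), rep(30, 13)), 50, 5)
nutrientPulseRule <- function(time_h, viability, threshold,
                              minDurationH = 0) {
  if (length(time_h) != length(viability))
    stop("time_h and viability must have equal length")
  if (is.unsorted(time_h, strictly = TRUE))
    stop("time_h must be strictly increasing")
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 100)
    stop("threshold must lie in (0, 100)")
  .assertScalarNumeric(minDurationH, "minDurationH", min = 0)
  below <- !is.na(viability) & viability < threshold
  alerts <- numeric(0)
  i <- 1; n <- length(below)
  while (i <= n) {
    if (below[i]) {
      j <- i
      while (j < n && below[j + 1]) j <- j + 1
      k <- which(time_h[i:j] - time_h[i] >= minDurationH)
      if (length(k)) alerts <- c(alerts, time_h[i + k[1] - 1])
      i <- j + 1
    } else i <- i + 1
  }
  alerts
}

#' Read / write a process monitoring CSV
#'
#' Plain CSV with the documented schema: \code{time_h},
#' \code{viable_per_ml}, \code{dead_per_ml}, \code{background_per_ml},
#' optional \code{single_per_ml}, \code{budding_per_ml}, \code{dw_g_l},
#' \code{etoh_g_l}, \code{sugar_g_l}, \code{phase}. Concentrations are
#' events/mL, times hours.
#'
#' @param path CSV file path.
#' @param workingVolume,dilutionRate,feedParticleConc reactor metadata
#'   attached to the returned object.
#' @return A \code{\link{ProcessTimeSeries-class}}.
#' @export
readProcessCsv <- function(path, workingVolume = 1, dilutionRate = 0,
                           feedParticleConc = NA_real_) {
  if (!file.exists(path)) stop(sprintf("process file not found: %s", path))
  s <- as.data.frame(data.table::fread(path))
  need <- c("time_h", "viable_per_ml", "dead_per_ml", "background_per_ml")
  missing <- setdiff(need, names(s))
  if (length(missing))
    stop(sprintf("process CSV %s is missing columns: %s", path,
                 paste(missing, collapse = ", ")))
  ProcessTimeSeries(s, workingVolume = workingVolume,
                    dilutionRate = dilutionRate,
                    feedParticleConc = feedParticleConc)
}

#' @rdname readProcessCsv
#' @param ts a \code{\link{ProcessTimeSeries-class}} to write.
#' @export
writeProcessCsv <- function(ts, path) {
  s <- .samples(ts)
  .atomicWrite(path, function(tmp) data.table::fwrite(s, tmp))
}
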