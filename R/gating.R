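#' Fit the three-population gate set from reference measurements
#'
#' Gates are fitted from pure-population reference measurements rather
#' than hard-coded: for each reference the central \code{quantile} mass
#' of events in (log10 green total, log10 red total) fluorescence space
#' (Mahalanobis-trimmed) is enclosed in its convex hull. Cell size and
#' shape windows span the pooled 0.5-99.5 % quantiles of the cell
#' references' FSC sample length and SSC total, so that medium particles
#' far outside the cell size range are rejected even when particle-dye
#' interaction produces spurious red fluorescence. Totals of zero or
#' less than 1 a.u. are floored to 1 before the log transform.
#'
#' If singlet and doublet morphology references are supplied, a straight
#' line discriminant between single and budding cells is fitted in
#' log-log (FSC length, SSC total) space as the equal-covariance linear
#' discriminant boundary between the two references; the log scale lets
#' the boundary cancel the shared particle-size factor of the two
#' features.
#'
#' @param pureViable,pureDead,mediumBlank
#'   \code{\link{EventFeatureTable-class}} reference measurements of the
#'   pure viable suspension, the pure dead suspension, and cell-free
#'   medium; each needs at least 100 events.
#' @param quantile central probability mass enclosed by each fluorescence
#'   hull (default 0.99).
#' @param singletRef,doubletRef optional feature tables of known single
#'   and budding (doublet) cells for the morphology boundary.
#' @param maxOverlap maximum tolerated cross-membership between the
#'   trimmed viable and dead reference clouds before fitting fails
#'   (default 0.01).
#' @param hullExpand factor by which each fluorescence hull is inflated
#'   about its centroid after fitting (default 1.3). The quantile trim
#'   makes the hull robust against stray reference events; the expansion
#'   then covers the population tails the trim removed, the way bench
#'   gates are drawn generously around a cluster. Cluster separation is
#'   checked on the trimmed clouds before expansion.
#' @param windowPad fractional padding added to each side of the size
#'   and shape windows (default 0.25 of the window span), for the same
#'   reason.
#'
#' @return A \code{\link{GateSet-class}}.
#' @export
#' @examples
#' v <- extractFeatures(simulatePopulation(populationSpec("viable"), 300, 1))
#' d <- extractFeatures(simulatePopulation(populationSpec("dead"), 300, 2))
#' b <- extractFeatures(simulatePopulation(populationSpec("ssl_particle"), 300, 3))
#' fitGates(v, d, b)
fitGates <- function(pureViable, pureDead, mediumBlank, quantile = 0.99,
                     singletRef = NULL, doubletRef = NULL,
                     maxOverlap = 0.01, hullExpand = 1.3,
                     windowPad = 0.25) {
  for (ref in list(pureViable, pureDead, mediumBlank)) {
    stopifnot(is(ref, "EventFeatureTable"))
    if (nEvents(ref) < 100)
      stop("each reference population needs at least 100 events")
  }
  if (!is.numeric(quantile) || quantile <= 0 || quantile > 1)
    stop("quantile must lie in (0, 1]")
  ptsV <- .fluorPoints(pureViable)
  ptsD <- .fluorPoints(pureDead)
  ptsB <- .fluorPoints(mediumBlank)
  keepV <- .centralMass(ptsV, quantile)
  keepD <- .centralMass(ptsD, quantile)
  overlap <- (sum(.inPolygon(ptsV[keepV, 1], ptsV[keepV, 2],
                             .hull(ptsD[keepD, , drop = FALSE]))) +
              sum(.inPolygon(ptsD[keepD, 1], ptsD[keepD, 2],
                             .hull(ptsV[keepV, , drop = FALSE])))) /
    (sum(keepV) + sum(keepD))
  if (overlap > maxOverlap)
    stop(sprintf(paste0("viable and dead reference populations overlap in ",
                        "fluorescence space (overlap fraction %.3f); ",
                        "check staining or references"), overlap))
  f <- rbind(featureTable(pureViable), featureTable(pureDead))
  pad <- function(w) w + windowPad * diff(w) * c(-1, 1)
  sizeWindow <- pmax(0, pad(as.numeric(
    quantile(f$FSC_length_um, c(0.005, 0.995)))))
  shapeWindow <- pmax(0, pad(as.numeric(
    quantile(f$SSC_total, c(0.005, 0.995)))))
  boundary <- if (!is.null(singletRef) && !is.null(doubletRef))
    .fitMorphologyLine(singletRef, doubletRef) else rep(NA_real_, 3)
  new("GateSet",
      viableGate = .expandPolygon(.hull(ptsV[keepV, , drop = FALSE]),
                                  hullExpand),
      deadGate = .expandPolygon(.hull(ptsD[keepD, , drop = FALSE]),
                                hullExpand),
      backgroundGate = .expandPolygon(
        .hull(ptsB[.centralMass(ptsB, quantile), , drop = FALSE]),
        hullExpand),
      sizeWindow = sizeWindow, shapeWindow = shapeWindow,
      morphologyBoundary = boundary, quantile = quantile)
}

.fluorPoints <- function(features) {
  f <- featureTable(features)
  cbind(.logFloor(f$FL_GREEN_total), .logFloor(f$FL_RED_total))
}

# Logical index of the central `q` mass by Mahalanobis distance.
.centralMass <- function(pts, q) {
  cv <- cov(pts)
  # guard against degenerate (collinear) reference clouds
  if (abs(det(cv)) < 1e-12) cv <- cv + diag(1e-6, 2)
  d2 <- mahalanobis(pts, colMeans(pts), cv)
  d2 <= as.numeric(quantile(d2, q))
}

.hull <- function(pts) {
  h <- chull(pts)
  m <- pts[h, , drop = FALSE]
  colnames(m) <- c("log10_green_total", "log10_red_total")
  m
}

.expandPolygon <- function(poly, factor) {
  ctr <- colMeans(poly)
  out <- sweep(sweep(poly, 2, ctr) * factor, 2, ctr, "+")
  colnames(out) <- colnames(poly)
  out
}

# Equal-prior LDA boundary in (log10 FSC length, log10 SSC total)
# space: a*log10(len) + b*log10(ssc) + c, positive scores call budding.
# Size and side scatter are log-normal with a shared particle-size
# factor; on the log-log scale that factor is a common additive term
# the linear discriminant can cancel, which makes the equal-error
# boundary a straight line there.
.fitMorphologyLine <- function(singletRef, doubletRef) {
  fs <- featureTable(singletRef)
  fd <- featureTable(doubletRef)
  x <- rbind(cbind(.logFloor(fs$FSC_length_um), .logFloor(fs$SSC_total)),
             cbind(.logFloor(fd$FSC_length_um), .logFloor(fd$SSC_total)))
  g <- factor(c(rep("single", nrow(fs)), rep("budding", nrow(fd))),
              levels = c("single", "budding"))
  fit <- MASS::lda(x, grouping = g, prior = c(0.5, 0.5))
  w <- as.numeric(fit$scaling[, 1])
  mid <- colMeans(fit$means)
  s <- c(w, -sum(w * mid))
  # orient so doublets score positive
  if (sum(s[1:2] * fit$means["budding", ]) + s[3] < 0) s <- -s
  s
}

#' Classify events into viable, dead, background and unclassified
#'
#' Decision order per event: (1) inside the viable fluorescence gate and
#' inside both cell size/shape windows, viable; (2) inside the dead gate
#' and inside the windows, dead (events falling in both fluorescence
#' gates are called dead, since PI positivity is the membrane-integrity
#' criterion); (3) inside the background gate or outside the windows,
#' background; otherwise unclassified. Events with saturated green
#' fluorescence that pass the size/shape windows and are not PI-positive
#' are kept viable (saturation reflects high esterase activity of
#' strongly stained cells, typically budding agglomerates) and are
#' reported in the \code{saturationFraction} flag.
#'
#' @param features an \code{\link{EventFeatureTable-class}}.
#' @param gates a \code{\link{GateSet-class}}.
#' @param analyzedVolumeUl analyzed sample volume in microliters; when
#'   given, per-class concentrations are reported.
#' @param dilutionFactor total sample dilution applied before
#'   measurement (>= 1; e.g. 1000 for the standard 1:10 staining step
#'   followed by 1:100 measurement dilution).
#' @param overload logical flag propagated from acquisition QC.
#'
#' @return A \code{\link{ClassificationResult-class}}.
#' @export
classifyEvents <- function(features, gates, analyzedVolumeUl = NULL,
                           dilutionFactor = 1, overload = FALSE) {
  stopifnot(is(features, "EventFeatureTable"), is(gates, "GateSet"))
  f <- featureTable(features)
  g <- .logFloor(f$FL_GREEN_total)
  r <- .logFloor(f$FL_RED_total)
  inWin <- f$FSC_length_um >= gates@sizeWindow[1] &
    f$FSC_length_um <= gates@sizeWindow[2] &
    f$SSC_total >= gates@shapeWindow[1] &
    f$SSC_total <= gates@shapeWindow[2]
  inV <- .inPolygon(g, r, gates@viableGate)
  inD <- .inPolygon(g, r, gates@deadGate)
  inB <- .inPolygon(g, r, gates@backgroundGate)
  satG <- f$FL_GREEN_saturated

  lab <- rep("unclassified", nrow(f))
  lab[inB | !inWin] <- "background"
  lab[inV & inWin] <- "viable"
  lab[inD & inWin] <- "dead"              # doubly stained events go dead
  lab[satG & inWin & !inD] <- "viable"    # green saturation = strong FDA signal
  counts <- setNames(integer(4), .POPULATION_LABELS)
  tab <- table(factor(lab, levels = .POPULATION_LABELS))
  counts[names(tab)] <- as.integer(tab)

  nv <- counts[["viable"]]; nd <- counts[["dead"]]
  viability <- if (nv + nd > 0) 100 * nv / (nv + nd) else NA_real_
  conc <- if (!is.null(analyzedVolumeUl))
    vapply(counts, countsToConcentration, numeric(1),
           analyzedVolumeUl = analyzedVolumeUl,
           dilutionFactor = dilutionFactor)
  else setNames(rep(NA_real_, 4), names(counts))
  satFrac <- if (nv > 0) sum(satG[lab == "viable"]) / nv else 0
  new("ClassificationResult", counts = counts, concentrations = conc,
      viabilityPercent = viability,
      flags = list(overload = overload, saturationFraction = satFrac),
      eventLabels = lab)
}

#' Split viable events into single and budding cells
#'
#' Applies the straight-line morphology discriminant of the gate set in
#' log-log (FSC sample length, SSC total) space: events on the
#' high-scatter / long-pulse side are called budding. Intended to run on
#' events already classified viable.
#'
#' @param viableFeatures an \code{\link{EventFeatureTable-class}} holding
#'   viable events only.
#' @param gates a \code{\link{GateSet-class}} with a fitted morphology
#'   boundary.
#'
#' @return List with counts \code{single} and \code{budding}, the
#'   \code{buddingRatio} (budding/single; \code{Inf} with
#'   \code{infiniteRatio = TRUE} when no singles were seen), and the
#'   per-event \code{morphology} vector.
#' @export
classifyMorphology <- function(viableFeatures, gates) {
  stopifnot(is(viableFeatures, "EventFeatureTable"), is(gates, "GateSet"))
  b <- gates@morphologyBoundary
  if (!all(is.finite(b)))
    stop("gate set has no fitted morphology boundary; fit gates with ",
         "singletRef/doubletRef references")
  f <- featureTable(viableFeatures)
  score <- b[1] * .logFloor(f$FSC_length_um) +
    b[2] * .logFloor(f$SSC_total) + b[3]
  morph <- ifelse(score > 0, "budding", "single")
  nb <- sum(morph == "budding"); ns <- sum(morph == "single")
  list(single = ns, budding = nb,
       buddingRatio = if (ns > 0) nb / ns else Inf,
       infiniteRatio = ns == 0, morphology = morph)
}

#' Convert an event count to a concentration
#'
#' \code{concentration = count / analyzedVolumeUl * 1000 *
#' dilutionFactor} in events/mL.
#'
#' @param count number of events observed.
#' @param analyzedVolumeUl analyzed volume in microliters (> 0).
#' @param dilutionFactor total pre-measurement dilution (>= 1).
#'
#' @return Concentration in events/mL.
#' @export
#' @examples
#' countsToConcentration(500, 100)         # 5000 events/mL
#' countsToConcentration(500, 100, 1000)   # 5e6 events/mL in the sample
countsToConcentration <- function(count, analyzedVolumeUl,
                                  dilutionFactor = 1) {
  .assertScalarNumeric(count, "count", min = 0)
  .assertScalarNumeric(analyzedVolumeUl, "analyzedVolumeUl", min = 0,
                       strict = TRUE)
  .assertScalarNumeric(dilutionFactor, "dilutionFactor", min = 1)
  count / analyzedVolumeUl * 1000 * dilutionFactor
}

#' Serialize / restore a gate set
#'
#' Gates round-trip exactly through JSON so that a classification run is
#' reproducible from its serialized gate file.
#'
#' @param gates a \code{\link{GateSet-class}}.
#' @param path output (input) JSON file path.
#' @return \code{writeGates} the path, invisibly; \code{readGates} a
#'   \code{GateSet}.
#' @export
writeGates <- function(gates, path) {
  stopifnot(is(gates, "GateSet"))
  payload <- list(
    format = "cytogate-gates-v1",
    viableGate = unname(gates@viableGate),
    deadGate = unname(gates@deadGate),
    backgroundGate = unname(gates@backgroundGate),
    sizeWindow = gates@sizeWindow, shapeWindow = gates@shapeWindow,
    morphologyBoundary = gates@morphologyBoundary,
    quantile = gates@quantile)
  .atomicWrite(path, function(tmp)
    jsonlite::write_json(payload, tmp, digits = NA, auto_unbox = TRUE))
}

#' @rdname writeGates
#' @export
readGates <- function(path) {
  if (!file.exists(path)) stop(sprintf("gate file not found: %s", path))
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "cytogate-gates-v1"))
    stop(sprintf("%s is not a cytogate gate file", path))
  poly <- function(m) {
    m <- as.matrix(m)
    colnames(m) <- c("log10_green_total", "log10_red_total")
    m
  }
  new("GateSet", viableGate = poly(p$viableGate),
      deadGate = poly(p$deadGate), backgroundGate = poly(p$backgroundGate),
      sizeWindow = as.numeric(p$sizeWindow),
      shapeWindow = as.numeric(p$shapeWindow),
      morphologyBoundary = as.numeric(p$morphologyBoundary),
      quantile = as.numeric(p$quantile))
}
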