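# Minimal FCS 3.1 listmode writer/reader for derived feature tables.
# FCS has no standard representation for full pulse traces, so export is
# feature-level: one float parameter per channel x feature, plus integer
# code parameters for the population and morphology labels. Data are
# single-precision floats ($DATATYPE F, $MODE L), little-endian.

.FCS_DELIM <- "/"
.LABEL_CODES <- c(unclassified = 0, viable = 1, dead = 2, background = 3)
.MORPH_CODES <- c("n/a" = 0, single = 1, budding = 2)

.fcsParamNames <- function() {
  per <- unlist(lapply(cytoChannels(), function(ch)
    paste0(ch, c("_total", "_max", "_length_um", "_saturated"))))
  c("event_id", per, "label_code", "morph_code")
}

#' Write / read an FCS 3.1 listmode file of event features
#'
#' \code{writeFcsListmode} stores an
#' \code{\link{EventFeatureTable-class}} as an FCS 3.1 file with named
#' parameters (\code{$PnN}) \code{event_id}, \code{<CH>_total},
#' \code{<CH>_max}, \code{<CH>_length_um}, \code{<CH>_saturated} (0/1)
#' per canonical channel, and integer-coded \code{label_code} /
#' \code{morph_code} parameters (0 = unclassified/none, 1 = viable /
#' single, 2 = dead/budding, 3 = background). Acquisition metadata
#' travel in the custom keywords \code{CYTOGATESPACING} and
#' \code{CYTOGATEADCMAX}. Values are float32, so round-trips are exact
#' to single precision. \code{readFcsListmode} accepts only FCS 3.1
#' files in this layout and rejects other versions.
#'
#' @param features a non-empty \code{EventFeatureTable}.
#' @param path FCS file path.
#' @return \code{writeFcsListmode}: the path, invisibly;
#'   \code{readFcsListmode}: an \code{EventFeatureTable}.
#' @export
writeFcsListmode <- function(features, path) {
  stopifnot(is(features, "EventFeatureTable"))
  if (nEvents(features) == 0)
    stop("refusing to write an empty feature table to FCS")
  f <- featureTable(features)
  pn <- .fcsParamNames()
  mat <- cbind(f$event_id,
               as.matrix(f[, setdiff(pn, c("event_id", "label_code",
                                           "morph_code"))]) * 1,
               .LABEL_CODES[f$label], .MORPH_CODES[f$morphology])
  storage.mode(mat) <- "double"
  ntot <- nrow(mat); npar <- ncol(mat)
  d <- .FCS_DELIM
  kw <- c("$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
          "$BEGINSTEXT", "0", "$ENDSTEXT", "0",
          "$BEGINDATA", "%BD%", "$ENDDATA", "%ED%",
          "$BYTEORD", "1,2,3,4", "$DATATYPE", "F", "$MODE", "L",
          "$NEXTDATA", "0", "$PAR", as.character(npar),
          "$TOT", as.character(ntot),
          "CYTOGATESPACING", sprintf("%.10g", features@sampleSpacing),
          "CYTOGATEADCMAX", sprintf("%.10g", features@adcMax))
  for (i in seq_len(npar)) {
    rng <- max(1, ceiling(max(mat[, i], na.rm = TRUE) + 1))
    kw <- c(kw, sprintf("$P%dN", i), pn[i],
            sprintf("$P%dB", i), "32",
            sprintf("$P%dE", i), "0,0",
            sprintf("$P%dR", i), sprintf("%d", rng))
  }
  text <- paste0(d, paste(kw, collapse = d), d)
  # fixed-width (10-digit) offsets so TEXT length is known before filling
  textStart <- 58L
  textLen <- nchar(text) - nchar("%BD%") - nchar("%ED%") + 20L
  textEnd <- textStart + textLen - 1L
  dataStart <- textEnd + 1L
  dataEnd <- dataStart + 4L * npar * ntot - 1L
  text <- sub("%BD%", sprintf("%010d", dataStart),
              sub("%ED%", sprintf("%010d", dataEnd), text, fixed = TRUE),
              fixed = TRUE)
  hdr <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d", textStart, textEnd,
                 if (dataEnd <= 99999999) dataStart else 0,
                 if (dataEnd <= 99999999) dataEnd else 0, 0, 0)
  .atomicWrite(path, function(tmp) {
    con <- file(tmp, "wb")
    on.exit(close(con))
    writeChar(hdr, con, eos = NULL)
    writeChar(text, con, eos = NULL)
    writeBin(as.vector(t(mat)), con, size = 4, endian = "little")
  })
  invisible(path)
}

#' @rdname writeFcsListmode
#' @export
readFcsListmode <- function(path) {
  if (!file.exists(path)) stop(sprintf("FCS file not found: %s", path))
  raw <- readBin(path, "raw", n = file.size(path))
  version <- rawToChar(raw[1:6])
  if (version != "FCS3.1")
    stop(sprintf("unsupported FCS version '%s' in %s (only FCS3.1 is read)",
                 version, path))
  off <- function(a, b) as.integer(trimws(rawToChar(raw[a:b])))
  # FCS offsets are 0-based byte positions; R indexing is 1-based
  textStart <- off(11, 18); textEnd <- off(19, 26)
  text <- rawToChar(raw[(textStart + 1):(textEnd + 1)])
  d <- substr(text, 1, 1)
  parts <- strsplit(substr(text, 2, nchar(text)), d, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  kw <- setNames(parts[seq(2, length(parts), 2)],
                 parts[seq(1, length(parts), 2)])
  if (!identical(kw[["$DATATYPE"]], "F") || !identical(kw[["$MODE"]], "L"))
    stop(sprintf("%s: only list-mode float FCS data are supported", path))
  endian <- if (identical(kw[["$BYTEORD"]], "4,3,2,1")) "big" else "little"
  npar <- as.integer(kw[["$PAR"]]); ntot <- as.integer(kw[["$TOT"]])
  dataStart <- as.integer(kw[["$BEGINDATA"]])
  vals <- readBin(raw[(dataStart + 1):length(raw)], "double", n = npar * ntot,
                  size = 4, endian = endian)
  mat <- matrix(vals, nrow = ntot, ncol = npar, byrow = TRUE)
  colnames(mat) <- vapply(seq_len(npar), function(i) kw[[sprintf("$P%dN", i)]],
                          character(1))
  need <- .fcsParamNames()
  if (!all(need %in% colnames(mat)))
    stop(sprintf("%s does not carry the cytogate feature parameter set", path))
  f <- as.data.frame(mat[, need, drop = FALSE])
  out <- data.frame(event_id = as.integer(round(f$event_id)))
  for (ch in cytoChannels()) {
    out[[paste0(ch, "_total")]] <- f[[paste0(ch, "_total")]]
    out[[paste0(ch, "_max")]] <- f[[paste0(ch, "_max")]]
    out[[paste0(ch, "_length_um")]] <- f[[paste0(ch, "_length_um")]]
    out[[paste0(ch, "_saturated")]] <- f[[paste0(ch, "_saturated")]] > 0.5
  }
  out$label <- names(.LABEL_CODES)[match(round(f$label_code), .LABEL_CODES)]
  out$morphology <- names(.MORPH_CODES)[match(round(f$morph_code),
                                              .MORPH_CODES)]
  spacing <- as.numeric(kw[["CYTOGATESPACING"]])
  adc <- as.numeric(kw[["CYTOGATEADCMAX"]])
  EventFeatureTable(out,
                    sampleSpacing = if (is.finite(spacing)) spacing else 0.5,
                    adcMax = if (is.finite(adc)) adc else
                      max(4095, max(out$FL_GREEN_max)))
}
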