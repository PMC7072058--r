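#' Read and write the pulse-trace CSV dialect
#'
#' Plain-text interchange format for full pulse traces (documented
#' stand-in for instrument-native profile exports). A header block of
#' \code{#}-prefixed \code{key=value} lines carries the acquisition
#' metadata, followed by a long-format table:
#' \preformatted{
#' # cytogate-pulse-csv v1
#' # sample_spacing_um=0.5
#' # adc_max=4095
#' event_id,channel,sample_index,value
#' 1,FSC,1,0
#' ...
#' }
#' Every event must carry all four canonical channels with equal sample
#' counts per channel; within a file, events with shorter traces are
#' right-padded with zeros to the longest trace on read (a trace window
#' with no signal), which leaves derived features unchanged. Malformed
#' input is rejected, never coerced: a missing channel names the event,
#' a non-numeric value names the data line.
#'
#' @param path CSV file path.
#' @return \code{readPulseCsv}: a \code{\link{PulseEventSet-class}};
#'   \code{writePulseCsv}: the path, invisibly.
#' @export
readPulseCsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("pulse CSV not found: %s", path))
  con <- file(path, "r")
  header <- character(0)
  repeat {
    line <- readLines(con, n = 1)
    if (!length(line) || !startsWith(line, "#")) break
    header <- c(header, line)
  }
  close(con)
  meta <- .parsePulseHeader(header, path)
  nskip <- length(header)
  dt <- data.table::fread(path, skip = nskip, header = TRUE,
                          colClasses = list(character = "value"))
  need <- c("event_id", "channel", "sample_index", "value")
  if (!all(need %in% names(dt)))
    stop(sprintf("pulse CSV %s lacks required columns %s", path,
                 paste(setdiff(need, names(dt)), collapse = ", ")))
  val <- suppressWarnings(as.numeric(dt$value))
  bad <- which(!is.finite(val))
  if (length(bad))
    stop(sprintf("non-numeric value in %s at data line %d ('%s')", path,
                 bad[1], dt$value[bad[1]]))
  dt$value <- val
  ids <- sort(unique(dt$event_id))
  chans <- cytoChannels()
  have <- unique(dt[, c("event_id", "channel")])
  counts <- table(factor(have$channel, levels = chans), have$event_id)
  missing <- which(counts == 0, arr.ind = TRUE)
  if (nrow(missing))
    stop(sprintf("event %s is missing channel %s in %s",
                 colnames(counts)[missing[1, 2]],
                 rownames(counts)[missing[1, 1]], path))
  ns <- max(dt$sample_index)
  traces <- setNames(lapply(chans, function(ch) {
    sub <- dt[dt$channel == ch, ]
    m <- matrix(0, length(ids), ns)
    m[cbind(match(sub$event_id, ids), sub$sample_index)] <- sub$value
    m
  }), chans)
  PulseEventSet(traces, eventId = ids,
                sampleSpacing = meta$sample_spacing_um,
                adcMax = meta$adc_max)
}

.parsePulseHeader <- function(header, path) {
  if (!length(header) || !grepl("cytogate-pulse-csv", header[1]))
    stop(sprintf("%s is not a cytogate pulse CSV (missing header block)",
                 path))
  kv <- header[grepl("=", header)]
  keys <- sub("^#\\s*([^=]+)=.*$", "\\1", kv)
  vals <- sub("^#[^=]+=(.*)$", "\\1", kv)
  meta <- setNames(as.list(suppressWarnings(as.numeric(vals))), trimws(keys))
  for (k in c("sample_spacing_um", "adc_max"))
    if (is.null(meta[[k]]) || !is.finite(meta[[k]]))
      stop(sprintf("pulse CSV %s header lacks a numeric '%s'", path, k))
  meta
}

#' @rdname readPulseCsv
#' @param events a \code{\link{PulseEventSet-class}} to write.
#' @param labelPath optional path for a ground-truth sidecar CSV
#'   (\code{event_id,label,morphology}); written only when the events
#'   carry annotation.
#' @export
writePulseCsv <- function(events, path, labelPath = NULL) {
  stopifnot(is(events, "PulseEventSet"))
  ns <- ncol(events@traces[[1]])
  long <- data.table::rbindlist(lapply(cytoChannels(), function(ch) {
    m <- events@traces[[ch]]
    data.table::data.table(
      event_id = rep(events@eventId, times = ns),
      channel = ch,
      sample_index = rep(seq_len(ns), each = nrow(m)),
      value = as.vector(m))
  }))
  data.table::setorder(long, event_id, channel, sample_index)
  .atomicWrite(path, function(tmp) {
    writeLines(c("# cytogate-pulse-csv v1",
                 sprintf("# sample_spacing_um=%.10g", events@sampleSpacing),
                 sprintf("# adc_max=%.10g", events@adcMax)), tmp)
    data.table::fwrite(long, tmp, append = TRUE, col.names = TRUE)
  })
  if (!is.null(labelPath) && nrow(events@eventData)) {
    side <- cbind(data.frame(event_id = events@eventId), events@eventData)
    .atomicWrite(labelPath, function(tmp) data.table::fwrite(side, tmp))
  }
  invisible(path)
}
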