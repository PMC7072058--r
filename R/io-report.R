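#' Write a result report to JSON or CSV
#'
#' Lossless, stably named serialization of classification, calibration
#' and monitoring outputs. JSON keeps the nested structure; CSV flattens
#' it to \code{key,value} rows (nested names joined with \code{.}).
#' Writes are atomic (temp file + rename), so a failed run never leaves
#' a partial report.
#'
#' Field names: classification reports carry \code{counts.*},
#' \code{concentrations.*}, \code{viability_percent}, \code{flags.*};
#' accuracy reports \code{mean}, \code{sd}, \code{deviation},
#' \code{expected}, \code{tolerance}, \code{pass}; data.frames are
#' written as CSV tables directly (or JSON arrays).
#'
#' @param result a \code{\link{ClassificationResult-class}}, an
#'   \code{\link{ExpectedRatioResult-class}}, a list (e.g. from
#'   \code{\link{evaluateAccuracy}} or \code{\link{qcParticleLoad}}), or
#'   a data.frame.
#' @param path output file path.
#' @param format \code{"JSON"} or \code{"CSV"} (case-insensitive).
#' @return The path, invisibly.
#' @export
writeReport <- function(result, path, format = c("JSON", "CSV")) {
  if (is.character(format) && length(format) == 1)
    format <- toupper(format)
  format <- tryCatch(match.arg(format), error = function(e)
    stop(sprintf("unknown report format '%s' (use JSON or CSV)",
                 paste(format, collapse = "/"))))
  payload <- .reportFields(result)
  if (format == "JSON") {
    .atomicWrite(path, function(tmp)
      jsonlite::write_json(payload, tmp, digits = NA, auto_unbox = TRUE,
                           dataframe = "rows"))
  } else {
    .atomicWrite(path, function(tmp) {
      if (is.data.frame(payload)) data.table::fwrite(payload, tmp)
      else {
        flat <- .flatten(payload)
        data.table::fwrite(data.frame(
          key = names(flat),
          value = vapply(flat, function(v) as.character(v)[1],
                         character(1)),
          check.names = FALSE, row.names = NULL), tmp)
      }
    })
  }
  invisible(path)
}

#' Read back a JSON report
#'
#' @param path a JSON report written by \code{\link{writeReport}}.
#' @return The deserialized list / data.frame.
#' @export
readReport <- function(path) {
  if (!file.exists(path)) stop(sprintf("report not found: %s", path))
  jsonlite::read_json(path, simplifyVector = TRUE)
}

.reportFields <- function(result) {
  if (is(result, "ClassificationResult")) {
    list(type = "classification",
         counts = as.list(classCounts(result)),
         concentrations_per_ml = as.list(concentrations(result)),
         viability_percent = viabilityPercent(result),
         flags = qcFlags(result))
  } else if (is(result, "ExpectedRatioResult")) {
    list(type = "expected_ratio",
         n_exp_viable = result@nExpViable, n_exp_dead = result@nExpDead,
         ratio_viable = result@ratioViable, ratio_dead = result@ratioDead,
         reported = as.list(reportedRatio(result)))
  } else if (is.data.frame(result) || is.list(result)) {
    result
  } else stop("unsupported result type for writeReport")
}

.flatten <- function(x, prefix = "") {
  out <- list()
  for (nm in names(x)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    v <- x[[nm]]
    if (is.list(v) && !is.data.frame(v)) out <- c(out, .flatten(v, key))
    else out[[key]] <- v
  }
  out
}
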