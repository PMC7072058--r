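# Internal helpers shared across modules.

# log10 with a floor of 1 a.u. so that zero totals map to 0 rather than -Inf
.logFloor <- function(x) log10(pmax(x, 1))

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
      stop("seed must be a single finite number")
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a stream of reproducible sub-seeds below 2^31 from a master seed.
.subSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483629)
}

# Point-in-polygon membership (boundary counts as inside).
.inPolygon <- function(x, y, poly) {
  if (length(x) == 0) return(logical(0))
  pracma::inpolygon(x, y, poly[, 1], poly[, 2], boundary = TRUE)
}

# Fraction of each polygon's vertices lying inside the other.
.polygonOverlapFraction <- function(a, b) {
  na <- sum(.inPolygon(a[, 1], a[, 2], b))
  nb <- sum(.inPolygon(b[, 1], b[, 2], a))
  (na + nb) / (nrow(a) + nrow(b))
}

# Conservative polygon intersection test: vertex containment either way or
# any pair of crossing edges.
.polygonsIntersect <- function(a, b) {
  if (any(.inPolygon(a[, 1], a[, 2], b))) return(TRUE)
  if (any(.inPolygon(b[, 1], b[, 2], a))) return(TRUE)
  segs <- function(p) cbind(p, p[c(2:nrow(p), 1), , drop = FALSE])
  sa <- segs(a); sb <- segs(b)
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(nrow(sa))) {
    d1 <- cross(sa[i, 1], sa[i, 2], sa[i, 3], sa[i, 4], sb[, 1], sb[, 2])
    d2 <- cross(sa[i, 1], sa[i, 2], sa[i, 3], sa[i, 4], sb[, 3], sb[, 4])
    d3 <- cross(sb[, 1], sb[, 2], sb[, 3], sb[, 4], sa[i, 1], sa[i, 2])
    d4 <- cross(sb[, 1], sb[, 2], sb[, 3], sb[, 4], sa[i, 3], sa[i, 4])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  }
  FALSE
}

# Write text/JSON/CSV atomically: to a temp file in the same directory,
# then rename into place, so failures never leave partial output.
.atomicWrite <- function(path, writer) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(tmpdir = dir, fileext = paste0(".", basename(path)))
  ok <- FALSE
  on.exit(if (!ok && file.exists(tmp)) unlink(tmp))
  writer(tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  ok <- TRUE
  invisible(path)
}

.assertScalarNumeric <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    stop(sprintf("%s must be a single finite number", name))
  if (strict && x <= min) stop(sprintf("%s must be > %g", name, min))
  if (!strict && x < min) stop(sprintf("%s must be >= %g", name, min))
  invisible(x)
}
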