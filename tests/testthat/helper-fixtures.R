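# Fixture builders used across the test files. All fixtures are built in
# code; nothing is stored on disk.

# Event set where every channel carries the same given traces.
rectEventSet <- function(traces, sampleSpacing = 1, adcMax = 4095) {
  if (!is.matrix(traces)) traces <- matrix(traces, nrow = 1)
  PulseEventSet(setNames(rep(list(traces), 4), cytoChannels()),
                sampleSpacing = sampleSpacing, adcMax = adcMax)
}

# Event set with per-channel trace matrices given explicitly.
channelEventSet <- function(..., sampleSpacing = 1, adcMax = 4095) {
  tr <- list(...)
  stopifnot(setequal(names(tr), cytoChannels()))
  PulseEventSet(tr[cytoChannels()], sampleSpacing = sampleSpacing,
                adcMax = adcMax)
}

# Random non-negative traces for property tests.
randomTraceSet <- function(n, nSamples = 24, seed = 1, adcMax = 4095) {
  set.seed(seed)
  m <- matrix(runif(n * nSamples, 0, adcMax * 0.9), n, nSamples)
  rectEventSet(m, adcMax = adcMax)
}

# Brute-force per-event feature computation, independent of the
# vectorized implementation: plain loops over samples.
bruteForceFeatures <- function(events, baseline = 0, threshold = 10) {
  out <- list()
  for (ch in cytoChannels()) {
    m <- events@traces[[ch]]
    tot <- mx <- len <- numeric(nrow(m))
    for (i in seq_len(nrow(m))) {
      s <- 0; mxi <- 0; li <- 0
      for (j in seq_len(ncol(m))) {
        v <- m[i, j]
        if (v - baseline > 0) s <- s + (v - baseline)
        if (v > mxi) mxi <- v
        if (v > threshold) li <- li + 1
      }
      tot[i] <- s; mx[i] <- mxi; len[i] <- li * events@sampleSpacing
    }
    out[[ch]] <- data.frame(total = tot, max = mx, length = len)
  }
  out
}

# Default gates fitted once per session on a fixed seed (reused by
# several test files to keep runtime down).
sharedGates <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- referenceGates(seed = 424242, nRef = 4000)
    cache
  }
})
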