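---
title: "Methods: viability gating and monitoring in particle-rich media"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: viability gating and monitoring in particle-rich media}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytogate)
```

# Scope and model

cytogate quantifies viable cells, dead cells and solid medium particles
in flow-cytometry measurements of yeast suspended in complex,
particle-rich media such as spent sulfite liquor (SSL). The workflow
assumes dual viability staining: fluorescein diacetate (FDA), whose
hydrolysis by esterases marks metabolically active cells green, and
propidium iodide (PI), which enters membrane-compromised cells and
marks them red. Three populations are expected: green⁺/red⁻ viable
cells, red⁺/green⁻ dead cells, and medium particles with little green
but occasionally partial red fluorescence from dye adsorption.

## Pulse features

Pulse-shape instruments record the full signal trace per particle and
channel. Each trace is reduced to:

* **total** — sum of samples above the baseline (default baseline
  0 a.u.; instruments usually subtract it upstream);
* **maximum** — largest sample;
* **sample length** — number of samples above a threshold (default
  10 a.u., just above the noise floor) times the sample spacing
  (default 0.5 µm/sample; the true value depends on flow speed and
  sampling rate and is configurable). Length counts *all*
  above-threshold samples rather than the longest run: for the
  unimodal or two-lobed pulses of cells this equals the pulse extent,
  and it keeps the feature monotone under pointwise signal increase.
* **saturation** — at least 2 consecutive samples at the ADC ceiling
  (a run of 2 ignores isolated single-sample spikes).

## Gating

Gates are *fitted from reference measurements*, not hard-coded, because
detector settings shift between processes. From a pure viable run, a
pure dead run and a cell-free medium blank (each ≥ 100 events):

1. Events are mapped to (log₁₀ green total, log₁₀ red total); totals
   are floored at 1 a.u. before the log to avoid log of zero.
2. Each reference is trimmed to its central 99 % mass by Mahalanobis
   distance and enclosed in its convex hull. Trimming makes the hull
   robust to stray events; the hull is then inflated by a factor 1.3
   about its centroid to cover the tails the trim removed, the way
   bench gates are drawn generously around a cluster. If the trimmed
   viable and dead clouds overlap by more than 1 %, fitting aborts and
   reports the overlap fraction (this catches mislabeled or unstained
   references).
3. Cell size and shape windows span the pooled 0.5–99.5 % quantiles of
   the cell references' FSC length and SSC total, padded by 25 % of the
   span per side. The windows reject medium particles far outside the
   cell size range even when PI adsorption gives them red fluorescence.

Classification order per event: viable gate ∧ windows → viable; dead
gate ∧ windows → dead; background gate ∨ outside windows → background;
otherwise unclassified. Two tie-breaks are deliberate: an event inside
*both* fluorescence gates is called dead, because PI positivity is the
membrane-integrity criterion and residual esterase activity does not
imply an intact cell; and an event with *saturated* green fluorescence
that passes the windows and is not PI-positive stays viable — green
saturation reflects very high esterase signal (typically budding
agglomerates), not an invalid event. The saturated fraction is reported
as a QC flag because saturation marks a loss of quantitative signal
that detector settings should eventually fix.

The expansion and padding constants are design parameters of the fit,
chosen once so that a pure reference population re-classifies to ≥ 99 %
into its own gate (the self-consistency the gate is meant to have)
while keeping the viable and dead gates disjoint and the windows tight
enough to exclude off-scale particles; all are arguments of
`fitGates()`.

## Morphology

Budding cells pass the flow cell as mother–daughter doublets: longer
pulses and higher total side scatter. The boundary between single and
budding cells is a straight line fitted as the equal-prior linear
discriminant between simulated singlet and doublet references in
log–log (FSC length, SSC total) space. The log scale is deliberate:
both features share the particle-size factor, which becomes an additive
term on the log scale that the discriminant can cancel, so the
equal-error boundary is genuinely linear there. With the default
populations the residual misclassification is about 3 % per class,
which biases a recovered budding fraction of 0.30 by well under 0.02.

## Mixture calibration

For defined volumetric mixtures of a viable and a dead suspension the
expected counts are the volume-weighted sums of the pure-suspension
counts, and the expected viable ratio is their normalized share (see
the README for the formulas). Cross-staining counts default to zero —
measured endpoint mixtures (100/0 and 0/100) come out at 100 %/0 %, so
cross-staining is negligible, but both terms remain parameters.

Dead reference suspensions prepared by harsh (microwave) killing lose
countable events to partial cell disintegration. Under zero
cross-staining this leaves one free parameter, the dead:viable
event-yield factor *r* in Ratio_V(P) = 100·P/(P + r(100 − P)).
`fitYieldFactor()` estimates *r* by least squares over non-endpoint
design points (bounded optimization on (0, 1]; endpoints carry no
information about *r*). Yield factors of 0.51 and 0.96 reproduce, after
integer rounding, published expected-ratio rows for buffer and filtered
SSL backgrounds, and r = 1 the unfiltered row equal to the volumetric
ratios; these three values are the media presets of the simulator. One
published buffer row (93/84/77/70/46) is *not* reproducible by any
single-r zero-cross-staining model (a grid search leaves 1 integer
point of error at two entries), so the model is not forced onto it —
with unknown raw pure counts the discrepancy is unresolvable and is
simply a documented limit of the single-parameter model.

Ratios are kept in double precision internally and rounded to integer
percent only at the reporting layer. Accuracy of measured against
expected viability is summarized per design point as mean ± SD over
technical replicates with a default tolerance of 10 percentage points
on both.

## Particle-load QC

Above roughly 10⁶ particles·mL⁻¹ the acquisition software throttles
data intake and measured ratios become biased, so samples must be
checked in a preliminary count. `qcParticleLoad()` passes
concentrations at or below the limit (≤ semantics, boundary inclusive)
and otherwise recommends the smallest power-of-ten dilution reaching
it, matching serial-dilution bench practice (1:10 at staining, 1:100 at
measurement).

## Monitoring

Per-timepoint series are simple ratios — viability
100·viable/(viable+dead), SSL fraction
100·background/(viable+dead+background), budding ratio
budding/single — with zero denominators reported as missing, never as
zero. Continuous-culture dynamics use the standard chemostat forms:
feed rate F = D·V·1000 (mL/h), washout X(t) = X₀e^{(µ−D)t}, background
wash-in C(t) = C_feed + (C₀ − C_feed)e^{−Dt}.

Specific ethanol productivity divides the volumetric rate
r(t) = D·c(t) + dc/dt (central finite differences, one-sided at the
boundaries; at steady state simply D·c) by the biomass of the chosen
basis. The viable basis reconstructs viable dry weight as viable count
× per-cell dry mass, default 15 pg/cell — an order-of-magnitude
literature value for budding yeast, configurable, and irrelevant to
normalized output, which divides the series by its maximum. Comparing
the two bases separates population productivity from per-viable-cell
productivity: with constant titer and falling viability the
viable-basis rate rises while the total-basis rate does not. The
retentostat ethanol balance assumes full cell retention with free
solute passage. The nutrient-pulse rule alerts when viability stays
below a threshold for a minimum duration, once per sustained excursion,
at the first timepoint meeting the duration.

# The simulator: what it emulates and what it does not

`simulatePopulation()` draws log-normal pulse widths and per-channel
amplitudes and renders Gaussian-profile traces with truncated-Gaussian
detector noise (σ = 2 a.u.), clipped at a 12-bit ADC ceiling
(4095 a.u.) so that strong signals genuinely saturate. Scatter
amplitudes scale with relative particle size; SSL particles draw from
broad distributions (σ_log = 0.8) overlapping and exceeding the cells,
carry no green fluorescence, and with probability 0.3 a low-level
heavy-tailed red amplitude (PI–particle interaction). Budding doublets
are two overlapping lobes (offset 5σ, second lobe 0.95×) with elevated
side scatter and green fluorescence — bright enough to saturate
occasionally. The populations separate in fluorescence but overlap in
scatter, so the classifier must use both, as the method prescribes.

`simulateMixture()` draws event counts multinomially in proportion to
event concentrations: viable ∝ P, dead ∝ r·(100 − P) (the yield factor
models disintegration losses), background from the medium preset
(5 × 10³ / 2.5 × 10⁴ / 5 × 10⁵ events·mL⁻¹ for PBS / filtered /
unfiltered SSL at a cell-suspension concentration of 4 × 10⁵ at OD
scale 1 — a measurement-ready dilution; unfiltered carries 20× the
filtered particle load). Default budding fraction 0.15.
`applyInstrumentLimit()` models acquisition throttling as thinning with
retention probability proportional to forward-scatter signal mass —
the direction (larger/brighter events preferentially retained) is an
assumption; only the existence of a bias is established behaviour.

Not emulated: optics and fluidics physics, spectral spillover beyond a
configurable green→red bleed coefficient (default 0, as the targeted
acquisition software performs no compensation), staining kinetics,
coincidence/doublet artifacts other than budding, and drift in detector
gain. Passing tests on simulated data therefore demonstrate the
*internal* consistency of gating, calibration and monitoring under the
stated population model, not instrument-level accuracy; on real data
the gate-fit step absorbs instrument specifics via the reference runs.

# Numerical choices and degenerate inputs

* log₁₀ with floor 1 a.u. before all fluorescence gating.
* Hull trim quantile 0.99, expansion 1.3, window quantiles 0.5–99.5 %
  with 25 % padding (see above).
* Covariance of a reference cloud is ridged by 10⁻⁶ if singular
  (collinear degenerate references).
* `fitYieldFactor` optimizes on (10⁻⁴, 1] and returns 1 when the
  boundary is optimal; endpoint-only rows are rejected.
* `expectedRatio` errors on a zero denominator rather than returning
  0/0; time-series ratios return NA on zero denominators.
* Empty traces, missing channels, non-numeric values, unknown formats
  and non-FCS-3.1 files are rejected with messages naming the event,
  line or file; readers never coerce silently.
* All file writes go to a temp file in the target directory followed by
  an atomic rename, so failures leave no partial output.
* Every stochastic function takes an explicit seed and restores the
  caller's RNG state; sub-seeds are derived deterministically and stay
  below 2³¹.

# Problem sizes

The bundled verification uses reference runs of 4000–6000 events, pure
population checks at 10 000 events, mixture recovery at 50 000 events
over 10 seeds, and a full calibration sweep of 3 media × 7 mixing
ratios × 3 replicates × 20 000 events with gates refitted per medium —
about 1.3 million simulated events end to end, chosen so that sampling
error (binomial SD ≈ 0.3 percentage points at n = 20 000) is well below
the 10-point accuracy tolerance while the whole suite runs in a few
minutes on one CPU.

# Known limitations

* Gate quality is bounded by the reference runs; references measured at
  different detector settings than the samples invalidate the gates.
* The single-r yield model cannot represent viability-dependent
  staining efficiency (see the calibration section).
* The morphology boundary is linear in log–log space; chains or clumps
  of more than two cells are outside the model.
* Absolute specific productivities depend on the per-cell dry mass
  assumption; only normalized trends are assumption-free.
* The overload bias model fixes a direction for the thinning
  preference; real acquisition firmware may bias differently, so only
  the *increase* in ratio error above the particle limit should be
  relied upon.
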