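# cytogate

Flow-cytometry viability gating and bioprocess monitoring for yeast
cultivated in particle-rich complex media.

## The problem

Spent sulfite liquor (SSL), a sugar-rich by-product of sulfite pulping,
is an attractive feedstock for second-generation bioethanol production
with *Saccharomyces cerevisiae* — but it carries a heavy load of solid
lignosulfonate particles. Turbidity, dry weight and optical density
cannot tell viable biomass from that background, and the particles
accumulate further in cell-retention (retentostat) processes. cytogate
implements an at-line flow-cytometry workflow for exactly this setting,
for bioprocess engineers and cytometrists who need per-sample viable /
dead / background counts and physiology readouts:

* **Pulse-shape feature extraction** — per-channel *total* (area),
  *maximum*, *sample length* (above-threshold extent in µm) and ADC
  *saturation* flags from full signal traces (FSC, SSC, green
  fluorescence from fluorescein diacetate staining of esterase-active
  viable cells, red fluorescence from propidium iodide in
  membrane-compromised dead cells).
* **Three-population gating** — convex polygon gates in
  (log₁₀ green total, log₁₀ red total) fluorescence space fitted from
  pure-population reference runs, combined with cell size (FSC length)
  and shape (SSC total) windows so that dye-adsorbing medium particles
  cannot read as cells.
* **Morphology** — a straight-line discriminant separating single cells
  from budding mother–daughter doublets; the budding ratio indicates
  growth activity.
* **Mixture calibration** — expected counts and ratios for defined
  viable/dead mixtures:

  N_exp,viable = N_FDA,V100 · P_viable/100 + N_FDA,D100 · P_dead/100
  N_exp,dead  = N_PI,V100 · P_viable/100 + N_PI,D100 · P_dead/100
  Ratio_V,exp = 100 · N_exp,viable / (N_exp,viable + N_exp,dead)
  Ratio_D,exp = 100 − Ratio_V,exp

  plus a least-squares fit of the dead-suspension event-yield factor
  *r* in Ratio_V(P) = 100·P / (P + r·(100 − P)), which accounts for
  partial disintegration of harshly killed reference cells.
* **Sample QC** — the method cannot cope with particle loads above
  1 × 10⁶ particles·mL⁻¹ (the acquisition software throttles intake and
  results become biased); `qcParticleLoad()` checks a preliminary count
  and recommends a power-of-ten dilution.
* **Process monitoring** — viability, budding and SSL-fraction time
  courses, chemostat washout / background wash-in dynamics, specific
  ethanol productivity on a total-dry-weight or viable-cell basis, and
  a low-viability nutrient-pulse alert rule.
* **A seeded event simulator** generating realistic pulse-shape events
  for all three populations (plus budding doublets and instrument
  overload), so the entire pipeline is testable without an instrument.

I/O: a documented plain-text pulse CSV dialect for traces, FCS 3.1
listmode export/import for feature tables, JSON/CSV reports, and a thin
command-line front end (`inst/cli/cytogate.R`) with `simulate`,
`classify`, `calibrate` and `monitor` subcommands.

## Worked example

```r
library(cytogate)

## fit gates from simulated pure-population reference measurements
gates <- referenceGates(seed = 1, nRef = 6000)

## measure a 60/40 viable/dead mixture in unfiltered SSL medium
spec <- mixtureSpec(60, medium = "unfiltered_SSL", rYield = 1,
                    nEvents = 20000)
m <- measureMixture(spec, gates, seed = 2)
m$result
#> ClassificationResult
#>   counts: viable=5246, dead=3698, background=11044, unclassified=12
#>   viability: 58.7 %
#>   flags: overload=FALSE, green saturation fraction=0.012

## budding activity of the viable population
classifyMorphology(m$features[eventLabels(m$result) == "viable"],
                   gates)$buddingRatio
#> [1] 0.195

## expected ratio of an 80/20 mixture when the dead suspension yields
## only 510 of 1000 countable events per mL
expectedRatio(expectedCounts(PureSuspensionCounts(1000, nPiD100 = 510), 80))
#> ExpectedRatioResult: N_viable=800, N_dead=102 events/mL
#>   expected ratio V/D: 88.69 / 11.31 % (reported 89/11)

## recover the yield factor from a reported expected-ratio row
fitYieldFactor(c(80, 60, 50, 40, 20), c(89, 75, 66, 57, 33))
#> [1] 0.506

## particle-load QC: 3e7 particles/mL needs a 100x dilution
qcParticleLoad(3e7)$recommendedDilution
#> [1] 100

feedRate(0.07, 1)   # retentostat feed, mL/h
#> [1] 70
```

The measured viability (58.7 %) recovers the 60 % ground truth of the
simulated mixture against a background where medium particles outnumber
cells; the half-percent shortfall is the residual classification error
the calibration sweep quantifies.

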