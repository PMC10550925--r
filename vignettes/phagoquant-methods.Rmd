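---
title: "Measurement models and synthetic validation in phagoquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurement models and synthetic validation in phagoquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagoquant)
```

phagoquant quantifies membrane contact sites (MCS) between the
endoplasmic reticulum (ER) and phagosomes, and the downstream readouts of
phagosome maturation: Ca²⁺ signalling, phospholipid dynamics,
phagolysosome fusion, luminal pH and antigen degradation. This vignette
records the measurement models, the conventions and defaults, the design
choices made where the procedures were underdetermined, and what the
synthetic-data validation does and does not establish.

## Conventions

All images live in a fixed 5-D axis order (channel, time, z, y, x) with y
increasing downward, 0-based physical pixel coordinates, and a pixel's
site at its center. Areas are `pixel_count × pixel_size_nm²`. Connected
components default to 8-connectivity (the particle-analysis convention of
common image-analysis software). Every intensity threshold is strict
(`>`): a uniform image never contains detections, which makes degenerate
inputs safe. Background subtraction (`background_subtract`) removes a
per-plane scalar — the mean of a user-supplied cell-free region when one
exists, otherwise the 1st percentile of the plane as a stand-in — and
clamps negatives to zero; downstream formulas assume it has been applied.

## EM contact sites

A cross-section profile is a phagosome boundary (circle or simple
polygon, nm) plus ER membranes abstracted as open polylines (cisterna
midlines); classifying EM texture is human judgement and out of scope —
the counting rule is purely geometric. `detect_contacts` samples each
polyline at 1 nm (the granularity of a manual caliper), computes the
nearest Euclidean distance to the boundary, and returns maximal runs
within the 30 nm criterion; runs shorter than `min_run_nm = 20` (about
one EM section thickness) are discarded as grazing artifacts. Only
slices with diameter strictly above 1 µm are analysed
(`filter_profiles`), since near-polar cuts under-sample the contact zone.
Group differences in length *diversity* use the two-sided variance
F-test (`variance_f_test`, F = larger/smaller sample variance); all
other group comparisons are reported descriptively with seeded bootstrap
95% CIs rather than re-implementing a menagerie of significance tests.

## Ring puncta

`make_ring` builds, per phagosome, the set of outside pixels within
0.2 µm (≈ 4 px at confocal scale) of the phagosome; overlapping rings are
partitioned to the nearer phagosome so no pixel is counted twice.
`detect_ring_puncta` counts connected above-threshold components with
area strictly greater than 0.01 µm². At 50 nm pitch, 4 px is exactly
0.01 µm², so "strictly greater" means ≥ 5 px; the strict reading is
adopted and configurable. A manually chosen per-cell threshold is not
reproducible, so the default `"auto"` threshold is cytosolic mean + 2
cytosolic SD (the same spirit as the hotspot criterion); a numeric
override is accepted. Multi-plane inputs are max-projected first —
whether counting was done on single slices or projections was not
specified; projection is the default and configurable by projecting
upstream.

## Ca²⁺ readouts

`soce_metrics` summarises store-operated Ca²⁺ entry from a Fura-2
F340/F380 trace: baseline = mean ratio over a window ending at Ca²⁺
re-addition; peak amplitude = post-re-addition maximum minus baseline
(invariant to additive offsets); max slope = the largest slope among
least-squares line fits over 5 consecutive samples (15 s at the 3 s
frame interval), which suppresses single-frame noise.

`detect_hotspots` implements the periphagosomal hotspot rule: after 6 s
temporal averaging, connected regions of ≥ 4 px above cytosolic
mean + 2 SD whose centroid lies within 750 nm of a phagosome border.
The stated "4 pixel areas (500 nm²)" is internally inconsistent with
"3 pixels (750 nm)" (which implies 250 nm pixels); the adopted reading
is min area = 4 px at 250 nm pitch with the distance = 750 nm, both
configurable. Centroid-to-border distance uses a bounded exact Euclidean
distance/nearest-label transform (all integer pixel offsets scanned in
increasing distance order). Hotspot *frequency* is reported as hotspots
per phagosome per analysed frame-set; with what cadence frame-sets were
sampled in the original protocol is not fully specified.

## TIRF kinetics

`detect_tirf_puncta` thresholds each frame at whole-cell mean + 1
within-cell SD, recomputed per frame (holding a baseline threshold fixed
is a config alternative), and keeps components strictly larger than
4 px. Cells with any detectable punctum at baseline are excluded
(`exclude_baseline_cells`), since their contacts predate the stimulus.
`fit_boltzmann` fits y(t) = A1 + (A2−A1)/(1+exp((t₅₀−t)/slope)) by
bounded least squares (`nls`, port) with robust starts — A1 = min, A2 =
max, t₅₀ = half-range crossing, slope = (t₉₀−t₁₀)/4.4 — returning a
classed model object; constant series are flagged degenerate rather than
fitted. Condition kinetics are fitted on the across-cell mean count
track (fitting per-cell tracks is also possible); "value at 6 min" style
quantities use the sample nearest the requested time (`value_at_time`).

## Phospholipid enrichment

Enrichment is E(t) = mean phagosomal fluorescence at t divided by the
initial whole-cell mean fluorescence, minus 1, computed on
background-subtracted max projections; it is scale-invariant by
construction. The initial peak is the global maximum of E within 10 min
of ingestion start (the probe influx peak occurs promptly after
ingestion). Window anchoring is explicit per metric because the headline
windows mix conventions: the post-peak window (5–25 min) is anchored to
each track's detected peak, the early window (5–10 min) to ingestion
start, and the phosphatidylserine contrast uses the full-observation
mean. `condition_contrast` reports per-arm mean ± SEM plus fold and
percent change against a reference with a seeded bootstrap 95% CI
(10⁴ resamples).

## Fusion, pH and antigen

The phagolysosome-fusion index is computed per cell: the pixel-wise
FRET/donor ratio is averaged within each phagosome, summed over the
cell's phagosomes, and divided by the cell's total acceptor (red)
fluorescence on the max projection. Pixel-wise ratioing before averaging
was chosen (ROI-mean ratioing is the config alternative); donor-zero
pixels are excluded and phagosomes with > 50% excluded pixels are
flagged. Cells without phagosomes yield an undefined (NA) index, not
zero. A donor-independent `fret_ratio` (phagosomal FRET sum over total
red) is reported alongside, since construct brightness differences can
bias the donor channel.

pH calibration fits a monotone Boltzmann of the 440/480 excitation ratio
against buffer pH (4.0–9.0 in 0.5 steps); the direction is auto-detected
(the fluorescein-type ratio falls as pH rises). The inverse is analytic;
ratios outside the calibrated range are clamped with a warning because a
sigmoid plateau cannot be inverted meaningfully. A calibration is
rejected when buffer means are flat or show a reversal above 5% of the
dynamic range — strict monotonicity of the raw means would spuriously
reject noisy plateau points. Percent antigen remaining is the
sum-projection fluorescence of each ingested bead as a percentage of the
mean over free beads, invariant to global illumination.

## The synthetic world

Each generator renders the inputs its assay consumes, records ground
truth, and is deterministic given a `scenario_config` (the seed is part
of the config; generators use isolated RNG streams and restore the
caller's). Named presets fix the condition contrasts at their published
effect sizes — 4.5 vs 3.0 contacts/phagosome with overall median lengths
93 vs 81 nm and a 3% very-large (> 400 nm) population in the knockdown;
a 50% loss of ring-puncta recruitment; a 2.5-fold higher post-peak
PI(4)P window with unchanged initial peak; 45% lower early-window
PI(3)P; 20% lower PS; a rescue that cuts PI(4)P by 35% at peak and 48%
in the window; a 1.5-fold fusion-index increase; unchanged hotspot
frequency, phagocytic index and pH. Quantities the figures do not print
as numbers — absolute puncta and hotspot rates, absolute enrichment
scale, the fluctuating-track fraction (0.3 control / 0.6 knockdown),
noise levels — are fixed once at field-realistic values here and not
revisited.

Choices a reader should know about:

* **Deterministic effect injection.** The very-large contact population
  is injected at exactly its configured rate (every ⌊k·frac⌋-increment
  contact in generation order) rather than by Bernoulli draws, so the
  generator's ground truth is the configured fraction itself; with ~1500
  contacts a binomial draw would carry ~15% relative noise, more than
  the recovery tolerance being tested. The configured median length is
  the overall median including that population; the lognormal component
  is shifted by the closed-form mixture correction
  `exp(−σ·qnorm(0.5/(1−frac)))`.
* **Separation guarantees.** Generators place structures (contacts on
  the boundary, puncta in rings, hotspot blocks, TIRF sites) with
  minimum separations chosen so that distinct true structures remain
  distinct to their detectors, and verify hotspot placement against the
  detector's own pixel-quantised distance rule. A structure that cannot
  be placed on a genuinely saturated ring is dropped and the truth
  records that. This makes the perfect-recall-at-zero-noise invariant
  exact; real images contain merged and ambiguous structures that this
  world deliberately excludes.
* **TIRF noise.** The adaptive mean + 1 SD threshold has a scale-free
  false-positive density under iid Gaussian pixel noise (≈ 16% of pixels
  exceed it no matter the SD), so TIRF scenarios render noise-free
  images and put stochasticity into punctum placement and appearance
  order; fit robustness to trace noise is validated separately on
  simulated noisy curves (SNR 10).
* **Lipid track model.** All tracks share a Gaussian influx pulse
  peaking 2 min post-ingestion (SD 0.9 min) and a logistic plateau gate;
  "low" tracks settle at a flat level, "fluctuating" tracks swing ± 20%
  sinusoidally around a moderately higher one. Plateau levels are solved
  in closed form so the arm-level expected window mean equals
  `lipid_window_level` for any fluctuating fraction, and the renderer
  anchors phagosome intensities to the frame-1 whole-cell mean so the
  image-measured enrichment equals the track-space truth exactly up to
  noise. The class gap (0.45 × window level) is a free parameter chosen
  so n = 60 arms resolve the published fold changes; larger gaps make
  the two populations more visually distinct but the arm means too noisy
  to test against 10% tolerances.
* **Scaled-down geometry.** One cell per tile, static phagosomes, a
  single focal plane (or a thin z-stack for the fusion assay), no
  point-spread function, photobleaching or motility. Recovery of an
  effect size here establishes that the *measurement statistics* are
  implemented correctly, not that they are robust to segmentation error,
  drift or optical artifacts.

## Numerical notes and limitations

Boltzmann fits can fail to converge on pathological inputs; the fit
object then carries `converged = FALSE` and diagnostics instead of
raising. The bounded distance transform is exact within its search
radius and returns `Inf` beyond it. TIFF support is a deliberate minimal
subset (uncompressed, single sample, little-endian write) sufficient for
round-tripping the package's own data and reading plain exports;
compressed or tiled vendor TIFFs are out of scope. Tests and the
acceptance script are everything the synthetic world can certify;
applying the pipelines to real microscopy additionally requires
registration, segmentation and drift control upstream, which this
package intentionally leaves to the acquisition side.
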