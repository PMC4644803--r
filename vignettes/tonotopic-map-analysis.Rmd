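---
title: "Methods: receptive fields, tonotopic maps and their synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: receptive fields, tonotopic maps and their synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tonomapr)
```

This vignette is the package's own account of the models and the numerical
decisions behind them: what each estimator computes, what the synthetic
cohort generator does and does not emulate, and where open design choices
were settled.

## 1. The measurement model

A mapping experiment presents pure tone pips over a frequency × intensity
grid (defaults: 66 tones, 1–70 kHz, geometric spacing; 0–70 dB SPL in 10-dB
steps; 3 trials; 25-ms tones at 2/s) while multiunit spikes are recorded at
each site of an 8 × 8 electrode array (375 µm between columns, 500 µm
between rows), two penetrations per animal, i.e. 128 sites. Spike counts
are kept in 1-ms bins from 50 ms before tone onset to 100 ms after.

A note on the tone grid: the classic description of this design ("66
frequencies, 1–70 kHz in 0.1-octave increments") is internally inconsistent
— 0.1-octave steps over 1–70 kHz give 62 tones. The package honors the tone
count and the endpoints: 66 geometrically spaced tones, a step of ~0.0943
octaves. This step is the frequency-grid resolution quoted below.

## 2. Receptive-field estimators

**FRA and significance.** For each (frequency, intensity) cell, spikes in
the response window (5–50 ms after onset; bracketing the 6–20 ms AI onset
latencies and the 25-ms tone) are summed across trials and compared with the
pooled pre-stimulus baseline (50 ms per presentation, pooled over all 1 584
presentations). A cell is *significant* when its count's upper Poisson tail
under the baseline expectation is below `alpha = 0.01` **and** it belongs to
a 4-connected cluster of at least 3 such cells. The original analyses do not
state a per-cell criterion; with 528 cells per site an uncorrected 1% test
yields ~5 false positives per site, and the cluster rule suppresses exactly
those isolated cells while leaving any real, contiguous response area
untouched.

**CF and threshold.** Threshold is the lowest intensity with any significant
cell; the CF is the significant frequency at that intensity (the tuning-curve
tip). Ties are resolved the way flat tips are handled: the median frequency
among the significant cells at threshold, taking the lower median for even
counts; when the threshold row splits into disjoint frequency runs (two
apexes tied at threshold), the lower-frequency run is used. Multi-peaked
fields need no special casing beyond this: the apex with the lowest
threshold *is* the tip.

**BW10** is `log2(f_max/f_min)` over the significant cells in the row 10 dB
above threshold; 0 for a single cell; undefined (`NA`) when that row was not
tested (threshold at the top intensity) or is empty. "Responses" here means
significant cells, not raw counts — the default resolution of an ambiguity
in the verbal definition.

**Latency.** All presentations at or above the site threshold are pooled
into a mean PSTH (spikes/bin/presentation). The criterion is the PSTH's own
pre-stimulus mean + 4 SD; the latency is the start of the first run of 2
consecutive supra-criterion bins within 5–50 ms. Requiring 2 bins rejects
single-bin noise crossings at 1-ms resolution; `latency_consec = 1` restores
the literal single-crossing rule. Pooling across stimuli (rather than
per-stimulus latencies) is the default resolution of another unstated
detail; it matches the "multiunit response level" phrasing of the criterion.

**Irregularity index.** On the binarized significance mask `M`,
`c00 = sum(M^2)`, `c10` and `c01` are the one-step autocorrelation terms
along the two grid axes, and the index is
`(c00 − (c10 + c01)/2)/sqrt(c00) − 3`. Computing on the binarized mask
(rather than counts) makes the index scale-free; compact rectangles satisfy
the closed form `(a + b)/(2*sqrt(a*b)) − 3` (verified exhaustively in the
tests for all a ≤ 8, b ≤ 66), and fragmented masks rise above the
conventional irregular/regular cutoff of 2.

**Shape class.** The per-frequency threshold curve (lowest significant
intensity per frequency column) is median-filtered with a 3-column window;
apexes are its local minima with prominence ≥ 10 dB, merged when closer
than 0.3 octaves. More than one apex ⇒ `multi`; no apex ⇒ `flat`; one apex
whose *unfiltered* minimal-threshold plateau spans more than 1 octave ⇒
`flat`; otherwise `single_v`. Two numerical details matter on a 10-dB
intensity grid. First, the plateau must be judged on the unfiltered curve:
the median filter necessarily widens a sharp one-column tip into its 10-dB
neighborhood, and a filtered-plateau rule would classify every v-shaped
field as flat. Second, prominence uses the convention that a flank reaching
the grid edge without a lower point does not bound prominence, so
edge-truncated v-shapes remain single-peaked.

## 3. Map-level analysis

**AI delineation.** A site is in AI iff it is responsive with a defined CF,
is not VAF-like (significant only below 30 dB SPL with nothing at or above
that level), and either has threshold ≤ 50 dB or touches ≥ 2 directly
qualifying 4-neighbors on the electrode grid (high-threshold sites embedded
in the AI core are kept; isolated high-threshold or unresponsive surround
sites are excluded). The posterior field's phenomenology (few, broad,
discontinuous fields caudal to AI) is not separately modeled; the non-AI
handling subsumes it.

**Normalized axis and tonotopic index.** A line is fit to the AI site
coordinates by ordinary least squares (y on x, axes swapped when the slope
magnitude would exceed 1; a principal-axis fit is available via
`axis_fit = "tls"` and is the exactly rotation-invariant choice), the map is
rotated so the line is horizontal, positions are collapsed onto it and
min-max normalized to [0, 1]. Synthetic maps carry no anatomical "rostral"
reference, so the axis is oriented by requiring a non-negative correlation
between position and normalized CF. CFs are normalized by mapping the log
range 1–63 kHz to [0, 1]; CFs above 63 kHz are clipped to 1 rather than
discarded. The tonotopic index is the mean perpendicular distance
`mean(|pos − cf|)/sqrt(2)` to the identity diagonal. Fitting on AI sites
only (not all responsive sites) is the default resolution of an unstated
choice.

**Voronoi maps.** The tessellation is built by half-plane clipping against
a buffered convex-hull outline (offset by half the median nearest-neighbor
spacing), so the cells tile the outline exactly and each site lies in its
own cell — both properties are asserted in the tests. Collinear or
duplicated site geometries raise errors naming the condition.

**Group statistics.** Per-animal summaries are computed over responsive AI
sites (percentages per frequency band with default edges 1, 4.3, 10, 50,
70 kHz; % irregular; % single vs multi/flat; % threshold > 50 dB; mean BW10;
mean latency; tonotopic index). Group contrasts use the pooled-variance
two-tailed Student's t-test with the animal as the unit of analysis;
zero-variance degenerate cases return `p = 1` (equal means) or `p = 0`.
Percentages are averaged per animal, then compared — the per-animal-first
reading of the ambiguous "percentages … obtained from the total number of
recorded sites inside AI".

## 4. The synthetic cohort generator

The generator is the inverse of the measurement model. Each site's truth is
drawn from a condition preset; the expected firing-rate surface follows a
frequency-dependent threshold curve
`thr(f) = thr + (20/bw10)·|log2(f/cf)|`, so the supra-threshold span
measured 10 dB above the tip equals the true BW10 exactly. Above `thr(f)`
the rate is `onset + gain·(I − thr(f))`, saturating at 100 Hz; evoked mass
occupies `[latency, latency + tone + 10 ms]`; spiking is independent Poisson
per bin on top of a 2 Hz baseline.

Three generator choices are deliberate and load-bearing:

* **A step onset at threshold** (`evoked_onset_hz`, default 60 Hz; 100 Hz in
  high-gain recovery experiments). A purely linear rate is exactly zero at
  `I = thr(f)`, so the tip cell could never respond at threshold and no
  estimator could recover the threshold to grid precision. The step makes
  the generative model self-consistent with its own estimators.
* **Grid-quantized truths.** True CFs are snapped to the tone grid and true
  thresholds to the 10-dB intensity grid. With off-grid thresholds the
  estimated threshold exceeds the truth by a fractional step δ and the
  BW10 row sits (10 + δ) dB above the tip, inflating BW10 by (1 + δ/10) —
  up to twofold. On-grid truths give grid-exact recovery: CF exact,
  threshold exact, BW10 within one grid step per flank.
* **Detectable multi-peak layout.** Multi-peaked truths are two v-shapes
  3 octaves apart, secondary apex 10 dB above the primary, per-peak
  bandwidth capped at 1.5 octaves. With the classifier's ≥ 10 dB prominence
  rule on a 10-dB-quantized threshold curve, closely spaced or broad double
  peaks are mathematically indistinguishable from a single apex; this
  layout guarantees a ≥ 20 dB quantized valley.

Flat truths have a constant threshold across 1.5 octaves. 15% of border-ring
sites are marked outside AI, split between high-threshold-only (responsive
at the top two levels) and unresponsive, exercising the delineation rules.
True CFs follow a rostro-caudal log-frequency gradient spanning the tone
range over the map extent (~1.09 oct/mm) with Gaussian jitter
(`cf_jitter_oct_sd`), plus a `hi_freq_bias` probability of resampling the CF
uniformly (in log frequency) into 10–50 kHz.

**Preset calibration.** The shipped presets pin every parameter that the
study reports as a group mean: BW10 1.24/3.02 octaves, latency 14.97/10.27
ms, shape mixture 93.47/76.25% single-peaked (control/VPA). Thresholds are
reported only as the percentage of sites above 50 dB (9.99%/37.58%), so the
latent normal mean is calibrated as `55 − qnorm(1 − p)·15` (SD 15 dB):
35.8 dB control, 50.3 dB VPA. CF jitter (0.4/1.0 oct) and `hi_freq_bias`
(0.135/0.36; from the reported 46.28%/60.29% of CFs in 10–50 kHz against
the 37.9% that the uniform gradient alone would place there) are set once
from the printed map-level statistics. Cohort sizes default to 6 control and
8 VPA animals; the original VPA count (832 sites from N = 8) is not 8 × 128
— the generator keeps 128 sites/animal and does not emulate that mismatch.

**Seeding.** Child seeds are a fixed 32-bit arithmetic hash of
(master seed, animal index, site index), so identical master seeds
reproduce byte-identical datasets and partial regeneration is stable.

## 5. What passing tests do and do not show

The generator emulates stimulus design, array geometry, Poisson multiunit
statistics and the group-level receptive-field contrasts. It does not
emulate: correlated (non-Poisson) spiking, adaptation, trial-to-trial
latency jitter (available via config but off by default so the 4-SD
estimator's target is unambiguous), LFPs or spike waveforms, anatomical
landmarks, or fragmented receptive-field masks. The last point matters for
one statistic: synthetic significance masks are compact by construction, so
the irregularity index stays below 2 in both conditions and the *percentage
of irregular sites* does not differentiate the synthetic groups even though
its estimator is verified against the closed form. Parameter-recovery
results therefore validate the estimators, not the biological realism of
the simulated cortex.

Estimator biases worth knowing: estimated BW10 is floor-quantized by the
tone grid (≤ one step per flank, ~3% at 3 octaves) and censored when a
broad field reaches the tested frequency edge — recovery experiments sample
CFs with a margin of half the target bandwidth so the measurement is
defined at every site, and cohort means of BW10 in full maps run slightly
below the generative truth for the broad-tuned condition. Latency estimates
are quantized upward to the next bin boundary (+0.5 ms on average at 1-ms
bins).

## 6. Problem sizes and numerical conventions

The test suite and the acceptance script use: 500 sites for BW10 recovery
and 200 for latency recovery (high gain, fixed truths); 150-site cohorts
for classifier accuracy; 20 replicate maps per jitter level for the
tonotopic-index monotonicity sweep; and a full 6-vs-8 animal cohort
(1 792 sites) for the directional group contrasts. Undefined metrics are
explicit `NA`s end to end (empty cells in CSV output), never sentinel
numbers. All tolerances asserted in tests are stated next to the assertion;
dataset and results writers produce byte-identical files for identical
inputs, which the determinism tests check by hashing.
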