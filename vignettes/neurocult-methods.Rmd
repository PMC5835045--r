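---
title: "Quantifying co-culture effects in low-density neuronal assays: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying co-culture effects in low-density neuronal assays: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurocult)
```

## The measurement problem

Low-density primary neuron cultures (1,000–50,000 cells/cm²) are the working
material of bottom-up neuroscience: sparse enough that single cells and
neurites can be resolved and targeted, but notoriously hard to keep alive.
Suspending a feeder culture of astrocytes above the neurons — physically
separated but sharing the medium — markedly improves survival, outgrowth and
spontaneous activity. Quantifying that effect requires three image-based
assays plus a replicate-aware statistical comparison:

1. **Viability** at 5 days in vitro: live/dead staining with a nuclear
   counterstain, imaged at three randomized positions per well. The total
   cell count comes from the nuclear channel, the dead count from the
   dead-stain channel; live = total − dead (the live stain itself is never
   counted, as its esterase signal is unreliable for counting). Viability is
   live/total; live-cell density is live cells per imaged area, which unlike
   viability also captures cells lost to detachment.
2. **Neurite length** on the same images: binarize the neurite stain,
   skeletonize, and sum the skeleton length per image.
3. **Spiking activity** at 14 days in vitro: calcium imaging (2-minute
   recordings at 32 Hz, 3–5 positions per well) with a genetically encoded
   indicator; cells are segmented, ΔF/F traces extracted, and calcium
   transients ("spikes") detected; the total spike frequency is the summed
   event count over the recording duration, and dividing by the number of
   detected cells gives the mean frequency per cell.

Comparisons use a one-sided Mann–Whitney U test (the data are not normally
distributed), 1.5·IQR outlier exclusion, and per-biological-replicate fold
changes against the control mean. The replicate structure is 2–3 biological
replicates (independent preparations) of 5 technical replicates (wells).

Because no raw microscopy data from such experiments are bundled with the
package, a synthetic-data generator produces every input with known ground
truth — cell positions and dead flags, polyline neurite geometry, Poisson
spike trains — so every stage of the pipeline can be validated end to end.

## The synthetic generator: what it emulates

**Field geometry.** 512 × 512 px at 1.3 µm/px (≈0.0044 cm² per field). This
is a declared assumption, not a measured value: over the density range of
interest it yields roughly 4–220 cells per field, the regime in which
individual cells are easily resolved. All geometry is configurable.

**Nuclei fields.** Cells are placed by dart throwing with a minimum
center-to-center spacing (default 12 px) and rendered as isotropic Gaussian
spots (σ = 3 px) of peak height `contrast × noise_sd` on a noisy baseline
(defaults: baseline 1000, noise 10, contrast 10 — spots 10 noise-sd above
background). `round(n × dead_fraction)` cells are flagged dead and rendered
in the dead channel; the rest go to the live channel, which the pipeline
never counts. An `overlap_fraction` places a fraction of cells as close
pairs (2–3.3 σ apart) that merge into single connected components above
threshold, exercising the declumping path. The number of cells per field in
a generated experiment is Poisson(density × field area).

**Viability and activity condition curves.** The generator's default curves
transcribe the trends reported for this assay family: co-culture viability
rising from 0.70 at 1,000 cells/cm² to a plateau of ≈0.91 from
10,000 cells/cm² upward; control viability climbing mildly from 0.50 to
0.75 with 0.69 at 10,000 cells/cm²; per-cell firing rates increasing with
density, with co-culture roughly doubling the rate at the low end.
Unreported intermediate points are linear interpolations chosen once. The
generator injects no additional well-to-well biological variability: the
per-well dead fraction is exactly the curve value, so the only measurement
scatter is Poisson placement, rounding, and counting error. Passing tests
therefore demonstrate correctness of the measurement chain, not robustness
to biological heterogeneity, staining artifacts, uneven illumination or
focus drift — none of which the generator emulates.

**Neurite arbors.** Each cell grows 2–4 neurites as persistent random walks
(step 4 px, turning sd 0.25 rad). The true total length is the exact vertex
sum of all polylines, recorded before rasterization; lines are rasterized
with a Gaussian cross-profile (σ = 0.6 px, max-blended) so their core
brightness does not dip between pixel centers.

**Calcium movies.** Per-cell homogeneous Poisson spike trains are convolved
with a difference-of-exponentials transient, rise 0.18 s, decay 0.55 s,
amplitude 0.2 ΔF/F — representative of a slow genetically encoded
indicator; the literature on the exact indicator variant used in such
experiments is ambiguous, so all kernel constants are parameters rather
than fixed. Cells are disks (radius 3 px) at `baseline × (1 + ΔF/F)` on a
slightly dimmer background; Gaussian pixel noise of `noise_sd` ΔF/F units
(relative to the resting cell fluorescence) is added per pixel, so
footprint-averaged traces are correspondingly cleaner — as in real
recordings, where ROI averaging suppresses camera noise. Network synchrony
and photobleaching are not modeled: the pipeline measures frequency, not
correlation structure, and baseline drift handling can be probed by adding
a drift term to traces directly.

## Counting by semi-automatic thresholding

"Semi-automatic" is operationalized as: one user-chosen relative multiplier,
converted per image to an absolute threshold `value × (median + k_mad × MAD)`
from robust background statistics (defaults `value = 1`, `k_mad = 5`). In a
dataset run, the threshold is resolved once per condition on a reference
image and then applied verbatim to every image of that condition — the
in-silico analogue of setting the threshold manually for one image and
reusing it. Because median and MAD both scale linearly with intensity,
counts are invariant to global gain changes.

After binarization, 8-connected components are labeled; components below
`min_object_area` (5 px) are discarded as debris, and components above
`max_object_area` are declumped by watershed on the distance transform
(tolerance 0.5). The default ceiling of 45 px sits just above the area of a
single rendered nucleus at the default contrast (≈34–45 px), so touching
pairs (≈50–70 px) get split while single nuclei never do — and an oversized
blob that the watershed cannot split still counts as one object, never
zero. Dead counts can in principle exceed nuclei counts on pathological
input since the two channels are thresholded independently; the well-level
summary clamps dead ≤ total so that live = total − dead is never negative.

## Neurite length by skeletonization

The neurite mask (after dropping components under 10 px) is thinned to
1-px centerlines with the two-subiteration Zhang–Suen algorithm, followed by
a corner-pruning pass: any non-endpoint pixel whose occupied neighbors
already form a single mutually 8-connected cluster is redundant and removed.
Without this pass, thinning a 2-px-wide oblique ribbon leaves staircase
corners that inflate the length estimate well beyond the metric's intrinsic
bias. Length is then the sum over skeleton adjacencies of 1 (orthogonal) or
√2 (diagonal) pixel steps, with a diagonal pair not counted when the two
pixels are already connected through a shared orthogonal neighbor. This
diagonal-step metric overestimates a digitized straight segment by at most
≈8% (worst near 22.5°), which motivates the package's ±10% accuracy
commitment for arbors; measured worst-case straight-segment error across
rotations is ≈7.5%. Somata can optionally be excluded from the skeleton
(`soma_exclusion_radius`), off by default since whether cell bodies
contribute to a "neurite length" readout is a convention, not a fact.

Per-well totals are sums over the well's fields — lengths and cell counts
are each summed before any ratio or fold change is formed. Fold changes are
computed within each biological replicate as value / mean(control values of
the same replicate and density), so the mean control fold change is exactly
1 by construction; this identity is asserted on every run. Whether total
length should be normalized per cell before fold change is genuinely open;
the package reports both `fold_change_length` and the per-cell variant.

## Wavelet spike detection

The detector computes a continuous wavelet transform of the ΔF/F trace with
a Mexican-hat (second-derivative-of-Gaussian) mother wavelet over 8
geometrically spaced scales spanning 0.1–1.2 s — bracketing the transient's
rise-to-peak width (≈0.3 s for the default kernel). Per scale, the noise
floor is the MAD of the coefficients (scaled to estimate a Gaussian sd). An
event requires:

- **ridge support**: coefficients above `k_ridge = 3.5` noise floors at
  ≥3 contiguous scales, allowing each scale a time jitter of half its width;
- **peak strength**: a coefficient of ≥ `k_peak = 5.5` noise floors within
  ±0.5 s;
- **localization**: a local maximum of the mean z-score of the 3 finest
  scales exceeding 2.8, taken as the event frame. Fine scales are used for
  localization because coarse-scale maxima lag the spike by up to ~0.6 s on
  an asymmetric transient; the fine-scale response tracks the transient peak
  (≈0.25 s after the underlying spike, well inside a ±0.5 s matching
  window).

Candidates closer than the 0.25 s refractory interval merge, keeping the
larger coefficient. All three thresholds are multiples of the per-scale
noise floor, so detection is invariant to rescaling the trace; the circular
FFT convolution makes it equivariant under circular time shifts. The
constants were calibrated once on simulated transients at amplitude-to-noise
5 (the hardest regime the package commits to): the two-threshold design
separates the operating point for sensitivity (ridge) from the guard against
pure-noise false positives (peak), reaching ≈0.95 recall and ≈0.97 precision
while leaving noise-only traces event-free. A trace shorter than four times
the largest scale returns no events rather than unstable coefficients, and
constant traces are recognized as degenerate (coefficients at machine
precision relative to the trace magnitude) and return an empty train.

Segmentation operates on a temporal summary image — per-pixel 95th minus
5th percentile by default — so silent cells are invisible by construction.
"Number of cells detected" therefore means active, segmentable cells; this
matches how per-cell frequency is defined here (events pooled over all
positions of a well, divided by total detected cells, never averaged per
position). Whether silent-but-visible cells should count is unknowable from
the assay description; the summary-image semantics makes the package's
choice explicit.

## Statistics

The Mann–Whitney U statistic is computed from rank sums with midranks for
ties. For `n1 × n2 ≤ 100` the one-sided p-value is exact under the
permutation distribution of group labels: a rank-sum counting recursion
(identical to full enumeration) when the pooled sample is tie-free, explicit
enumeration of all label assignments when ties are present. Larger samples
use the normal approximation with tie-corrected variance and continuity
correction. The exact path is validated in the test suite against a
brute-force enumeration oracle that shares no code with the implementation,
and against the classical distribution on tie-free data.

Quartiles use linear interpolation between order statistics (R's type 7,
also the convention of the common Python plotting stack) — stated explicitly
because the quartile convention changes which points are outliers. Outlier
exclusion is single-pass: fences at q1 − 1.5·IQR and q3 + 1.5·IQR are
computed once and not re-derived after exclusion, so a second pass may
exclude more; a regression test pins this semantics. Whiskers sit at the
extremes of the kept values. Significance stars use strict inequalities at
0.05, 0.005, 0.0005 and 0.00005, so p = 0.05 exactly earns no star.

Technical replicates are the statistical unit. By default they are pooled
across biological replicates for testing raw values (10 vs 10 wells in the
2 × 5 design), while fold changes are always computed within biological
replicate; `within_biological = TRUE` tests each replicate separately for
users who prefer the stricter unit.

## Pipeline, determinism and problem sizes

`run_all()` executes generate → viability → neurite → activity → stats on a
seeded configuration; every per-well seed derives from the master seed, so
identical configurations give bit-identical images, tables and CSVs. Stage
outputs are cached keyed on a configuration digest, since calcium stacks
dominate runtime. The manifest records the configuration snapshot, package
version, timestamps and an MD5 checksum of every output file.

Validation problem sizes were chosen to exercise the full design while
remaining desk-scale: 200 counting fields of 80 cells; one complete
experiment (6 densities × 2 conditions × 2 biological × 5 technical
replicates, 3 fields per well — 120 wells); 50 arbor images of 10 cells at
200 µm each; 200 two-minute traces at 32 Hz for detection scoring plus 100
noise-only traces; 2,000 null simulations for the test's size and 100
simulated experiments for its power. The activity assay writes full movies
only on request (`assays = "activity"`); a 2-minute 32 Hz stack is ~60 MB in
memory per position, and the detection properties are equally well probed at
trace level.

## Known limitations

- The generator's clean-field assumptions (flat illumination, isolated
  Gaussian nuclei, no debris) mean recovery tolerances here are lower bounds
  on real-data error, not estimates of it.
- The declumping heuristic splits touching pairs but will undercount dense
  clumps of 3+ nuclei whose distance-transform peaks merge.
- The skeleton length metric inherits an angle-dependent bias bounded by
  ≈8%; sub-pixel tracing would be needed to do better.
- Spike detection reports transient events, not underlying action
  potentials; bursts faster than the refractory interval (0.25 s) merge.
- No multiple-testing correction is applied across densities or measures,
  matching the assay convention this package reproduces; users comparing
  many conditions should correct externally.
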