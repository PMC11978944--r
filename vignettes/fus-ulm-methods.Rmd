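---
title: "Methods: combined fUS + ULM analysis on synthetic ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: combined fUS + ULM analysis on synthetic ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusulm)
```

## Overview

`fusulm` implements the analysis chain of a combined transcranial functional
ultrasound (fUS) and ultrasound localization microscopy (ULM) experiment:
scan timing/geometry modelling, SVD clutter filtering and power Doppler,
microbubble localization–tracking–rasterization, Fourier ring correlation
(FRC) resolution estimation, voxel-wise GLM activation mapping with
ΔCBV/rCBV quantification, and group-level correlation of the functional
response with microbubble speed. Because no animal data ships with the
package, a synthetic-data module generates every input with known ground
truth; this vignette documents the models, the defaults and their units,
the numerical choices, and what the synthetic tests do and do not show
about real data.

## Scan timing and geometry

The probe model is four 64-element linear sub-arrays (15 MHz, 0.11 mm
pitch) spaced 2.1 mm apart, stepped by a motor along the elevation axis.
With `n_steps = 4` the step is 2.1/4 mm = 525 µm and 4 arrays × 4 stops
tile 16 planes spanning 7.875 mm. Two motor schemes matter:

- functional: 0.4 s acquisition / 0.2 s move, 4 positions → 2.4 s volume
  cycle, 0.42 Hz volume rate, 67% duty cycle;
- microbubble: 10 s acquisition / 1.2 s move → 89% duty cycle; over a
  1000 s recording, complete cycles allocated round-robin over 4 positions
  give `floor(89/4) × 10 s = 220 s` of imaging per plane. A truncated final
  cycle is counted as contributing nothing — the conservative convention,
  and the one consistent with the 220 s figure.

Plane coordinates are reported in mm with 0 at the first plane of the
first array; a configurable bregma offset maps them onto skull coordinates,
since no absolute origin is derivable from the hardware description alone.
Rates are stored at full precision and rounded only when printed (2
decimals for Hz, nearest percent for ratios).

One stated inconsistency is deliberately surfaced rather than resolved: 10
tilted plane waves at a 4 kHz PRF imply a 400 Hz compounded rate, while the
nominal rate is 500 Hz. The frame rate is therefore a configuration value
(default 500 Hz) and `geometry_report()` flags the discrepancy.

## Synthetic data

**Vascular phantom.** Straight vessel segments grouped into `L = 4`
hierarchy levels. Defaults (chosen once as plausible mouse cortical
values): per-level speed ranges 1.5–3, 3–6, 6–12, 12–24 mm/s and diameter
ranges 10–20, 20–40, 40–80, 80–160 µm, so level-mean speeds are monotone in
level — the "speed is a proxy for vessel rank" structure the group analysis
probes. Every segment carries an evoked fraction (default 0.15 at all
levels): the steady-state fractional CBV increase under stimulation.

**Microbubble frames.** Bubbles arrive per segment as a Poisson process
(rate proportional to flow = speed × cross-section by default; a
length-proportional mode gives comparable coverage of all levels for
analyses that need slow vessels sampled), advect at the segment speed, and
are rendered as isotropic Gaussian spots (σ default 50 µm, of the order of
half the 15 MHz wavelength; tests often use 20–30 µm to keep small frames
well-sampled) with a per-track random echo phase, on 10 µm pixels at
500 Hz. Low-rank clutter (separable smooth-space × slow-time components)
and complex white noise are added on top. The generator returns the exact
sub-pixel position of every bubble in every frame, which is what makes
localization and tracking testable.

**Doppler voxel series.** Voxel baselines `B(v)` are a positive tissue
floor plus the flow-weighted vessel density; the series is
`PD(v,t) = B(v)·[1 + A(v)·x(t)]·(1 + ε)` with multiplicative Gaussian
noise (default 5%), where `x(t)` is the stimulus box-car convolved with the
hemodynamic response and rescaled to unit plateau — so `A(v)` *is* the
steady-state fractional increase. Doppler power is positive, hence the
multiplicative noise model; negative samples (possible at extreme noise)
are clipped to a small positive floor with a warning.

All generators draw from named sub-streams of one master seed
(`derive_seed(seed, name)`) and are bit-reproducible.

## Clutter filtering and power Doppler

The stack is reshaped to a space × time Casorati matrix and the `rank_cut`
largest singular components are zeroed (default 10% of the ensemble
length; the threshold is a free parameter of the method and is exposed in
the configuration). Power Doppler is the per-pixel temporal mean of the
squared magnitude, kept linear on disk; dB scaling
(`10·log10(P/max P)`) is render-time only.

## Microbubble localization, tracking, speed maps

Localization applies a matched Gaussian pre-filter (default σ 1 px) before
regional-maximum detection — without it, pixel noise dominates the
centroid and sub-pixel precision at realistic SNR is lost — then refines
each maximum by a background-subtracted intensity-weighted centroid over a
7 px window, merging maxima closer than the window into the brighter one.
The weighted centroid was preferred to a Gaussian fit for speed and
robustness; its truncation bias is below 0.1 px for PSFs up to ~2 px.

Tracking is frame-to-frame optimal assignment (a Hungarian solver written
for the package and verified against brute-force enumeration) with a
gating radius `max_link_um` per frame of gap (default 20 µm/frame ≈
10 mm/s at 500 Hz; raised to 60 µm when phantoms contain faster
arterioles), gap closing up to 2 missed frames, and a minimum retained
track length of 5. None of these values is prescribed by the method
itself; all are configurable.

Step speeds are displacement × frame rate (mm/s). An optional centered
moving average over positions (default 5 frames in the pipelines) removes
the upward bias that localization jitter induces on slow flows; for a
constant-velocity track it preserves the speed exactly, at the cost of
trimming the track ends. Rasterization interpolates each step at the 5 µm
grid resolution so fast bubbles leave no gaps; density counts interpolated
samples (conserved exactly), and the speed map averages the step speeds of
the contributing samples.

## FRC resolution

Localization events are split in two (uniform random by default; odd/even
frame blocks available), each half rasterized to a 5 µm count map, and the
normalized spectral correlation computed over iso-frequency rings out to
Nyquist. The resolution is the reciprocal of the first crossing below the
fixed 1/7 threshold (half-bit criterion available), with 3-ring smoothing
and linear interpolation of the crossing; a curve that never crosses is
reported as grid-limited at 2 × pixel with a flag. By construction the
estimate can never beat twice the rasterization grid (10 µm at 5 µm
pixels).

## GLM activation mapping

The hemodynamic response is a gamma variate `h(t) ∝ (t/τ)^α e^{−t/τ}`
with α = 3, τ = 0.5 s (peak at ατ = 1.5 s, typical of mouse cortical CBV
responses; both parameters are configurable since the method fixes no
values). The design has three columns: the convolved stimulus (unit
plateau), a centered linear drift, and an intercept; samples sit at
`t = k·dt` with `n = floor(duration/dt) + 1` rows (138 for 330 s at
2.4 s). Per voxel, OLS gives `t = β₁/SE(β₁)`, two-sided p (df = n − 3) and
a signed z score capped at |z| = 8 where p underflows; Bonferroni
correction uses the number of fitted voxels.

Quantification follows the absolute/relative distinction: ΔCBV = β₁,
rCBV = β₁/baseline, and the raw ratio stimulation/baseline is also
emitted. The baseline map defaults to the whole-series temporal mean (the
per-measurement average); note that this baseline contains response
samples, so the rCBV it yields is diluted by exactly
`1 + A·mean(x)` (≈ 14.0% for a true 15% effect under the default
protocol) — a property the tests assert in closed form. The resting
(pre-stimulus) baseline option recovers the injected steady-state fraction
itself and is what the parameter-recovery analyses report. Zero-variance
voxels are flagged and excluded from all maps.

## Group-level statistics

For each acquisition the functional maps are resampled to the ULM grid by
nearest-neighbor block assignment (each 5 µm pixel inherits its enclosing
functional voxel's value) and correlated with the speed map over a mask of
pixels that are Bonferroni-significant *and* carry at least one track
sample (a whole-field mask is available; the method itself does not state
which was used). Per-acquisition Pearson r values are Fisher-transformed
and tested for zero median with the Wilcoxon signed-rank test — exact null
for n ≤ 25 without ties, normal approximation with continuity correction
beyond, zeros dropped.

The headline qualitative pattern is reproduced on synthetic cohorts: with
the evoked *fraction* constant across levels, the absolute response
ΔCBV = B·A still couples to speed because the flow-weighted baseline B is
larger where vessels are larger and faster — so the ΔCBV–speed group test
is significant while the rCBV–speed test is not. For n = 10 one-signed
correlations the exact two-sided p is 2/2¹⁰ ≈ 0.00195.

## Problem sizes and limitations

The shipped analyses run on desk-scale scenes chosen once: 1.5–2 mm plane
patches at 10 µm pixels, 0.4–1 s of 500 Hz frames, 15 × 15 to 20 × 20
functional voxel grids, cohorts of 10 acquisitions and 10 replicate
ensembles. Group-level cohorts build their speed maps by running the
tracker and rasterizer on ground-truth localizations with 1 µm jitter
rather than re-rendering and re-filtering frames for every acquisition;
the frame → filter → localize → track route is validated separately at
full depth.

What passing on synthetic data does **not** show: the phantom has straight
vessels, no skull aberration, no bubble disruption or aggregation, no
motion, white (not speckle) noise, and an exactly known HRF; real-data
performance depends on all of these. The synthetic bubble concentration is
a free parameter — no in-vivo per-frame density is prescribed — and
co-registration between the functional and ULM grids is exact by
construction, whereas real acquisitions require registration that is out
of scope here. OLS ignores temporal autocorrelation of Doppler noise
(deliberately: no prewhitening is part of the method), and planes are
processed independently — no 3D track linking across the 525 µm slices.
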