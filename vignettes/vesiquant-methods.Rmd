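---
title: "Methods: vesicle motility classification and organelle image quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vesicle motility classification and organelle image quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesiquant)
```

`vesiquant` packages the quantitative analyses that accompany live-cell
studies of endosome-to-TGN receptor trafficking: classification of
single-particle trajectories by their mean-squared-displacement scaling,
run-length statistics of motor-driven transport phases, and the standard
image quantifications (maximum-entropy segmentation, colocalization,
radial profiles, CTCF, degradation normalization, ratiometric pH). This
vignette explains each model, its assumptions, the tunable parameters, and
the design choices made where the underlying procedures are conventionally
left unspecified.

## Trajectory model and MSD

A trajectory is an ordered set of 2D positions (µm) at a fixed frame
interval `dt` (s). Frames must be consecutive: tracking gaps are rejected
rather than interpolated, because every lag-k MSD pair assumes equal
spacing. The time-averaged MSD uses the overlapping all-pairs estimator,

$$\mathrm{MSD}(k\,dt) = \frac{1}{n-k}\sum_{i=1}^{n-k} |r_{i+k} - r_i|^2,$$

which maximizes the number of displacement pairs per lag. Long lags average
few pairs and are dominated by noise, so the power-law fit uses only lags up
to `max_lag_fraction` (default 0.25) of the track length. The fit is
unweighted ordinary least squares of `log(MSD)` on `log(lag)` in natural
logarithms; the intercept `C` is reported in that convention. Zero-MSD lags
(motionless stretches) carry no exponent information and are dropped; a
track with fewer than two positive-MSD lags is flagged degenerate and
classified non-processive, the limiting case of a motionless particle.

## Classification thresholds

Tracks of at least `min_frames = 25` frames enter the analysis (the
boundary is inclusive). The fitted exponent α classifies each track with
the boundaries exactly as printed in the operational definition: α > 1.45
processive, 1 ≤ α ≤ 1.45 diffusive (both endpoints diffusive), α < 1
non-processive. These are decision constants, not fitted parameters; the
test suite locates both boundaries by bisection to machine precision.

A consequence worth knowing when interpreting class fractions: for a purely
Brownian track the per-track estimate of α is centred at 1 (slightly below,
because the log transform biases noisy long-lag MSD values downward) with a
spread of roughly ±0.16 at 100 frames. The diffusive band therefore
captures only about half of a Brownian population, the rest falling in
non-processive. This is a property of any per-track exponent classifier
with a boundary at α = 1, not of this implementation; ensemble-mean α over
hundreds of Brownian tracks is within a few percent of 1, and directed or
confined populations classify essentially perfectly. Tests assert exactly
these attainable statements.

## Active/passive phase segmentation

The phase segmentation the original motility assays rely on is performed by
unpublished tracker-side code, so the algorithm here is the package's own,
stated in full:

1. **Window votes.** Every rolling window of `phase_window = 10` frames is
   fitted for a local exponent (lags up to half the window); a window votes
   "active" when its exponent exceeds `phase_alpha_active` (default: the
   processive threshold, 1.45). Each frame takes the majority vote of the
   windows covering it; ties are passive. Runs shorter than
   `min_phase_frames = 3` are absorbed into their neighbours.
2. **Gap splitting.** Brief pauses bridged by the vote smoothing are
   recovered by a changepoint test: an active run is split into
   active/passive/active segments where the three-segment step model beats
   the single-run model by a BIC-style margin (penalty `10 log m` on the
   profile Gaussian log-likelihood of the steps; active steps are modelled
   as Gaussian about a mean step vector, passive steps as zero-mean).
   Per-segment variances are floored at 5% of the track's mean squared step
   so short collinear stretches cannot claim unbounded likelihood.
3. **Boundary refinement.** Each phase boundary is relocated to the
   maximum-likelihood changepoint within one window of the voted position;
   window votes alone blur boundaries by several frames, which matters
   because a 2-frame error on a 30-frame run is already a 7% run-length
   error.
4. **Validation.** Each active run is re-examined in isolation: it must be
   at least 5 frames, sustain a local exponent above the threshold, and be
   nearly straight (net/path displacement ratio ≥
   `phase_straightness_min = 0.8`). Short random-walk excursions
   occasionally mimic runs under the exponent criterion alone; their
   straightness rarely exceeds 0.8 (about 1% of 7-frame Brownian segments),
   while directed runs with realistic localization noise sit near 1.

Tracks shorter than the window collapse to a single phase whose state
follows the whole-track classification. On simulated state-switching
cargo (1 µm/s runs, D = 0.02 µm²/s pauses, mean dwell 40 frames, 10 nm
localization noise) over 90% of recovered active phases have run lengths
within 10% of the ground-truth net displacement of the matching true run.

**Run length** is the net Euclidean displacement between an active phase's
endpoints, not the summed path length: net displacement reads as transport
distance and is robust to localization noise, whereas path length grows
without bound with noise. The path-length variant is available via
`measure = "path"`.

## Synthetic trajectory generator

The generator provides the ground truth every motility test reads.
Stationary, ballistic, Brownian (independent Gaussian axis displacements of
variance `2 D dt`), confined (Brownian reflected radially at a circle) and
two-state switching motion (per-frame Markov chain; active = ballistic with
a heading redrawn at each activation, passive = Brownian) are supported,
with additive i.i.d. Gaussian localization noise per coordinate. All draws
flow from one seeded generator, so identical arguments reproduce identical
populations bitwise; the caller's RNG state is saved and restored.

Default study conditions were chosen once to be realistic for vesicular
cargo imaged by spinning-disk or SIM time lapse: speeds near 1 µm/s
(dynein-range), passive diffusion 0.02–0.1 µm²/s, confinement radii a few
hundred nm, mean state dwell tens of frames, and 10 nm localization noise.
The localization precision of any particular instrument is not claimed;
`localization_noise_sd` is a free parameter. The generator does not model
photophysics (blinking, bleaching), 3D motion, or detection/linking errors —
passing tests therefore validate the estimators on idealized motion, not
the upstream tracking software.

## Maximum-entropy threshold and morphometry

`kapur_threshold()` builds a 256-bin equal-width histogram over the
observed min–max range (the ImageJ convention for non-8-bit data) and
returns the boundary maximizing the summed Shannon entropies of background
and foreground; ties break toward the lowest threshold, and a constant
image is a signalled error rather than a threshold. The implementation is
validated against an exhaustive brute-force maximizer on random histograms.

`segment_particles()` labels the supra-threshold mask by connected
components (8-neighbour by default, the ImageJ Analyze Particles
convention; 4-neighbour available and cross-checked against
`EBImage::bwlabel`), discards components below `min_area_px` (default 1),
and reports areas as pixel counts × `pixel_size²` with 0-based pixel-center
coordinates. No watershed splitting of touching organelles is attempted;
the size/circularity filters of interactive particle analysis are exposed
as plain arguments rather than reproduced as defaults.

## Colocalization

Pearson's r is the product-moment correlation of raw intensities; Manders
coefficients are the thresholded variants: M1 is the fraction of channel-A
intensity (over A's supra-threshold pixels) residing where both channels
are supra-threshold, M2 symmetrically. This construction is bounded in
[0, 1] without clamping and reduces to the classic coefficients at zero
thresholds. A formulation that sums all A intensity under the B mask in the
numerator can exceed 1 and was deliberately not used. Note the documented
asymmetry: M1/M2 are invariant to positive rescaling of the
non-denominator channel only if its threshold scales along.

`coloc_pipeline()` applies per-channel maximum-entropy thresholds, then
computes r and M1/M2. Whether the study-style PCC is taken over the whole
cell or only the thresholded mask is ambiguous in common practice, so both
modes exist: `union_mask` (default; raw intensities over the union of the
two masks) and `whole_image`. The mode and thresholds are recorded in the
result. One degenerate corner is worth noting: on a noiseless pair of
identical binary-like channels the union mask has constant intensity and
masked PCC is undefined (a signalled error); whole-image mode is the
appropriate choice there.

## Radial and rim profiles

`radial_profile()` integrates intensity over concentric equal-width rings
(half-open, lower edge inclusive) about a center and normalizes by total
in-circle intensity, matching "normalized integrated intensity" semantics;
a per-ring mean variant is available since the interactive Radial Profile
tool averages rather than integrates. Refining rings and re-aggregating
pairs reproduces the coarse profile exactly, and profiles are invariant
under joint translation.

`ring_profile_from_rim()` measures distance from the nuclear rim, not the
nuclear centroid: a Euclidean distance transform from the rim contour
(via `EBImage::distmap`) assigns each cytoplasmic pixel its distance to the
nearest rim pixel, distances are binned in `ring_width` increments (5 µm in
the mitochondria-redistribution assays), and ring sums are normalized by
total cell intensity — the published normalization. Because the nucleus is
excluded from the rings but included in the normalizing total, fractions
sum to 1 only when the nucleus carries no signal; this is intentional and
documented. Pixels beyond the last full ring accumulate into a final
partial ring flagged in the result.

## Scalar intensity assays

* `ctcf()` evaluates `integrated density − cell area × mean background`
  (ImageJ Measure conventions: area in pixels, background per pixel).
  Negative values are reported with a warning, never clamped.
* `degradation_fractions()` normalizes a pulse-chase time course to the
  time-0 pulse; it is scale-invariant by construction.
* `fit_ph_calibration()` fits the 340/380 excitation ratio linearly on
  buffer pH. The dye response over a wide range is sigmoidal, but
  calibration and extrapolation here operate on the narrow acidic window
  (pH 4–6) where a line is adequate; linearity is an assumption, stated,
  and the residual standard error is reported. `ph_from_ratio()` inverts
  the line and flags extrapolation beyond the calibrated range rather than
  suppressing it.

## Numerical choices and degenerate inputs

Throughout, degenerate data raise classed conditions
(`vesiquant_degenerate`) distinct from argument errors
(`vesiquant_invalid`); nothing silently returns 0. Tie-breaks are fixed:
classification boundaries exactly as printed (1.45 excluded from
processive, 1.0 included in diffusive), Kapur ties to the lowest threshold,
frame-vote ties to passive. Histogram bins, ring intervals and run-length
bins are all half-open with the lower edge inclusive.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` use population sizes a desk-scale
study would: 200-track populations per motion regime, 500-track Brownian
ensembles for exponent calibration, 40 switching tracks of 160 frames for
run-length recovery, 100 random histograms/tracks for oracle equivalence,
512² px fields with up to 200 puncta for colocalization, and 100-seed
repeats for calibration-noise recovery. These sizes give the stochastic
checks comfortable margins over their thresholds while keeping a full run
in tens of seconds.

## Known limitations

* The phase segmentation is a principled stand-in, not a reconstruction of
  the unpublished tracker-side algorithm; its parameters are exposed in
  `classifier_config()`.
* Per-track exponent classification near α = 1 is intrinsically noisy (see
  above); population fractions, not single-track labels, are the reliable
  readout for diffusive cargo.
* Image assays are 2D single-plane; no 3D stacks, deconvolution, Costes
  randomization, or object-based colocalization.
* The pH calibration is linear over pH 4–6 only; extrapolation outside the
  buffer range is flagged.
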