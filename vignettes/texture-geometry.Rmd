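---
title: "Methods: texture statistics, cortical responses, and discriminability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: texture statistics, cortical responses, and discriminability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, parameter choices, and numerical
conventions behind `texgeom`, and states precisely what the synthetic-data
generators emulate — and what they do not — so that the meaning of a passing
test suite is clear.

## Stimuli

A stimulus image is a square grayscale matrix with a pixel scale
(`pixels_per_degree`) tying it to visual angle. All images are normalized to
mean luminance µ = 0.5 and RMS contrast σ = 0.15 by z-scoring pixel values;
the z-score uses the population (ddof = 0) standard deviation, as do all
image moments in the package. Scrambles are produced by keeping the Fourier
amplitude spectrum and replacing phases with those of a seeded Gaussian-noise
image. Because the noise image is real, its phase field is Hermitian-odd and
the scramble is real by construction; the DC term is copied from the source,
so the mean is preserved exactly and the amplitude spectrum to ~1e-15
relative error. Rotation by 90° is an exact array permutation, never an
interpolation.

Band rescaling iteratively magnifies an image (trigonometric interpolation
of the central crop, so no interpolation harmonics are created) until at
least 95% of its non-DC Fourier amplitude lies at or below 0.5 cycles per
degree, the upper edge of high mouse spatial-frequency sensitivity. Because
stimulus crops are aperiodic, coverage is measured on a Hann-windowed
spectrum; without tapering, the wrap-around discontinuity leaks amplitude
across all frequencies and the criterion is unreachable even for smooth
images. The raised-cosine vignette has unit gain inside the central plateau,
a half-cosine ramp over the outer `transition` fraction (default 0.2) of the
radius, and returns the background level µ outside; it never increases
|pixel − µ|.

## Steerable pyramid and the 740-coefficient inventory

The pyramid is built in the frequency domain as a tight frame at full
resolution: raised-cosine radial filters with one-octave log-frequency
transitions split the spectrum into a highpass residual, four octave-spaced
band levels, and a lowpass residual; `cos³` angular windows restricted to a
half-plane make the four oriented bands analytic, so band magnitudes are
local energy envelopes. Tightness gives reconstruction to machine precision
and an exact energy identity (residuals plus twice the complex-band energy).
Keeping all bands at full resolution makes periodic-shift invariance of
every statistic exact; statistics at scale *s* use lags strided by 2^(s−1)
pixels, which for these band-limited subbands equals working on the
critically downsampled band. Boundary handling is circular throughout.

The Portilla–Simoncelli vector contains exactly 740 coefficients in four
groups (4 scales, 4 orientations, 7-pixel neighborhood):

| group | count | contents |
|---|---|---|
| marginal | 2 | pixel skewness and kurtosis (population moments; kurtosis is the raw fourth standardized moment). Mean and SD are equalized upstream and excluded. |
| spectral | 18 | RMS magnitude (root band energy) of the 16 oriented bands; variances of the highpass and lowpass residuals. All are exact functionals of the amplitude spectrum, so a scramble matches its texture here by construction. |
| linear_cc | 240 | central 7×7 auto-correlations of the five partial lowpass reconstructions (24 point-symmetry-unique off-centre offsets × 5 levels = 120); within-scale cross-orientation correlations of the real band outputs (6 × 4 = 24); correlations of real child bands against the real and imaginary parts of the phase-doubled parent (4 × 4 × 2 × 3 = 96). |
| energy_cc | 480 | variances of the 16 centred band magnitudes; magnitude auto-correlations (24 × 16 = 384); within-scale magnitude cross-correlations (6 × 4 = 24); cross-scale magnitude correlations (4 × 4 × 3 = 48); same-orientation two-octave ("grandparent") magnitude correlations (4 × 2 = 8). |

All auto-correlations are stored as correlation coefficients — the centre,
identically 1, is dropped and variances are carried as separate
coefficients. Two definitional choices deserve a note. First, the spectral
band statistic is the RMS magnitude rather than the mean magnitude: the mean
of an analytic-band envelope depends on the coefficient distribution's
tails, so it would leak higher-order (energy) information into the spectral
group and spectrum-matched scrambles would no longer match their textures
there. Second, skewness and kurtosis of partial reconstructions are excluded
for the same reason; the higher-order content they would carry lives in the
energy group, where it belongs.

Dimensionality reduction z-scores each coefficient across images (dropping
columns constant to numerical precision), applies PCA per group with at most
8 components, and re-z-scores the scores so the four groups are
commensurate. Component signs are fixed by making the largest-magnitude
loading positive. The marginal group (two raw dimensions) bypasses PCA. The
retained explained variance is reported per group and flagged when it falls
below 70%: on the desk-scale synthetic sets used in the tests (64-px images)
the linear and energy groups fall below that mark because sampling noise
across hundreds of correlation slots inflates their apparent dimensionality;
at 128 px the energy group clears 70%, and low-dimensional groups clear it
at every size. The flag — not silent acceptance — is the designed behavior.

Cluster geometry in a 2-D group subspace uses radius r = (σx + σy)/2
(sample SDs) and centroid distances normalized by the mean of the two radii,
which makes them invariant to global rescaling. Bootstrap CIs resample
within clusters and use the Šidák-adjusted per-comparison level
1 − (1 − α)^(1/m) (99.15% for α = 0.05, m = 6).

## Widefield pipeline

Per pixel, ΔF/F is obtained by fitting a linear trend a·t + b over time and
computing (F − (a·t + b))/b — the only reading of a "detrend and normalize
by baseline" transform in which a ramp maps to zero and the intercept is the
baseline. Pixels with |b| below 1e-3 of the mean signal are masked.
Hemodynamic correction low-pass filters the violet (calcium-independent)
ΔF/F with a 6th-order Butterworth at 5 Hz applied forward–backward (zero
phase), regresses the blue ΔF/F on it per pixel, and subtracts the fitted
component; (c, d) are reported per pixel. A constant ΔF/F offset cannot
survive the per-channel trend fit, so the generator programs d = 0 and the
regression-level tests exercise nonzero offsets directly.

Trial tensors take frames in [−500, +1000] ms around onset (frame 0 at
onset; trials extending beyond the movie are dropped with a warning), with
blanks held separately. Significance maps pair each repeat-averaged texture
exemplar with a seeded random scramble exemplar of the same family, build
the 80-point difference distribution in the [200, 400] ms window and its
counterpart in [−350, −100] ms, and report two-sided paired-t p-values per
pixel. Area d′ averages over repeats, ROI pixels, and the response window
before applying the pooled-SD standardized mean difference across the 80
texture and 80 scramble exemplar values; the null interval applies the same
computation to a [−300, 0] ms window under seeded random class assignments
and reports the 5th/95th percentiles. Pre-stimulus windows are half-open
(onset frame excluded). d′ denominators use sample variances; the statistic
is invariant to common affine rescaling.

## Two-photon pipeline

Traces are neuropil-corrected with Fc = Fs − 0.7 Fn, baselined on the first
5 stimulus-free seconds, linearly detrended to a zero-mean residual, and
expressed as ΔF/F in percent. Responsive cells need a maximum per-exemplar
d′_stim = (µ_stim − µ_blank)/(σ_stim + σ_blank) of at least 1 and a maximum
repeat-averaged response of at least 6% ΔF/F in the [250, 500] ms window;
the 6% criterion is interpreted against the repeat-averaged exemplar
response. The encoding model solves the ridge problem per cell with an
unpenalized intercept, an explicit closed-form solver, five stratified and
seeded CV folds, and a 13-point λ grid log-spaced from 1e-3 to 1e3;
explained variance is the held-out 1 − SSE/SST in percent, averaged over
folds, with negative values reported as-is. The permutation threshold refits
after permuting the assignment of feature rows to stimuli — several
independent permutations pooled across cells (count configurable) — and
takes the 95th percentile of the shuffled EV distribution; exclusion of
noise cells is therefore calibrated at the nominal 5%, so tests compare the
realized exclusion fraction against a binomial confidence band rather than
a hard 95% cut. Unique explained variance refits four reduced models, each
omitting one group, for cells whose full-model EV is at least 10%.

## Population geometry and decoding

Embeddings z-score each cell across stimuli (population SD) and apply PCA on
the stimuli × cells matrix with the same sign rule as above. The binary
texture/scramble decoder is a logistic fit with a small fixed ridge penalty
(1e-3) for stability on separable data; the family decoder is an L1
multinomial fit whose penalty is chosen by an inner cross-validated grid
search on the training folds. The shared V1–LM space concatenates the
z-scored cells of both areas, fits one PCA, and projects each area by
zeroing the other's cells; since the projection is linear and applied
without re-centring, the per-area projections are exactly additive.
In k dimensions the cluster radius generalizes to the mean of the
per-component SDs, which reduces to (σx + σy)/2 at k = 2. Mahalanobis
distances use the pooled within-pair covariance with Ledoit–Wolf shrinkage
toward the scaled identity (40 points in 16 dimensions is ill-conditioned);
the shrinkage intensity is reported, and affine invariance holds up to that
shrinkage.

## Behavior

Session d′ is Z(hit rate) − Z(false-alarm rate); rates of exactly 0 or 1 are
moved by 1/(2N) before the probit transform and the adjustment is flagged.
Per-family d′ pools counts within a session and averages across sessions
(pooled-counts-then-transform within session). The training criterion scans
for the first run of 10 consecutive sessions with d′ > 1. The link table
joins per-family behavioral d′ (mean ± SE over sessions), decoder accuracy,
and energy-subspace normalized distances, reporting Spearman rank
correlations with bootstrap CIs over sessions; with constant distances the
correlation is undefined and reported as NA.

## What the synthetic data emulate — and what they do not

Texture families are envelope-modulated filtered noise: an oriented
band-pass carrier multiplied by a smooth positive random envelope raised to
the power κ ∈ [0, 1], then passed through a mild odd pointwise nonlinearity
whose strength also scales with κ. The envelope creates exactly the
magnitude correlations across positions, scales, and orientations that the
energy group measures; κ = 0 yields Gaussian images statistically identical
to their own scrambles. The envelope cutoff is specified as 5 cycles per
image so each exemplar contains a comparable number of envelope patches at
any image size (exemplar-to-exemplar ergodicity is then size-independent);
at the default 256-px size this equals 0.02 cycles/pixel. Family defaults:
κ = 0.70 (scales), 0.10 (rocks), 0.90 (honeycomb), 0.55 (plants), with
distinct orientation biases and spectral peaks. `rocks` is deliberately the
family with the weakest higher-order structure, so it sits closest to its
scrambles in the energy subspace and anchors the low end of every
downstream discriminability ranking.

The widefield generator programs two Gaussian cortical areas with linear
retinotopy, an LM:V1 texture-gain ratio of 2, an upper-visual-field bias of
the V1 texture modulation, a shared band-limited (< 5 Hz by construction,
matching the pipeline's low-pass assumption) hemodynamic artifact with
coupling c = 0.8, per-frame pixel noise of 0.2% ΔF/F (shot-noise-limited
widefield pixels pool many photons; the 1–2% hemodynamic fluctuations
dominate), and a double-exponential calcium kernel (50 ms rise, 500 ms
decay) as a generic indicator surrogate. The two-photon generator draws
per-cell weights on the 8 reduced features with the energy features an
order of magnitude stronger, rectifies trial amplitudes, shares one neuropil
trace across cells with mixing 0.7 (so neuropil correction is exact in the
noiseless case), and adds linear drift. The behavioral observer is the
equal-variance signal-detection model with an unbiased criterion.

Not emulated: optics and photobleaching, eye movements, cell segmentation,
spike-to-fluorescence nonlinearities beyond the fixed kernel, realistic
vascular geometry, non-stationary behavior within sessions, and CNN-based
texture synthesis (families here are procedural). Passing tests therefore
demonstrate that the analysis chain recovers programmed effects under its
own assumptions — correct algebra, calibration, and effect-direction
recovery — not that real cortical data would satisfy those assumptions.

## Problem sizes

The test suite and examples run at desk scale: 64-px images, 4 families × 6
exemplars × 2 rotations (96 images) for the statistics fixtures and a
320-image set (20 exemplars) for the structural checks; widefield
simulations on 8–16 px grids, using the full 1800-trial schedule where a
property (residual artifact correlation) scales with session length and
reduced schedules elsewhere; two-photon sessions with 40–50 cells and 6
repeats. Full-scale parameters (256-px images, 64-px movies, full-length
schedules) are the documented defaults of the generators themselves.

## Known limitations

* The coefficient inventory matches the documented totals but is one of
  several defensible de-duplications of the raw Portilla–Simoncelli
  parameter set; projections between inventories are not provided.
* The iterative band rescaling measures coverage on a Hann-windowed
  spectrum; images whose content is genuinely confined to the outermost
  frequencies may need a larger `max_iter`.
* The permutation EV threshold pools shuffled EVs across cells; a per-cell
  threshold variant is not implemented (the pooled variant is the one the
  downstream 1% inclusion rule consumes).
* Retained-EV flags (not errors) are the only guard against over-reduced
  groups; users analyzing unusually diverse image sets should inspect
  `ev_retained`.
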