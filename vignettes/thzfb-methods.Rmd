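---
title: "Methods: THz-TDS foreign-body detection with thzfb"
author: "thzfb authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: THz-TDS foreign-body detection with thzfb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement and the signal model

Terahertz time-domain spectroscopy records the electric field of a
sub-picosecond THz pulse after it has interacted with a sample, as a
uniformly sampled trace E(t). Organic foreign bodies such as insect
fragments absorb THz radiation more strongly than the surrounding tea
matrix (fat, protein and chitin all have broad THz absorption), and
they increase the optical path, so a contaminated sample shows a pulse
that is both *attenuated* and *delayed*. Those two effects are the
entire contrast mechanism this package exploits: attenuation separates
the classes in the amplitude spectrum, and delay separates them in the
per-pixel time of flight of a raster-scanned reflection image.

Spectral analysis uses the discrete Fourier transform of the trace,
Ẽ(ω) = A(ω)·e^(−iφ(ω)). `fft_spectrum()` returns a one-sided spectrum
in which all non-DC, non-Nyquist bins are doubled, so a unit cosine at
a grid frequency has amplitude 1; times in ps give frequencies directly
in THz. The phase is stored as the *negative* argument, the engineering
convention in which a pure delay Δt appears as a linear phase +ωΔt.
Amplitude spectra are unchanged by a delay (`|Ẽ|` is shift-invariant),
which is why classification features are built from A(ω) and the delay
information is exploited separately by the imaging arm. No window
function is applied by default (a Hann window is available as a flag):
the synthetic pulses decay to numerical zero well inside the record, so
leakage control is not needed for the package's own study, while a
measured trace with a truncated echo may benefit from the window.

Discrimination uses the 0.3–1.0 THz band by default (`band_select()`,
closed interval). Below ≈0.3 THz the classes nearly coincide; above
≈1.0–1.2 THz the single-cycle pulse carries little energy and the noise
floor dominates. The alternative 0.3–1.2 THz band is one configuration
flag away (`thzfb_config(band = c(0.3, 1.2))`).

## What the synthetic generator emulates — and what it does not

No measured THz dataset for this problem is publicly deposited, so the
package ships a seeded phenomenological generator that reproduces the
*statistical structure* the analysis relies on, together with the
ground truth needed to score it:

* **Pulse.** A single-cycle THz pulse is modeled as the first
  derivative of a Gaussian, rescaled so its positive lobe peaks at
  exactly `amplitude_scale`. Defaults: time axis 0–40 ps with 2048
  points (sub-0.02 ps resolution; Nyquist ≈ 25 THz, far above the
  analysis band), tea pulse centred at 10 ps with width 0.5 ps and unit
  amplitude.
* **Class contrast.** The insect class uses `amplitude_scale = 0.6`
  and `delay_shift = +0.8 ps`. The generator *enforces* this direction
  (insect weaker and later than tea) and refuses contradictory models,
  because the downstream accounting assumes it. A 25 %-insect mixture
  tablet can be emulated by interpolating the two models.
* **Baseline drift.** Scattering at medium boundaries produces a slow
  additive drift. Each sample draws a degree-3 polynomial (coefficients
  ~ N(0, drift_sd²) on the normalized axis) plus one sinusoid with
  period uniform in [t_max/2, t_max]. The default `drift_sd = 0.05`
  makes the drift peak-to-peak ≈ 15 % of the tea pulse peak — large
  enough that baseline removal is a meaningful step, small enough that
  the study stays solvable. By construction all drift content lies well
  below the pulse's own spectral band.
* **Noise and speckle.** White Gaussian noise with sd = 1 % of the tea
  peak; image cubes additionally get per-pixel multiplicative lognormal
  speckle (σ = 0.1 on the log scale) emulating reflection off randomly
  oriented leaves.
* **Populations.** The default dataset has 88 + 88 samples with a
  deterministic stratified calibration fraction of 125/176, realizing
  the classic two-population design of 125 calibration and 51
  prediction samples. The split is stored with the data so every model
  in the study grid sees identical populations.
* **Ground truth.** Every trace keeps its noise-free drift, pulse and
  noise realization (`trace = pulse + true_baseline + noise` exactly);
  every cube keeps its per-ellipse implant masks and the programmed
  delay. All randomness flows from one explicit seed through a named
  sub-seed derivation, so identical seeds give bit-identical outputs.

The generator is deliberately *not* a physical-optics simulation: no
Fresnel reflection, no Fabry–Pérot etalon ringing, no
frequency-dependent absorption line shapes, no tablet-thickness
covariate, no humidity lines. Consequently, passing the package's tests
demonstrates that the algorithms do what they claim on data with the
assumed structure (additive smooth drift, multiplicative attenuation,
rigid delay, white noise) — it does not certify performance on measured
spectra, where scattering is frequency-dependent and the two classes
are far less cleanly separated. Under the default synthetic contrast
the study grid saturates at 100 % accuracy; the corrections' value
shows up in the ground-truth recovery benchmarks and in harder
configurations (weaker contrast, stronger drift), not in the headline
grid.

## Baseline correction

All three estimators decompose a signal y into a slowly varying
baseline and the structure above it. Two are iterated weighted
Whittaker smoothers; the third is a sparsity-based decomposition.

**Whittaker core.** `whittaker_smooth()` solves
(W + λDᵀD) z = W y, with D the order-d finite-difference matrix
(d = 2 by default). The system is banded; it is assembled sparsely and
solved by sparse Cholesky, so the cost is linear in the signal length
and the result is the exact minimizer of
Σᵢ ωᵢ(yᵢ−zᵢ)² + λ‖Dz‖². The test suite verifies equality with a dense
normal-equations solve to 1e-9 and minimizer optimality against random
perturbations.

**AsLS.** Weights start at 1 and are re-derived after each smoothing
pass as ω = p where y > z and ω = 1 − p where y ≤ z, with p = 0.01 by
default (the conventional range is 0.001–0.1) and λ = 1e5. Iteration
stops when the weight vector stops changing (`tol = 0`, i.e. exact
equality — weights take only two values, so this is a natural fixed
point) or at `max_iter = 50`. The p = 1/2 case collapses to the
symmetric smoother, which the tests exploit as a sanity anchor.

**AirPLS.** At iteration t the negative-residual vector d (the values
yᵢ − zᵢ < 0) drives both the stopping rule and the reweighting: the fit
stops when |d| < 0.001·|y| (L1 norms — the rule needs a scalar, and the
L1 norm matches the additive way d accumulates), points at or above the
baseline get weight exactly 0, and points below get
ω = exp(t·(yᵢ−zᵢ)/|d|). The exponent argument is negative, so weights
lie in (0, 1] and shrink with the iteration count for points far below
the baseline. An all-zero |d| is treated as converged; otherwise the
next weighted system would be singular (the difference penalty
annihilates constants).

**BEADS.** The signal is modeled as y = x + f + w: sparse peaks x with
sparse first and second differences, a low-pass baseline f, and noise
w. A zero-phase banded high-pass filter H = BA⁻¹ (order 1, normalized
cutoff 0.006 by default) separates the baseline band from the peak
band; an asymmetry ratio r = 6 penalizes negative excursions of x six
times more than positive ones, appropriate for non-negative amplitude
spectra. The non-differentiable |·| penalties are smoothed at
δ = 1e-6, exactly the two-branch majorizer form: each
majorization–minimization step builds the diagonal majorizers
Ψ = (1+r)/(4·max(|x|, δ)) and Λᵢ = 1/max(|Dᵢx|, δ), forms
M = 2λ₀Ψ + Σᵢ λᵢ DᵢᵀΛᵢDᵢ, and solves one banded system
x ← A(BᵀB + AᵀMA)⁻¹d with the pre-iteration vector
d = BᵀB A⁻¹y − λ₀Aᵀ(1−r)/2·𝟙. The regularization weights default to
λ₀ = 0.5a, λ₁ = 5a, λ₂ = 4a with a = 2 % of the signal's peak
amplitude, following the method's published defaults, which scale the
penalty to the data rather than fixing absolute numbers. The MM tail is
sublinear near the δ-smoothed kink, so the iteration stops when the
relative step falls below 1e-3 (changes at that level are far below any
realistic noise floor) or at 30 iterations, with a warning in the
latter case. The reported baseline is f = y − x − H(y − x) and the
noise w = H(y − x), so x + f + w reconstructs y *identically* — a
bookkeeping invariant the tests assert at 1e-10 relative.

**Where correction is applied.** `run_study()` corrects the one-sided
amplitude spectra (row-wise over samples) before band selection. This
is the right domain for these estimators: an amplitude spectrum is a
non-negative bump over a smooth scattering background, matching the
positive-peak assumption built into the asymmetric weight rules. The
raw time traces are *bipolar* — the pulse has equal positive and
negative lobes — and an asymmetric estimator run directly on them will
dive into the negative lobe and corrupt the pulse. A `correction_domain
= "time"` switch exists for signals whose time-domain shape is
predominantly positive, and the baseline-recovery benchmarks
accordingly use drift plus a positive peak of the pulse's height and
width as their test signal.

No automatic λ selection is provided; the defaults are documented,
config-overridable, and recorded as provenance in the corrected set's
metadata.

## Classification and accounting

**KNN.** `knn_fit()` stores the calibration data verbatim (a lazy
learner); `knn_predict()` votes among the k Euclidean-nearest
calibration rows. k = 3 by default — small enough to stay local, odd to
avoid most ties in a two-class problem. Remaining vote ties are broken
by the class of the nearest tied neighbour, then by the lowest class
index; distance ties are broken by class index. Every rule is
deterministic, so reports are reproducible.

**PLS-DA.** Labels are dummy-coded 0/1 (first factor level = 0),
features and response are mean-centered, and latent components are
extracted sequentially: each weight vector is the covariance direction
between the feature residuals and response residuals, scores are
projected out of both, and the accumulated decomposition collapses to
one regression vector. Features are centered but *not* scaled to unit
variance: amplitude magnitude is precisely the discriminative signal,
and autoscaling would inflate noise-floor variables. The class cut is
at response 0.5, with the boundary itself assigned to class 0 (a fixed
tie rule). The component count is chosen by stratified 5-fold
cross-validation on the calibration split (seeded fold assignment,
capped at 10, ties to the smaller count). At full rank the regression
vector equals the least-squares dummy regression, and the
implementation is cross-checked in the tests against an independent
latent-variable implementation (mixOmics) to 1e-8.

**Accounting.** `evaluate()` reports, per population, the
misclassification count, the accuracy 100·(1 − m/n) rounded *half-up*
to two decimals (base R's round-half-even would disagree with
conventionally printed tables on exact halves), and the 2×2 confusion
table. The study grid (`run_study()`) always contains the eight
{KNN, PLS-DA} × {No, AirPLS, AsLS, BEADS} cells, evaluated on one
shared dataset and split, and embeds a hash of its configuration.

## Time-of-flight imaging

A reflection cube holds one waveform per raster position (default
step 0.2 mm). Pixel indices are 1-based (row, col) with the origin at
the top-left — the R-native convention; physical coordinates are
(index − 1) × step.

* `grayscale_map()` reduces each pixel to a scalar; the default `peak`
  (max |E(t)|) is the simplest statistic consistent with the physics —
  insect bodies attenuate the reflection, so they appear dark. Peak-to-
  peak and energy variants are available.
* `delay_map()` returns each pixel's pulse-arrival time: the discrete
  argmax of |E(t)| refined by 3-point parabolic interpolation
  (sub-sample accuracy at negligible cost, with the refinement clamped
  to ±half a sample); an all-zero pixel gets the first sample time by
  convention.
* `window_grayscale()` clamps to [lo, hi] and rescales to [0, 1]. A
  narrow window bracketing the insect reflectance level saturates the
  tea background and stretches the implant contrast — the digital
  equivalent of narrowing an instrument's display range. The default
  study window (0.45, 0.85) brackets the attenuated insect peak
  (≈0.6 × speckle) and saturates the tea level (≈1.0 × speckle).
* `detect_foreign_bodies()` thresholds *below* (insects are dark),
  using Otsu's threshold on the windowed map by default
  (deterministic and parameter-free), cleans with a 3×3 morphological
  opening, labels 8-connected components, and gates each component on
  area ≥ 20 px, eccentricity ≤ 0.97 and solidity ≥ 0.5 — gates that
  accept worm-like elongated blobs while rejecting single-pixel noise
  and line artifacts. Component eccentricity comes from second central
  moments (with the 1/12 per-pixel variance term so single-pixel rows
  do not degenerate) and solidity from the pixel count inside the
  convex hull of the component's pixel centers.

Morphological opening and Otsu thresholding are delegated to EBImage;
connected-component labeling is implemented in-package because the
required connectivity is 8-fold. Instrument grayscale units are
arbitrary: the generator makes no attempt to reproduce any particular
device's 68–1272 scale, only the windowing mechanism itself, which is
scale-equivariant.

## Numerical choices and degenerate inputs

* Banded/sparse solves throughout (Matrix); equality with dense solves
  is asserted in tests rather than assumed.
* Signals shorter than diff_order + 1 (or 8 for BEADS) raise
  invalid-argument errors — never silent truncation.
* All-zero weights with λ = 0 raise a singular-system error.
* Traces must be uniformly sampled within 1e-9 relative; band selection
  uses a 1e-9 relative tolerance so closed intervals behave on floating
  grids.
* Replicate averaging requires bit-identical time axes.
* The empty-band, empty-split, one-class, rank-deficient and
  dimension-mismatch cases each raise classed errors tested explicitly.

## Problem sizes

The shipped tests and the acceptance script use the package's default
study sizes: 176 traces of 2048 points, ten replicate seeds for the
stochastic checks, and a 96 × 96 × 512 reflection cube (desk-scale; the
generator caps nothing, but full bench scans of millions of pixels are
out of scope for a synthetic benchmark).

## Known limitations

* The generator's separability is optimistic: with a 0.6× amplitude
  contrast and 1 % noise the default grid saturates at 100 % accuracy,
  so the corrected-vs-uncorrected comparison in the default study
  mostly shows ties rather than gains.
* AsLS/AirPLS assume predominantly positive peaks; they are not
  suitable for raw bipolar pulse traces (see above).
* PLS-DA is binary only; no probabilistic calibration of the response
  is attempted.
* No material-parameter extraction (refractive index, absorption
  coefficient) and no phase unwrapping: the package classifies and
  localizes, it does not characterize.
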