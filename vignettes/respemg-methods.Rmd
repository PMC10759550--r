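---
title: "respemg: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{respemg: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respemg)
```

## The problem

Respiratory surface EMG measures the electrical activity of the
respiratory muscles through skin electrodes. The useful signal is small —
breath-modulated bursts of roughly 1–10 µV whose spectral content lies
mainly between 25 and 250 Hz — while the electrocardiogram projected onto
the same electrodes commonly exceeds it by orders of magnitude, on top of
baseline wander from cable and electrode motion, 50/60 Hz mains pickup and
broadband amplifier noise. All quantities of clinical interest (activity
amplitude and its normalizations, EMG-time product, onset/offset timing
against the ventilator, spectral fatigue indices, conversion to muscle
pressure) are computed downstream of artifact removal, so every filtering
choice propagates into them. `respemg` therefore (a) implements the three
standard cardiac-artifact strategies side by side, (b) records every
resolved parameter as provenance that re-executes deterministically, and
(c) ships a synthetic generator with complete ground truth so that each
stage of the chain is tested against a known answer.

## Signal model and the synthetic world

The generator models clean respiratory sEMG as zero-mean Gaussian noise
band-passed to 25–250 Hz (4th-order Butterworth magnitude, zero phase) and
multiplied sample-wise by a non-negative activation profile. The default
activation is a raised cosine: rise from 0 to the peak over the
inspiratory time (duty cycle × cycle duration), cosine decay over 25 % of
the cycle, zero elsewhere; a trapezoid variant is available. The
activation is scaled so that the in-breath 250 ms RMS matches the
requested peak (default 5 µV, the middle of the physiological range).

Contamination is additive: a PQRST train built from Gaussian deflections
with fixed widths (FWHM: P 40 ms, Q/R/S 25 ms each, T 70 ms) and amplitude
ratios (0.12, −0.15, 1, −0.25, 0.3 of the R amplitude), sinusoidal
baseline wander, a mains sinusoid, and white noise. The default scene —
1000 Hz sampling, 15 breaths/min at duty 0.4, 5 µV EMG, 100 µV R-wave at
80 bpm with 3 % RR jitter, 20 µV wander at 0.3 Hz, 5 µV mains at 50 Hz,
0.5 µV white noise — reproduces the strong-cardiac-interference regime
that motivates dedicated ECG removal. The heart rate and its jitter are
this package's choice (typical resting adult values); both are exposed.

A ventilator pressure channel can be synthesized with programmable trigger
and cycling-off delays, and selected breaths can be turned into
end-expiratory occlusions in which the airway pressure deflects by
`−k_true × activation`, which is exactly the maneuver used clinically to
estimate neuromechanical efficiency.

What the generator does **not** emulate: motor-unit physiology,
within-breath spectral nonstationarity, ectopic beats and arrhythmia,
electrode motion transients, crosstalk from neighboring muscles, or a
tonic (non-zero) baseline EMG between breaths. A green test therefore
establishes correctness of the algorithms under the stated model, not
clinical performance; the zero inter-breath floor in particular is
*harder* than reality for robust scale estimation (see the threshold
discussion below).

## Filtering: zero phase everywhere

Timing parameters are corrupted by filter delays, so every filter in the
package is applied with exactly zero phase: the signal is extended by odd
(antisymmetric) reflection — continuous in value and first derivative,
hence low spectral leakage at the joints — and multiplied in the frequency
domain by the *squared* magnitude response of the named design
(Butterworth high/low/band-pass, second-order notch), the same net
response as a forward–backward (`filtfilt`) application. Consequences
worth knowing: attenuation in dB is doubled relative to a single pass, and
a short transient (the analogue of the filtfilt edge transient, e.g.
~0.6 s for the Q = 30 notch) remains at the signal edges.

Resampling is Fourier-based on the same reflected extension; downsampling
first applies a raised-cosine antialiasing taper that is flat below
0.40 × the target rate, zero above 0.50 ×, half gain at 0.45 ×, so content
below 0.4 × the new rate is preserved with amplitude error well under 1 %.

## ECG removal

**High-pass filtering** (0.5–20 Hz cutoffs for wander removal; up to
200 Hz as a brute-force data-check mode) trades EMG power against cardiac
suppression and is used alone only in the `data_check` preset, paired with
the ARV envelope.

**QRS gating** blanks a 150 ms window centered on each detected R peak
(the window covers the QRS complex plus detection error; adjust to QRS
width) and fills it with zeros, the held pre-gate value, linear
interpolation, or the median of the surrounding second. It requires a
20 Hz high-pass first so that P and T waves outside the gates are already
gone, and refuses windows that are not shorter than the median RR interval
(tachycardia). Gating is *local*: samples outside gates are bit-identical
to the input, which also means amplitude information is preserved — the
amplitude-staircase test in the suite shows per-breath amplitudes tracking
ground truth at r ≈ 0.99 through the gating preset.

R peaks come from a Pan–Tompkins detector (5–15 Hz band-pass, derivative,
squaring, 150 ms moving-window integration, adaptive dual thresholds with
search-back and a 200 ms refractory period). Two implementation details
matter: a larger integrated peak arriving inside the refractory window
*replaces* the provisional beat (the first local maximum of the integrated
waveform can precede the true apex), and the final times are refined to
the extremum of the band-passed signal within ±50 ms, which restores
millisecond accuracy.

**Wavelet denoising** uses a stationary (undecimated) transform — chosen
over the decimated DWT for shift invariance, so results do not depend on
where beats fall relative to a decimation grid — implemented as à-trous
filtering in the frequency domain with orthonormal db2 (default) or db4
filters; reconstruction is exact to machine precision. In each detail
level the coefficients *exceeding* `threshold_multiplier × σ_k` (default
4.5) are set to zero: the high-amplitude content is the contaminant here,
inverting the classical keep-the-large-coefficients convention. The
approximation band (wander, P/T remnants) is discarded entirely. The
decomposition depth follows the sampling rate, `5 + round(log2(fs/1000))`,
keeping the deepest detail band over the 10–20 Hz artifact range.

The scale σ_k required a design decision. The level's plain standard
deviation is inflated by the very spikes being removed; the robust
MAD/0.6745 collapses on burst-modulated signals whose inter-breath floor
is near zero, and the resulting low threshold clips the EMG bursts
themselves — measured on the default scene, the MAD variant destroys a
clean-EMG signal (RMS ratio 0.15) while the plain SD variant under-removes
ECG (70 % QRS suppression target just missed). The default is therefore a
3-iteration *sigma-clipped* SD: the SD is recomputed after excluding
coefficients above the implied threshold, converging to the background
scale whether or not the signal is burst-modulated. Both `"sd"` and
`"mad"` remain selectable. Known limitation, by construction: a single
global threshold per level clips the largest bursts when burst amplitudes
are very heterogeneous (the staircase test measures r ≈ 0.70 through the
wavelet preset versus ≈ 0.99 through gating) — amplitude-centric analyses
should prefer gating.

## Envelopes

RMS, ARV and rectified-median envelopes use a centered 250 ms window by
default (causal windows are available and lag by half a window), with
partial windows at the edges so envelope and signal stay sample-aligned,
and a one-sample step. Under a single large outlier the three estimators
order as median ≤ ARV ≤ RMS, which is their robustness ranking.

Fixed sample entropy is computed in 250 ms windows at a 50 ms step (a
one-sample step is needlessly expensive) and interpolated back to the
signal rate. The tolerance `r = r_mult × SD` is computed once from the
whole signal — the "fixed" that turns sample entropy into an activity
envelope: louder windows show more dynamics relative to a fixed r. The
default `r_mult = 0.25` is the midpoint of the recommended 0.2–0.3 range.
Windows where no template pair matches (undefined entropy) map to the
maximum finite value attained elsewhere and are flagged. The
implementation is verified against an independent brute-force
template-counting oracle, exactly.

Baseline correction subtracts the noise *variance* for RMS envelopes
(`√(max(env² − noise², 0))`, since powers add), and the level itself for
ARV/median/fSampEn, clipping at zero. The noise level defaults to the 5th
percentile of the envelope — a robust between-breath floor estimate.

## Breath timing

The offset rule is the common 70 %-of-peak drop, located by linear
interpolation; if 70 % is never reached before the next onset the post-peak
minimum is returned, flagged. Return-to-baseline can be emulated by
setting the onset threshold low.

Onsets are declared where the corrected envelope stays above
`onset_k × noise` (defaults: 3 × the floor, sustained 300 ms) and then
refined by a least-squares changepoint fit — flat baseline plus a
quadratic rise whose foot is analytically convolved with the envelope's
own moving window — scanned on a 10 ms grid. The refinement exists because
threshold crossing on a smooth activation rise is structurally late: with
the default scene's amplitudes the activation spends its first ~330 ms
below the noise floor.

This is also the one place where the package's own acceptance suite is
deliberately red. The target of recovering onsets to ±50 ms on the default
scene turns out to be information-limited: the smooth (zero-slope) onset,
the noise floor, and the ~250 ms correlation length of an RMS envelope of
a stochastic carrier leave roughly half a dozen independent observations
per rise from which onset time, rise time, amplitude and baseline must be
estimated jointly. Across the estimator families evaluated during
development (threshold crossing, back-extrapolation in √ and asin-√
domains, generic and window-convolved changepoint fits, full sigmoid model
fits), median errors cluster near 0.15 s on the default scene and
0.06–0.08 s even with all contamination turned off. The assertion is kept
at 50 ms, and fails, rather than being widened to match the
implementation. Downstream consequences: trigger-delay and phase-angle
columns computed from *detected* EMG onsets inherit this scatter, while
the ventilator model itself is exact (programmed delays are recovered to
within the pressurization detector's ~10 ms bias against ground-truth
onsets).

## Magnitude, Pmus and timing metrics

Per-breath amplitude is max − min over the breath, or the more robust
95th − 5th percentile difference (linear-interpolation percentiles).
Normalization divides by a maximal-maneuver reference or by the recording
maximum. The EMG-time product is the trapezoidal area under the envelope
per breath (baseline included or not); the per-time-unit variant uses
fixed non-overlapping one-minute bins keyed by breath onset.

Neuromechanical efficiency is estimated from end-expiratory occlusions as
`k = correction × |ΔPaw| / envelope peak`, with the pre-occlusion baseline
taken as the median airway pressure over the preceding 0.5 s and a minimum
deflection of 0.5 cmH2O to accept the maneuver. The correction factor
(default 0.8, range (0, 1]) *multiplies* the occlusion-derived ratio,
reducing it toward tidal-breathing efficiency, because the diaphragm is
more efficient during the isometric contraction of an occlusion; the
factor is fully exposed. Since single maneuvers are noisy, practice (and
the acceptance test) averages several occlusions. `Pmus = k × envelope`
pointwise.

Delays are signed, positive when the ventilator event follows the EMG
event; the phase angle is `360° × delay / cycle`, with the reference cycle
taken as the median detected breath period. Breaths are paired to
pressurizations by nearest onset within half a cycle; unpaired EMG breaths
are counted as candidate ineffective efforts (no asynchrony phenotyping is
attempted).

## Fatigue indices

Welch spectra (Hann window, 256-sample segments, 50 % overlap) are scaled
so the integral equals the segment variance. MNF is the spectral centroid;
MDF uses the trapezoid cumulative, exact on flat spectra. The H/L ratio
integrates 150–350 Hz over 20–46.7 Hz; when the Nyquist frequency cannot
reach 350 Hz (legal at fs = 500 Hz) the H band is truncated there and the
result flagged rather than erroring. SMR5 follows the spectral-moments
family, `M(−1)/M(5)` over a 20–350 Hz support (Nyquist-truncated,
flagged); because the fifth moment weights high frequencies, compression
*raises* SMR5 while MNF/MDF/HL fall — this opposite directionality is
asserted on parameterized spectra and on seeded simulations with
progressive band compression (25–250 → 20–180 Hz). Indices are computed on
the denoised **raw** signal per breath — never on the envelope — and by
default after wavelet (not gating) denoising, since gating removes
segments and distorts spectra. Breaths shorter than 256 samples are
skipped and counted. No fatigue cutoff values are provided: none are
established for respiratory sEMG.

## Pipelines, provenance, reproducibility

The presets mirror common practice: `data_check` (high-pass up to 200 Hz →
ARV), `gating` (20 Hz high-pass → notch → Pan–Tompkins → gate → RMS →
baseline), `wavelet` (0.5 Hz high-pass → notch → wavelet → RMS →
baseline; the go-to default), `fsampen` (entropy envelope directly on raw
data — structurally free of any ECG-removal stage), plus `custom` chains
(e.g. wavelet followed by gating of the residue). Stage order is validated
before execution. Every default is resolved into the provenance record, so
nothing is implicit; re-running a provenance file reproduces envelope
samples hash-identically, which the suite asserts. Seeds are recorded;
all generator randomness is seed-deterministic.

## Known limitations

- Onset timing accuracy is bounded as analyzed above; report phase angles
  from detected onsets with that scatter in mind.
- The wavelet route compresses unusually large bursts (global per-level
  threshold); no automatic burst protection is attempted. The multiplier
  is exposed.
- Crosstalk between muscles is out of scope (identification is visual in
  current practice), as are asynchrony phenotype classifiers, amplitude
  comparisons across patients or recordings, and fuzzy approximate
  entropy.
- EDF support covers the common subset (1 s records, int16, per-channel
  rates); EDF+ annotations are ignored.
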