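---
title: "Masseter-jaw-tongue articulation kinematics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Masseter-jaw-tongue articulation kinematics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jawkin)
```

## The scientific problem

During a diadochokinetic exercise — the fast repetition of the diphthong
[aI] — the masseter pulls the jaw-tongue structure up against gravity and
the depressors, and the changing vocal-tract geometry moves the first two
formants: jaw raising lowers F1 and raises F2. Hypokinetic dysarthria, the
speech-motor disorder characteristic of Parkinson's disease, reduces both
the amplitude and the rate of this oscillation. `jawkin` implements a
three-modality analysis of this loop — masseter surface EMG, chin-mounted
accelerometry and speech acoustics — together with a synthetic-recording
generator used to validate every stage with known ground truth.

## The projection model

Displacements of a lumped jaw-tongue reference point in the sagittal plane,
$(\Delta x, \Delta y)$ in cm, are mapped linearly onto formant deviations:

$$\begin{pmatrix}\Delta F_1 \\ \Delta F_2\end{pmatrix}
 = A \begin{pmatrix}\Delta x \\ \Delta y\end{pmatrix},
 \qquad W = A^{-1}.$$

`fit_projection()` estimates the vertical column of $A$ by
cross-correlation lag alignment followed by ordinary least squares of each
unbiased formant oscillation on the vertical displacement, the latter
reconstructed by double trapezoidal integration of the rotated, detrended
vertical acceleration. Gains are reported in the tabulated
"$\times 10^3$" convention (Hz per metre divided by 1000), so the default
generator truth prints as $a_{21} = -55.5$ and $a_{22} = 110$. In that
convention a 2 mm peak-to-peak vertical oscillation produces roughly a
111 Hz swing in F1 and 220 Hz in F2, which is the scale the model is
calibrated for; per-cm labels would put these swings three orders of
magnitude too high.

Two derived velocity magnitudes summarize articulation speed:

* **AKV** (absolute kinematic velocity): rotate the device-frame
  accelerations into the sagittal frame, integrate each component
  (cumulative trapezoid), detrend, and take the per-sample norm.
* **AFV** (absolute formant velocity):
  $|v_f| = \sqrt{H_1 \dot F_1^2 + H_2 \dot F_2^2 + H_{12}\dot F_1 \dot F_2}$
  with $H_1 = w_{11}^2 + w_{21}^2$, $H_2 = w_{12}^2 + w_{22}^2$,
  $H_{12} = 2(w_{11}w_{12} + w_{21}w_{22})$. This expansion is the unique
  quadratic form making the expression equal $\lVert W \dot F\rVert$
  sample-by-sample, and it is adopted as the package's contract
  (`quad_coeffs()` + `afv()`).

Because only the vertical displacement is observable in the standard
protocol, the fitted $A$ is completed with a synthetic-convention
horizontal column — 20% of the magnitude of the fitted vertical gains,
positive sign — before inversion. The synthetic generator uses the same
convention for its true matrix, so on synthetic data the completion is
exact; on real data it is a stated convention, flagged by the
`vertical_only` field. A useful side effect of deriving $W$ from the
regression on the *same* formant tracks that later supply $\dot F$: any
multiplicative tracking attenuation cancels between $W$ and $\dot F$, so
the AFV is robust to it.

The ECMF (electromyographic correlate of masseter force) is the detrended
cumulative integral of the rectified sEMG, preceded by a 20 Hz high-pass
against motion artifact. The proportionality constant lumping torque and
lever arm is fixed at 1: the ECMF only ever enters correlations and
regression slopes.

Amplitude distributions of AKV and AFV are 100-bin half-open histograms on
[0, 20] cm/s (0.2 cm/s bins; overflow accumulates in the top bin so
probability is conserved). Participants are scored by the Jensen-Shannon
divergence, in nats, against the arithmetic mean of the control
distributions (controls are scored against a reference that includes them;
a leave-one-out switch exists). Natural logarithms keep scores within
$[0, \ln 2 \approx 0.693]$. Cohorts are compared with Welch's t,
Kolmogorov-Smirnov and exact Mann-Whitney tests after a Lilliefors
normality screen, and feature-wise tests across the ten regression
features use the Holm-Bonferroni step-down levels
$\alpha/(m - k + 1)$.

## The synthetic generator and what it emulates

`articulation_scenario()` fixes one participant. Defaults are the study
conditions and are not tuned per experiment:

| parameter | default | rationale |
|---|---|---|
| `syllable_rate` | 2.5 Hz | typical adult [aI] diadochokinetic rate |
| `amp_y` | 0.1 cm | 2 mm peak-to-peak vertical excursion, the scale at which the linear articulatory-acoustic regime holds |
| `amp_x` | 0.05 cm | horizontal excursion half the vertical, quarter-cycle phase lead (elliptical jaw path) |
| `A_true` | columns (111, 220) and (-555, 1100) Hz/cm | vertical gains from the tabulated convention; horizontal column 20% magnitude, positive |
| `F_base` | (600, 1400) Hz | mid [a]-[I] resting formants |
| `f0` | 110 Hz | aged male-typical pitch; see the pitch note below |
| `theta` | 0.15 rad | accelerometer mounting angle |
| `noise_accel` | 2 cm/s² | accelerometer noise RMS |
| `noise_semg` | 0.1 | relative sEMG measurement noise |
| `lag_ms` | 16 ms | neuromotor-to-acoustic latency, inside the 14-18 ms range such recordings show |
| `hypokinesia` | 1 | scales amplitude *and* syllable rate |

The trajectory is a zero-mean raised-cosine syllable cycle with a 0.6/0.4
open/close duty asymmetry (the masseter pull-up is the faster phase); a
pure-sine mode exists for closed-form checks. Speech is synthesized by a
glottal pulse train through a time-varying two-resonance all-pole filter
(bandwidths 80 and 120 Hz, coefficients updated every 2 ms). The filter
cascade runs at 10 kHz internally and is interpolated up to the 50 kHz
recording rate: running resonators directly at 50 kHz crowds all poles
near $z = 1$ and their skirts visibly shift each other's spectral peaks.
The source includes 2% cycle jitter, 4% slow pitch drift and a 5%
aspiration-noise floor. These are not decorative: a perfectly periodic
impulse train has a line spectrum with *no* energy between harmonics, the
known worst case for LPC formant estimation whenever formant excursions
(here about ±55 Hz for F1) are smaller than the harmonic spacing.

**Pitch note.** Even with a natural source, LPC envelope estimation
degrades when a strong harmonic sits exactly on a formant; the default
f0 = 110 Hz places the F1 region mid-gap between the 5th and 6th
harmonics. Cohort participants draw f0 from 100-160 Hz, so individual
participants do show harmonic-sampling attenuation of their fitted gains —
mirroring the wide gain spread seen in real cohorts — while the AFV
biomarker is immune by the cancellation argument above. The generator does
not emulate female-typical pitch (about 180-220 Hz), where framewise LPC
formant tracking would need pitch-synchronous or envelope-based methods
the package does not implement; conclusions from passing tests therefore
speak to low-pitch voices.

The lag chain is injected as: masseter drive leads the vertical
acceleration by 2 ms (one sample at the effective 500 Hz rate), and the
formant tracks lag the displacement by `lag_ms`. The sEMG amplitude
envelope carries the *time-derivative* of the low-passed net vertical
force correlate on a tonic pedestal (modulation depth 0.9, never
clipping). This construction is forced by the analysis definition: the
ECMF integrates the rectified sEMG, so for the ECMF to reconstruct the
force correlate — the quantity whose 2 ms lead the pipeline must
recover — the envelope must carry its derivative. An envelope carrying
the force itself would make the ECMF its integral, a quarter-cycle out of
phase with everything. The truth block stores both the envelope and the
force correlate.

Ground-truth conservation, seeded determinism, and the linear scaling of
peak speed with `hypokinesia x amp x rate` (pure-sine mode) are enforced
by tests.

## Numerical choices

* **Anti-aliasing and decimation**: zero-phase (forward-backward)
  order-8 Butterworth low-pass at the target Nyquist frequency, then
  linear interpolation onto the coarser grid. Zero phase is essential:
  any group delay would corrupt the cross-modal lag estimates.
  Odd-reflection padding is used after removing the endpoint-connecting
  line; without that line removal, a signal ending off-zero injects a
  $2x[n]$ step whose filter transient bleeds into the interior.
* **Detrending** (`detrend()`): subtraction of a Gaussian local-mean
  trend (kernel matched to the requested -3 dB cutoff, truncated and
  renormalized at the edges). An IIR high-pass at 0.5 Hz has a multi-second
  settling transient that three successive integration stages amplify
  into errors of the same order as the displacement signal itself; the
  Gaussian estimator is zero-phase, exact on DC and ramps, and leaves
  components above five times the cutoff untouched. Its settle region is
  ±4σ ≈ 1.5 s at the default 0.5 Hz cutoff, which is why peak-based
  checks evaluate the settled interior and regressions exclude a 0.25 s
  burn-in on top of their own robustness.
* **Formant tracking**: 64 ms Hann-tapered windows every 2 ms
  (512 samples, 97% overlap at 8 kHz), pre-emphasis 0.97,
  autocorrelation LPC of order 10, root candidates kept if
  150-3500 Hz with bandwidth under 400 Hz (a 700 Hz ceiling admits the
  broad spurious poles order-10 LPC places below F2), two lowest kept as
  (F1, F2), 5-frame running median, energy-gated voicing at 5% of the
  median frame RMS, linear bridging of unvoiced gaps up to 20 ms.
* **Derivative band** : differentiation on the 2 ms frame grid amplifies
  frame-level estimation jitter by the frame rate, so tracks are
  band-limited before central differencing. The default band is adaptive:
  three times the dominant articulatory frequency of the displacement
  (clamped to 4-15 Hz), which keeps essentially all articulatory velocity
  variance at any hypokinesia level.
* **Regression matching**: the formant track is inherently smeared by its
  64 ms analysis window; the displacement regressor is convolved with the
  same Hann window before the fit, otherwise gains are biased low by the
  window's passband droop (about 5-7% at these syllable rates).
* **Lag conventions**: positive lag means the second series is delayed.
  The per-formant lags carry equal and opposite quadrature bias from the
  horizontal-motion cross-talk (the horizontal column being proportional
  to the vertical), so their mean — `lag_consensus_ms` — estimates the
  common neuromotor-to-acoustic latency; ties in the lag search resolve
  toward zero.
* **ECMF latency measurement**: a single recording's ECMF carries in-band
  phase noise from the stochastic carrier (the rectified-carrier
  fluctuation passes the same integrator as the signal), which can move
  the cross-correlation peak by a sample. `estimate_emg_lag()` pools
  correlation profiles over repeated recordings before locating the
  maximum — the usual repeated-measurement remedy.
* **Histograms**: half-open bins $[b_{k-1}, b_k)$; speeds at or beyond
  20 cm/s go into the top bin rather than being dropped. No smoothing or
  pseudo-counts anywhere: the JSD mixture dominates both arguments, so
  empty bins never produce infinities.

## Problem sizes used in the shipped validation

The test-suite and the acceptance script use 6 s recordings per
participant (about 3000 analysis frames), 8-participant cohorts per arm,
and 8 pooled recordings of 8 s for the latency measurement. These sizes
were chosen so the full validation completes in a few minutes while every
statistic it reports is stable to well within its stated tolerance across
seeds.

## Known limitations

* Formant-gain recovery degrades at pitches whose harmonics land on a
  formant; the AFV/AKV biomarkers do not (see the pitch note).
* The horizontal column of the projection is a convention on real data;
  only the vertical gains are identified by the protocol.
* The ECMF reconstructs the force correlate up to scale and up to the
  carrier-noise floor (correlations around 0.85 at these settings, not 1).
* The generator produces sustained phonation only — no pauses, no
  unvoiced segments — so the voicing gate and gap bridging are exercised
  lightly; real recordings with silences will rely on them more.
* Cohort separation under a 0.4 hypokinesia factor is far stronger than
  in real patient data (the AKV score saturates near $\ln 2$): factor 0.4
  applied to both amplitude and rate scales peak speed by 0.16, while
  real hypokinetic cohorts overlap controls substantially. Passing the
  separation test demonstrates pipeline correctness, not clinical effect
  size.

## A worked example

```{r, eval = FALSE}
sc <- articulation_scenario(duration = 6, seed = 1,
                            noise_accel = 0, noise_semg = 0)
rec <- make_recording(sc)
an <- analyze_recording(rec)
an$projection
#> Articulatory-to-acoustic projection model (vertical displacement only)
#>   a21 = -55.63, a22 = 110.4  (x 10^3; Hz/m)
#>   r21 = -0.994, r22 = 0.998; lags = 22.0, 10.0 ms; n = 2740
jsd(an$akv_dist, an$afv_dist)   # ~0.06 nats: the two biomarkers agree
```
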