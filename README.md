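# jawkin

Masseter–jaw–tongue articulation kinematics and speech biomarkers for
hypokinetic dysarthria.

`jawkin` analyzes synchronized recordings of a diadochokinetic speech
exercise (fast repetition of the diphthong [aI]) across three modalities:
speech acoustics, chin-mounted accelerometry, and masseter surface EMG. It
is aimed at speech-motor and neurodegeneration researchers who want to
relate masseter drive, jaw–tongue kinematics and formant dynamics, and to
screen for the reduced articulatory range and rate of hypokinetic
dysarthria (as in Parkinson's disease) from these signals.

## The model

Displacements of a lumped jaw–tongue reference point in the sagittal plane
map linearly onto deviations of the first two formants,

```
(ΔF1, ΔF2)' = A (Δx, Δy)',    W = A⁻¹,
```

with jaw raising lowering F1 and raising F2 (`a21 < 0 < a22`). The package
estimates the vertical gains by lag-aligned least squares between the
double-integrated vertical acceleration and the LPC formant oscillations;
two absolute-velocity magnitudes then summarize articulation speed:

* **AKV** — rotate device-frame accelerations into the sagittal frame,
  integrate, detrend, take the per-sample norm;
* **AFV** — `sqrt(H1 dF1² + H2 dF2² + H12 dF1 dF2)` with quadratic
  coefficients built from `W`, i.e. the same speed estimated purely from
  acoustics.

Their 100-bin amplitude distributions on [0, 20] cm/s are compared across
participants by Jensen–Shannon divergence (nats) against the control-mean
reference; cohorts are tested with t / Kolmogorov–Smirnov / exact
Mann–Whitney statistics and Holm–Bonferroni-corrected feature-wise tests.
The ECMF — the detrended integral of the rectified sEMG — serves as the
masseter-force correlate and leads the vertical acceleration by one sample
at the effective 500 Hz rate.

A seeded generator (`make_recording()`, `make_cohort()`) synthesizes the
full three-modality protocol — source-filter speech at 50 kHz,
device-frame accelerations with gravity and mounting angle, sEMG as
activation-modulated band-limited noise at 2.5 kHz — with a tunable
`hypokinesia` factor and a known lag chain, so every stage of the analysis
is validated against ground truth.

## A worked example

```r
library(jawkin)

sc  <- articulation_scenario(duration = 6, seed = 1,
                             noise_accel = 0, noise_semg = 0)
rec <- make_recording(sc)     # speech @50 kHz, accel + sEMG @2.5 kHz
an  <- analyze_recording(rec)
an$projection
#> Articulatory-to-acoustic projection model (vertical displacement only)
#>   a21 = -55.63, a22 = 110.4  (x 10^3; Hz/m)
#>   r21 = -0.994, r22 = 0.998; lags = 22.0, 10.0 ms; n = 2740
```

The true gains of this scenario are −55.5 and 110 (×10³, Hz/m): both are
recovered within about 1%, with correlations beyond 0.99. The per-formant
lags (22 and 10 ms) straddle the injected 16 ms neuromotor-to-acoustic
latency because horizontal jaw motion adds equal-and-opposite quadrature;
their mean, `an$projection$lag_consensus_ms`, returns 16 ms. The two
velocity biomarkers agree: `jsd(an$akv_dist, an$afv_dist)` ≈ 0.06 nats.

A full cohort study:

```r
coh <- make_cohort(n_controls = 8, n_pd = 8, hypokinesia = 0.4, seed = 7)
rep <- run_study(coh)
rep          # per-participant JSD table + cohort p-values
plot(rep)    # score boxplots by cohort and modality
```

Every hypokinetic participant scores above the control median on both AKV
and AFV, and all three cohort tests reject at the 5% level.

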