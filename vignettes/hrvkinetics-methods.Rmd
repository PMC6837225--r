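---
title: "Methods: HRV, HR kinetics and recovery analysis of RR recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: HRV, HR kinetics and recovery analysis of RR recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrvkinetics)
```

This vignette describes the models and procedures the package implements,
the choices made where practice varies, and the limits of what its tests
demonstrate.

## The data and its preprocessing

The pipeline's currency is the RR series: beat-to-beat intervals in
milliseconds, with the k-th beat placed at the cumulative sum of the first
k intervals (beat times at the *end* of each interval, zero at recording
start). The end-of-interval convention matters only when the tachogram is
resampled for spectral analysis, and it is the common one.

Artifacts in exercise recordings are dominated by two signatures: a missed
beat produces one interval roughly twice as long as its neighbours, and a
noise spike read as a beat splits one interval into two short ones.
`detect_artifacts()` codifies the standard percentage filter: an interval
strictly more than 30% longer than the reference is `artifact_long`,
strictly more than 30% shorter is `artifact_short`. Two choices were open:

- **The reference interval.** Comparing each beat to its immediate
  predecessor lets a single ectopic beat cascade — the short interval makes
  the next (normal) interval look long. The reference here is the previous
  *accepted* interval, which flags exactly the aberrant beats of a
  short/long pair and nothing downstream.
- **"Approximately 30%"** is implemented as an exact threshold of 0.30,
  exposed as a parameter; exactness is what makes the rule testable.

Correction (policy `interpolate`, the default) replaces flagged intervals
by linear interpolation between the nearest clean neighbours, preserving
beat count and recording duration — deletion (`remove`, also available)
distorts the time base the spectral resampler needs. Correction is
idempotent.

For HRV a 256-beat window of "greatest stability" is selected.
Stability is quantified as the minimum sample SD over all windows of 256
consecutive intervals (ties to the earliest window): the same statistic
family as SDNN, and the simplest definition that is exactly testable
against a brute-force scan. The window is selected per analysis phase
(rest, recovery), since autonomic state differs across phases.

## HRV metrics

Time domain, on a segment of N intervals: SDNN with divisor N−1; RMSSD
with divisor N−1 over the N−1 successive differences (as the defining
formula is printed, rather than the N−2 some software uses); pNN50 with a
strict `> 50 ms` comparison, the standard definition.

Frequency domain: the unevenly sampled (beat time, RR) tachogram is
resampled to an even grid at 4 Hz by cubic spline, linearly detrended, and
a Welch periodogram is computed with 256-sample Hann-windowed segments at
50% overlap (mean removed per segment; one-sided density). Band powers are
trapezoidal integrals over LF = [0.04, 0.15) Hz and HF = [0.15, 0.40] Hz.
At 4 Hz a 256-sample window spans 64 s, giving ~0.016 Hz resolution — three
bins inside the narrowest band edge region — while still averaging several
segments on a 256-beat recording. All settings are exposed via
`spectral_settings()` and recorded in the result's `method_meta`.

Normalized units are defined as shares of LF+HF (`lf_nu + hf_nu = 100`),
not of total-minus-VLF; published tables in this area sum LF and HF
normalized units to ≈100, which fixes the convention. When HF power is
exactly zero the LF/HF ratio is reported as `Inf` rather than a number.
No installed R package provides an averaged-segment (Welch) periodogram,
so it is implemented in the package directly against the textbook
definition; the single-tone and two-tone tests pin its calibration.

## HR kinetics

The on-transient (rest → exercise) is modelled as
Y(t) = Y_LB + A·(1 − e^{−(t−TA)/τ}) with Y(t) = Y_LB for t ≤ TA; the
off-transient (exercise → recovery) as Y(t) = Y_LB + A·e^{−(t−TA)/τ} with a
plateau at Y_LB + A before the delay TA elapses — HR need not start falling
the instant the load stops. A multiplicative off-form
Y_LB·(A·e^{−(t−TA)/τ}) + Y_LB appears in print in this literature; it is
dimensionally inconsistent (the baseline scales the amplitude term, so A
becomes a unitless fraction), and reported off-amplitudes on the order of
100 bpm are only consistent with the additive form. The additive form is
therefore the default, with `form = "multiplicative"` available for
auditing against software that uses the printed variant.

Fitting is bounded Levenberg–Marquardt (`minpack.lm::nls.lm`, ftol/ptol
1e-14) over (Y_LB, A, τ, TA), multi-started at TA ∈ {0, 5, 10} s with the
baseline initialized from the first (on) or last (off) 10 s, the amplitude
from their difference, and τ from one-third of the span; the lowest SSE
wins, ties to the smallest TA. Bounds keep the optimizer physiological
without constraining reported ranges: τ ∈ [0.1, 1000] s, TA ∈ [0, 60] s, A
free-signed. The trajectory is instantaneous HR (60000/RR) at beat times;
no pre-binning is applied, since least squares at beat resolution uses
every sample and the 5-s averaging the delta analysis needs is done there,
not here.

Diagnostics follow standard curve-fitting practice: r is the Pearson
correlation between observed and fitted values, and a fit is accepted only
when r > 0.95 — plus two guards the gate implies but does not state: a τ
estimate pinned at its bounds or an amplitude below 0.5 bpm (a flat
trajectory) marks the fit unidentifiable and not accepted, whatever its r.
`fit_quality()` adds a Wald–Wolfowitz runs test on residual signs
(systematic lack of fit gives too few runs) and a pointwise 95% confidence
band from the parameter covariance via the delta method, with parameter
CIs from t quantiles on n−4 degrees of freedom.

## Recovery deltas

Δ(x) = (mean HR over [x−5, x+5] s) − HR_peak at landmarks x = 0, 30, …,
180 s after cessation. Window means are *time-weighted* (trapezoidal over
the sampled trajectory, with interpolated values at the exact window
edges), so irregular beat spacing does not bias them; on analytic inputs
they agree with closed-form integrals to 1e-9. Three conventions had to be
fixed:

- HR_peak is the mean HR of the final 5 s of exercise, symmetric with the
  landmark windows, since no averaging window is standard for the peak.
- Landmark 0 uses [0, 5] s only: recovery windows must not mix in
  exercise beats. Beat-sampled recoveries cannot start exactly at t = 0,
  so a window start is clamped to the first available sample when that
  sample falls in the window's first half; later landmarks with missing
  data are reported `NA`.
- The first-minute benchmark flag (`hrr_classification`) is inclusive:
  |Δ(60)| ≥ 30 bpm.

Negative deltas mean HR below peak; a faster recovery gives larger |Δ|.

## Protocol schedules

Schedules are ordered stages of (duration, intensity as a fraction of the
treadmill speed at maximal oxygen uptake, kind). The presets share a 5-min
warm-up at 55% and 3-min cool-down at 50%: `hiit-4x3` interleaves 3 × 4 min
at 90% with 2 × 3 min at 60% (work, recovery, work, recovery, work — the
only ordering consistent with those counts), totalling 26 min; `hiit-30-30`
is 29 × (30 s at 100% + 30 s passive, encoded as intensity 0), totalling
37 min; `mict` is 21 min continuous at 70%, stage sum 29 min. Published
totals for the continuous protocol (32 min) and the printed total distances
are mutually inconsistent with the stated stage fractions under any single
reference speed; the module reports computed sums and does not force
agreement. `total_distance()` is Σ duration × intensity × reference speed.

## The synthetic generator

`generate_session()` builds a continuous instantaneous-HR trajectory —
rest plateau, exponential relaxation toward each stage's HR target
(target = rest HR + intensity × HR reserve) with the on/off τ and delay,
exponential recovery back to rest — converts it to instantaneous RR,
adds sinusoidal Mayer-wave (default 0.10 Hz) and respiratory (default
0.25 Hz) modulation and white noise in the ms domain, and emits beats by
integrate-and-fire: the next beat falls one current-RR after the last.
Defaults place resting HR at 62 bpm, HR reserve at 110 bpm, τ_on at 36 s,
τ_off at 100 s, and modulation depths of 30/40 ms — mid-range values for
healthy adults in exercise-HRV work. Artifacts are injected by halving one
interval and doubling the next, the short/long signature both detection
rules exercise; injected pairs are kept non-adjacent. HF/LF modulation is
attenuated in proportion to the fraction of HR reserve in use (floor 0.05,
optional but default), emulating vagal withdrawal so post-exercise spectra
shift toward LF dominance as observed in recovery data.

Integrate-and-fire on instantaneous RR was chosen over integral-pulse
frequency modulation on instantaneous rate: it is simple and exactly
invertible at desk scale, and the difference between the two is below the
pipeline's tolerances at these modulation depths.

What the generator does **not** emulate: respiratory frequency drift and
sighs, baroreflex coupling between the LF tone and blood pressure,
non-stationary ectopy bursts, and measurement quantization of real
monitors. Pipeline tests passing on synthetic data therefore demonstrate
the *estimators* are correct (they recover known truth under the stated
noise), not that real recordings meet the estimators' assumptions.

## Numerical choices and problem sizes

Noiseless kinetics recovery is tested to 1e-6 relative; with 3-bpm Gaussian
noise, mean τ̂ over 50 seeded replicates is required within ±10% of truth
(τ_on = 30 s on 301 samples, τ_off = 100 s on 601), and the 95% CI for τ must
cover truth in ≥90% of 100 replicates. Time-domain metrics are compared to
a naive loop oracle on 1000 random series at 1e-10 relative; stable-segment
selection against brute force up to 1000 beats (rolling-moment computation
guards negative variance from cancellation by clamping at zero). Spectral
fidelity uses 300-s single-tone tachograms (band purity > 95 normalized
units) and a two-tone amplitude-square split within 5%. The end-to-end
check runs a 10-subject × 3-protocol cohort (rest 300 s, recovery 240 s per
session) with per-protocol off-τ truths of 120–140, 70–85 and 95–110 s,
verifying determinism under a fixed seed and recovery of the generated
ordering; it completes in a few seconds. These sizes keep the full suite
under a minute while leaving each estimate's sampling error well inside the
asserted tolerances.

## Known limitations

- The artifact rules are ratio filters; slow drifts of ectopy that stay
  inside ±30% pass through, and model-based ectopic classification is out
  of scope.
- Phase marks (exercise onset, cessation) are supplied explicitly, as
  protocols timestamp them by design; the package does not detect
  transitions from the signal.
- Frequency-domain results depend on the stated resampling/Welch settings;
  comparisons across software should match `method_meta`.
- Group-level inference (ANOVA and friends) is deliberately left to
  external statistics tools; `summarize_cohort()` emits the tidy table they
  consume.
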