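---
title: "Harmonic pulse-spectrum analysis: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonic pulse-spectrum analysis: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsespec)
```

## The analysis in one paragraph

Continuous arterial pulse recordings — radial blood-pressure waveforms
(BPW) or finger photoplethysmography (PPG), sampled at 1024 Hz for a
few minutes — are high-pass filtered to remove baseline drift, cut into
individual beats at their feet (diastolic minima), and each beat is
expanded in a truncated Fourier series on its own period. Four families
of harmonic indices summarize each beat and its local variability:
amplitude proportions $C_n$, their 15-beat coefficients of variation
$CV_n$, phase angles $P_n$, and their 15-beat dispersions $P_{n,SD}$,
for harmonics $n = 1,\dots,10$ — forty indices per beat. These feed a
subject-level statistical comparison (two-tailed t-tests at
$\alpha = 0.05$) and a five-layer perceptron classifier evaluated with
subject-level cross-validation and a hold-out set. Changes in arterial
stiffness alter how efficiently each frequency component of the pulse
propagates, so these spectral indices are sensitive to vascular changes
that accompany conditions such as Alzheimer's disease.

## The model

For one beat of $k$ samples $x_0,\dots,x_{k-1}$ between consecutive
feet, the Fourier coefficients are

$$A_n = \frac{2}{k}\sum_{s=0}^{k-1} x_s \cos\frac{2\pi n s}{k},\qquad
  B_n = \frac{2}{k}\sum_{s=0}^{k-1} x_s \sin\frac{2\pi n s}{k},$$

so $A_0$ is twice the beat mean. Amplitudes are
$Amp_n = \sqrt{A_n^2+B_n^2}$ with $Amp_0 = |A_0|$, phases
$P_n = \operatorname{atan2}(B_n, A_n)$ in degrees on $(-180, 180]$, and
$C_n = Amp_n/Amp_0 \times 100\,\%$. Over a sliding window of a beat and
its 14 followers, $CV_n = SD(C_n)/\overline{C_n}\times 100$ and
$P_{n,SD} = SD(P_n)$; a series of $m$ beats yields $m - 14$ windows and
as many 40-dimensional feature rows.

Three conventions deserve notice, because the defining formulas leave
them open:

* **Summation limits.** A $k$-sample period is indexed half-open,
  $s = 0,\dots,k-1$; including both endpoints would double-count the
  boundary sample and break the orthogonality that makes the
  coefficients exact.
* **Phase branch.** $\arctan(B/A)$ alone is quadrant-ambiguous; the
  two-argument arctangent on $(-180, 180]$ preserves the formula on the
  principal branch while resolving the sign. A vanishing harmonic gets
  $P_n = 0$ by convention and is flagged.
* **The DC term after high-pass filtering.** A high-pass filter removes
  the mean, so per-beat $A_0$ hovers near zero and the ratios $C_n$
  would explode. The default `baseline_mode = "min_zero"` subtracts the
  beat minimum before the transform, guaranteeing a positive DC term;
  mode `"none"` (no baseline adjustment) is retained and is the mode
  under which a noise-free synthetic beat reproduces its generating
  template exactly. The defining formulas do not settle which
  convention applies to filtered signals; both are provided and only
  the default is asserted in the pipeline.

## Filtering

Baseline drift is removed with an 11th-order type-I Chebyshev high-pass
at 0.01 Hz (passband ripple 0.5 dB, configurable). At 1024 Hz this
filter's poles lie within $10^{-4}$ of $z = 1$: expanding the transfer
function into direct-form polynomial coefficients is numerically
hopeless, so the package designs the filter analytically (Chebyshev
low-pass prototype, low-pass-to-high-pass transform, bilinear transform
with prewarping) and realizes it as cascaded second-order sections —
mathematically the same response, stable in double precision. "Chebyshev"
without qualification is read as type I, the conventional meaning.

Application is zero-phase by default (forward–backward), for two
reasons: foot timings are not delayed, and the effective stopband
attenuation doubles in dB. The signal mean is subtracted and both ends
are extended by odd reflection (2 s by default) before filtering, which
suppresses the start-up transient a causal pass exhibits; consequently
no edge region is flagged by default. In `one_pass` mode the first and
last $2/f_c$ seconds are flagged as transient and beats whose feet fall
there are excluded. Note that $2/f_c = 200$ s exceeds a 3-minute
recording — a causal 0.01 Hz high-pass genuinely cannot serve such
short recordings, which is why zero-phase application is the default.

## Segmentation

No particular foot-detection algorithm is prescribed by the protocol
this package implements; it uses a standard, fully testable approach:
candidate systolic upstrokes are maxima of the smoothed first
difference above an adaptive threshold (half the 98th percentile of
positive slopes) with a 0.4 s refractory period; from each upstroke the
detector walks down the left flank to the nearest non-positive-slope
point and refines the foot with a quartic polynomial fit over ±40 ms on
a lightly smoothed copy of the signal. The quartic (rather than
parabolic) fit matters: the diastolic valley is asymmetric — flat
approach, steep exit — and a parabola's vertex is biased toward the
flat side by ~8 ms. On default-noise synthetic recordings the detector
recovers over 99 % of ground-truth feet within ±5 samples (±4.9 ms).

Beats are half-open intervals $[\mathrm{foot}_i, \mathrm{foot}_{i+1})$,
so concatenating segments reproduces the recording span exactly and $k$
equals the inter-foot interval.

## The synthetic cohort

No public recordings of this kind are available, so the package ships
a phenomenological generator whose defaults define the study conditions
for all tests:

* **Beat template.** Ten harmonic amplitude proportions and phases,
  derived once from a two-component kernel (a fast-rise,
  exponential-decay systolic wave plus a smaller, smoother dicrotic
  echo) and frozen as package constants. The BPW template has stronger
  high-harmonic content than the PPG one, reflecting the sharper
  pressure upstroke at the wrist. Both are rotated so the waveform
  minimum — the foot — is sample 0; phases are therefore defined at the
  foot. The diastolic decay is sustained (time constant ≈ 0.4–0.45 of
  the beat), which is physiological and also what makes the foot a
  well-defined landmark; with a flat late diastole the foot position
  carries almost no information and no detector could localize it.
* **Scaling convention.** A beat is
  $x_s = d + \sum_n 2d\,(c_n/100)\cos(2\pi n s/k - \phi_n)$ with
  constant term $d$ = `dc_level`. Since the analysis defines
  $Amp_0 = |A_0| = 2 \times \mathrm{mean} = 2d$ and harmonic $n$ has
  amplitude $2d\,c_n/100$, the template's `amp_proportions` are
  *exactly* the $C_n$ the analysis recovers from a clean beat. This
  round-trip identity (to $10^{-9}$ relative error, in practice machine
  precision) anchors the whole test suite.
* **Beat-to-beat variability.** Periods are lognormal with CV 3 %
  (mean period drawn per subject from a truncated normal, 0.85 ± 0.06 s
  on [0.73, 0.99] s — keeping 3-minute recordings within the realistic
  180–250 beats). Template jitter is Gaussian: multiplicative on
  amplitude proportions (CV 2 %) and additive on phases (2°). Jittered
  beats are re-aligned so each beat's minimum is at its own foot and
  anchored to a common diastolic level, keeping the assembled trace
  continuous — without the anchoring, concatenation leaves small steps
  at the junctions that no real vessel exhibits.
* **Drift and noise.** A slow sinusoid (amplitude 0.3 signal units,
  0.004 Hz — below the filter cutoff, so the filter's effect is
  verifiable) plus white Gaussian sensor noise (SD 0.01, about 0.5 % of
  the peak-to-peak pulse, ~46 dB SNR — typical of a clinical pressure
  transducer at this rate).
* **Between-subject variation.** Subject templates are drawn around the
  channel template with 10 % relative SD on amplitude proportions, 3°
  SD on phases, and 10 % lognormal variation of `dc_level`.
* **Group effects.** AD subjects' templates receive additive offsets on
  chosen harmonics; `cohort_effect()` expresses them in pooled-SD units
  (multiples of the between-subject SDs) and applies them to both
  amplitude proportions and phases, the two fields the group effect
  defines. Both channels matter: an amplitude offset is diluted in the
  extracted $C_n$ because it also enlarges the per-beat DC term that
  normalizes them (a 2-SD template shift surfaces as ≈ 0.8 SD in
  extracted subject means), whereas phase offsets propagate into the
  extracted $P_n$ undiluted. Severity grades scale the effect (mild
  0.5×, moderate 1×, severe 1.5×) — a plausible monotone progression,
  not an empirical claim.

What the generator does **not** emulate: respiratory modulation,
motion artifacts, ectopic beats, sensor saturation, or any genuine
hemodynamics (it is a phenomenological Fourier-domain model, not a
transmission-line model of the arterial tree). Tests passing on this
cohort therefore demonstrate the *pipeline's* correctness and
calibration, not clinical performance on real patients.

## Classification protocol

Subjects (never rows) are split 2:1 into training and hold-out sets,
per class with largest-remainder rounding — 87 + 74 subjects would
yield 58/49 training and 29/25 hold-out. The stated cross-validation —
"threefold, with 80 % and 20 % of training subjects for training and
validation" — is internally inconsistent with classic 3-fold
partitioning (which would use 67/33); the package follows the stated
percentages literally: three independent seeded 80/20 subject draws,
stratified by class. Each fold's validation subjects drive early
stopping (patience 50 epochs, best weights restored). The final model
is trained on **all** training subjects with no validation monitor, for
an epoch budget transferred from cross-validation (the mean of the
folds' best epochs) — the classic early-stopping transfer. Two design
traps are worth recording: early-stopping the final model on the
hold-out subjects leaks their labels into epoch selection and inflated
hold-out accuracy by ≈ 10 points under the null before we closed it;
and training the final model for the full schedule instead overfits
the training-subject clusters.

The network is the stated 40–20–20–20–1 architecture. Unstated
hyperparameters are implementation choices, config-exposed: rectified
linear hidden units, sigmoid output, binary cross-entropy, full-batch
adaptive-moment (Adam) optimization at rate 0.01, at most 300 epochs,
He-scaled Gaussian initialization from a recorded seed. Scores ≥ 0.5
are labeled AD (ties to the positive class). Metrics are computed at
pulse (row) level by default, matching the reported pulse counts;
subject-level aggregation (mean score per subject, then threshold) is
available. AUC is the Mann–Whitney rank statistic with ties counted
half.

## Statistical comparisons

`comparison_table()` produces the 40-row index table with Welch t-tests
by default (the pooled-variance test is an option; the t-test variant is
left open by the protocol). The unit of analysis matters:
consecutive beats of one subject are strongly correlated, so
pulse-level tests inflate the effective sample size and their type-I
error. The table therefore supports `unit_of_analysis = "subject"`
(each subject contributes its mean), which is the calibrated choice and
the one used for the package's type-I-error acceptance check (empirical
rejection rate at $\alpha = 0.05$ within [0.02, 0.09] under the null
cohort). Row-level units remain available because that is how the
indices natively exist. No multiple-testing correction is applied by
default (40 raw tests at $\alpha = 0.05$); Benjamini–Hochberg is
available.

## Numerical choices and degenerate inputs

* Phase dispersion near the ±180° branch cut: phases are unwrapped
  within each window by cutting the circle at its largest gap; this
  equals the linear SD whenever the phases span < 180° and avoids
  spurious dispersion at the cut.
* Windows whose mean $C_n$ falls below $10^{-9}$ have an undefined CV;
  the row is dropped with a message. Beats whose DC term degenerates
  ($Amp_0 \le 10^{-9}\max Amp$) are skipped and counted.
* Constant features abort normalization with the offending column
  named; normalization parameters are fitted on training rows only and
  applying a fitted model never re-fits.
* Zero-variance groups with equal means in a t-test follow the
  convention $t = 0, p = 1$.
* All randomness flows from explicit seeds through an internal
  `with_seed()` that restores the caller's RNG state; every pipeline
  stage is bit-reproducible given its seed, and stage seeds derive
  deterministically from one master seed.

## Simulation sizes

The package's standard in-silico study sizes, used by the tests, the
acceptance script and the analysis drivers: 30 + 30 subjects with
60-second recordings for effect-response runs; 12 + 12 subjects with
45-second recordings for null classification runs (10 seeds); 16 + 16
subjects with 90-second recordings for the t-test calibration runs
(10 seeds × 40 indices = 400 comparisons); five 3-minute
single-subject recordings for segmentation checks. A 60-second
recording yields ≈ 70 beats ≈ 56 windows per subject — enough for
stable window statistics while keeping a complete
simulate-extract-train-evaluate cycle in seconds.

The calibration sizes deserve a note: phase indices of weak harmonics
are estimated with very different precision for different subjects
(phase noise scales inversely with harmonic amplitude), and a t-test
on such a variance mixture is conservative at small samples — with
12 + 12 subjects and 45-second recordings the empirical per-index
type-I error is ≈ 0.02 rather than 0.05. Longer recordings shrink the
within-subject component and restore calibration (≈ 0.03 at 16 + 16
subjects, 90 s); subject-level phases are aggregated by the circular
mean, since an arithmetic mean across the ±180° cut is meaningless.

## Known limitations

* The generator's template distributions are plausible placeholders, not
  fitted to any cohort — no usable distributional ground truth for
  per-harmonic values in real patients is available to fit against.
* Clinical cohort-specific results reported for this kind of
  analysis come from private patient data and are not reproduction
  targets; the deliverable is the protocol, its correctness, and its
  calibration.
* Whether the reported phase dispersions are in degrees or
  percent-of-mean is ambiguous in practice; both modes are computed
  (`phase_sd_mode`), degrees being the default per the defining
  formula.
* The foot detector is tuned for pulse-like signals with a clear
  systolic upstroke; it is not an artifact-robust clinical-grade
  detector.
* Foot localization to ±5 samples (±4.9 ms at 1024 Hz) is
  noise-limited for subjects whose drawn template has an unusually flat
  diastolic valley: with the default sensor noise, a minority of
  random cohort subjects fall below the 99 % recovery mark even though
  default-template recordings sit at ~100 %. This is an information
  limit of the landmark, not a detector defect — a 10-harmonic beat
  bounds how sharp a foot can be.
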