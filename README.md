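# pulsespec

Frequency-domain analysis and classification of arterial pulse
waveforms in R.

Changes in arterial stiffness alter how each frequency component of the
heart's pressure pulse propagates to the periphery. A line of clinical
work exploits this by recording a few minutes of continuous radial
blood-pressure waveform (BPW) or finger photoplethysmography (PPG) at
1024 Hz, decomposing every beat into its Fourier harmonics, and using
the resulting spectral indices to separate patient groups — including
Alzheimer's disease (AD) patients from controls, where cerebrovascular
atherosclerosis leaves a vascular signature. `pulsespec` is a complete,
tested implementation of that analysis pipeline, together with a
synthetic-waveform generator that makes every stage verifiable without
access to clinical recordings.

## The method

For each beat of `k` samples between consecutive feet (diastolic
minima), the pipeline computes

    A_n = (2/k) Σ_{s=0}^{k-1} x_s cos(2πns/k)
    B_n = (2/k) Σ_{s=0}^{k-1} x_s sin(2πns/k)
    Amp_n = √(A_n² + B_n²),  P_n = atan2(B_n, A_n)  (degrees)
    C_n = Amp_n / Amp_0 × 100 %,                     n = 1…10

and, over each beat plus its 14 followers, the variability indices
`CV_n` (coefficient of variation of `C_n`, %) and `P_n_SD` (dispersion
of `P_n`, degrees) — forty indices per beat. Upstream, baseline drift
is removed by an 11th-order type-I Chebyshev high-pass at 0.01 Hz
(realized as stable second-order sections, applied zero-phase);
downstream, the forty Z-scored indices feed per-index two-tailed
t-tests and a 40–20–20–20–1 multilayer perceptron evaluated with
subject-level 2:1 train/hold-out splitting and three 80/20
cross-validation folds. See the methods vignette
(`vignettes/pulse-harmonics.Rmd`) for the model, conventions and design
decisions.

## Worked example

The numbered scripts under `analysis/` form a complete in-silico
study; each step prints what it found and writes its tables under
`results/`. Steps 1–5 simulate a 30 + 30-subject cohort (60-second
recordings, a 2-pooled-SD group effect on harmonics 2–4 of the AD
templates), extract per-beat harmonics through the filter/segmentation
pipeline, compare the forty indices between groups, and run the MLP
protocol:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_extract_indices.R   # foot recovery: 98.54% within ±5 samples
Rscript analysis/03_feature_matrix.R    # 3355 windows x 40 features from 60 subjects
Rscript analysis/04_group_comparisons.R # 25 of 40 indices significant at p < 0.05
Rscript analysis/05_mlp_protocol.R
```

The protocol report printed by step 5:

```
    stage accuracy sensitivity specificity    auc
1   fold1    98.90       98.23       99.56 0.9984
2   fold2    85.33       98.27       71.69 0.9664
3   fold3    90.59       81.62      100.00 0.9915
4 average    91.61       92.71       90.42 0.9854
5 holdout    90.73       90.39       91.06 0.9676
```

The three fold rows are the cross-validation results (fit on 80 % of
training subjects, evaluated on the other 20 %); `holdout` is the final
model — trained on all 40 training subjects — evaluated once on the 20
subjects it has never seen, at pulse (window) level. Step 6 re-runs
the whole study at group effects of 0, 1, 2 and 4 pooled SD and shows
the dose–response of the pipeline (55 %, 78 %, 99.8 %, 100 % hold-out
accuracy at seed 42); at zero effect the classifier sits at chance,
which is the single most important sanity check of a subject-level
protocol.

Equivalent one-liner from R:

```r
library(pulsespec)
cfg <- cohort_effect(cohort_config(n_per_group = c(control = 30, AD = 30),
                                   duration_s = 60, seed = 42), 2)
sim <- protocol_simulation(cfg)
sim$report
```

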