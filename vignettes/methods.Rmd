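---
title: "Noncontact sleep staging: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noncontact sleep staging: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somnosense)
```

## The problem and the signal model

A piezoelectric pressure sensor placed under the pillow records a single
channel in which four components superpose: the ballistocardiogram (BCG, a
damped mechanical pulse per heartbeat whose energy lies roughly in the
3–10 Hz band), the respiratory oscillation (≈0.1–0.5 Hz), intermittent
high-amplitude body-movement artifacts, mains interference at 50 Hz, and
broadband sensor noise. Sleep stages modulate the first three: deep (NREM)
sleep shows slow, regular heartbeats and breathing and little movement;
wake shows faster, more variable rhythms and frequent posture changes; REM
resembles wake autonomically but with little movement. The package turns
these physiological regularities into an epoch-by-epoch Wake/REM/NREM
classifier.

## Separation chain

1. **Mains removal** — 49–51 Hz Butterworth band-stop (two biquad stages),
   run forward and reverse (`signal::filtfilt`) so event times are not
   phase-shifted. When a recording's Nyquist frequency sits at or below the
   stop band (sample rates ≲100 Hz) the stage is skipped; the filter itself
   rejects out-of-Nyquist corners.
2. **Movement detection** — the peak-to-valley difference (PVD) of each
   non-overlapping 2-s window is compared with running medians of PVD over
   30/60/120/300-s contexts centred on the window and truncated at the
   edges. A window is movement when its PVD exceeds 2.2 x the *smallest*
   of the four medians ("greater than any one of them"); reading the
   comparison as "all four" is the stricter alternative we rejected, since
   a single quiet context is already evidence the window is atypical.
   Medians below 1% of the recording's global median PVD are floored there,
   so a flat recording (all PVD = 0) flags nothing.
3. **BCG extraction** — 2.5–10 Hz Butterworth band-pass, zero-phase.
   Samples inside movement windows are retained; exclusion is the
   detectors' job, keyed to the mask.
4. **Beat detection** — a band-limited RMS envelope (0.12 s window, applied
   twice: the second pass removes the ripple at twice the BCG carrier),
   candidate maxima at ≥0.3 s spacing, an adaptive threshold at 40% of the
   85th-percentile candidate height (anchoring on the upper heights keeps
   between-beat noise maxima out), a forward accept pass, and a backward
   re-scan of gaps longer than 1.5 x the running median interval at a
   reduced threshold. Each accepted beat is refined to the local energy
   centroid of the envelope, which for a symmetric BCG pulse pins the beat
   time well below one sample period of error.
5. **Respiration** — the detected BCG is subtracted from the recording and
   the residual decomposed to 8 levels on the sym8 wavelet. The transform
   is an orthogonal periodized pyramid implemented in-package (the
   synthesis step is the adjoint of the orthonormal analysis step, hence an
   exact inverse; verified to 1e-10 in the tests). Reconstruction keeps the
   level-8 approximation plus any detail level whose dyadic band overlaps
   0.1–0.5 Hz, so the retained band tracks the respiratory band at every
   sample rate. The signal is reflection-padded to a multiple of 2^8 and
   trimmed, so length is preserved. Breaths are local maxima at ≥1.5 s
   spacing above 25% of the 95th-percentile amplitude.

## Interval estimation on t-second windows

Heartbeat and respiratory intervals are estimated on t-second windows
(t ∈ {1, 3, 5, 7, 9, 11, 13, 15}) tiling the recording from time zero, as
the overlap-weighted mean Σαβ·I / Σαβ over the intervals crossing each
window, with α the fraction of the window covered and β = 0 for intervals
touching any movement window (a conservative reading of "occurs in a
movement episode"). A window is invalid when it lies wholly inside
movement or Σαβ = 0 (denominator tolerance 1e-12). Intervals outside
physiological bounds (0.3–2 s heartbeat, 1.5–10 s breath) are discarded
before weighting. Because t values such as 9 do not divide 60, a window
belongs to the 60-s epoch containing its *start*; this tiling convention
is fixed and shared by all features. The default t = 9 s is the
best-performing working point of the method; it is user-overridable
everywhere.

## The 41 features

Per epoch: HI features 1–9 and RI features 10–18 (mean; CV = SD/mean;
percentile ratios P100/P0 … P60/P40 with linear-interpolation percentiles,
P0 = min, P100 = max; median absolute deviation, unscaled; and the averaged
cumulative difference ACD), CHR ratios 19–33 (each HI statistic over the
matching RI statistic, plus eleven cross percentile ratios down to
P0/P100), and BM features 34–41 read off the movement mask (epoch movement
proportion, run count, longest run, mean run proportion, and the
proportions of the two preceding and two following epochs, zero outside
the recording).

ACD slides a split point u in steps of t over ±2 min around the epoch
centre and averages |mean of valid values in (u−30 s, u] − mean in
(u, u+30 s]|, skipping positions where either half is empty; the half-open
convention means a step change in the series is isolated at the last slide
whose left half precedes it. Epochs with fewer than two valid windows
invalidate features 1–9/10–18; any ratio with a zero or invalid operand is
invalid; BM features are always valid. Invalid entries are imputed with the
per-feature median over the recording's valid epochs (keeping
cross-validation leakage-free, since imputation never crosses recordings),
and the pre-imputation validity pattern is preserved alongside.

## Classification, cross-validation, agreement

Five classifiers sit behind one interface: random forest (100 trees, the
default analysis classifier), SVM (RBF), decision tree, KNN (k = 5) and a
multiclass AdaBoost (SAMME over rpart trees, written in-package). Training
folds supply inverse-class-frequency weights to counter the NREM majority;
features are z-scored from the training fold for the scale-sensitive SVM
and KNN only. A training fold containing a single class predicts that class
directly. Evaluation is leave-one-out at the recording level — each
recording is held out once — with training rows assembled in sorted
recording-id order so results are invariant to corpus ordering.

Agreement uses overall accuracy p0 = ΣTP/T and chance agreement
pe = Σ((TP+FP)/T)·((TP+FN)/T) over the three classes, with
kappa = (p0−pe)/(1−pe); the degenerate pe = 1 case returns kappa 1 when
agreement is perfect and 0 otherwise (a continuity convention). Summary
dispersion uses the population divisor n, which reproduces the bundled
benchmark's printed accuracy SD; its printed kappa SD instead matches the
sample divisor applied to rounded values, an inconsistency we do not try
to reproduce. Random-forest feature importance is reported from bagged
trees (mtry = number of features): with subspace sampling, duplicating a
feature inflates the pair's combined share, whereas bagged importance is
invariant to duplication.

## Stage fusion

Four rules, applied once each in order: (1) single-epoch REM runs
immediately followed by Wake become Wake (multi-epoch runs are left; the
"discrete labels" reading); (2) an interior epoch differing from both
neighbours takes the previous label, one left-to-right pass seeing already
updated left neighbours; (3) every sliding 5-min window whose Wake
proportion *strictly* exceeds 0.8 fuses to Wake — at 60-s epochs only
all-Wake windows qualify, so the rule is an intentional no-op at the
default resolution and activates for shorter epochs; (4) with the REM
proportion P_REM measured on the labels entering the rule, non-REM gaps
between REM runs strictly shorter than 20/15/7 min (P_REM < 5%, in
[5%, 10%], > 10%) are relabelled REM, iterated to a fixed point with the
threshold held fixed. The thresholds bound the *gap*, not the combined
span, since merging semantics act on the separation. The composition is
idempotent (property-tested over random sequences).

## The synthetic-data generator

Because no recordings ship with the method, a simulator generates whole
nights with exported ground truth. Its defaults are the study conditions:
per-stage heartbeat interval mean/SD 0.85/0.06 s (Wake), 0.90/0.07 (REM),
1.00/0.03 (NREM); breath interval 3.5/0.5, 3.6/0.5, 4.0/0.15 s; movement
60/4/6 events/h with 2–8 s bursts; 1 kHz sampling. Intervals are normal
draws clipped to physiological bounds, so zero-SD configs degenerate
exactly. The signal mix is one Gaussian-windowed 6 Hz cosine pulse per
beat (its spectrum sits mid-BCG-band), a sinusoid whose phase is pinned to
π/2 at every ground-truth breath time, uniform ±10 bursts over movement
intervals, a 0.1-amplitude 50 Hz sinusoid and 0.05-SD white noise. The
hypnogram grammar begins with 5–20 min of Wake, then alternates 40–70 min
NREM with REM runs starting at 10–16 min and lengthening 1.3 x per cycle
(capped at 30 min), with occasional 1–3-epoch Wake intrusions — giving the
classical ~90-min cycle, NREM-dominant early nights and an all-seed NREM
fraction comfortably inside 0.4–0.8 for 8-h nights. The REM base range is
set near the middle of its plausible band because shorter bases push
NREM-heavy seeds over that fraction bound.

The simulator emulates timing statistics, stage-dependent variability,
movement load and the gross spectral layout. It does **not** emulate BCG
waveform morphology changes, posture-dependent coupling, sensor
nonlinearity, apnea-driven breathing patterns, or gradual stage
transitions — so passing tests demonstrate correct signal processing and
above-chance stage separability, not clinical-grade accuracy on real
patients. Synthetic stages are in fact *more* separable than real ones:
the classifier approaches ceiling on the default corpus, and at ceiling
the fusion rules can only cost accuracy — rule 2 necessarily erases
genuine single-epoch Wake intrusions (which the grammar deliberately
contains) even when they were predicted correctly. The rules pay off in
the realistic 75–85% accuracy regime, not at 99%+; the package reports
pre- and post-fusion metrics side by side so this trade-off stays visible.

## Problem sizes and numerical conventions

The shipped validation runs use a 21-min default-configuration recording
at 1 kHz for parameter recovery, and an 8-recording, 120-min-per-night
corpus at 200 Hz for end-to-end cross-validation — sizes chosen to
exercise every code path at full fidelity while staying desk-scale
(sampling rate is a simulator parameter with a 100 Hz floor; every filter
is rate-parametric). All randomness descends from one top-level seed via a
deterministic fan-out, and identical configurations produce bit-identical
recordings and reports. Equality tolerances: the interval estimator is
property-tested against brute force at 1e-12; wavelet reconstruction at
1e-10; agreement metrics at 1e-12 against an independent contingency-table
computation.

## Known limitations

- The beat detector is a contract-level forward–backward design, not a
  reproduction of any proprietary detector; on heavily corrupted real data
  its adaptive threshold may need re-anchoring.
- Breath detection assumes a dominant single respiratory mode; periodic
  breathing or apneas will fragment the interval series (the movement mask
  does not model them).
- Fusion rule 3 is inert at 60-s epochs by construction (see above).
- LOOCV is the only evaluation protocol; no hyperparameter search is
  performed, matching the method's fixed-defaults design.
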