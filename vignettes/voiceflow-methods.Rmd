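---
title: "Estimating glottal airflow from neck-surface acceleration: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating glottal airflow from neck-surface acceleration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voiceflow)
```

## The problem

Phonotraumatic vocal hyperfunction (PVH) — chronic voice misuse associated
with vocal-fold nodules and polyps — expresses itself in *aerodynamic*
quantities of the voice source: patients compensate for their lesions by
driving more air through the glottis, elevating the peak-to-peak glottal
airflow (ACFL) and the maximum flow declination rate (MFDR) relative to
matched controls at comparable loudness. These quantities are measured
directly only in the laboratory, with a circumferentially vented (CV)
pneumotachograph mask. A week of ordinary life cannot be recorded through a
mask; it can be recorded through a small accelerometer glued to the front
of the neck below the larynx. `voiceflow` implements the full chain that
turns such a neck-surface acceleration recording into glottal airflow
estimates, aerodynamic features, group statistics and a screening
classifier.

## Subglottal impedance-based inverse filtering (IBIF)

The neck skin moves because the subglottal air column below the glottis is
driven by the glottal flow. In the frequency domain the chain is

    u_g --> subglottal line (sub1) --> junction at the sensor
             --> skin branch (Z_skin) --> skin acceleration

and the package models it with:

* **Transmission line.** The trachea is a uniform lossy cylinder (area
  2.5 cm^2) of length `10 * Q4` cm, split at the accelerometer position
  `5 * Q5` cm from the glottis into sections *sub1* and *sub2*. Each
  section is represented by its exact chain (ABCD) matrix with
  viscothermal boundary-layer losses, so responses are continuous in the
  geometry factors regardless of any internal segmentation. `Zsub2` is the
  input impedance looking from the sensor toward the bronchi; `Hsub1` is
  the flow transfer from the glottis to the sensor, loaded by `Zsub2`.
* **Termination.** The distal end is terminated by a pressure-release
  condition (Z = 0), the standard idealization of the opening into the
  large lung volume. This choice matters: a line terminated by its own
  characteristic impedance has a *length-independent* input impedance,
  which would make the tracheal-length factor Q4 unidentifiable during
  calibration. The quarter-wave resonances of the pressure-release line
  are also what make the model's subglottal resonances visible in the
  signal. Characteristic, closed and numeric terminations remain available
  as options.
* **Skin branch.** A series resistance-mass-stiffness branch per unit
  area, `Z_skin = (R_m + jw M_m - j K_m / w + jw M_acc / A_acc) / A_acc`,
  with defaults `R_m = 2320` g s^-1 cm^-2, `M_m = 2.4` g cm^-2,
  `K_m = 491000` dyn cm^-3 at the all-ones scale factors. The stiffness
  reactance is the mechanical `-jK/w` form — the only form dimensionally
  consistent with a stiffness in dyn cm^-3.
* **Composition.** `T_skin(w) = Hsub1 Zsub2 jw / (Zsub2 + Z_skin)` maps
  glottal flow to volume acceleration at the skin; dividing by the sensor
  contact area and negating gives the measured acceleration.

Five dimensionless factors `Q1..Q5` scale the three skin constants, the
tracheal length and the sensor position, absorbing between-subject anatomy
so airflow estimates are comparable across subjects. Their search box is
`[0.25, 4]` for the skin factors and `[0.7, 1.3]` for the geometry, with
the all-ones default inside.

### The inverse filter

The estimated flow is the acceleration convolved with a 1102-tap FIR whose
response approximates `-A_acc / T_skin`. The filter is realized by
frequency sampling with three numerical safeguards, each of which was
necessary in practice:

1. **DC and infrasound.** The accelerometer is AC-coupled and glottal flow
   carries no recoverable DC, so the DC bin is zeroed and bins below 40 Hz
   are tapered to zero by a raised cosine.
2. **Oversampled design grid with a centered truncation.** Sampling the
   inverse spectrum on exactly 1102 bins makes the response exact *at* the
   bins but leaves up to 9% ripple between them (time-aliasing of the long
   ideal inverse response). The package samples on a 4x-oversampled grid,
   inverse-transforms, centers, and truncates to 1102 coefficients under a
   raised-cosine edge taper covering half the filter.
3. **Tikhonov floor.** Where the forward transfer has near-zeros (the
   half-wave resonances of sub2), the ideal inverse gain diverges; those
   frequencies carry no recoverable flow. The inverse spectrum is
   `-A_acc conj(T) / (|T|^2 + eps^2)` with `eps` equal to 1% of the median
   in-band (60-2000 Hz) magnitude of `T_skin`.

The centering introduces a known group delay of 551 samples which the
convolution engine removes again. Week-long signals are processed in
consecutive one-hour chunks with an overlap of the filter length, so the
concatenated output is identical (to round-off) to a single-pass
convolution. On forward-simulated pulse trains (100-400 Hz, any in-bounds
Q) the forward-inverse round trip recovers the band-limited flow with
under 2.5% normalized RMS error.

## Subject calibration

Per subject, the five Q factors and a small residual delay `d` are fitted
by particle swarm optimization (PSO) against a reference flow derived from
a simultaneous CV-mask recording of a sustained vowel.

* **Mask inverse filtering.** The mask channel is band-passed to
  60-1100 Hz and the first vocal-tract resonance is removed with a single
  second-order FIR anti-resonance constrained to unity gain at DC. The
  resonance frequency *and bandwidth* are estimated by closed-phase
  covariance analysis: a two-coefficient all-pole model is fitted by least
  squares on short sliding segments of the differenced signal, and the
  segments with the smallest normalized residual — the free-decay
  intervals of the closed glottal phase — vote by median. On sustained
  vowels this outperforms picking the peak of the smoothed spectrum, which
  locks onto the harmonic of f0 nearest the formant and leaves residual
  coloring larger than the entire calibration error budget.
* **Objective.** The normalized weighted absolute error (NWAE) sums, over
  derivative orders 0-2 with weights 1/3 each, the absolute difference
  between the reference and the IBIF estimate normalized by the absolute
  sum of the reference derivative; higher orders re-weight the error
  toward upper harmonics and prevent overfitting the fundamental. Both
  signals are compared in the common mask band (the same 60-1100 Hz
  bandpass is applied to the IBIF estimate inside the objective), after
  discarding 50 ms of filter transients at each end. Signals are trimmed
  per the delay convention: the estimate on `[d0, N-1-d0]`, the reference
  on the same window shifted by `d`, with `d0` initialized to half the
  average glottal cycle.
* **Alignment.** A cross-correlation scan within one period pre-aligns the
  two channels; the residual integer delay rides along as a sixth PSO
  dimension. The reported delay is the total (coarse + residual), so a
  planted 7-sample delay is reported as 7.
* **Search.** Global-best PSO with 40 particles, inertia 0.72, cognitive
  and social coefficients 1.49, 200 iterations, early stop after 20
  iterations without 1e-6 improvement, reflective bounds, and one particle
  seeded at the physiological all-ones default. The geometry-dependent
  responses are precomputed on an equally spaced (Q4, Q5) grid (spacing
  0.05) covering the bounds; lookups snap to the nearest cell, which takes
  the transmission-line evaluation out of the inner loop. The run is fully
  reproducible from its seed, and with multiple gestures the objective is
  their mean NWAE.

On noiseless synthetic gestures the machinery recovers planted skin
factors within a few percent, the delay exactly, and final NWAE below
0.01.

## Framing, gating and the eleven measures

The estimated flow is cut into non-overlapping 50 ms frames (551 samples
at 11025 Hz, floor rounding). Three independent gates decide which frames
are analyzed:

* **Voicing**: normalized autocorrelation peak of at least 0.4 in the
  70-1000 Hz lag band, a low/high band-energy ratio about 1 kHz of at
  least 1, and an energy floor.
* **Onset/offset stability**: the frame is rejected when the RMS ratio of
  its first and second half exceeds 1.5 in either direction
  (`max(r, 1/r) > 1.5`), removing onsets *and* offsets symmetrically.
* **f0 gate**: autocorrelation f0 (smallest lag among peaks within 85% of
  the maximum, parabolic refinement) must not exceed 500 Hz — inverse
  filtering degrades for very high-pitched phonation because the closed
  phase becomes too short.

Within an accepted frame, cycles are delimited at successive flow minima
near integer multiples of `1/f0` (each cycle within 20% of the nominal
period), and the cycle measures are averaged over all cycles in the frame:

| measure | definition | units |
|---|---|---|
| ACFL | cycle peak-to-peak flow | mL/s |
| MFDR | most negative first-difference derivative | L/s^2 |
| OQ | open phase over period, `(t1 + t2) / T0` | — |
| SQ | opening over closing time, `t1 / t2` | — |
| NAQ | `ACFL / (|MFDR| T0)` | — |
| H1-H2 | `20 log10(A1 / A2)` | dB |
| HRF | `20 log10((A2 + ... + A8) / A1)` | dB |
| logACFL, logMFDR | `10 log10 |X|^2` | dB |
| ACFL', MFDR' | SPL over the log measure | — |

The open/speed quotients use a robust line construction: on each flank a
line is drawn from the cycle peak through the flank point at the flank's
median amplitude and extended to the level 80% of the peak-to-peak
amplitude below the peak; the crossing abscissae delimit the open phase.
On linear flanks this construction is exact for SQ and measures 80% of
each open-phase arm, so OQ is reported at 0.8 of its geometric value — a
deliberate property of the estimator, which trades absolute accuracy for
robustness against the closed-phase fluctuations of ambulatory signals.
Harmonic amplitudes are peak-picked within `±f0/4` of each harmonic on the
Hann-windowed, zero-padded spectrum; HRF sums harmonics 2-8 in the
numerator (the upper-harmonics-to-fundamental convention). SPL is mapped
from the frame acceleration RMS in dB through the subject's daily linear
calibration `y = m x + b`.

## Window and week statistics, hypothesis testing

Voiced frames are summarized per 5-minute window (6000 frames; windows
with fewer than 30 voiced frames — the 0.5% gate — are discarded) and per
week by seven statistics: mean, median, 5th and 95th percentile
(interpolated order statistics, type 7), standard deviation, skewness and
non-excess (Pearson) kurtosis. Constant windows report zero skewness and
kurtosis rather than being dropped, keeping window counts stable.

Week-long statistics (7 x 11 = 77 per subject) enter two-sided paired
t-tests across patient/control pairs, with Cohen's d on the pooled
standard deviation of the two groups and an advisory chi-square
goodness-of-fit normality screen that never gates the tests. Multiplicity
is controlled by the Benjamini-Hochberg step-up rule at a false discovery
rate of 0.1: with the sorted p-values `P_(k)` of a family of `m` tests,
the threshold index is the largest `k` with `P_(k) <= (k/m) alpha`, and
all hypotheses with `p <= P_(L)` are rejected. The family size `m` may
exceed the number of enumerated p-values, as when only the smallest 11 of
77 tests are tabulated; with the published top-11 p-values and `m = 77`
the rule rejects exactly 8.

## Classification

Window statistics are z-normalized two ways — *weekly* (pooled across all
subjects' voiced windows) and *daily* (within each subject-day) — and
concatenated to a 154-feature vector (7 statistics x 11 measures x 2
normalizations). The pooled weekly scheme follows the original analysis
design and shares normalization constants across the cross-validation
split; `normalize_within_train = TRUE` recomputes them from training
windows only, for a leakage-free variant.

Dimensionality can be reduced by greedy forward selection under a
5-fold-cross-validated quadratic discriminant cost with a 1e-6
improvement threshold (a ridge-regularized per-feature fallback handles
singular class covariances). Two sparse linear models are provided:

* **L1 logistic regression** — average negative log-likelihood plus
  `lambda * ||beta||_1`, solved by glmnet with an unpenalized intercept;
* **L1 squared-hinge SVM** — `sum max(0, 1 - y w'x)^2 + C ||w||_1`,
  solved by an in-package FISTA proximal-gradient routine (soft-threshold
  prox, Lipschitz step from the top eigenvalue of `X'X`), since no
  installed solver addresses the L1-penalized squared-hinge program.

Evaluation is leave-one-pair-out nested cross-validation: every
patient/control pair is held out once; the training pairs are split into
five pair-stratified inner folds; the penalty grid (20 log-spaced values
from the full-shrinkage `lambda_max` down to `0.01 lambda_max`) is scored
by mean inner-validation AUC and selected by the one-standard-error rule —
the strongest penalty within one SE of the best. The 1-SE rule is not
cosmetic here: under label permutations, noise-driven selection of weak
penalties produces systematic *anti-learning* in leave-pair-out designs
(mean AUC well below 0.5); the 1-SE rule collapses null models to full
shrinkage, whose constant scores give midrank AUC of exactly 0.5. Window
scores on the held-out pair yield fold metrics (rank-statistic AUC with
midrank ties, and the confusion-matrix family), and each subject receives
a call from the proportion of positive windows against a threshold chosen
to maximize training-subject accuracy. Reports include per-fold
coefficients, consensus features (nonzero in every fold), odds ratios
`exp(mean beta)` with normal confidence intervals from the across-fold
dispersion, and a beta-magnitude ablation curve (repeatedly dropping the
smallest-|beta| feature, ties by column order).

## The synthetic cohort and what it does and does not show

All tests run on data from the package's own forward models:

* **Pulse trains** use piecewise-linear opening/closing flanks with
  independently parameterized open and speed quotients, optional jitter
  and shimmer. Linear flanks make ACFL, MFDR, OQ, SQ and NAQ analytic
  properties of the waveform *and* exactly recoverable by the line-fit
  construction; smooth-cornered pulse shapes bias any implementation of
  that construction (a cosine closing flank turns a true SQ of 2 into a
  measured 1.1), which would conflate generator shape with estimator
  error.
* **Calibration gestures** color the flow with one vocal-tract resonance
  (700 Hz, 90 Hz bandwidth by default), add an optional delay and noise;
  the accelerometer channel comes from the forward skin/subglottal model
  at a planted Q.
* **Cohorts** are generated at the frame-feature level: subject-level
  latent means with between-subject spread, within-subject noise, day and
  window structure, and a patient shift of Cohen's d = 0.5 (the magnitude
  reported for ACFL-family statistics in clinical data) applied to the
  log-ACFL family, propagating into ACFL' and weakly into the MFDR family
  through the physiological `|MFDR| ~ ACFL * f0` link. Cohort scale is
  reduced relative to a real week (by default 48 pairs, 7 days, 6 windows
  per day, 60 voiced frames per window) while preserving the structure the
  statistics consume.

Passing tests on these cohorts demonstrates that the statistical and
learning machinery is calibrated (null rejection rates, permutation AUC)
and sensitive (planted effects are detected); it does not demonstrate
clinical performance on real ambulatory recordings, which contain
vocal-tract variation, sensor placement drift, nonstationary noise and
behavior that no frame-level generator reproduces.

## Numerical choices and limitations

* Problem sizes in the test-suite and acceptance runs are scaled-down
  study analogues (e.g. 200 null-cohort replicates of 12 pairs; one
  48-pair cohort with 8 windows per subject for the classifier checks),
  chosen to exercise every code path at full fidelity.
* The transfer grid trades exactness for speed in the PSO inner loop;
  at 0.05 spacing the objective differs from the exact-geometry objective
  by well under 0.02 on synthetic gestures.
* PSO is stochastic; all entry points record their seed and are
  bit-reproducible from it. Increasing the iteration cap can only
  decrease the returned objective.
* The calibration assumes the planted/true vocal tract is dominated by a
  single first resonance in 300-1200 Hz; running speech and nasalized
  vowels violate this, which is why calibration uses sustained vowels.
* The accelerometer sensitivity (signal units to cm/s^2) is assumed to be
  applied upstream; SPL mapping absorbs any residual scale through the
  daily regression.
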