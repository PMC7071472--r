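---
title: "Predicting pBCI feature dynamic ranges from resting EEG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting pBCI feature dynamic ranges from resting EEG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Passive brain–computer interfaces (pBCI) infer a user's affective or
cognitive state from spontaneous EEG — typically from two prefrontal
electrodes (Fp1, Fp2), the montage of consumer headbands. Three features
carry most applications: frontal alpha asymmetry (FAA, a valence marker),
relative frontal theta power (rFTP, relaxation), and relative frontal
low-beta power (rFLBP, attention). A pBCI is only usable if the feature
actually *moves* for that user: the **dynamic range**, measured as the
interquartile range (IQR) of the per-segment feature values over a task
session, varies several-fold between people, and users at the bottom of that
distribution need individual calibration before the application works.

`restdyn` implements a screening pipeline for this problem: from one minute
of resting EEG it extracts 112 quantitative-EEG predictors, and predicts each
user's task dynamic ranges with regression models wrapped in forward
sequential feature selection (FSFS) under leave-one-participant-out
cross-validation (LOOCV), scored by normalized RMSE (nRMSE) and compared with
paired permutation tests. Because no human recordings ship with the package,
a synthetic cohort generator with exact ground truth stands in for the study
population, and every stage is validated against it.

## Feature definitions and spectral conventions

All features are computed per 1-s segment from a periodogram with a
rectangular window (one-sided, 1 Hz resolution at 256 Hz), and band powers
integrate the periodogram over half-open intervals $[lo, hi)$:

* **FAA** $= \ln(P_{\mathrm{Fp1}}^{\alpha_2} / P_{\mathrm{Fp2}}^{\alpha_2})$
  with $\alpha_2$ = 10–12 Hz.
* **rFTP** and **rFLBP**: theta (4–8 Hz) and low-beta (12–15 Hz) absolute
  powers averaged across the two channels, divided by the likewise
  channel-averaged total power (2–18 Hz). Averaging happens on *powers*, not
  on signals.

The canonical band set is delta 2–4, theta 4–8, alpha1 8–9, alpha2 10–12,
alpha3 8–12, low beta 12–15, beta 15–18, and total 2–18 Hz. Several bands
share edges (4, 8, 12, 15 Hz); the half-open convention assigns each shared
1-Hz bin to the upper band, so the disjoint subset {delta, theta, alpha3,
low beta, beta} tiles the total band exactly and band powers are additive up
to spectral leakage. Two quirks of the published band set are reproduced
deliberately rather than "fixed": alpha1/alpha2 leave 9–10 Hz uncovered, and
alpha3 overlaps both.

With a 1-s rectangular window, Parseval's identity makes the estimator
exactly calibrated on bin-centered sinusoids (amplitude $A$ at an integer
frequency contributes $A^2/2$), which is what the unit tests pin.

## The 112 resting-state predictors

For each of the 8 bands × 7 quantities (absolute power at Fp1, Fp2 and the
two-channel mean "Fp12"; the same three relative powers; interhemispheric
asymmetry $\ln(P_{\mathrm{Fp1}}/P_{\mathrm{Fp2}})$ of the absolute powers) ×
2 statistics (mean and IQR over valid resting segments), one predictor is
produced — 112 in total, named
`[Mean|IQR]-[Abs|Rel|Asym]-[channel]-[band]`, e.g. `IQR-Asym-Alpha-8-12` or
`IQR-Rel-Fp12-Beta-12-15`. The two full-band relative predictors are
degenerate by construction (`Mean-Rel-*-total` ≡ 1, `IQR-Rel-*-total` ≡ 0);
they are retained so the vector always has exactly 112 entries — feature
selection simply never gains from them.

## Preprocessing

Stage order is fixed: downsample → (LMS, attention sessions only) →
band-pass → segment → blink detect/reject (non-LMS sessions only).

* **Downsampling** to 256 Hz by integer-factor decimation: a linear-phase
  FIR low-pass (Hamming design, 20·M taps, cutoff 0.8× the target Nyquist)
  applied by FFT convolution with the group delay shifted out exactly, then
  every M-th sample kept. 2048→256 Hz is the exact ratio 8:1.
* **Band-pass** 0.5–30 Hz with a forward–backward order-4 Butterworth:
  zero phase, so filtering never shifts segment boundaries.
* **Segmentation** into 1-s windows with 50% overlap, half-open
  $[t, t+1)$; a trailing partial window is discarded (60 s → 119 segments).
* **Blink detection** uses a multiwindow derivative-sum statistic: the sum
  of signed first differences over a window telescopes to the net amplitude
  change $x(t) - x(t-w)$, evaluated at $w$ = 50/100/200 ms on the mean
  prefrontal channel, each scale robust-standardized (median/MAD) and
  thresholded at 8 on the max across scales; flagged samples closer than
  100 ms merge, and intervals are padded by 50 ms. The *signed* sum is a
  deliberate choice: a blink is a slow, high-amplitude swing, so its net
  change over 100–200 ms is huge while ongoing alpha/beta activity cancels;
  a rectified (absolute-difference) sum is dominated by the fast background
  rhythms and, in our simulations, misses more than half of the injected
  blinks that the signed statistic detects completely.
* **Segment rejection** invalidates every window intersecting a detected
  interval (idempotent; the segment list itself never changes).
* **LMS ocular filtering** (attention sessions, which have EOG references):
  normalized LMS predicting each EEG channel from 3 tapped-delay copies of
  each EOG channel, initial step 0.005, with the step annealed
  hyperbolically (time constant 4 s). Both choices matter: EOG is narrowband
  (0.5–8 Hz), so successive NLMS updates are strongly correlated and the
  steady-state weight noise at a fixed step is several times the white-input
  prediction — and that noise grows with the total tap count, since the
  weight vector random-walks in the delay line's near-null directions. A
  lean 3-tap line (the EOG-to-forehead mixing is essentially instantaneous)
  with a decaying step keeps the distortion of the retained EEG below 0.2×
  the artifact RMS while the residual EOG correlation stays under 0.1. For
  offline analysis nothing is lost, because the mixing geometry is static
  within a session.

The attention sessions skip blink rejection (LMS handles ocular artifacts
there); the other sessions skip LMS (no EOG needed). Both treatments share
all remaining stages.

## Dynamic ranges

The dynamic range of a feature is the IQR — computed with linear
interpolation between order statistics (quantile type 7, declared so every
value is bit-reproducible) — of its per-segment series, concatenated across
that feature's sessions. Resting segments join the pool for the
relative-power features but not for FAA (configurable); the asymmetry
feature is a task-modulation marker and its resting baseline would dilute
the task-session spread. Groups with fewer than 4 segments are omitted with
a message, mirroring recordings lost to technical problems.

## Evaluation

* **nRMSE** $= \mathrm{RMSE}/(\max(\mathrm{actual}) - \min(\mathrm{actual}))$
  over the LOOCV predictions of all participants.
* **LOOCV**: for each held-out participant, feature selection and model
  fitting see only the remaining participants; predictors are standardized
  with training-fold statistics.
* **FSFS** starts from the empty set and, each round, adds the candidate
  minimizing the *training-fold fit* nRMSE, but only if it strictly reduces
  the current criterion; ties break by canonical predictor order. The
  training-fit criterion (rather than an inner CV) is the simplest reading
  of a selection rule driven by the training set; an inner leave-one-out
  criterion is available (`fsfs(..., criterion = "inner_loo")`) but is
  deliberately not the default. A
  `max_predictors` cap is exposed because margin-based fitters can keep
  harvesting marginal training-fit gains long after the real signal is
  captured; the recovery experiment uses a cap of 3, chosen a priori to
  match its single-predictor design (asymmetry-feature screening
  characteristically selects very small sets).
* **Model registry**: MLR (`stats::lm`), tree regression (`rpart`), bagged
  trees (`randomForest` with `mtry = p`), linear and radial SVR (`e1071`,
  cost 1, epsilon 0.1 on the standardized response), Gaussian process
  regression (posterior mean computed from `kernlab` RBF kernel matrices,
  noise variance 1e-4 — below the floor `kernlab::gausspr()` would impose,
  so that noise-free targets are near-interpolated), and a Baseline
  fitting MLR on a fixed feature-matched predictor
  (`IQR-Asym-Alpha-10-12` for FAA, `IQR-Rel-Fp12-Theta-4-8` for rFTP,
  `IQR-Rel-Fp12-Beta-12-15` for rFLBP) with no selection. The response is
  standardized inside the scale-sensitive fitters (epsilon tube, GP noise)
  and predictions mapped back — rFTP IQRs live around 0.02 while FAA IQRs
  live around 1, and absolute hyperparameters would otherwise mean
  different things per feature. Stochastic fitters draw from a
  caller-supplied seed; everything is deterministic end to end.
* **Permutation comparison**: one-tailed paired permutation test on the
  per-participant squared errors of two models; the statistic is the RMSE
  difference (proportional to the nRMSE difference, as both models share
  the actual-value range), the null swaps the two models' errors within
  participants, and the p-value uses add-one smoothing
  $(1 + \#\{d_{\pi} \le d_{\mathrm{obs}}\})/(B+1)$. Under a simulated null
  its size is within [0.03, 0.07] at $\alpha = 0.05$ (checked in the
  acceptance suite with 500 replicates × 2000 permutations).

## The synthetic cohort

Each EEG channel is a sum of five band-limited Gaussian processes (delta,
theta, alpha 8–12, low beta, beta; drawn directly in the frequency domain)
over a 1/f-power background, sampled at 2048 Hz. Baseline RMS amplitudes
(8/6/10/4/3 µV, background 10 µV) are typical prefrontal scalp values. Band
log-amplitudes follow a participant-specific epochwise random walk
(centered, rescaled to unit IQR, multiplied by a per-participant depth drawn
uniformly from the configured range), so each participant has a controllable
feature dynamic range; an independent walk drives the interhemispheric alpha
log-amplitude difference, hence FAA. Analytic per-epoch truth features and a
full analytic truth predictor vector are recorded before waveform synthesis
or artifacts.

Blinks are raised-cosine biphasic pulses (200–400 ms, positive lobe then a
35% negative lobe) at Poisson onsets (default 12/min), with peak amplitude
8× the channel RMS on the prefrontal channels and a stronger copy on the EOG
channels (which otherwise carry 0.5–8 Hz band-limited noise).

**Link semantics.** The generator ties each task feature's dynamic range to
one designated resting predictor: target IQR = coefficient × predictor +
Gaussian noise (noise SD given absolutely or as a fraction of the cohort SD
of the linked component). The predictor in this equation is the value
*measured* from the clean resting recording by the package's own spectral
pipeline, not the analytic truth value. This is a considered choice: a 1-s
periodogram band power has chi-square sampling noise (for a 4-bin band the
log-ratio noise is ≈0.75 nats per segment), which inflates any measured IQR
by a roughly constant but noisy amount. Linking to the analytic truth would
bury the measurable association under that noise and no pipeline could
recover it; linking to the measured value makes "noise SD → 0 implies
R² → 1" hold exactly and keeps the recovery experiment a test of the
*evaluation machinery* rather than of an unbeatable noise floor. Task
sessions then realize the target exactly at truth level: the linked walk is
rescaled so the truth feature series has precisely the target IQR (for the
relative-power features via
$P_{\mathrm{band}} = \frac{r}{1-r} P_{\mathrm{other}}$, clamped to
[0.02, 0.95]).

All randomness flows from one root seed through counter-based per-participant
substreams, so any participant is reproducible in isolation and cohorts are
byte-identical across re-runs.

**What the generator does not emulate:** real scalp EEG nonstationarities
(drift, electrode pops, EMG), saccadic EOG geometry, spectral peaks with
finite width and individual alpha frequency variation, and any true
psychophysiology behind the predictor–dynamic-range association — the link
is a statistical construction. Passing tests therefore demonstrate that the
pipeline measures what it claims and recovers planted associations at
realistic noise levels, not that such associations exist in any particular
human population.

## Suitability screening

The pipeline's report flags a user for calibration when the predicted
dynamic range falls below mean − SD (sample SD, n−1) of the cohort's actual
IQRs. The rule is labeled heuristic in the output: it is a screening
convention, not a validated clinical threshold.

## Problem sizes and numerical choices

* Unit tests run on 3–12-participant cohorts with 20–30-s sessions; the
  acceptance suite runs the recovery experiment at the full study conditions
  (35 participants, 60-s resting, 2048 Hz native) over 20 replicate cohorts
  and takes the bulk of the suite's runtime.
* Default task-session length is 120 s (two-minute blocks are typical of
  affective pBCI tasks and give ~239 segments, plenty for a stable IQR);
  the analysis drivers use 60-s sessions for a faster demonstration.
* Zero-variance predictor columns are left centered but unscaled;
  zero-range responses short-circuit to mean prediction; truth band powers
  are floored at 1e-20 so silent bands keep log-ratios finite; IQRs require
  ≥4 finite values by contract.
* FSFS tie-breaks are deterministic (canonical order), and every stochastic
  step (cohort generation, bagging, permutation draws) derives from explicit
  seeds, making the full pipeline re-run byte-identical.

## Limitations

The FSFS training-fit criterion overfits by design intent (it mirrors the
described selection rule); with flexible fitters it benefits from the
parsimony cap. The degenerate full-band relative predictors are retained for
count fidelity. EDF ingestion is not provided — recordings enter as
delimited tables (one row per sample: `time_s`, `Fp1`, `Fp2`, optional EOG
columns) — and the blink detector is a documented derivative-sum stand-in
for the multiwindow-summation family of detectors, not a reimplementation of
any specific published algorithm.
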