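---
title: "Classifying conversation affect from EEG: models and methods"
author: "rteeg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying conversation affect from EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(rteeg)
```

## The problem

Reminiscence therapy engages older adults in conversation around memory
prompts — here, old photographs discussed for one minute each. Assessing how
pleasant or stressful each conversation felt usually relies on
questionnaires, which are discontinuous and hard for some participants.
`rteeg` implements a pipeline that instead classifies each one-minute
conversation as *positive* or *negative* affect from 8-channel
dry-electrode EEG (F3, F4, F7, F8, T7, T8, P3, P4 in the 10-20 system,
250 Hz), using recurrent neural networks on the raw, cleaned signal.

The pipeline has six stages, each an exported function:

1. **Synthetic cohort generation** (`generate_cohort()`) — raw recordings
   plus per-trial self-assessments;
2. **Labeling** (`label_ps()`, `va_quadrant()`) — ratings to emotion
   classes;
3. **Preprocessing** (`preprocess_trial()`) — Butterworth band-pass, then
   Chebyshev-I high-pass detrend;
4. **Dataset assembly** (`assemble_dataset()`) — drop excluded trials, cut
   20 three-second segments per trial, one-hot the labels;
5. **Classification** (`eeg_classifier()`) — LSTM or bidirectional LSTM on
   single segments;
6. **Evaluation protocol** (`run_cv()`, `run_grid()`) — fourfold
   cross-validation with early stopping, epoch re-selection and an
   optimizer × learning-rate grid.

## Emotion labeling

Each trial carries three integer self-ratings: pleasure and arousal in
$[-4, 4]$ and stress in $[1, 7]$. Two schemes are implemented.

The **valence–arousal quadrant** scheme maps $(P, A)$ to happy (quadrant I),
frightened (II), boredom (III) or relaxed (IV) by strict sign tests;
anything with $P = 0$ or $A = 0$ is `on_axis` and unusable. In
conversation data nearly all ratings pile into quadrant I and onto the
axes, which motivates the second scheme.

The **pleasure/stress (PS)** scheme defines

* positive ⇔ $P > 0$ and $S \le 1$ (stress at the scale minimum),
* negative ⇔ $P < 0$ or $S > 2$,
* excluded otherwise.

On the integer grid, "$S \le 1$" means exactly $S = 1$. The two rules are
disjoint, and exhaustive enumeration of all $9 \times 9 \times 7 = 567$
rating cells gives 36 positive, 477 negative and 54 excluded cells — a
brute-force oracle the test suite recomputes independently and compares
cell by cell against `label_ps()`.

## The synthetic cohort generator

The study's raw recordings are not publicly deposited, so every downstream
stage is exercised on synthetic cohorts with the statistical structure the
analysis assumes: 11 subjects × 36 one-minute trials at 250 Hz by default
(396 sessions). Each channel is a sum of

* a $1/f$ background (power-law PSD, exponent 1, 100 µV² total, shaped by
  FFT filtering of white noise),
* band-limited theta (4–8 Hz, 30 µV²), alpha (8–13 Hz, 60 µV²) and beta
  (13–30 Hz, 20 µV²) oscillations — Butterworth-filtered white noise
  rescaled to its target variance,
* 60 Hz mains interference (5 µV amplitude; the recording region uses a
  60 Hz grid),
* slow baseline drift: a sinusoid with random frequency in 0.05–0.3 Hz and
  amplitude 20 µV.

These magnitudes are ordinary for dry-electrode scalp EEG (channel SD
around 15 µV) and were fixed once as the package's study conditions; they
are configurable but the defaults are not tuned per experiment.

**The class signal** is a lateralized alpha-power asymmetry, chosen because
the discriminative channels in this setting are the lateral pairs F7/F8 and
T7/T8: for a positive trial the left (F7, T7) vs right (F8, T8) alpha-power
log-ratio is $+\delta/2$, for a negative trial $-\delta/2$, so the classes
differ by the effect size $\delta$; trials destined for exclusion get half
the effect with random sign. Because a Welch periodogram measures
oscillation *plus* in-band background power, the generator solves for the
left/right oscillation scales so that the *measured* in-band ratio hits the
target — the test suite verifies the recovered class difference is within
±20 % of $\delta$ with an independent Welch oracle, and that $\delta = 0$
yields statistically indistinguishable classes.

Between-trial variability is modelled as lognormal band-power jitter
(SD 0.15 on the log scale) shared across channels — so the lateral ratio is
preserved — plus a small per-channel jitter (SD 0.05). Ratings are drawn
uniformly from the enumerated grid cells of the requested class, which
makes the generate → label round trip exact by construction.

What the generator does **not** emulate: volume conduction and realistic
topographies, eye-blink/EMG artifact morphology, non-stationarity within a
trial, and subject-level idiosyncrasies beyond the trial jitter. Passing
recovery tests on this data therefore shows that the pipeline and models
can extract a planted spectral-power class difference at realistic SNR —
not that comparable accuracy would be reached on real conversation EEG.

## Preprocessing

Cleaning follows a fixed order: band-pass, then high-pass detrend, both
zero-phase (forward–backward; the analysis is offline and phase distortion
would corrupt segment alignment):

* **Butterworth band-pass 1–45 Hz, order 6.** The band removes slow
  artifacts and high-frequency noise, and puts 60 Hz mains deep in the stop
  band, so no separate notch is used. Order 6 is the smallest for which the
  effective (squared) response attenuates 60 Hz by more than 40 dB
  (42 dB; order 4 reaches only ~28 dB) while the 10 Hz passband deviation
  stays within 1 dB.
* **Chebyshev type-I high-pass, cutoff 0.5 Hz, order 4, 0.05 dB ripple.**
  Removes residual baseline drift; 0.5 Hz preserves the delta-edge content
  already passed by the 1 Hz band edge. The small ripple keeps repeated
  filtering near-idempotent (< 5 % RMS change) and broadband variance
  preserved within a few percent — at the conventional 0.5 dB ripple the
  squared response costs ~11 % of passband power.

Amplitude assertions in the tests exclude one second at each trial edge;
the near-zero DC-suppression check allows the 1 Hz-edge transient its full
~10 s settling time. Filters are designed and applied with the `signal`
package; the tests judge them against a hand-evaluated polynomial frequency
response, independent of the time-domain path.

## Dataset assembly

Excluded trials are dropped before assembly (396 → 195 under the default
composition: 126 positive, 69 negative). Each retained trial is cut into 20
contiguous, non-overlapping 3-second segments (750 timesteps at 250 Hz);
concatenation reconstructs the trial bit-exactly and any other length is an
error. Labels are one-hot with column order (positive, negative). Channel
subsets — `eyewear` (F7, F8, T7, T8) and `headband` (F3, F4, F7, F8) — are
taken in canonical montage order. The segment axis is kept explicit
(trials × segments × timesteps × channels) so the experiment layer chooses
the training granularity; here one 3-s segment is one training instance
inheriting its trial's label.

## The classifiers

`model_spec()` declares the architecture: by default three recurrent layers
of 64, 32 and 16 units, dropout 0.2 after layers 1 and 2, and a dense
softmax read-out over two classes trained with categorical cross-entropy.
Gates use the logistic function, cell input and hidden state tanh. Layers
before the last return full sequences; the last returns its final state. In
the bidirectional variant every layer runs a forward-time and a
backward-time pass whose outputs are concatenated (so the next layer sees
twice the width, and the read-out sees the forward pass's final state next
to the backward pass's state at $t = 1$).

The engine — forward pass and backpropagation through time — is implemented
in RcppArmadillo (`src/lstm.cpp`), with SGD, RMSprop and Adam updates in R.
Correctness is established two ways in the tests: analytic gradients agree
with central finite differences to $10^{-4}$ on small specs of both
architectures, and trainable-parameter totals of built models match the
closed form $4\,[(F + H + 1)\,H]$ per direction and layer (e.g. 18,688 for
the first unidirectional layer on 8 channels) plus $(F_\text{last}+1)K$ for
the read-out.

**Initialization.** Input and dense kernels are Glorot-uniform, recurrent
kernels orthogonal per gate block, and the gate biases are set for long
sequences: forget bias 3 (retention $\sigma(3) \approx 0.95$, a memory
horizon of tens of timesteps) and input bias −1 (damping cell growth so
$\tanh(c)$ stays unsaturated). With the conventional forget bias of 1 the
cell's half-life is ~3 timesteps — far too short to integrate band power
over a 750-step segment — and in our experiments training then spends tens
of epochs re-learning the gate operating point before any validation
improvement appears. The chosen biases make slow power features visible to
the read-out from the first epochs, which matters under patience-2 early
stopping. Dropout is plain inter-layer dropout (no recurrent dropout);
inference is deterministic.

**Scaling.** Inputs are standardized per channel with training-fold
mean/SD (configurable off). Raw microvolt magnitudes destabilize recurrent
training; the per-channel variance ratios that carry the class signal are
preserved.

## The evaluation protocol

`make_folds()` cuts folds at the *trial* level — all 20 segments of a trial
share a fold — which prevents segment-level leakage while matching the
printed split sizes (195 trials, $k = 4$: three folds of 49 and one of 48;
validating on a 49-fold leaves 146 training trials). Disjointness is
asserted on every run.

`run_cv()` is two-phase. Phase 1 trains each fold with early stopping
(monitor validation loss, mode min, min-delta 0, patience 2 — training
stops after two consecutive epochs without improvement; weights are *not*
restored to the best epoch, matching the quoted callback settings), giving
per-fold stopping epochs $T_1..T_4$. The selected epoch is
$\max(T_1..T_4)$. Phase 2 retrains every fold for exactly that many epochs
and reports the mean validation accuracy at segment level; trial-level
majority-vote accuracy (ties toward positive) is recorded alongside. Both
the early-stopped and fixed-epoch accuracies are kept, since it is not
obvious which variant a results table of this kind reports.

`run_grid()` sweeps optimizers (SGD, RMSprop, Adam) × learning rates
(0.01, 0.001, 0.0001 in the printed protocol) and flags a cell — dash, no
accuracy — when its final validation loss exceeds 1 or it reaches 100 %
validation accuracy within ≤ 5 epochs ("very few" fixed at 5,
configurable): both symptoms of non-convergence or overfitting.

All randomness (fold shuffle, weight init, batch order, dropout) derives
from one master seed; repeating a run reproduces its `cv_result` exactly.
Because phase 2 re-derives each fold's stream from the same per-fold seed,
its trajectory extends phase 1's deterministically.

## The desk-scale validation profile

`run_acceptance()` regenerates the study end to end at desk scale. The
cheap checks (cohort arithmetic, labeling enumeration, shapes, round
trips, filter responses, parameter counts) run at full size. The two
training checks use `reduced_profile()`:

* a 60-trial stratified cohort (39 positive / 21 negative — the 126/69
  composition scaled down), full-length trials;
* the eyewear channel subset (F7, F8, T7, T8 — the channels that carry the
  lateral effect);
* a single bidirectional layer of 8 units (the full 64/32/16 stack at this
  data size is dominated by optimization cost, not capacity);
* RMSprop, learning rate 0.003, batch 30, at most 20 epochs, patience 2.

With the strong effect ($\delta = 1.5$) the fourfold-CV mean segment
accuracy is expected above 0.85; with $\delta = 0$ the same protocol must
land inside the 95 % binomial interval of the majority-class proportion at
$n = 60$ trials (the conservative count, since segments within a trial are
correlated). RMSprop was chosen for this profile because its validation
loss descends near-monotonically on this problem, which keeps patience-2
early stopping from firing during the initial plateau; Adam at comparable
rates shows post-convergence oscillations that interact badly with the
no-weight-restore stopping rule.

Problem sizes throughout the test suite are chosen so the whole suite runs
in minutes on one core: full-length trials wherever geometry matters,
reduced cohort sizes and epoch caps for the training checks, and tiny
specs (units ≤ 4, 5–20 timesteps) for the gradient and parameter oracles.

## Known limitations and open choices

* The VA-quadrant wording for relaxed/boredom ("medium arousal") is
  interpreted as the strict quadrant reading (negative arousal); axis
  ratings are never assigned an emotion.
* Whether printed accuracies of this protocol family come from
  early-stopped or fixed-epoch runs is ambiguous; both are computed.
* Folds are unstratified by class ("randomly divided"); stratification is
  not implemented beyond the generator's exact-count mode.
* The acquisition-table sampling rate (one source says 256 Hz) is taken as
  250 Hz, consistent with 15,000 = 60 s × 250 Hz everywhere else.
* Subject-independent (leave-subject-out) evaluation is out of scope; the
  protocol is subject-dependent.
* The synthetic effect is a single spectral mechanism; real affective EEG
  is richer, and transfer of these recovery results to real data is an
  open empirical question, not a claim of this package.
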