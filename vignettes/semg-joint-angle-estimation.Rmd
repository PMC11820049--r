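---
title: "Estimating lower-limb joint angles from surface EMG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating lower-limb joint angles from surface EMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Surface electromyography (sEMG) records the electrical activity of muscles
from skin electrodes. Because muscle activation precedes and drives joint
motion, the slow-varying amplitude (the *envelope*) of sEMG from a set of
lower-limb muscles carries enough information to estimate the continuous
hip, knee and ankle angles during movement — the basis of intuitive control
for exoskeletons, prostheses and rehabilitation robots. `semg2angle`
implements a complete offline estimation pipeline for this task:
preprocessing, sliding-window dataset construction, a cascaded temporal
convolutional network with attention (the `cb_tcn` estimator), four
reference estimators, a fixed training recipe, cross-validated evaluation,
and statistical model comparison. A synthetic-session simulator with a
fully known forward model makes every stage testable without human
recordings.

## Signal model and preprocessing

Raw sEMG (7 channels at 2000 Hz) is band-passed with a fourth-order
Butterworth filter (20–450 Hz), cleaned of power-line interference with a
second-order notch at 50 Hz (Q = 35), full-wave rectified, and low-passed
at 10 Hz to form the envelope. Motion-capture markers (100 Hz) are
low-passed with a fourth-order zero-phase Butterworth at 15 Hz; the angle
at each joint is the included vertex angle of a marker triple,

$$\theta = \arccos\!\frac{(\mathbf a-\mathbf b)\cdot(\mathbf c-\mathbf b)}
{\lVert \mathbf a-\mathbf b\rVert\,\lVert \mathbf c-\mathbf b\rVert},$$

with the cosine clamped to $[-1,1]$. Both streams are resampled to a
common 20 Hz analysis rate (joint kinematics are band-limited well below
10 Hz, so this loses nothing and cuts computation).

Two points the protocol leaves open were resolved as follows and are
flagged for anyone comparing against other implementations:

* **Rectification before the envelope low-pass.** A low-pass applied to a
  zero-mean EMG signal yields approximately zero; full-wave rectification
  first is standard envelope practice and is what `extract_envelope()`
  does.
* **Zero-phase EMG filtering.** Only the kinematic filter is explicitly
  zero-phase in the source protocol. This is an offline tool, so all EMG
  filters default to forward–backward application (zero lag, squared
  magnitude response — a fourth-order design therefore has an
  eighth-order magnitude characteristic); `zero_phase = FALSE` switches
  every stage to a causal chain.

Butterworth designs use the bilinear transform of the analog prototype and
were verified coefficient-by-coefficient against an independent reference
implementation; the notch is the standard Q-parameterised biquad. The
package implements `lfilter`/`filtfilt` itself (with odd-reflection edge
padding) because no DSP package is assumed; the recursions run through
`stats::filter()` at C speed.

## Sliding windows

A trial of length $T$ becomes overlapping windows
$w_i = (x_i, \dots, x_{i+W-1})$ with $W = 10$ and step $S = 1$, giving
$T - W + 1$ windows — each an independent training sample. The window's
target is the angle at its **last** sample (causal alignment, matching the
network's design; a centre-sample policy is available). Per-channel
z-scoring is fitted on training folds only and applied to held-out folds.

## The estimators

The `cb_tcn` estimator is a cascade **TCN → attention → TCN → linear
head**:

* **Causal dilated convolutions**: output at time $t$ sees only inputs at
  $t' \le t$, via left zero-padding of $(K-1)d$ for kernel size $K$ and
  dilation $d$. The current sample carries the first coefficient; the
  textbook variant that excludes the current sample (an indexing
  convention, not a different operator) is kept in the test suite as an
  oracle only.
* **Residual blocks**: two (conv → batch-norm → ReLU → dropout) stages
  plus an identity (or 1×1-conv) shortcut, with ReLU after the addition.
  Batch normalization follows the protocol being implemented; the original
  TCN literature's weight normalization is not used.
* **Attention (CBAM, adapted 1-D)**: channel attention pools the feature
  map over time (average and max), pushes both descriptors through a
  shared two-layer MLP ($C \to k \to C$, $k = \max(C/8, 1)$), sums, and
  applies a sigmoid; temporal ("spatial") attention pools over channels,
  concatenates the two pooled rows, convolves with a width-3 kernel
  (symmetric zero padding) down to one channel, and applies a sigmoid.
  Both attention maps lie strictly in $(0,1)$, so reweighting never
  amplifies. A published notational ambiguity (the channel-MLP output
  written as a scalar) is resolved as the standard per-channel form. A
  `cbam_bypass` flag forces both maps to 1, turning the cascade into an
  exact ED-TCN — used for the architectural-ablation identity test.
* **Baselines**: `ed_tcn` (the cascade without attention), `tcn` (one
  stage), `lstm` (gated recurrent layer, hidden size = channel width), and
  `wiener` — ridge-regularised FIR least squares on the flattened window
  (intercept unpenalised, default ridge $10^{-6}$, i.e. effectively the
  least-squares optimum: the strongest honest linear baseline).

There is no deep-learning framework in this stack, so all layers carry
hand-written backward passes; the test suite checks every layer type
against numeric differentiation (relative error $< 5\times10^{-4}$).

**Defaults and why.** Two residual blocks per stage, kernel 3, dilations
(1, 2): receptive field $1 + 2(K-1)(1+2) = 13 \ge W$. Channel width 32 and
dropout 0.1: a width of 64 (with dropout 0.2) works but pushes the default
five-fold protocol past a ten-minute single-CPU budget for no accuracy
gain at these data sizes; both are plain arguments of `model_spec()`.
Weight initialisation is the fan-in uniform scheme under a recorded seed.
Targets are z-scored internally during network fitting (training-fold
statistics) and predictions mapped back to degrees — raw-degree targets
(~100–170) destabilise early training under MSE with the fixed
learning-rate recipe; metrics are always computed in degrees.

## Training recipe and evaluation

Adam with MSE loss, batch size 50, 50 epochs, L2 weight decay (default
$10^{-4}$, unstated in the source recipe), and step-decay learning rate
$\mathrm{lr}(e) = 0.001 \cdot 0.5^{\lfloor e/10 \rfloor}$. Evaluation is
5-fold cross-validation. Fold assignment defaults to **whole trials per
fold** (`by_block`): with $S = 1$ adjacent windows share $W-1$ samples, so
randomly splitting windows (`by_window`) leaks near-duplicates into the
held-out folds; the option exists, and a test demonstrates its optimism.

Per fold and joint the package reports

$$R^2 = 1 - \frac{\sum_t(\hat y_t - y_t)^2}{\sum_t(\bar y - y_t)^2},\quad
\mathrm{RMSE} = \sqrt{\tfrac1N\sum_t(\hat y_t-y_t)^2},\quad
\mathrm{NRMSE} = \frac{\mathrm{RMSE}}{\max y_t - \min y_t},$$

with $R^2$ never clipped (negative values are reported) and the NRMSE
range taken from the measured series. Models are compared per joint by
one-way ANOVA on per-fold metric values followed by Tukey HSD at 0.05; the
unit of analysis (CV fold) is recorded in the result object because
subject-level and fold-level analyses differ in general. All-tied groups
make F undefined and are reported as degenerate rather than significant.

## The synthetic world

The simulator emulates the four movement patterns of the underlying
experimental protocol (gait ≈ 5.5 s trials, obstacle crossing ≈ 5 s,
squatting 25 s / 10 repetitions, seated knee flexion–extension 20 s / 10
repetitions; 5 trials per pattern) at the protocol's rates (2000 Hz sEMG,
100 Hz markers). Published sources give durations and repetition counts
but no joint-angle ranges, so trajectory shapes and amplitudes are
simulator configuration, chosen once to be physiologically plausible
(e.g. gait cycle 1.1 s; included knee angle swinging roughly 120°–170°)
and never asserted as measured values.

The forward model, chosen for transparency rather than biomechanical
fidelity:

1. **Trajectories**: smooth harmonics (< 5 Hz) of the cycle phase, with
   smooth cycle-amplitude modulation and slight phase drift (self-paced
   movement is not metronomic; ~30 % for the fast many-cycle patterns,
   ~10 % at a small fraction of the cycle rate for the counted-repetition
   patterns so each repetition keeps exactly one peak), a per-trial
   amplitude jitter, and a smooth `tanh` range guard keeping every
   included angle inside (5°, 175°) so the marker construction is always
   well-posed.
2. **Activation**: each of the seven muscles (RF, TA, SOL, GAS, VM, VL,
   BF) has a fixed drive — a weighted sum of normalized joint angles,
   angular velocities, and *co-contraction* terms (the magnitude of joint
   velocity: stabilising effort is paid in both movement directions) —
   advanced by a 50 ms electromechanical delay and passed through
   rectified-linear-plus-saturation, $a = \tanh(5\,\mathrm{relu}(u))$.
   Antagonists therefore alternate within the cycle and saturate near full
   effort.
3. **EMG synthesis**: activation multiplies a unit-RMS Gaussian carrier
   band-limited to 20–450 Hz; a 50 Hz line component (amplitude equal to
   the modulated-signal RMS) and broadband baseline noise at a configured
   SNR (default 20 dB) are added. Markers are three per joint in a fixed
   plane — the minimum the cosine formula needs, not a full-body set.

Design notes on the forward map: early drafts used a smooth monotone
(logistic) map of strictly periodic trajectories. That world is almost
linearly invertible — a static nonlinearity of a periodic signal stays
harmonic, and rectified antagonist pairs can be linearly recombined — so a
lagged least-squares baseline matched the networks and the world failed
its own purpose of rewarding nonlinear temporal modelling. The frozen
model's co-contraction terms (even functions of velocity) and deep
saturation remove that degeneracy while keeping the map transparent and
partially invertible for tests.

**What a green test establishes — and what it does not.** The simulator
produces envelopes whose correlation with the commanded activation exceeds
0.9 at 20 dB SNR, and an envelope→angle relation nonlinear enough that the
attention-TCN cascade beats the Wiener baseline out of fold. It does *not*
reproduce real sEMG's nonstationarity, electrode-shift and crosstalk
artefacts, subject-to-subject variability, or true musculoskeletal
dynamics (no ground-reaction forces, no anthropometry). Accuracy numbers
obtained on this world say the pipeline is implemented correctly, not that
the method will reach any particular accuracy on human data.

## Numerical choices and degenerate inputs

* Zero-phase filtering needs more than `3 * (taps)` samples; shorter
  series are an explicit error, not a silent truncation.
* `resample()` anti-aliases with a zero-phase Butterworth at
  `0.45 * fs_out` before cubic-spline evaluation on the new grid;
  upsampling warns.
* `joint_angle()` clamps the cosine into $[-1, 1]$; a vertex coinciding
  with a limb marker is a degeneracy error, and the simulator refuses to
  build markers for angles outside (0°, 180°).
* Trials shorter than one window yield an empty window set with a
  warning, never a crash; more than one sample of misalignment between
  the 20 Hz envelope and angle streams is an error.
* Wiener normal equations are solved with an unpenalised intercept; a
  singular system with `ridge = 0` surfaces as an error suggesting
  regularisation.
* Strict per-time-step causality holds for the TCN stacks (in evaluation
  mode; batch statistics couple time steps during training, as they do in
  any batch-normalised TCN). The full attention cascade pools over its
  window, so its causality contract is at window level: nothing outside a
  window ever influences that window's prediction.

## Known limitations

Single-subject, offline scope: no transfer across subjects, no streaming
inference path, no hyperparameter search, no critically-damped kinematic
filter variant, no gap-filling for occluded markers. The comparison
statistics assume independent metric samples per fold, which trial-blocked
folds make defensible but not exact.
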