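# semg2angle

Continuous estimation of lower-limb joint angles (hip, knee, ankle) from
multi-channel surface electromyography (sEMG), for researchers in
rehabilitation engineering, exoskeleton control and movement science.

Muscle electrical activity precedes joint motion, so the slow-varying
amplitude (*envelope*) of sEMG from seven lower-limb muscles carries
enough information to reconstruct joint kinematics continuously — the
signal a myoelectric exoskeleton controller needs. This package implements
the full offline pipeline:

* **Preprocessing** — 4th-order Butterworth band-pass (20–450 Hz), 50 Hz
  notch (Q = 35), full-wave rectification + 10 Hz low-pass envelope;
  marker trajectories low-passed (15 Hz, zero-phase) and converted to
  included joint angles by the cosine formula
  `theta = acos((a-b).(c-b) / (|a-b||c-b|))`; everything resampled to a
  common 20 Hz rate.
* **Sliding windows** — a trial of length `T` becomes `T - W + 1`
  overlapping windows (`W = 10`, step `S = 1`), each predicting the angle
  at its last sample.
* **Estimators** — the cascaded `cb_tcn` network (causal dilated TCN →
  channel + temporal attention → TCN → linear head) and four baselines:
  `ed_tcn`, `tcn`, `lstm`, and a ridge-regularised FIR `wiener` filter.
  All neural layers carry hand-written backward passes (no deep-learning
  framework is required) verified by numeric gradient checks.
* **Training / evaluation** — Adam, MSE, L2 weight decay, batch 50,
  50 epochs, learning rate `0.001 * 0.5^floor(epoch/10)`; 5-fold
  cross-validation with whole trials per fold; R², RMSE (deg) and NRMSE
  per joint; one-way ANOVA + Tukey HSD across models.
* **Synthetic sessions** — a seeded simulator with a known
  activation→angle forward model (rectified-linear + saturation drives,
  co-contraction terms, electromechanical delay, 50 Hz interference,
  configurable SNR) emulating gait, obstacle crossing, squatting and knee
  flexion–extension, so the whole pipeline is testable without human
  recordings.

## Worked example

Simulate five gait trials, preprocess them, and compare the attention-TCN
cascade against the linear Wiener baseline on identical trial-blocked
folds:

```r
library(semg2angle)

cfg    <- sim_config("gait", seed = 1, snr_db = 20)   # 5.5 s, 2000/100 Hz
trials <- simulate_trials(cfg, 5)
proc   <- lapply(trials, preprocess_session)           # 20 Hz envelopes+angles
ws     <- concat_trials(lapply(seq_along(proc), function(i)
            make_windows(proc[[i]], window_spec(), trial_id = i)))

tspec <- train_spec(seed = 1)                          # the fixed recipe
df <- run_comparison(list(cb_tcn = model_spec("cb_tcn"),
                          wiener = model_spec("wiener")),
                     ws, tspec)
aggregate_metrics(df)
compare_models(df, "rmse")
```

On this machine the run prints (about two minutes on one CPU):

```
   model joint n_folds r2_mean  r2_sd rmse_mean rmse_sd nrmse_mean nrmse_sd
1 cb_tcn ankle       5   0.962 0.0177      1.41   0.365     0.0505  0.00881
2 wiener ankle       5   0.950 0.0206      1.62   0.256     0.0589  0.01110
3 cb_tcn   hip       5   0.971 0.0144      1.29   0.289     0.0462  0.00534
4 wiener   hip       5   0.954 0.0166      1.65   0.290     0.0594  0.00583
5 cb_tcn  knee       5   0.965 0.0227      1.73   0.658     0.0461  0.01100
6 wiener  knee       5   0.943 0.0241      2.23   0.568     0.0602  0.00740
Model comparison on rmse (unit: cross-validation fold )

ANOVA:
 joint        F df1 df2         p note
   hip 3.912455   1   8 0.0833071
  knee 1.669342   1   8 0.2324181
 ankle 1.071651   1   8 0.3308487

Tukey HSD (alpha = 0.05):
 joint          pair      diff     p_adj significant stars
   hip wiener-cb_tcn 0.3620470 0.0833071       FALSE    ns
  knee wiener-cb_tcn 0.5022354 0.2324181       FALSE    ns
 ankle wiener-cb_tcn 0.2065642 0.3308487       FALSE    ns
```

Reading: each simulated trial holds one fold out; `cb_tcn` explains ≈ 96 %
of held-out knee-angle variance (R²) with an RMSE of 1.7° and beats the
linear FIR baseline on every joint on the same folds — the
envelope→angle map of the synthetic world is genuinely nonlinear
(saturating, co-contracting muscles), which a linear filter cannot fully
invert. With only five folds per group the per-joint ANOVA does not reach
significance at 0.05; the comparison machinery is the same one used for
larger designs, and the report states its unit of analysis.

A command-line interface wraps the same steps
(`inst/cli/semg2angle simulate|preprocess|train|evaluate|compare`, see
`?semg2angle_main`).

## Layout

```
R/           sim, preprocess (filters), windows, layers/nets, trainer,
             evalstats, cli
tests/       testthat suite incl. test-acceptance.R
scripts/     acceptance.R
vignettes/   methods vignette (model, assumptions, design decisions)
inst/cli/    command-line launcher
```
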