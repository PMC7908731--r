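---
title: "Continuous EMG decoding for prosthesis control: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous EMG decoding for prosthesis control: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgdec)
```

## The problem

A continuous myoelectric decoder maps multichannel surface EMG (sEMG)
from the forearm onto the positions of a prosthesis's
degrees-of-freedom (DOFs) — anywhere in the movement range, not a fixed
menu of grips. `emgdec` implements a complete offline stack for
building and evaluating such decoders: feature extraction, mimicry
training-protocol generation, feature selection, three decoder
families, nonlinear output smoothing, and the post-hoc analyses used to
compare conditions. A seeded forward simulator stands in for human
recordings so every stage can be exercised and tested end to end.

All kinematics are normalized positions in $[-1, 1]$ per DOF, with $0$
= rest and the sign convention $+1$ = flexion/close/pronation. Decoders
operate under *position control*: if the user relaxes (features at
baseline), the decoded position returns to rest.

## Signal chain

Raw EMG is acquired as 32 single-ended channels at 1 kHz. The
preprocessing chain (`preprocess()`) is a causal cascade — output at
time $t$ uses samples up to $t$ only, matching the real-time contract —
of a 6th-order high-pass Butterworth at 15 Hz, a 2nd-order low-pass at
375 Hz, and biquad notches (Q = 30, a 2 Hz band at 60 Hz) at 60, 120
and 180 Hz. The notch Q is our choice; the surrounding corner
frequencies and orders are the standard chain for this sleeve.
Channels found shorted at setup are listed in `bad_channels` and are
removed before filtering, shrinking everything downstream.

Features are trailing-window mean absolute values (MAV):
`expand_differential()` appends all $n(n-1)/2$ pairwise differences to
the $n$ monopolar channels (528 dimensions at $n = 32$), and
`mav_features()` emits, every 33 samples, the mean of $|x|$ over the
trailing 300-sample buffer. The printed frame rate of such systems is
30 Hz with a 33-ms update; at 1 kHz those are mutually inconsistent, and
we resolve the conflict in favour of whole-sample hops: hop = 33
samples, effective rate 1000/33 ≈ 30.3 Hz. Per-feature resting activity
(`estimate_baseline()`, a 10-s rest average) is subtracted and floored
at zero — MAV features are magnitudes and every decoder here assumes
nonnegative inputs.

## Mimicry training protocols

Training data come from *mimicry*: the prosthesis executes programmed
movements and the user copies them, so the programmed kinematics serve
as labels. `build_phase1_schedule()` produces the two-DOF protocol
(hand open/close, wrist rotation): 12 trials of each of four individual
movements (trapezoids with 0.7-s rise, 3-s hold, 0.7-s fall; 4.4 s), a
second period of 4 trials each, and a third period of 4 trials of each
of eight ordered *combination* movements, in which a second DOF starts
0.4 s after the first reaches its plateau so that both are
simultaneously at full excursion mid-trial (6.6 s total).
`build_phase2_schedule()` extends this to five DOFs (thumb, index,
coupled middle–ring–little, wrist flexion, wrist rotation) with four
periods: 20 individual trials, then 36-trial periods pairing grasp,
open and pinch grips with the four wrist movements in both orders.

Two choices are ours. Trapezoid interpolation is linear (the ramp shape
is not otherwise parameterized), and an inter-trial rest gap of 2 s is
inserted: the protocol's stated wall-clock period lengths exceed the
sum of trial durations, implying rest between trials of unstated
length, and we do not force period durations to match printed minutes.
Trial order is deterministic and blocked by movement; permutation
happens only under an explicit `shuffle_seed`.

`merge_training_sets()` concatenates two sets and, by default,
truncates the longer one at a trial boundary so conditions compared
against each other train on equal data durations. The two phase-one
condition sets (periods 1+2 vs. periods 2+3) are already equal by
protocol design ($48 \times 4.4 = 32 \times 6.6$ s), so in the pipeline
the within-condition concatenation runs with `equalize = FALSE`.

## Alignment and feature selection

Muscle activity leads the prosthesis it is mimicking, and the MAV
window itself smears features backward in time, so features and
kinematics are first temporally aligned: `align_lag()` scans integer
frame lags (±15 by default, about ±0.5 s) and keeps the lag maximizing
the mean absolute Pearson correlation over all (feature, DOF) pairs,
breaking ties toward smaller |lag| and then toward the negative lag.
Positive lag means the kinematics trail the features. The correlation
ridge of box-filtered trapezoids is flat to roughly one frame, so
recovered lags are meaningful at ±1 frame resolution; the synthetic
round-trip tests allow exactly that.

The Kalman and MLP decoders use 48 of the 528 features, chosen by
stepwise Gram–Schmidt selection (`gram_schmidt_select()`): at each step
the candidate whose component orthogonal to the span of the selected
features maximizes the summed squared correlation with the kinematic
DOFs is taken, and that component is orthogonalized out of the
remaining candidates. Features are mean-centered first, making the
criterion invariant to positive rescaling. Combining the DOFs by the
*sum* of squared correlations is our design choice — the multi-output
combination is otherwise open — because it treats DOFs symmetrically.
The number 48 is the established operating point for this feature set.

## The three decoders

**Threshold-modified Kalman filter (mKF).** `fit_kalman()` fits the
standard neural-decoding Kalman filter by least squares over *all*
training frames (no validation split): state model
$x_{t+1} = A x_t + w$, $w \sim (0, W)$, on the kinematics; observation
model $z_t = C x_t + q$, $q \sim (0, Q)$, of features on kinematics.
The state is positions only — no velocity augmentation — consistent
with position-control semantics. Decoding runs the classic
predict/update recursion with the covariance symmetrized each step and
estimates clamped to $[-1, 1]$. The "modification" is a per-DOF output
dead zone: $|v| \le \theta \mapsto 0$, otherwise
$\mathrm{sign}(v)\,(|v| - \theta)/(1 - \theta)$, a continuous map that
keeps full scale reachable. The dead-zone-with-rescale form is our
reconstruction of the published mechanism, which is referenced but not
printed; it satisfies the observable contract (suppresses rest jitter,
identity at $\theta = 0$, continuous, full scale preserved).
`optimize_thresholds()` picks each DOF's $\theta$ from a grid (0–0.5 by
0.02, per-DOF independently; joint search rejected for cost) by
minimizing training MSE of the thresholded output.

**MLP.** `fit_mlp()` trains a fully connected network — two hidden
layers of 128 tanh units, linear output, MSE loss — on the 48 selected
features, split 80/20 *by trial* (percentages are given; the split
granularity is ours, chosen to prevent temporal leakage between
adjacent frames). Training runs three dataset-aggregation iterations of
ten epochs each; true aggregation interleaves newly collected online
data, which an offline build cannot do, so each iteration re-shuffles
and re-concatenates the training set and `aggregate_fn` is the hook
where online data could be injected. Inputs are standardized by
train-split mean and variance.

**Temporal CNN.** `fit_cnn()` uses all 528 features over a trailing
window of 15 frames (~0.5 s) per prediction. The architecture is eight
counted layers: temporal convolution (kernel 5, 64 filters) → tanh →
temporal convolution (kernel 3, 32 filters) → tanh → flatten → dense
128 → tanh → dense DOF. Only the layer count and input width are fixed
by the published description; the kernel/filter/window sizes are our
reconstruction and are exposed as arguments. Data split 75/25 by trial;
training stops when the validation loss has been *equal to or larger
than* the previously smallest loss for five consecutive epochs, with a
200-epoch backstop. Inputs are scaled by the train-split maximum.
Predictions for the first 14 frames of a stream are rest, so the output
is frame-synchronous with the input and causal.

Both networks train with Adam (learning rate $10^{-3}$, batch 64; the
optimizer is unstated in the source description and these are the
field's defaults) implemented in plain vectorized R, deterministic
given (data, seed) on one thread. All decoders share the
`predict_stream()` contract — one clamped kinematic frame per feature
frame — so smoothing and analysis are decoder-agnostic.

## Latching filter

`latch_stream()` smooths decoder output with a recursive nonlinear
filter: per DOF, with $d$ = estimate − previous output,

$$\alpha = \mathrm{clamp}\!\left((|d|/d_\mathrm{full})^{\gamma},\ \alpha_\mathrm{min},\ 1\right),
\qquad y \leftarrow y + \alpha d.$$

Small changes (jitter) move the output by only $\alpha_\mathrm{min}$ of
the way; changes of at least $d_\mathrm{full}$ pass through whole, so
large movements incur zero added latency. The published filter's exact
equations are not printed in its application context; this power-law
form is our reconstruction satisfying every stated qualitative property
(heavy smoothing for small changes, near-pass-through for large ones,
recursive, O(DOF) per step). Defaults $d_\mathrm{full} = 0.3$,
$\gamma = 2$, $\alpha_\mathrm{min} = 0.01$ damp 0.02-range jitter about
a hundredfold while letting half-range movements settle within two
frames; the hyperparameter was reportedly not tuned per algorithm,
which is why the config is exposed.

## Simultaneity statistic

For a two-DOF decoded trace, `simultaneous_proportion()` reports the
time the hand and wrist are simultaneously active divided by the time
either is active. Active means ≥ 35% of the movement window for wrist
rotation (either direction) and ≥ 20% *closing* for the hand — holding
an object requires closure, so the hand criterion is directional while
the wrist's uses magnitude. Simultaneous frames are grouped into
contiguous bouts and bouts shorter than 1 s are discarded as sporadic
predictions; the denominator is not bout-filtered, since the exclusion
rule applies to simultaneous movements only. The statistic is computed
on the output stream the prosthesis would receive (post-latching when
latching is enabled). `compare_simultaneity()` runs the per-participant
comparison: Shapiro–Wilk gate, one-way ANOVA across algorithms, Tukey
HSD pairwise follow-ups — all delegated to the standard `stats`
implementations.

## Statistical comparison plans

`participant_medians()` aggregates trial tables to one median
completion time per participant-condition cell over *successful* trials
only (cells without a success are kept and flagged), summing auxiliary
counts such as drops. `run_comparison()` executes a declared
`comparison_plan`: paired Wilcoxon signed-rank (two groups, paired on
declared id columns), Kruskal–Wallis with paired signed-rank follow-ups
when significant, or ANOVA + Tukey. Pre-planned hypotheses run
uncorrected; post-hoc plans apply the Dunn–Šidák correction
$p' = 1 - (1-p)^m$. An all-ties signed-rank case returns a flagged
no-information result instead of an arbitrary p-value.
`preference_rank_analysis()` covers algorithm preference ranks
(permutations of 1..k per participant-task): Kruskal–Wallis over the
pooled ranks, Šidák-corrected pairwise follow-ups, median ranks.

## The synthetic-EMG forward model

`synth_config()`/`gen_emg()` emulate a mimicry recording session well
enough to exercise every pipeline stage:

1. Each DOF excursion is rectified into two nonnegative directional
   drives — flexion and extension use different muscles.
2. A nonnegative synergy matrix (default: one muscle per drive plus
   mild seeded cross-talk) maps drives to muscle activations, and a
   nonnegative muscle-to-channel matrix maps activations to per-channel
   envelopes. Default channel tuning places muscle bellies at evenly
   spaced, jittered locations along the electrode array with Gaussian
   spatial falloff: antagonists occupy distinct electrodes, as real
   flexor and extensor compartments do. (Fully random placements can
   make antagonist pairs linearly indistinguishable, which no real
   forearm exhibits.)
3. The raw signal is white Gaussian noise amplitude-modulated by
   baseline + gain × envelope at 1 kHz. There is no motor-unit-level
   structure: MAV statistics are faithful, spectral/waveform detail is
   not, so passing tests demonstrate pipeline correctness, not
   physiological realism. Electrode shift, fatigue and imperfect user
   mimicry are likewise not modelled.

The SNR is defined in the feature domain: `snr_db` is $10\log_{10}$ of
the mean squared full-scale envelope excursion over the variance of the
baseline-only MAV noise ($\sigma_b^2 (1 - 2/\pi)/B$ for a $B$-sample
window). The gain is calibrated once per configuration against
full-scale single-DOF excursions — not against the realized kinematics
— so envelopes remain exactly linear in the drive. The default 20 dB
represents a clean surface recording.

`make_training_set()` renders a schedule's kinematics (plus a 12-s
leading rest that supplies the 10-s baseline window), synthesizes EMG,
runs the full feature chain, and pairs each feature frame with the
ground-truth kinematics at its MAV window centre, so the paired data
carry no intrinsic lag and an injected `lag_frames` is recovered by
`align_lag()` (to within the one-frame ridge noted above).

## Numerical and testing choices

- Filtering, envelope interpolation and MAV are exact integer-sample
  computations; the MAV oracle in the tests is a brute-force double
  loop.
- Degenerate inputs: constant series are excluded from alignment
  correlations (all-degenerate errors out); exhausted Gram–Schmidt
  residuals stop selection early with a warning; rank-deficient
  least-squares fits fall back to a small ridge with a warning; a
  singular innovation covariance (possible with noiseless synthetic
  data) is solved with a $10^{-10}$-scale regularizer.
- Ties: alignment prefers smaller |lag| then negative; threshold grids
  prefer the smaller threshold.
- Reproducibility: every stochastic step (simulation, splits,
  initialization, shuffling) derives from an explicit seed through a
  save/restore RNG wrapper, so fits are bit-identical given (data,
  seed).

The test and acceptance harnesses run reduced problem sizes chosen to
exercise every code path at desk scale: two-DOF schedules of 2–3 trials
per movement on 8 synthetic channels (36 features) for the
decoder-recovery checks, with the full 32-channel/528-feature geometry
covered in the feature-extraction and protocol tests. At 20 dB SNR all
three decoders reconstruct held-out kinematics with per-DOF correlation
well above 0.8 under these conditions, and accuracy degrades
monotonically as SNR drops — properties the suite asserts over fixed
seeds.

## Known limitations

- The dead-zone rescale, CNN internals and latching equations are
  documented reconstructions of referenced-but-unprinted mechanisms;
  each satisfies all stated observable properties but may differ in
  detail from the originals.
- Human-subject outcomes (task times, drops, workload, preferences)
  cannot be reproduced without participants and a physical prosthesis;
  the statistics module reproduces the *plans* (grouping, pairing,
  N's, corrections), not the published p-values.
- No EDF or HDF5 I/O; recordings, features and traces exchange as CSV,
  models and configurations as JSON.
- The simulator's linear synergy model cannot probe the nonlinear
  EMG-kinematics relationships that favour deep networks on real data;
  decoder rankings on synthetic data should not be read as predictions
  of real-world rankings.
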