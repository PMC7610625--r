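---
title: "Closed-loop thalamic DBS for essential tremor: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop thalamic DBS for essential tremor: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Essential tremor is intermittent: it appears during voluntary movement and
sustained, tremor-provoking postures, and is largely absent at rest.
Continuous thalamic (VIM/ZI) deep brain stimulation therefore delivers
much of its current when none is needed. `tremorloop` implements a
closed-loop alternative: local field potentials (LFPs) recorded from the
*same* electrodes used for stimulation are decoded in real time to detect
tremor-provoking movement states, and stimulation is switched on only
while those states persist. The package provides every stage of that
loop — a physiologically structured session simulator with ground truth,
causal preprocessing, feature extraction on a 100 ms update grid,
data-driven labeling, classifier training and selection, the on/off
controller, and the offline evaluation metrics — so the whole system can
be developed and stress-tested without patient recordings, which are not
publicly available for this paradigm.

# The decoding and control model

Decoding runs at 10 Hz: every 100 ms frame, a trailing analysis window of
each bipolar LFP channel is summarized by 12 features, and a pre-trained
classifier emits a probability-like score. Thresholding the score gives a
binary detection; the controller is the raw state machine

* stimulator off + detection 1 → on,
* stimulator on + detection 0 → off,
* otherwise unchanged,

with no debounce or ramping. Because stimulation contaminates the
recording (and alters neural activity), separate models are trained for
the stimulation-on and stimulation-off states, and separate models per
task (voluntary movement vs. sustained posture); the model consulted at
frame *k* is chosen by the stimulator state at frame *k − 1* — the
one-frame model-selection lag is the loop's only delay. The stimulation
amplitude is binary: 0 V or the clinically determined value (1–3 V,
default 1.95 V) at 130 Hz, biphasic pulses of 60 µs per phase with a
20 µs interphase gap.

## Features

The exact 12-feature set used clinically is not public; the package fixes
a defensible, configurable choice (`feature_spec()`): log mean
periodogram power (Hann taper, trailing window) in eight bands —
3–7 (theta/tremor), 8–12, 13–20 and 21–30 (beta), 31–45, 55–95 (gamma),
105–195, 205–395 Hz — plus RMS, line length, and Hjorth mobility and
complexity. The bands cover the state effects the decoder exploits
(postural theta increase, movement/postural beta desynchronization,
movement gamma increase) and leave out 50 Hz and its first harmonic; the
two high bands carry stimulation artifact and aliased energy, which is
informative *within* a stimulation state because models never cross
states. Features are concatenated across channels (12 per channel); no
cross-channel features are computed. Per-column z-scoring statistics are
estimated on each model's own training frames only.

## Labeling

Training labels are derived from the wearable reference signals, not from
the protocol: movement/posture labels threshold the per-frame RMS
envelope of the 10 Hz high-passed, rectified EMG; tremor labels threshold
the per-frame 3–7 Hz accelerometer band power. Both thresholds are the
midpoint of the two cluster centers of an *exact* 1-D 2-means (sorted
scan — no random restarts), computed on the log scale so labels are
invariant to overall gain, with a 300 ms (3-frame) hysteresis. An
envelope whose cluster centers are closer than 1% of the observed range
*or* closer than 0.5 log units (≈ 1.6× amplitude — windowed noise
envelopes cluster far tighter than any genuine task contrast) is declared
contrast-free and yields all-zero labels with a warning. Accelerometer
band power is summed over the three axes, which equals the band power of
the 3-D vector signal; a sample-wise root-sum-of-squares magnitude would
rectify the signal (a single-axis 5 Hz tremor acquires a 10 Hz component
and a gravity offset) and was deliberately avoided.

## Classifiers, cross-validation, selection

Seven algorithms are available (`ALGORITHMS`): linear SVM (default
`C = 1`; the linear kernel is the default because linear methods are the
strongest performers in this setting and keep real-time cost trivial),
logistic regression, LDA, naive Bayes, decision tree, 5-NN, and a
hierarchical extreme learning machine implemented as a seeded two-layer
random-projection network with a ridge readout (its reference
architecture is unpublished; ours is fixed and deterministic given the
seed). Cross-validation is 5-fold and *block-wise*: folds are contiguous
groups of protocol blocks, never frame-level splits, because neighbouring
frames share 80% of their analysis window and frame-level CV would leak.
Out-of-fold scores are pooled into a single ROC; the AUC is its
trapezoidal integral, which equals pair-counting AUC exactly (an
equivalence the test suite asserts against a brute-force oracle, and
cross-checks against pROC). Per (task × stimulation-state) cell, the
algorithm with the best cross-validated AUC is retrained on all of that
cell's data; ties break by the fixed order svm > lr > lda > nb > dt >
knn > helm.

Tremor *intensity* is regressed from the same features with linear
support-vector regression on stimulation-off frames, fit on the log of
the 3–7 Hz accelerometer power and exponentiated back. Held-out
performance is reported as Pearson r on the log-power scale: per-frame
band power is heavy-tailed, and a linear-scale correlation is dominated
by a handful of full-tremor frames; `r_power` is reported alongside.

# The session simulator

`generate_session()` produces aligned LFP (µV), triaxial accelerometer
(g) and EMG (µV) at 2048 Hz plus the stimulation trace and ground-truth
motor states on the 100 ms grid. Per LFP channel the model is

> 1/f background + beta + theta + gamma + tremor-band oscillations +
> stimulation artifact,

where every oscillation is band-pass filtered white noise (so spectra
show bands, not lines) and the state envelopes do the decoding work:
beta (13–30 Hz, resting RMS 2 µV) is attenuated by 60% during movement
*and* posture; theta (4–7 Hz, resting 1 µV) doubles during posture;
gamma (55–95 Hz, resting 0.5 µV) gains 1.5× during movement; and a
tremor-band component (4 µV RMS at full tremor) follows the limb tremor
envelope — tremor-related thalamic oscillation strong enough that tremor
intensity is recoverable from single-channel LFP, as observed in
patients. Envelopes are smoothed with a 0.2 s first-order constant
(movements start gradually). The background RMS is 5 µV with spectral
exponent 1. `snr_scale` multiplies all four state-modulated components;
setting the individual effect sizes to zero removes all decodable signal,
which the tests use as a negative control.

## Tremor dynamics

Limb tremor amplitude is the product of two first-order processes on the
frame grid:

* **development** `e(t)`: zero at rest; after a task block has been active
  for `tremor_onset_delay_s` (default 5 s — tremor follows movement
  onset with a delay, which is exactly why decoding *movement* can
  anticipate tremor), `e` relaxes toward the full amplitude (0.1 g RMS)
  with `tremor_rise_tau_s = 1.5 s`;
* **stimulation effect** `m(t)`: relaxes toward
  `1 − stim_suppression_fraction` (default 0.53, matching the continuous
  stimulation group mean) with the wash-in constant `stim_tau_s = 1.5 s`
  while stimulation is on, and back toward 1 with the wash-out constant
  `stim_washout_tau_s = 15 s` when it is off.

The asymmetry is deliberate and load-bearing: thalamic stimulation
arrests tremor within seconds, while re-emergence after stimulation stops
takes tens of seconds. A single symmetric constant cannot be both fast
enough for stimulation to act within one movement bout and slow enough
that sub-second missed-detection gaps do not release tremor — and both
behaviours are required for intermittent, decoder-triggered stimulation
to match continuous stimulation's suppression at a fraction of its
energy, which is the phenomenon of interest. With stimulation
permanently on, the steady-state amplitude ratio equals
`1 − stim_suppression_fraction` exactly; a test holds this to 2% after
10 wash-in constants.

The accelerometer carries the tremor oscillation (axis weights 1 / 0.4 /
0.2), broadband noise (0.01 g RMS), and a 0.5–3 Hz voluntary-movement
component (0.05 g) during movement blocks. The EMG is 20–450 Hz noise
whose envelope is multiplied by `1 + 2 × task envelope`, with
tremor-frequency modulation proportional to the tremor envelope.

## Stimulation artifact and aliasing

The artifact is the sampled image of the biphasic pulse train: +1 for
60 µs, 0 for 20 µs, −1 for 60 µs, repeating at 130 Hz, synthesized on a
25× fine grid (51.2 kHz), scaled by `artifact_gain_uv_per_v` (default
2000 µV per volt of stimulation — after front-end shaping this yields
~18 µV peaks at 1.95 V, modest for DBS artifact even in bipolar
recordings, and a 130 Hz line that towers over the LFP background as in
real stimulated recordings), and then **decimated by stride without
anti-alias filtering**, so pulse harmonics above the 1024 Hz Nyquist
frequency fold back to `|k·130 − 2048·round(k·130/2048)|` Hz — the
aliased peaks characteristic of stimulated recordings at this sampling
rate.

One modelling choice deserves emphasis. An *ideal* rectangular doublet
has harmonic amplitudes `|G(f)| = w·sinc(πfw)·2·sin(πf(w+g))`, which
grow with frequency through the low kilohertz; raw decimation of such a
train would make the folded images of harmonics 8–15 dominate the
130 Hz fundamental, which is not what stimulated LFP spectra look like.
Physically, the recorded artifact is not an ideal rectangle: electrode–
tissue interface and amplifier charge-transfer dynamics low-pass the
pulse shape. The artifact path therefore applies a 2-pole front-end
response (default cutoff 100 Hz) on the fine grid *before* decimation.
With it, the fundamental dominates the recorded band above 100 Hz while
the folded components remain present and measurable; the test suite
verifies the folded-line powers against the analytic
`|G(f)·H(f)|²` ratios to 10%.

## Determinism and causality

Every stochastic component draws from its own sub-seeded stream, and all
noise synthesis is causal: 1/f noise is white noise convolved with the
truncated impulse response of a fractional integrator (fixed 8192-sample
kernel; the FFT is used only as a fast convolution engine), band-limited
noise passes through the causal SOS filter and is normalized by the
filter's *analytic* stationary gain rather than the realization's sample
SD. Consequently a session over a longer protocol extends a shorter one
sample-for-sample, and re-running a closed loop whose protocol differs
only after time *t* reproduces the trace before *t* (to floating-point
roundoff of order 1e-14). Identical seed, configuration and stimulation
sequence give identical sessions.

# Preprocessing

The recording chain's filter is reproduced as specified: a forward-only
8th-order Butterworth band-pass, 0.5–500 Hz at 2048 Hz. It is designed
and run in second-order sections (analytic prototype poles → band-pass
transform → bilinear with prewarping) because the 0.5 Hz lower edge makes
the single-polynomial form numerically fragile, and it is applied
strictly causally with carried per-biquad state — chunked (streaming)
filtering is sample-exact equal to whole-signal filtering, which the
real-time loop relies on. Start-up transients are handled by warm-up
flags on the frame grid, never by backward filtering.

The analysis window is 500 ms, trailing (only past samples), updated
every 100 ms. Only the update interval is externally fixed; the window
length is a first-class configuration knob. 500 ms is the default
because it resolves the 3–7 Hz tremor band (2–3 cycles) with acceptable
control latency; the first four frames of a session are warm-up.

# Evaluation

All metrics live on the 100 ms frame grid, warm-up excluded: accuracy
over all frames, TPR over truth-positive frames, FPR over truth-negative
frames, FNR ≡ 100 − TPR; false-negative episodes are maximal runs of
(truth positive, stimulation off), whose total duration equals
FNR × positive time exactly. Tremor power is the mean per-frame 3–7 Hz
accelerometer band power (same estimator as labeling — the two are
commensurable by construction). Delivered energy is indexed by
`Σ [on] · amplitude² · f_stim · 2·pulse_width · frame_s`; the electrode
impedance is a constant factor that cancels in the A-DBS/C-DBS ratio,
the only form in which energy is reported. Anticipation latency compares
the movement decoder and the tremor decoder at thresholds chosen so
their true-positive rates match (ties go to the lower threshold): per
task trial, latency is the time from onset to the first supra-threshold
frame. Session-level condition comparisons use a paired t test.

For synthetic sessions, metric truth comes from the generator's
`truth_states`; for real-style sessions, from the accelerometer/EMG
labels. Both paths are exposed.

# Problem sizes used by the test suite

The suite runs the full system at reduced scale, chosen once: most unit
fixtures use 2 LFP channels and 3 × (10 s task + 10 s rest) protocols;
the closed-loop property checks train one posture bundle on
4 × (20 s + 20 s) sessions at the default 3 channels and evaluate
no-DBS/adaptive/continuous runs across 5 seeds; anticipation checks use
3 seeds. Block durations below the ~30 s of a clinical session change
nothing structural (the frame grid, dynamics and protocols are
identical); they keep the whole suite in the minutes range.

# What the generator does and does not emulate

It emulates: state-dependent band-power modulation with realistic
(band, not line) spectra; delayed, dynamically suppressed tremor;
EMG/accelerometer label sources with their own noise; the stimulation
artifact including its aliasing; block protocols with ~50% task
occupancy; stimulation-state-dependent recording conditions.

It does not emulate: non-stationarity across a session or across days
(electrode stun effect, impedance drift); cross-channel structure and
volume conduction; EEG; amplifier saturation or nonlinearity (the
artifact is purely additive); individual differences in tremor
frequency or spectra; movement-kinematics diversity (one generic
"movement" envelope). Passing tests therefore demonstrate that the
*system* — filtering, features, labeling, training, control, scoring —
behaves correctly and reproduces the qualitative closed-loop phenomena
under a plausible signal model; they are not evidence about decoding
accuracy in patients.

# Numerical conventions

Frames are half-open intervals `[k·0.1, (k+1)·0.1)` from session start;
a session's frame count is `floor(duration × 10)` exactly. Log band
powers are floored at `log(1e-12)`; normalization SDs at `1e-12`
(constant columns normalize to zero). Decision thresholds default to
0.5; detection requires score > threshold. Algorithm ties break by fixed
order; 2-means is exact, not restarted. All seeds are explicit arguments
or config fields; nothing reads the global RNG state without restoring
it.
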