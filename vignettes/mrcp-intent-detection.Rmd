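---
title: "Detecting motor intent from movement-related cortical potentials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting motor intent from movement-related cortical potentials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrcpbmi)
```

## The problem

A slow negative cortical potential — the movement-related cortical
potential (MRCP), the family that includes the Bereitschaftspotential and
the contingent negative variation — builds up over sensorimotor cortex
from roughly 1.5–2 s before a voluntary movement and peaks near movement
onset. An asynchronous brain–machine interface (BMI) can watch the ongoing
EEG for this signature and trigger an assistive device (here, an elbow
exoskeleton for stroke rehabilitation) the moment intent is detected,
ideally *before* the limb moves. The difficulty is single-trial detection:
MRCPs are a few microvolts buried in tens of microvolts of background EEG,
and their peak latency jitters from trial to trial — especially in the
injured brain.

`mrcpbmi` implements the full detection pipeline — signal conditioning,
adaptive-window feature extraction, classifier calibration with a
simulated real-time cross-validation, and a closed-loop replay simulator
with EMG gating — together with a synthetic session generator so that
every stage is testable without access to patient recordings.

## The signal model the generator emulates

`generate_session()` produces what the pipeline assumes the amplifier
delivers: 64-channel EEG (µV, 500 Hz), two bipolar EMG channels (mV, same
clock), elbow position/velocity at 1000 Hz, and trigger events
(target-onset, movement-onset, target-reached; catch trials carry a
distinct target-onset kind).

* **MRCP template.** A half-cosine descent from `ramp_start_s` (default
  −1.5 s relative to movement onset) to the negative peak
  (`amplitude_uV`, default −8 µV), followed by a linear return to baseline
  over `rebound_s` (1 s). The half-cosine was chosen because the empirical
  grand averages are smooth and unimodal and two parameters (onset, depth)
  control it completely; nothing downstream depends on the exact shape.
  Per-trial peak latency is jittered (`peak_jitter_sd_s`, default 0.3 s)
  to reproduce the trial-to-trial variability that motivates the adaptive
  window. `peak_offset_s` (default 0) shifts the whole cortical waveform
  relative to the *kinematic* onset; negative values emulate the slowed
  motor execution of paretic movement, where the measurable velocity
  crossing lags the cortical event.
* **Background EEG.** Independent 1/f-shaped (pink) noise per channel at
  `noise_level` µV RMS (default 2), plus one shared pink component with
  random channel loadings, so that spatial re-referencing has cross-channel
  structure to remove and is not a no-op.
* **Spatial distribution.** The template enters a fronto-central /
  centro-parietal patch (`default_mrcp_gains()`), gain 1 at FCz/Cz tapering
  to 0.4 at the surrounding ring — the bilateral sensorimotor distribution
  reported for stroke patients.
* **EMG.** Baseline 30–200 Hz noise at 2 mV RMS; attempted trials add a
  Gaussian-windowed broadband burst (default 25 mV RMS peak) starting at
  movement onset. Catch trials stay at baseline.
* **Kinematics.** Minimum-jerk elbow excursion over 0–60° in 1.5 s,
  starting at movement onset.
* **Schedule.** Blocks of 20 trials, fixation gaps drawn uniformly from
  4–6 s, self-paced preparation delays of 2.5–4.5 s between target onset
  and movement, 15 s trial budget, catch trials shuffled within block
  (0 per block for calibration sessions, 1–5 for closed-loop blocks).

What the generator does **not** model: ocular/muscular artifact classes
(only an optional amplitude outlier exercises the rejection rule), lesion
topography, electrode impedance drift, or day-to-day nonstationarity. A
green test therefore establishes that the *pipeline machinery* behaves as
specified under the stated signal model — not that any particular clinical
performance level would be reached on patient data.

## Preprocessing

`filter_chain()` applies, in order: a causal 4th-order Butterworth
high-pass at 0.1 Hz, a Large-Laplacian re-reference (each channel minus
the mean of its next-nearest montage neighbours, two 10-10 grid steps ≈
6 cm; edge channels use whatever neighbours exist), a causal 4th-order
Butterworth low-pass at 1 Hz, and decimation to 20 Hz. Design notes:

* **No zero-phase filtering anywhere.** The causal chain delays the
  observed MRCP peak by ~0.5 s; calibration and replay see the same
  distortion, which is the point.
* **Decimation without an extra anti-aliasing stage** — content is already
  limited to ≤1 Hz, so 20 Hz sampling is alias-safe.
* **Streaming equals batch.** All filters carry explicit state
  (`stream_chain()`), and decimation emits one output per full 25-sample
  frame, so chunked processing is bit-identical to whole-record
  processing. This is asserted in the tests; it guarantees the classifier
  meets the same signal online as offline.
* Filter design is done in-package (bilinear transform to second-order
  sections) because no DSP package is available in the target environment;
  coefficients are pinned to reference values in the tests.

Epochs span [−2.5, 1) s (70 samples at 20 Hz) around movement onset
("Go") and non-catch target onset ("No-go"). Artifact rejection is an
automated amplitude criterion (default 100 µV peak-to-peak) standing in
for the original visual inspection, with paired removal so classes stay
balanced. Baseline correction over [−2.5, −2.25] s exists for
grand-average display only and is never applied in the classification
path.

## Features and the adaptive window

The selected MRCP channels are averaged pointwise into a single trace
X(t). A feature window of length `wl` spans `[edge − wl, edge]`:

* **Fixed mode**: Go edge at +0.5 s after movement onset (compensating the
  causal-filter lag), No-go edge at −0.5 s before target onset.
* **Adaptive mode**: the Go edge coincides with the trace's negative peak
  (searched in [−2, 0.5] s), so the window always captures the descending
  limb regardless of latency jitter. Training trials peaking strictly
  earlier than −1.5 s are treated as artifact-corrupted and dropped; a
  peak at exactly −1.5 s is retained (the rejection rule is "earlier
  than"). No-go windows stay fixed in both modes.

From each windowed amplitude vector four features are computed: the
least-squares slope (µV/s; an endpoint-difference estimator is available
as a config alternative), the negative peak (window minimum, µV), the
trapezoidal area (µV·s), and the Mahalanobis distance to the Go cluster,
`d = sqrt((x − µ)' Σ⁻¹ (x − µ))` with µ, Σ estimated from the training
Go windows and ridge-regularized (`1e-6 · tr(Σ)/dim` by default, with a
tiny absolute floor for degenerate inputs). The positive-root exponent is
used: the distance must vanish when x equals the cluster mean. µ and Σ
are fitted **per training fold** — pooling all Go samples, read literally,
would leak test trials into the feature definition under cross-validation.

## Classifier and calibration

A binary C-SVC with RBF kernel `K(xi, xj) = exp(−γ‖xi − xj‖²)` is trained
on z-scored features (scaling fitted per training fold). Because no SVM
package exists in the target environment, the package ships its own SMO
solver (maximal-violating-pair selection, the standard dual formulation
and 1e-3 stopping rule) with Platt sigmoid probabilities fitted to 5-fold
cross-validated decision values; the tests pin its decision values to
LIBSVM reference outputs and verify the KKT conditions directly.

**Pseudo-online cross-validation.** Stratified 10-fold CV whose test phase
mimics deployment: a window of the current length slides through each
held-out epoch in 50 ms steps; a placement is Go when `P(Go|x) ≥ τ`
(τ = 0.5 offline); three consecutive Go placements classify the trial as
Go with the mean probability of those three placements, otherwise the
trial is No-go with the mean probability over its No-go placements.
Chronological order inside trials is preserved and nothing after a
placement's edge can influence it.

**Hyperparameters.** Grid search over C ∈ {10, 100, 1000} ×
γ ∈ {0.2, 0.5, 0.8, 1}, maximizing mean fold accuracy; exact ties break
toward the smaller C, then the smaller γ. The grid runs once per window
length on the full CV rather than nested per fold — the grid is tiny and
nesting would multiply runtime 10× for no change in the selected pair on
the data scales involved.

**Window length.** `wl` is iterated from 0.5 s to 1 s in 50 ms steps (11
candidates); the shortest length attaining the maximum ROC area (computed
from the assigned trial probabilities pooled over folds) is `wl_O`.

**Final model.** The fold with the highest accuracy at `wl_O` (first fold
on ties) supplies the deployed SVC, Go statistics and scaling.

**Permutation test.** Labels are shuffled, the full CV repeated, and the
observed mean accuracy compared against the null with the add-one
correction `p = (1 + #{null ≥ obs})/(1 + n)`. On balanced classes the
null mean sits at ~50%, the chance level the method is benchmarked
against.

## Closed-loop replay

`stream_predict()` scores the trailing `wl_O` window of the spatial
average every 50 ms. An intent fires after `N_c` consecutive predictions
above `τ_c`; the counter then resets fully (both after a fired intent and
after a gate rejection), so one sustained run cannot re-fire immediately.
Every intent is validated by the EMG gate: accepted iff either muscle's
trailing 300 ms RMS (30–200 Hz band, causal) crosses its threshold within
1 s — a logical AND whose TPR and FPR are bounded above by the BMI-only
and EMG-only rates, a bound the tests assert exactly. The first accepted
intent ends the trial (prediction is suspended until the next trial,
mirroring the robot's guided movement); catch-trial acceptances are false
positives; intents during fixation are logged and gate-checked but never
trigger movement and do not enter block metrics. Detections must complete
within the 15 s trial budget, including the gate confirmation.

Two latencies are reported per detected trial because the reference
definition is ambiguous: `latency_s` measures the BMI intent against the
kinematic onset (velocity-threshold crossing; the quantity that can be
negative when intent precedes movement) and `latency_gated_s` measures
the EMG-confirmed detection time. "Time to detect intent" for intents/min
runs from trial start (target onset), the only origin defined for catch
trials as well.

## Numerical and design choices worth knowing

* Event samples and slice indices are 1-based with half-open ranges,
  the R idiom; an epoch is always exactly `round(3.5 · fs)` samples.
* Negative-peak ties break toward the latest time.
* `session_plan()` accepts 0 catch trials per block because calibration
  blocks have none; closed-loop blocks use 1–5.
* The EMG band-pass is realized as a 4th-order high-pass at 30 Hz
  cascaded with a 4th-order low-pass at 200 Hz (8th order overall) —
  numerically safer than a direct band-pass transform for this wide band.
* CoV uses the sample SD (n − 1). Rank-sum comparisons are exact for
  small untied samples, normal-approximated otherwise.
* All stochastic steps (session generation, fold assignment, Platt
  splits, permutations) run under explicit seeds; identical seeds give
  bit-identical containers and replay logs.
* Offline CV fixes τ = 0.5; test trials are never screened by the
  adaptive rule (an online system cannot screen unseen data), so the
  offline accuracy estimate is conservative in the same way deployment is.

## What the acceptance checks establish

The reference results on patient EEG are not reproducible (no recordings
were deposited); the quantitative anchor is the *chance level*: the mean
label-shuffled pseudo-online CV accuracy on a ~150-trial-per-class
synthetic calibration set, which must land at ~49.6% (±2.5 points, ≥100
permutations). The permutation world runs on a 27-channel sensorimotor
strip at a fixed 0.9 s window (a typical optimized length) because the
chance level depends on neither montage size nor window length; this
keeps the run at desk scale. The remaining checks are properties: adaptive
≥ fixed under jitter (SD 0.4 s, five seeds, compared on seed means),
exact gate bounds, oracle equivalences (Mahalanobis/Euclidean, spatial
average/brute-force mean, trapezoidal AUC/rank statistic, rank-sum/exact
enumeration), an end-to-end replay on a clean world (−8 µV, 2 µV RMS,
jitter-free, cortical peak leading the kinematic onset by 0.4 s) that must
detect ≥90% of attempts with negative mean intent latency and zero catch
acceptances, structural contracts (2N × 4 features, 70-sample epochs, 11
window candidates, paired rejection), and bit-exact streaming/batch
equivalence.

## Known limitations

* The synthetic world is stationary within and across blocks; effects the
  reference study attributes to learning or fatigue cannot emerge.
* Platt probabilities are implementation-defined; two solvers that agree
  on decision values may disagree slightly on probabilities, which shifts
  τ-threshold crossings by at most a tick in practice.
* The Laplacian neighbour table is a documented convention (two grid
  steps on a 10-10 layout); the original hardware's exact edge-channel
  assignments are unpublished.
* Marker codes in BrainVision files are rig-specific; the default map is
  only a self-consistent convention for round-tripping.
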