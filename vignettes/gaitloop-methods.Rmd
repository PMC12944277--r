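---
title: "Methods: gait-phase detection and phase-locked stimulation in gaitloop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gait-phase detection and phase-locked stimulation in gaitloop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitloop)
```

`gaitloop` models the analysis-and-control chain of a closed-loop
neuromodulation experiment in mice walking on a treadmill: landmark
trajectories from markerless pose estimation are turned into joint angles,
gait phases, spatiotemporal metrics, a lightweight phase classifier, and
phase-locked biphasic stimulation commands. This vignette explains the
models and procedures, the parameters that matter, the synthetic-data
generator that stands in for animal video, and the package's numerical and
design choices.

## Kinematic model

Five hindlimb landmarks are tracked per frame: iliac crest, hip, knee,
ankle and metatarsophalangeal (MTP) joint, each with an `(x, y)` position
in image coordinates (y grows downward) and a likelihood in [0, 1] from
the pose estimator. Three joint angles are computed by the vector-cosine
method — the interior angle at a joint vertex subtended by its two
neighboring landmarks:

- hip angle at the hip, between iliac crest and knee;
- knee angle at the knee, between hip and ankle;
- ankle angle at the ankle, between knee and MTP.

Because these are angles between difference vectors, they are invariant to
translation, rotation, uniform scaling (hence to the mm-per-pixel
calibration, which is a single scalar from a checkerboard cube of known
square size) and to the y-axis direction. `acos` arguments are clamped to
[-1, 1] so floating-point overshoot cannot produce NaN; coincident
landmarks raise a degenerate-geometry condition that invalidates the frame
rather than aborting a session.

The **pendulum angle** treats the limb as a pendulum about the hip: the
signed angle between the downward vertical through the hip and the
hip-to-MTP vector, positive when the MTP is anterior to the hip. Anterior
is a session-level flag (`direction`), because camera placement determines
whether travel is toward +x or -x in image coordinates and nothing in a
single frame reveals it.

A frame is **valid** when all five likelihoods are at or above the gate
(default 0.8). The gate treats frames *strictly below* 0.8 as unreliable,
so a likelihood of exactly 0.8 passes.

## Event detection, labeling and cycles

Touch-down (stance onset) occurs at maximal limb protraction — a local
maximum of the pendulum angle — and lift-off (swing onset) at maximal
retraction. `detect_transitions()`:

1. smooths the pendulum trace with a centered moving average
   (`smooth_window`, default 5 frames; edges fall back to the raw trace);
2. locates local extrema of the smoothed trace, carrying slope signs
   through plateaus;
3. suppresses extrema closer together than `min_half_cycle_ms`
   (default 60 ms, about half the shortest swing durations seen at this
   scale), keeping the one deviating most from the trace median — this is
   what absorbs one-frame spikes;
4. enforces alternation (exactly one swing onset between consecutive
   stance onsets), keeping the more extreme of same-type neighbors;
5. refines each extremum to the raw-trace argmax/argmin within a
   half-window. The refinement matters: the stance and swing flanks of the
   pendulum wave have different slopes (stance is roughly twice as long),
   and the moving average systematically shifts extrema toward the slow
   flank, which would bias stance durations short by 1–2 frames. The raw
   extremum under symmetric per-frame noise is unbiased.

Extremum-based detection was chosen over velocity sign-change because it is
robust to belt-speed drift and requires no velocity estimate from noisy
position data.

Frames between a stance onset and the next swing onset are stance; between
a swing onset and the next stance onset, swing; frames outside the first
and last detected transition are abnormal, and the likelihood gate
overrides any phase label with abnormal. Cycles run stance-onset to
stance-onset (so stance precedes swing within a cycle), durations are
frame counts times `1000/fps`, and a cycle fails QC if any frame inside it
is abnormal. Adding likelihood dropouts can therefore only convert labels
to abnormal, never swap stance and swing.

## Spatiotemporal metrics and statistics

The stance duty factor is `100 * stance/cycle`, computed per cycle and
then averaged per animal (mean of ratios) — matching the convention that
each plotted point is one animal's mean over its valid cycles; the
ratio-of-means variant is available but not the default. Note the two
conventions genuinely differ: the ratio of the sham group's mean stance
and cycle durations (298.72/438.87 ms) is 68.07%, while the printed
duty-factor statistic for the same group is 67.14%, which is why the
generator parameterizes duty directly (below).

Normalized cycles resample each QC-passing within-cycle trace linearly
onto a 101-point 0–100% grid (grid size is a package choice; the
convention is one point per percent) and average pointwise across cycles.
Group statistics are computed over animal means only — cycles are never
pooled across animals, which would be pseudoreplication.

`welch_t_from_summary()` implements Welch's unpaired t-test from group
means, SDs and sizes, with Welch–Satterthwaite degrees of freedom and a
two-sided p-value. For the stance-duration summaries above it gives
t = 3.94, df = 4.00, p = 0.017. A published one-sided or unrounded-input
analysis of the same summaries can print roughly half that p-value; the
package deliberately reports the two-sided value, since nothing in the
summary statistics justifies a directional prior.

## The phase classifier

The classifier is a feed-forward MLP with layer sizes 3–32–32–3: three
joint angles in, ReLU hidden layers, softmax posteriors over stance, swing
and abnormal. It has `(3*32+32) + (32*32+32) + (32*3+3) = 1283` trainable
parameters. Training minimizes categorical cross-entropy (the only natural
loss for a softmax classifier) with Adam (step size 1e-3, beta1 0.9,
beta2 0.999 — conventional defaults, exposed as arguments), mini-batches
of 128, up to 300 epochs, early stopping on validation loss with patience
25 and checkpoint restoration of the best epoch. The 80/20
train/validation split is a uniform shuffle; class proportions are
intentionally left at their natural imbalance (stance is inherently about
twice as long as swing) rather than rebalanced, so posteriors reflect
realistic priors.

Inputs are z-scored per feature using training-split statistics stored
with the model; `scale_inputs = FALSE` trains on raw degrees for
strict-raw-input deployments. Both modes are provided because a deployed
controller may prefer raw degrees for simplicity; scaling is the default
because it conditions optimization. Models serialize to a self-describing
JSON container (layer sizes, weights, scaling, training config); weights
are written with 17 significant digits, which round-trips IEEE doubles
bit-exactly.

Training runs entirely in R with vectorized matrix arithmetic; at the
package's test and acceptance scales (10^3–10^4 frames, tens of epochs)
this takes seconds. The tests verify the forward pass against an
independent loop-arithmetic oracle and verify that a label-shuffled
dataset trains to chance, ruling out information leakage through the
pipeline.

## Phase machine and stimulation synthesis

At runtime the classifier alone drives the controller state (no lookahead,
no pendulum-based detection — that path is reserved for offline
training-set construction; keeping the two paths separate mirrors how such
systems are deployed and evaluated). The posterior argmax becomes the
candidate state; a stance/swing switch requires the candidate to persist
`debounce_frames` consecutive frames (default 2 — one-frame classifier
blips are the dominant failure mode, and two frames at 156 fps adds only
~13 ms of latency), while an abnormal candidate switches *immediately*:
the safety contract is that stimulation stops without delay when the gait
becomes unreliable. Two indicator lines mirror the state (stance HIGH /
swing HIGH) and are reciprocal by construction — never simultaneously
HIGH; abnormal lowers both.

Stimulation pulses are symmetric biphasic — a negative then a positive
phase of equal width (default 200 µs each) and amplitude, so every pulse
integrates to exactly zero (charge balance, limiting residual charge at
the neural interface). Amplitude is a 12-bit DAC code (4096 levels).
Waveforms are synthesized on a 1 MHz grid so that 200 µs phases are exact
integer sample counts and charge balance is exact in integer arithmetic,
not approximate. The stance channel (DAC1) fires during detected stance,
the swing channel (DAC2) during detected swing. In the default
`phase_locked` mode pulses repeat at `frequency_hz` (default 100 Hz) for
as long as the phase persists; a `fixed_duration` burst mode is also
provided, because onset-triggered recordings alone cannot distinguish the
two continuation behaviors. A pulse, once started, always completes, and
no new pulse starts after its phase ends — this keeps the scheduler causal
(truncating the input at tick t leaves all outputs up to t unchanged, a
property the tests verify directly).

## Serial link model

Joint angles cross the PC-to-microcontroller boundary as a fixed-width
ASCII frame: three zero-padded `"%06.2f"` fields, comma separators, one
newline — exactly 21 bytes, the unique simple fixed-width encoding of
three angles at two-decimal precision. Transmission time is modeled as
`n_bytes * bits_per_byte / baud` with 10 wire bits per byte (8N1 framing):
1.82 ms at 115,200 bps, 0.23 ms at 921,600 bps for the 21-byte frame. The
analytic model is what the package reports — simulated latencies are
labeled as such and never presented as hardware measurements. Malformed
frames raise a condition that the streaming loop logs as a dropped frame
(state persists) rather than crashing.

## The synthetic gait generator

No deposited recordings exist for this kind of experiment, so the
generator is a first-class module that emulates the study conditions and
provides ground truth for every stage.

**Temporal structure.** Per-cycle stance duration and duty factor are
drawn from truncated normals (mean ± 3 SD, and physical bounds), with
cycle = stance/duty and swing the remainder. Group defaults: sham stance
298.72 ± 30.76 ms, duty 67.14%; SCI stance 200.15 ± 30.50 ms, duty
67.66%. Drawing *duty* (rather than cycle) as the second variable is
deliberate: with independent stance and cycle draws, the mean of per-cycle
ratios exceeds the ratio of means by a factor `(1 + cv_cycle^2)` — about
1.9 percentage points here — so a generator parameterized by stance and
cycle cannot simultaneously reproduce the duration means and the
duty-factor statistic. The per-cycle duty SD (2%) and the angle jitter SD
(1.5°) are realism choices: large enough that detection must cope with
cycle-to-cycle variability, small enough that the locomotor pattern stays
recognizable. The default generator adds no extra between-animal offset;
virtual animals differ only through sampling. An experimenter wanting
animal-level heterogeneity can pass per-animal configs.

**Joint trajectories.** Each joint follows a keypoint template on the
normalized cycle (0 = stance onset; stance spans the template's duty
fraction), interpolated with cosine easing: between consecutive keypoints
the curve follows a half-cosine, giving a C1, periodic curve whose extrema
fall *exactly* at the keypoints. A cubic spline would overshoot the
calibrated extreme values, which is why it was rejected. The sham ankle
template is calibrated to stance-onset 88.48°, maximum 118.30° at end of
stance (peak plantarflexion before toe-off), minimum 74.37° at mid-swing
(maximal dorsiflexion); the SCI ankle to 73.67°/76.42°/42.32° (ankle
depression). The sham hip rises in early stance then falls and the knee
does the opposite; the SCI hip shows the reversed early-stance trajectory
(initial decrease). Hip and knee keypoint *values* are package
calibrations consistent with those qualitative shapes. Each frame's
template phase is found by piecewise-linearly warping its within-cycle
stance/swing fraction onto the template's stance/swing spans.

**Landmark emission.** The limb chain is built by forward kinematics: a
canonical pose realizes the three interior joint angles with plausible
mouse segment lengths (crest–hip 8, hip–knee 15, knee–ankle 16, ankle–MTP
9 mm — these set geometry only; angles are scale-invariant), and the whole
chain is then rigidly rotated about the hip so the hip-to-MTP axis matches
a target pendulum trace. Rigid rotation preserves interior angles, so
angle recomputation recovers the generator's angles to floating-point
precision — the package's forward/inverse consistency oracle. The target
pendulum follows a half-cosine per half-cycle with extrema exactly at
stance and swing onsets (amplitude ±20°), making the generated touch-down
and lift-off ground truth unambiguous. The hip anchor sways slowly to
mimic trunk motion; translation affects no angle.

**Abnormal bouts.** Irregular behaviors (twisting, corner dwelling,
reversed running) appear as bouts (default 2/min, ~1 s) during which the
limb collapses to a crouched configuration far from the locomotor
manifold, coordinates are jittered, at least one landmark likelihood drops
below 0.8, and ground truth flips to abnormal. Likelihoods and labels are
consistent by construction: injected likelihood < 0.8 if and only if the
ground-truth label is abnormal.

**What the generator does not emulate** — and hence what passing tests do
*not* show about real data: pose-estimation error structure (correlated,
heavy-tailed landmark misplacement rather than white angle jitter),
belt-slip and speed drift, bilateral or forelimb coordination, gradual
behavioral drift within a session, and the visual confusability that caps
real-video classifier accuracy near 73%. Synthetic stance/swing/abnormal
classes are geometrically well separated, so classifier accuracies on
synthetic data (typically >90%) are a correctness check of the training
machinery, not a claim about real-world accuracy.

## Problem sizes and reproducibility

Tests run on short sessions (10–30 s, i.e. 1,500–4,700 frames) and small
training sets; the acceptance script regenerates three 70 s sham sessions
(about 158 cycles per virtual animal) for temporal-parameter recovery and
one 60 s noise-free session for ankle-template recovery, sizes chosen so
the whole analysis reruns in seconds while keeping Monte-Carlo error well
inside the stated tolerances. Every stochastic step (cycle draws, jitter,
bout placement, weight initialization, batch shuffling, splits) is
seed-controlled; functions that draw random numbers save and restore the
global RNG state, so package calls do not perturb a user's session-level
reproducibility.

## Known limitations

- Event detection assumes a roughly periodic pendulum trace; highly
  arrhythmic gait (long freezes, repeated half-steps) can merge or drop
  cycles. The QC flag marks affected cycles but cannot recover them.
- The duty-factor estimate carries a small negative bias (~0.5 percentage
  points at default noise) from residual flank asymmetry at the refined
  extrema; it is well inside the package's stated recovery tolerance of
  1 percentage point.
- The serial model is analytic; it reproduces wire arithmetic, not
  interrupt latency or driver buffering of a physical UART.
- The MLP trainer is plain R; it is deliberately sized for the 1283-
  parameter architecture and desk-scale datasets, not for large networks.
- Stick diagrams and stimulation amplitudes are expressed in pixels/DAC
  codes; mapping DAC codes to physical current is hardware-specific and
  out of scope.
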