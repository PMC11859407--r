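---
title: "Methods: from surface EMG to simulated robot control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from surface EMG to simulated robot control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`myointent` implements, end to end and fully offline, a myoelectric control
pipeline for an end-effector upper-limb rehabilitation robot: synthetic
surface-EMG (sEMG) acquisition, signal conditioning, nine-class movement-intent
classification with convolutional networks, admittance-style velocity control
of a simulated six-revolute-joint arm, and trajectory-quality scoring. This
vignette explains the models and the choices behind them; the package's tests
compute every empirical number referred to here.

## The synthetic acquisition campaign

Real multi-channel sEMG of this kind is rarely shareable, so the package
starts from a generator that emulates a standard isometric acquisition
protocol. One sequence lasts 85 s: seventeen alternating 5-s phases, nine of
rest (code 0) and eight directional isometric contractions (codes 1–8, one
per 45°-spaced planar direction, arranged clockwise with code 3 pointing
along +x, "right"). Signals are sampled at 2000 Hz on eleven named
shoulder/elbow muscles. A campaign crosses subjects, date groups (the unit of
cross-validation), sets and force levels (5–25 N); `generate_dataset()`
defaults to 3 sets per group so a seven-group subject contributes
7 × 3 × 5 = 105 sequences, matching the scale of a single-subject campaign.

Each channel is a cosine-tuned force generator. During a phase with direction
$d$, the drive of muscle $m$ with preferred direction $p_m$ and gain $g_m$ is

$$a^*_m = \max(0,\, d \cdot p_m)\; g_m \,(F/25\,\mathrm{N})^{\gamma},$$

with $\gamma = 1$ by default (the amplitude–force relation is configurable
because no functional form is established). Activation follows the drive
through a first-order lag (rise 30 ms, fall 60 ms — typical activation /
deactivation dynamics), computed exactly per phase since the drive is
piecewise constant. The activation amplitude-modulates a band-limited
(20–450 Hz) zero-mean Gaussian carrier — the textbook amplitude-modulation
view of the interference EMG signal. On top of the carrier the generator
injects the three artifacts the conditioning chain exists to remove:
broadband sensor noise, 50 Hz line interference, and low-frequency baseline
wander. Default preferred directions spread the eleven muscles evenly around
the circle with a small offset so no muscle is exactly aligned with an intent
direction; gains default to 1.

What the generator deliberately does *not* emulate: motor-unit firing
statistics, spectral compression under fatigue, ECG crosstalk, electrode
lift-off, or any temporal micro-structure that differs between movement
directions. Class information is carried purely by the spatial pattern of
channel amplitudes. Passing classification tests therefore demonstrate that
the pipeline recovers amplitude-coded intent under realistic noise — not that
it would reach the same accuracy on real recordings. Isotonic (moving)
contractions are not generated: with signals of this construction they add
nothing but label noise.

MVC (maximum voluntary contraction) references are synthesized per muscle
from maximal trials held 4 s and repeated five times; the reference is the
peak of the rectified-and-enveloped maximal signal, which bounds the envelope
of every sub-maximal recording at zero noise.

## Conditioning chain

The chain reproduces the standard stages: 4th-order Butterworth band-pass
20–450 Hz, band-stop notch at 50 Hz (quality factor 30 — only the target
frequency is standard, the width is ours), full-wave rectification, and a
linear envelope (2nd-order Butterworth low-pass at 10 Hz on the rectified
signal — the usual linear-envelope practice). All filters run zero-phase
(forward–backward) for offline work; a causal flag exists for simulated
real-time use. Amplitudes are normalized per channel by the MVC reference,
making them dimensionless fractions comparable across individuals.

Windows of exactly 450 samples (225 ms) feed the classifier. Windows that
straddle a label transition are discarded rather than majority-voted —
supervision at rest/contraction boundaries is ambiguous because muscle
activation lags the label. The default stride equals the window
(non-overlapping); 50 %-overlap is available for augmentation. The default
classifier input is the band-passed, notch-filtered, MVC-normalized raw
window; the envelope representation is available by configuration.

## Intent classifiers

Two 1-D convolutional architectures over the 450 × 11 window share a head
(dropout → dense → softmax over the nine classes):

* **cnn** — alternating convolution/pooling: conv(k = 7) → maxpool 4 →
  conv(k = 5) → maxpool 4;
* **mlcnn** — three parallel streams with kernel sizes 3, 9 and 27 and a
  large pooling window of 15 per stream, concatenated.

Kernel sizes and pooling widths are our parameterization of the two design
ideas (an alternating stack vs multi-scale streams with large pooling); the
filter counts, dense width, dropout, batch size, learning rate and L2
penalty are the seven tunable hyperparameters, with admissible ranges
learning_rate ∈ [1e-5, 1e-2], filters₁ ∈ [10, 128], filters₂ ∈ [20, 256],
dropout ∈ [0.1, 0.5], dense ∈ [64, 512], batch ∈ [32, 128], l2 ∈ [1e-7,
1e-3]. Defaults: 1e-3, 32, 64, 0.5, 128, 64, and no L2.

The networks are trained by minibatch Adam on softmax cross-entropy. The
convolution forward/backward passes run in compiled code (im2col + GEMM);
everything is seeded, so identical configuration and seed give bit-identical
models. Early stopping (patience 5, default 30 epochs) monitors **validation
loss**, not accuracy: on separable data validation accuracy saturates within
an epoch or two while the decision margins are still poor, and restoring
"best accuracy" weights would freeze the model in that undertrained state.
Ties at the prediction argmax break toward the lowest class code, i.e.
toward rest — the safe command for a rehabilitation robot.

Evaluation follows the grouped protocol: one fold per date group, the
held-out group never seen in training or validation, the remaining groups
split 80/20. `search_hyperparameters()` runs a seeded random search
(log-uniform for learning rate and L2, uniform otherwise) — random search is
the standard strong baseline when no Bayesian optimizer is available — and
estimates hyperparameter importance from the trial log with a random-forest
variance decomposition.

## Arm kinematics

The simulated plant is a six-revolute-joint arm described by standard
Denavit–Hartenberg parameters; the default set is the UR5, the arm the
control pseudocode addresses, and any 6R geometry can be configured. The
geometric Jacobian is assembled column-wise from the intermediate frames,
$J_i = [z_{i-1} \times (o_n - o_{i-1});\; z_{i-1}]$. The analytic Jacobian
follows as $J_a = \mathrm{blockdiag}(I, B(\alpha)^{-1}) J_g$ with the Z-Y-Z
Euler-rate matrix $B(\alpha)$ (determinant $\sin\theta$; the representation
singularity at $\theta \in \{0, \pi\}$ raises an explicit error). Joint
velocities solve $J\dot q = \xi$ by LU factorization with partial pivoting;
configurations with condition number above 1e8 are rejected as singular. The
geometric Jacobian is verified against a central finite-difference
differentiation of the forward kinematics on 100 random configurations
(max abs error ≤ 1e-5) — an oracle independent of the assembly rule.

## Controller simulation

The control loop runs at 60 Hz (the logging rate of the acquisition rig;
configurable). Per tick: intent is acquired (from a model, a script, or the
simulated patient); rest produces no virtual force, an active intent places a
target 30 mm ahead along the intent direction and produces a virtual force of
4 N (isometric-mimic mode) or 6.5 N (isotonic mode) toward it. On an intent
change the commanded force blends linearly from the previous command to the
new force over T = 0.4 s, which bounds the per-tick force change by
$\lVert \Delta F\rVert\,dt/T$ and removes the steps that would otherwise
excite the arm. The resultant force (virtual + patient hand force in
isotonic mode, combined by vector addition; gravity compensation is an
identity pass-through for the horizontal plane) enters a PID on the force
error with the printed gains Kp = 0.15, Ki = 0, Kd = 0.5 — the derivative
taken on the error — giving the commanded Cartesian velocity. The 6-D loop
structure is kept with the out-of-plane and torque channels driven at zero.
Joint velocities come from the LU inverse-Jacobian solve and are integrated
by explicit Euler at the control rate (the plant has no dynamics of its own,
so a higher-order integrator would only mask the controller's discrete-time
behavior). Positions are clamped to the 0.6 m × 0.3 m workspace with a
corrective velocity step at the boundary.

The simulated patient is a test double for the human: it walks the path's
goal points (for CO-PTP, the eight 0.1 m targets with a return to center
each time; other paths are resampled at 2 cm arc-length spacing), emits the
intent code whose direction best matches the direction to the current goal —
so the quantization error is at most 22.5°, half the 45° sector — and rests
for one tick on arrival (tolerance 10 mm). In isotonic mode it applies a
hand force along the true direction with magnitude
min(stiffness × distance, 25 N). The stiffness default, 40 N/m, was chosen
so the sampled-data interaction loop (patient stiffness × PD gains at 60 Hz)
is stable with a settling time around a quarter second; much stiffer
simulated hands destabilize the loop at the printed gains, which is a
property of the discrete simulation, not of the controller design. All
sessions are deterministic under a fixed seed.

## Standard paths and metrics

Four benchmark paths live on the workspace: the radius-0.1 m circle at the
center; CO-PTP (center-out point-to-point) to eight targets evenly spaced on
that circle, traversed center → target → center in clockwise order, total
standard length 16 × 0.1 = 1.6 m; and two sine paths
$y = 0.1\sin(10\pi x - 0.525)$ and $y = 0.1\sin(5\pi x - 0.525)$ for
$x \in [-0.2, 0.2]$ (the phase constant is read as a 0.525 rad shift; the
typeset source is ambiguous about the parenthesization). Paths are dense
polylines (10⁴ points) with exact point-to-segment distance queries,
cross-checked against a 10⁵-point sampling oracle to 1e-4 m.

Three metrics score a logged trajectory against its standard path:

* smoothness $\lambda_s = v_a / v_{max} \in [0, 1]$, speeds estimated by
  central differences of the logged positions (the estimator is not
  prescribed anywhere, so the package states its own);
* range deviation $\lambda_d = 1/(1 + R_x)$ with
  $R_x = \frac{1}{L}\frac{1}{N-1}\sum_k \Delta s_k^2$ — implemented exactly
  in this squared-distance form; because the sum of squares is not rooted,
  $R_x$ carries units of meters only after the division by the standard
  length $L$, so an `rms` variant (square root of the sum) is provided
  behind a flag;
* normalized path length $\lambda_l = L_r / L$, the traveled length over the
  standard length.

## Problem sizes used by the tests and the acceptance script

The package's own evaluation uses desk-scale versions of the campaign, stated
here as the package's choices: the classifier experiment generates one
subject × 7 groups × 1 set at 25 N (≈ 2 500 windows), trains 8 epochs, and
cross-validates both architectures over the 7 groups; the hyperparameter
search runs its 50 trials on a class-balanced two-group subset at 2 training
epochs (the search ranks configurations; it does not produce the final fit);
closed-loop sessions run up to 120 s per path. On this synthetic, amplitude-
coded task both architectures operate at ceiling; the comparison between
them is reported but cannot show the margin that multi-scale features yield
on real, temporally structured sEMG.

## Known limitations

* The generator encodes intent purely spatially; architectures that exploit
  temporal structure cannot show their advantage on it.
* The plant is kinematic: no joint dynamics, friction, or force sensor
  noise, so closed-loop runs are cleaner than hardware traces.
* The activation lag bleeds signal across label boundaries; discarded
  straddling windows mitigate but do not remove early-phase ambiguity.
* Per-region (workspace-partitioned) models are supported only as a dataset
  partition key; no geometric region definitions ship with the package.
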