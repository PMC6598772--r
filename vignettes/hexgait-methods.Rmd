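---
title: "Models and methods behind hexgait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hexgait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hexgait)
library(dplyr)
```

hexgait analyses limb coordination in walking hexapods from per-frame
kinematics: six limbs (L1, L2, L3, R1, R2, R3) tracked at a fixed frame
rate (150 frames/s by default), each with egocentric positions parallel
and perpendicular to the body axis and optionally camera-frame
positions, alongside body forward, lateral, and yaw velocities. This
vignette explains the models and procedures, the parameters that
matter, and the choices made where the design was genuinely open.

## Swing, stance, and steps

A limb is in *stance* while its foot is planted (stationary in the
camera frame) and in *swing* while it moves to its next foothold.
`classify_swing_stance()` computes the frame-to-frame displacement speed
of each limb in the camera frame, smooths it with a centered five-frame
moving average (shrinking symmetrically at record edges, an edge policy
chosen because it keeps the filter zero-lag), and labels frames with
smoothed speed below 20 mm/s as stance. The 20 mm/s default corresponds
to a per-frame displacement at the scale of typical tracking error;
both the threshold and the window are arguments.

`extract_steps()` converts a raster into one row per complete
swing-plus-stance cycle. Step length is the camera-frame displacement
between consecutive touchdown positions of the same limb; step
direction is the angle of that displacement relative to the body axis
at touchdown. Cycles truncated by the record boundaries are dropped.
Each step carries its mean forward velocity and mean yaw rate, which
later analyses condition on.

`fit_stance_power_law()` fits
$\tau_{\mathrm{stance}} = a\,(v_{\parallel}/v_0)^{b}$ with
$v_0 = 1$ mm/s fixed, by nonlinear least squares started from the
log--log ordinary-least-squares solution. $R^2$ is computed on the
untransformed scale, matching a generic nonlinear-fit report; the
log-scale fit would weight slow steps more heavily. An exactly-fitting
start can leave the initial Jacobian rank-deficient, so the fitter
retries from a nudged start when that happens.

Walking analyses exclude frames below 0.5 mm/s forward speed
(stops and grooming), and speed conditioning uses the named terciles
slow (0--10.2 mm/s), medium (10.2--19 mm/s) and fast (>19 mm/s)
(`speed_terciles()`).

### Stance configurations

`stance_config_stats()` encodes each frame as a 6-bit stance string
(order L1 L2 L3 R1 R2 R3, 1 = stance). A canonical tripod alternates
between 2 such configurations, a tetrapod cycles through 3, a wave gait
through 6. Dwell times are counted within contiguous walking bouts.
When counting the *distinct* configurations of continuous-time model
output, note that two transitions that are simultaneous in the model
can straddle a sampled frame and leave a one-frame sliver
configuration; `min_dwell_frames = 2` excludes configurations that only
ever appear as such slivers. Exact analytic rasters
(`canonical_gait_raster()`) need no filter.

## Instantaneous phase

`estimate_phase()` uses the discrete-time analytic signal: the limb's
parallel position is mean-subtracted per bout, optionally tapered (10%
cosine ramps) to suppress transform edge artifacts, and extended to a
complex signal via the FFT construction of the harmonic conjugate. The
instantaneous phase is the argument of that signal, unwrapped, smoothed
with a third-order Savitzky--Golay filter (15-frame window), and
re-wrapped to cycles on $[0, 1)$; instantaneous frequency comes from
the matching Savitzky--Golay differentiating filter. Smoothing is done
on the unwrapped phase because smoothing wrapped phases corrupts the
wrap jumps.

Phase zero is the maximally posterior point of the limb cycle, so swing
(anterior motion) occupies phases below one half and stance above it.
The raw analytic-signal argument of the parallel position is $\pi$ at
the posterior extreme, so the estimator subtracts half a cycle.

Two caveats matter for interpreting phase-based results on synthetic
data. First, for waveforms with duty factors away from one half the
analytic-signal phase advances non-uniformly within the cycle; the
estimator tracks the model's internal phase to about 0.02 cycles RMS at
moderate duty asymmetry, degrading slowly as stance lengthens. Second,
on *deterministic* model data every cycle is identical, so this
within-cycle distortion is coherent across cycles and can leak into
high harmonics of phase-conditioned statistics; real data decohere it.

All circular statistics (circular mean, mean resultant length, angular
deviation $\sqrt{2(1-R)}$ reported in cycles, von Mises kernel
densities with a plug-in concentration, the two-sample Kuiper $V$) are
implemented in `circ_*()`/`kuiper_statistic()` and verified in the test
suite against direct complex summation and exhaustive enumeration.

`feet_down_vs_phase()` conditions the number of feet in stance on a
reference limb's phase (normalized so the per-count distributions sum
and integrate to one) and reports the dominant periodicity as the
Fourier magnitudes, pooled over counts and computed per frame rather
than from phase bins, since binning aliases when the per-frame phase
step approaches the bin width. Tripod-like coordination modulates the
count twice per cycle. Two cautions on model data: single stance
durations include degenerate configurations whose count never changes
(the exact tripod; the wave that exactly spans its cycle), and the
cycle-coherent artifacts discussed above can rival the two-cycle at a
single stance duration - pooling a range of stance durations (for
instance thirds of the speed range, as the acceptance checks do)
averages them out.

## Template coherence

`template_coherence()` scores the six instantaneous phases against a
canonical template $\{\psi_k\}$ through the Kuramoto-style order
parameter
$r(t)e^{i\Phi(t)} = \tfrac16\sum_k e^{i(\phi_k(t) - \psi_k)}$,
giving 1 for an exact match and 0 for complete cancellation. The four
templates (tripod, left/right tetrapod, wave) are fixed
(`gait_templates()`); the tetrapod coherence of a perfect tripod gait
is $3^{-1/2}$, a useful analytic anchor. `best_gait_fraction()`
assigns each frame to the best-matching template, breaking exact ties
by the fixed priority tripod > left tetrapod > right tetrapod > wave
(the count of ties is reported).

## The six-limb phase model

The model has a single speed-controlling parameter: stance duration.
Each limb's phase advances at $\pi/\tau_{\mathrm{swing}}$ during swing
(phase $< \pi$ mod $2\pi$) and $\pi/\tau_{\mathrm{stance}}$ during
stance. A limb's swing advance is divisively halved while its
ipsilateral posterior neighbour also swings, which organises
posterior-to-anterior metachronal waves, and contralateral pairs are
pulled toward antiphase by a divisive
$\alpha \sin(\theta_{\mathrm{contra}} - \theta)$ term with
$\alpha = 1/8$ by default (behaviour is qualitatively unchanged for
$\alpha$ up to $1/2$; the test suite asserts this).

Integration is fixed-step Heun with the swing/stance indicators
evaluated at each stage point, at a 0.025 ms timestep
(`simulate_six_limb_model()`); `simulate_rule_based()` is the
forward-Euler form, which is the discrete-time rule-based statement of
the same dynamics. The right-hand side is discontinuous at the
indicator switches, so convergence at switching events is first order;
halving the timestep changes 5-second trajectories by a few
milliradians RMS, which is ample for every analysis here. The
integrator refuses timesteps above
$\min(\tau_{\mathrm{swing}}, \tau_{\mathrm{stance}})/20$.

The ipsilateral coupling is one-sided: it delays a limb only while its
swing overlaps its posterior neighbour's. Once swings separate there
is no restoring force, so ipsilateral lags are marginally stable at
long stance durations and, from random initial phases, freeze at
history-dependent values. The default initial condition (`init =
"wave"`) therefore starts on the contiguous metachronal wave - each
swing beginning as its posterior neighbour's ends, sides in antiphase,
with a seeded common offset - which is the configuration the
one-parameter family reaches when stance duration is varied
continuously from the tripod solution; `init = "random"` exposes the
history-dependent regime. From random initial phases the antiphase
coupling acts only during the short swing windows, so convergence to
the $\pm 0.01$-cycle contralateral band takes seconds of simulated
time at the longest stance durations; the default discards a 10 s
transient, which the compiled integrator makes cheap. Stepping
frequency is
$1/(\tau_{\mathrm{swing}} + \tau_{\mathrm{stance}})$; when a
velocity axis is needed for labelling, `stance_to_speed()` inverts the
stance-duration power law with the reference parameters, and is used
for nothing else.

`simulate_stance_sweep()` ramps stance duration continuously over a
run, which matters for manifold analyses: discrete stance durations
produce disconnected rings in segment space, whereas walking varies
speed continuously.

## The canonical-gait simulator

`simulate_canonical_gait()` drives six planar limit-cycle oscillators
(Hopf normal form with relaxation rate `alpha_self` and radius
$\sqrt{\mu}$); $x$ is the limb position and the sign of $y$ marks
swing ($y<0$) versus stance. Uneven duty factors come from a
state-dependent frequency that switches between
$\omega_{\mathrm{swing}}$ and
$\omega_{\mathrm{stance}} = \tfrac{1-\beta}{\beta}\omega_{\mathrm{swing}}$
through a sigmoid in $y$; duty factors are fixed per gait (tripod 1/2,
tetrapod 2/3, wave 5/6), as dictated by how many limbs swing at once.
The sigmoid steepness defaults high (`a_sig = 2000`) because a soft
switch biases the realized duty factor and transition timing.

The pairwise coupling is rotation-style and diffusive: each oscillator
is pulled toward every other oscillator's state rotated by the
template-implied offset. Because duty factors differ from one half, the
offsets are imposed in *cycle time*, not plane angle: the rotation
angle passes through the duty-factor warp between the oscillator plane
angle and the uniform (time-fraction) phase of the cycle. With that
warp, the exactly-phased canonical orbit is an equilibrium of the
coupled system, and the reported ground-truth phases (the uniform
phase) give template coherence 1 up to integration error. Swing
durations are drawn per run from the uniform distribution corresponding
to tripod stepping frequencies of 5--12.5 Hz. The realized wave
direction is checked post hoc and limbs are relabelled if the
time-reversed solution emerged, enforcing posterior-to-anterior
propagation. Integration uses an adaptive Runge--Kutta (`deSolve`,
ode45 method). A run that fails to reach template coherence 0.99 over
the record tail raises an error rather than returning unlocked data.

White Gaussian noise is added to the rendered traces at a
signal-to-noise ratio of 12.5, interpreted as signal power over noise
power (the convention is echoed in the run metadata); ground-truth
phases remain noiseless.

## Rendering and the synthetic scenario generator

`render_limb_positions()` maps phases to egocentric positions as
$x_\parallel = -A\cos\theta$ (phase zero maximally posterior;
amplitude default 1 mm, peak-to-peak 2 mm) plus per-limb anatomical
rest offsets, and builds camera-frame positions kinematically: the foot
is stationary during stance and advances one stride ($2A$) per cycle
during swing following a smoothstep profile, i.e. brief acceleration
and deceleration around a fast mid-swing. The smoothstep edges keep
speed-threshold classification faithful: the measured duty factor on
noiseless renders matches the model's to three decimals at the default
threshold.

`synth_behavior_generator()` composes ground-truth-labelled scenarios
on top of the six-limb model: Gaussian yaw-rate pulses with
limb-role-specific (inside/outside x fore/mid/hind) multiplicative
modulations of swing/stance durations, step lengths, and additive step
direction shifts, all scaled by the instantaneous relative yaw; and
slowing perturbations that step the stance duration of all limbs up at
event onset for a fixed hold. Turn onsets can be locked to a reference
limb phase; the generator finds lock frames on an unmodulated pre-pass
from the same initial state. Body forward velocity is derived from the
effective stance duration through the inverse power law. Everything
imposed is returned as ground truth so analyses can be scored for
recovery.

## Turning and perturbation analyses

`detect_yaw_extrema()` anchors turns at local maxima of |yaw rate|
with a prominence floor (default 100 deg/s) and a minimum event
separation; neither is specified by convention, so both are arguments
and recorded in the result. Steps are symmetrized by turn side: yaw is
folded to its magnitude, limbs are relabelled inside/outside, and step
directions are mirrored for right turns, making the analysis invariant
to mirroring the data (asserted as a test).
`turning_modulation_curves()` restricts to a forward-speed band
(default 15--20 mm/s, to decouple speed from yaw), bins steps by
symmetrized yaw, and reports each parameter relative to the
straight-walking bin (percent for durations and lengths, degrees for
direction), with BCa bootstrap intervals over videos.
`phase_distribution_at_extrema()` compares per-limb event-phase
distributions against the time-invariant ones with von Mises densities
and the Kuiper Monte-Carlo test.

`event_triggered_analysis()` selects trials walking above 5 mm/s on
average in the 100 ms before the trigger and never below 0.1 mm/s
within the post window, normalizes forward speed to the pre-event mean
(the normalization window equals the selection window), pools the
first post-event stance duration over all six limbs, and compares
against random-trigger controls drawn uniformly over valid epochs with
identical selection, using a two-sample Kolmogorov--Smirnov test.

## Statistics

BCa bootstrap intervals (`bca_bootstrap_ci()`) resample recording
units - videos for kinematic aggregates, trajectories for perturbation
analyses - with bias correction from the bootstrap distribution and
acceleration from a jackknife over units; undefined resamples are
redrawn and counted. The Kuiper Monte-Carlo test reports both the
add-one estimate $(x+1)/(n_{\mathrm{perm}}+1)$ and the bound
$x/n_{\mathrm{perm}}$ with an exact Clopper--Pearson interval; with
zero exceedances in $10^5$ permutations the 95% interval is
$[0, 3.68\times10^{-5}]$.

## Manifold embedding

`build_segments()` samples windows of $2h+1$ frames of all 12 limb
coordinates ($h$ = 15 frames at the default 100 ms half-window, giving
372 dimensions), removes each variable's mean per segment, and
standardizes every column across segments. `embed_manifold()` runs
UMAP to three dimensions, single-threaded and seeded so results are
reproducible; neighbor-graph defaults (20 neighbors, min_dist 0.1,
Euclidean) follow library conventions at the sample sizes used and are
recorded on the result. A stance-duration sweep embeds as a
vase-shaped tube: stepping frequency parameterizes its axis and the
global walking phase the angle around it. `manifold_coordinates()`
finds the axis geometrically - among the principal directions of the
embedding it picks the one whose perpendicular projection is most
annular (largest low-quantile radius over median radius), since the
manifold is hollow around its axis - and reports the Spearman
correlation of the axial coordinate with stepping frequency and the
circular correlation of the angle with the reference-limb phase.
`embedding_components()` counts connected components of the seeded
kNN graph after dropping edges beyond the 99th percentile of neighbor
distances; mixtures of distinct canonical gaits separate into multiple
components even at 1% admixture, while a continuous sweep stays in
one.

What the synthetic data do not emulate: tracking noise with realistic
temporal correlations, inter-individual variability, variable swing
durations within a bout, crab-walking, and start/stop transients.
Passing tests on these generators therefore validate the machinery and
the model-level claims, not recording-level robustness.

## Problem sizes

The test suite runs the stance sweep at 10 values x 5 s (Heun,
0.025 ms steps, compiled), embeddings at 1,500--10,000 segments,
bootstrap coverage at 1,000 Monte-Carlo repeats of 400 resamples, and
permutation tests at 500--20,000 permutations; these sizes give stable
statistics for every claim asserted while keeping the default test run
brief.

## A worked example

```{r example, eval = FALSE}
m <- simulate_six_limb_model(tau_stance = 80, duration_s = 5, seed = 1)
limbs <- render_limb_positions(m)
body <- tibble(frame = unique(limbs$frame), v_par = 15, v_perp = 0, v_rot = 0)
res <- run_pipeline(limbs, body)
res$rel_phase |> filter(pair == "L2-R2")
autoplot(best_gait_fraction(res$phase, body))
```
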