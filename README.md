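# hexgait

Quantitative analysis of limb coordination in walking hexapods.

Walking insects coordinate six limbs, each cycling between *stance*
(foot planted) and *swing* (foot moving to its next hold). hexgait is
for researchers who track limbs frame-by-frame (six limbs x two
egocentric coordinates at a fixed frame rate, plus body forward,
lateral and yaw velocities) and want to characterise the structure of
that coordination: how swing/stance patterns, inter-limb phasing and
gait-template similarity change with walking speed, how turning
modulates individual limbs, and how evoked slowing perturbs the
pattern.

The quantitative core:

- **Step kinematics.** Swing/stance classification by thresholding
  smoothed limb speed; per-step parameters; and the stance-duration
  power law `tau_stance = a (v/v0)^b` with `v0 = 1` mm/s, fitted by
  nonlinear least squares. Stance duration is the kinematic parameter
  that carries walking speed.
- **Instantaneous phase.** The discrete-time analytic signal
  `s_a(t) = s(t) + i H{s}(t)` of each limb's position along the body
  axis gives per-frame limb phases `phi_k(t)` (stored in cycles; zero
  at the maximally posterior point), with circular statistics
  (circular means, angular deviation `sqrt(2(1-R))`, von Mises kernel
  densities, two-sample Kuiper `V` with Monte-Carlo permutation and
  Clopper-Pearson p-value bounds, BCa bootstrap intervals over
  recording units).
- **Template coherence.** The Kuramoto-style order parameter
  `r e^{i Phi} = (1/6) sum_k e^{i(phi_k - psi_k)}` scores the
  instantaneous configuration against canonical tripod, tetrapod and
  wave templates; `r = 1` is an exact match, and the tetrapod coherence
  of a perfect tripod is `3^(-1/2)`.
- **Generative models.** A one-parameter six-limb phase model
  (piecewise-linear coupled oscillators producing posterior-to-anterior
  metachronal waves, speed set solely by stance duration; fixed-step
  Heun integration in compiled code) and a coupled limit-cycle
  (Hopf-style) simulator that produces canonical gaits at specified
  duty factors with additive noise. These are first-class, tested
  synthetic-data generators for every analysis stage, including
  configurable turning and slowing scenarios with ground truth.
- **Manifold embedding.** Fixed-length segments of the 12 limb
  coordinate series (372 dimensions at the default 100 ms half-window,
  150 frames/s), embedded with UMAP; the manifold's axial coordinate
  tracks stepping frequency and the cyclic coordinate the global
  walking phase.

## A worked example

Simulate five seconds of model walking at an 80 ms stance duration,
render it to limb positions, and push it through the analysis pipeline:

```r
library(hexgait)
library(dplyr)

m     <- simulate_six_limb_model(tau_stance = 80, duration_s = 5, seed = 1)
limbs <- render_limb_positions(m)
body  <- tibble(frame = unique(limbs$frame),
                v_par = stance_to_speed(80), v_perp = 0, v_rot = 0)
res   <- run_pipeline(limbs, body)
res
#> Gait analysis pipeline: 243 steps, 7 stance configurations

res$rel_phase |> filter(pair %in% c("L2-R2", "H-M"), n > 0)
#> # A tibble: 2 x 6
#>   pair  speed_bin  mean     R ang_dev     n
#>   <chr> <chr>     <dbl> <dbl>   <dbl> <int>
#> 1 L2-R2 medium    0.500 0.975  0.0354   748
#> 2 H-M   medium    0.355 0.979  0.0323  1496
```

The contralateral midlimbs sit at a mean relative phase of exactly half
a cycle (antiphase) with small angular deviation, while the hind-mid
pairing sits away from antiphase - the model's metachronal wave, read
out through the same Hilbert-phase machinery one would apply to
tracked flies.

Fitting the stance-duration power law to noiseless steps generated
from the reference parameters recovers them to machine precision:

```r
v <- runif(200, 2, 30)
glance(fit_stance_power_law(tibble(v_par_mean = v,
                                   stance_dur_ms = 932.8 * v^-1.025)))
#> # A tibble: 1 x 5
#>   r.squared  a_pl     b  nobs sigma
#>       <dbl> <dbl> <dbl> <int> <dbl>
#> 1         1  933. -1.02   200     0
```

`plot_gait_raster()`, `autoplot()` methods for fits, gait fractions and
embeddings, and `plot_modulation_curves()` cover the standard figures.

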