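# pigait — physics-informed gait fatigue assessment from wearable sensors

`pigait` estimates locomotor fatigue (five discrete levels, L0 baseline to
L4 severe) and continuous bilateral-asymmetry indices from multi-site
wearable inertial sensors (triaxial accelerometer / gyroscope /
magnetometer at 100 Hz on eight anatomical sites) and, when available,
vertical ground reaction force. It is written for movement scientists and
methods researchers who want every stage of such a pipeline — signal
conditioning, gait-cycle segmentation, biomechanical feature extraction,
physics-constrained learning — as tested, inspectable R code that runs
without any laboratory data.

## The model in brief

Training minimizes a multi-task objective

L(θ) = L_c + L_r + Σᵢ λᵢ(e, y_f) · L_p⁽ⁱ⁾ + L_u + η‖θ‖²,

where L_c is cross-entropy over the five fatigue levels, L_r the MSE of six
bilateral-asymmetry targets, L_u a heteroscedastic Gaussian
negative log-likelihood, and the four physics penalties are

* **kinematic** — hinge² excursions beyond anatomical limits (hip ±35°,
  knee 0–80°, ankle ±30°) + κ·(second differences)², κ = 0.1;
* **dynamic** — ‖F̂ − F_meas‖² + κ₁‖ΣF − m a_c‖² + κ₂‖Στ_e − Iα‖²,
  κ₁ = 0.5, κ₂ = 0.3, with a_c derived through a differentiable
  seven-segment forward-kinematics / centre-of-mass chain;
* **symmetry** — squared normalized left/right difference with the right
  side cyclically advanced half a cycle, weights decaying as
  exp(−0.15·y_f);
* **energy** — per-cycle balance |E(t_f) + W_d − E(t_i)|² with dissipated
  work W_d = c·∫‖F_g‖dt and a learnable coefficient c (init 0.05).

Effective weights factorize as λᵢ(e, y_f) = λᵢ⁰ · α(e) · β(y_f) with base
weights (0.10, 0.15, 0.08, 0.12), a two-phase warmup/ramp curriculum α and
fatigue amplification β = 1 + 0.15·y_f. The network is a hierarchical
attention model: cross-sensor multi-head attention fusion, a dilated causal
convolution pathway (receptive field 127 samples) in parallel with a
transformer pathway merged by a learned gate, biomechanical heads (joint
angles, GRF, COM velocity, energy), and classification/regression heads
with Monte-Carlo-dropout uncertainty. All gradients flow through a compact
tape-based reverse-mode autodiff engine included in the package; tests
verify every analytic gradient against finite differences.

A seeded synthetic gait-cohort simulator (Fourier gait templates,
double-bump GRF scaled to body weight, fatigue-dependent asymmetry and
variability growth, sensor-frame noise) makes the entire pipeline
verifiable end to end. See the methods vignette
(`vignettes/physics-informed-gait-fatigue.Rmd`) for assumptions, parameter
choices and limitations.

## Worked example

```r
library(pigait)

co <- simulate_cohort(n_subjects = 3, cycles_per_level = 5, seed = 42)
co
#> synthetic gait cohort: 180 cycles, 3 subjects, levels 0,1,2,3,4

sides <- vapply(co$cycles, function(c) c$side, "")
left  <- co$cycles[[which(sides == "left")[1]]]
right <- co$cycles[[which(sides == "right")[1]]]
left
#> normalized gait cycle (left): 101 points, 1.080 s, 72 channels

fs <- extract_features(left, right, mass = left$mass)
fs
#> feature set: 127 descriptors (0 missing)
#>   domains: frequency=35, kinematic=33, kinetic=9, spatiotemporal=11, symmetry=39

round(fs$values[c("cadence", "stance_fraction_left",
                  "peak_vertical_force_left", "sym_index_knee_rom")], 3)
#>                  cadence     stance_fraction_left
#>                  111.111                    0.614
#> peak_vertical_force_left       sym_index_knee_rom
#>                  783.573                    0.000
```

Cadence is in steps/min, stance fraction is the portion of the cycle with
the foot loaded above 20 N, peak vertical force is in newtons (about 1.15
body weight for this 69 kg subject), and the knee-ROM symmetry index is 0%
because this is a baseline (L0) cycle with no programmed asymmetry.

Physics pieces work standalone:

```r
kinematic_loss(left$theta_true)$value       # within limits, smooth
#> [1] 0.0003350096

effective_weights(e = 60, y_f = 3)          # mid-ramp, high fatigue
#> kinematic   dynamic  symmetry    energy
#>    0.0798    0.1196    0.0638    0.0957
```

Training and evaluation at desk scale:

```r
ds  <- prepare_dataset(easy_cohort(seed = 1))
fit <- train(ds, init_model(model_config("tiny"), seed = 1),
             train_config("desk"))
cl  <- classify_samples(fit$model, ds$samples[fit$split$val])
evaluate(cl$pred, cl$truth)[c("accuracy", "macro_f1", "kappa")]
rob <- robustness_suite(fit$model, ds, idx = fit$split$val)
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/pigait.R` (subcommands `simulate`, `preprocess`, `segment`,
`features`, `train`, `evaluate`, `predict`, `robustness`).

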