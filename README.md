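# saccsim

Saccadic suppression — the drop in visual sensitivity around the time of
saccades — is usually described as a perceptual phenomenon. `saccsim`
implements a sensorimotor account: when eye movements are driven by a
closed-loop optimal controller whose state estimator must extrapolate
*delayed* retinal feedback under *signal-dependent* motor noise, the optimal
(Kalman) weight given to sensory input necessarily collapses around each
saccade. The package simulates the full control loop and derives the
suppression window, its timing, its scaling with saccade amplitude, and the
contrast between catch-up saccades and smooth pursuit. It is aimed at
computational and sensorimotor neuroscientists who want a small, fully
inspectable reference implementation of this architecture.

## Model

The oculomotor plant is a second-order low-pass filter with time constants
τ₁ = 224 ms and τ₂ = 13 ms, augmented with a constant-velocity target, in
the state ordering x = (eye position, eye velocity, target position, target
velocity). Discretized at dt = 5 ms (Ad = e^{dt·A}, Bd = ∫₀^{dt}e^{sA}ds·B),
the true state evolves with multiplicative and additive noise

    x(t+dt) = Ad x(t) + Bd u(t) + α ε_t Bd u(t) + ξ_t,      ε_t ~ N(0,1)

with α = 0.08, Σ_ξ = 10⁻³·Bd Bdᵀ, and the retinal signal is delayed by
δt = 100 ms and noisy: y(t) = x(t−δt) + σ_t, Σ_σ = 10⁻⁶·I.

The estimator extrapolates the delayed observation to the present through
the stored command history (finite-spectrum-assignment style),

    x(t|y) = Ad^L y(t) + Σ_{k=1}^{L} Ad^{L−k} Bd u_k,       L = δt/dt = 20,

whose error covariance carries every motor-noise pulse injected during the
delay interval:

    V_t = M(δt) Σ_σ M(δt)ᵀ + Σ_k α² u_k² Ad^{L−k} Bd Bdᵀ (Ad^{L−k})ᵀ.

A Kalman filter with gain K = P⁻(P⁻ + V_t)⁻¹ fuses this extrapolated
pseudo-measurement with the forward-model prediction; `k_pos = K[1,1]` is
the weight of position feedback and the model's proxy for visual
sensitivity. The controller is a finite-horizon LQR (backward Riccati
recursion, u = −L_t x̂, control cost R u² with R = 0.01) over a task
timeline of fixation epochs, a 50 ms free-movement window, and target jumps.
Because V_t is quadratic in the buffered commands, the saccadic burst drives
V_t up — and `k_pos` down — from movement onset until the last burst command
has left the delay buffer: suppression lasts the movement time plus the
delay, and begins (in stimulus time) a full delay before the eye moves.

## Worked example

```r
library(saccsim)

cfg  <- sacc_config()                                  # all printed defaults
traj <- run_closed_loop(make_saccade_task(20, cfg), cfg)  # noise-free 20 deg

detect_saccades(traj)
#>   onset offset duration amplitude peak_velocity
#> 1 0.305   0.37    0.065      19.5          457.

suppression_window(traj)
#> <suppression_report>
#>   baseline gain 0.00293, minimum 4.493e-05 (relative drop 98.5%)
#>   time-locked window: +5 to +145 ms re saccade onset
#>   stimulus-locked:    -95 to +45 ms re saccade onset
```

The saccade lands on target (19.5 deg in 65 ms, peak velocity ≈ 460 deg/s —
main-sequence-like kinematics). The sensory weight drops 98.5 % below its
fixation baseline in a window spanning ≈ 0–150 ms after saccade onset;
shifted by the 100 ms delay, the *stimuli* that are discounted are those
appearing from ≈ 100 ms before to ≈ 50 ms after the eye starts moving.
Suppression deepens with amplitude at nearly fixed timing, and a 2-deg
catch-up saccade suppresses while smooth pursuit initiation does not:

```r
amplitude_scaling(c(5, 10, 20, 30))[, 1:6]
#>   amplitude baseline_gain  min_gain relative_drop onset_ms offset_ms
#> 1         5       0.0275  0.000532          0.981        5       140
#> 2        10       0.00995 0.000164          0.984        5       145
#> 3        20       0.00293 0.0000449         0.985        5       145
#> 4        30       0.00135 0.0000204         0.985        5       145

pursuit_contrast(20)[, c(1, 2, 4, 5)]
#>   variant  n_saccades suppressed relative_drop
#> 1 catch_up          1 TRUE               0.190
#> 2 smooth            0 FALSE              0
```

`autoplot(traj)` and `plot_suppression(traj)` draw the trajectory panels and
the shaded suppression window; `mc_covariance_oracle()` validates the
analytic extrapolation covariance against brute-force stochastic rollouts
(10⁴ rollouts, max entry-wise |z| ≈ 1.2). A thin command-line wrapper lives
at `inst/cli/sacsim.R` (`sacsim.R run --task saccade --amplitude 20 --out
traj.csv`).

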