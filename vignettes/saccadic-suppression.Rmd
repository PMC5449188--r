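---
title: "Methods: closed-loop control, delayed feedback, and the origin of saccadic suppression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: closed-loop control, delayed feedback, and the origin of saccadic suppression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(saccsim)
```

`saccsim` treats saccades as closed-loop movements: a linear-quadratic
controller acts on a state estimate that fuses the corollary discharge (the
forward model driven by the motor command copy) with retinal feedback that
arrives one sensorimotor delay late. This vignette is the package's own
account of the model, its assumptions, the parameters that matter, the
numerical conventions, and what the simulations can and cannot show.

## The model

**Plant.** A second-order low-pass filter: eye acceleration obeys
$\tau_1\tau_2\,\dot x_2 = -x_1 - (\tau_1+\tau_2)\,x_2 + u$ with
$\tau_1 = 224$ ms, $\tau_2 = 13$ ms, so at equilibrium the eye angle equals
the command ($x_1 = u$, in degrees). The state is augmented with a
constant-velocity target block carrying no control authority; the fixed
ordering is (eye pos, eye vel, target pos, target vel). Degrees and seconds
are used throughout internally; the YAML config loader accepts `ms`
suffixes.

**Discrete stochastic dynamics.** Zero-order-hold discretization at
$dt = 5$ ms, computed exactly via the matrix exponential of the augmented
block $[[A,B],[0,0]]$. Each step injects multiplicative motor noise
$\alpha\,\varepsilon_t B_d u$ — a *single scalar* standard-normal
$\varepsilon_t$ scaling the command along the input column — and additive
noise $\xi_t \sim N(0, 10^{-3} B_d B_d^\top)$. The observation is the full
state delayed by $\delta t = 100$ ms plus sensory noise of covariance
$10^{-6} I$.

**Estimator.** The delayed observation is extrapolated to the present with
the stored commands, $\hat x(t|y) = A_d^L y + \sum_k A_d^{L-k} B_d u_k$
($L = 20$ at the defaults). The discrete convolution uses the same $A_d$,
$B_d$ as the simulator, so with noise switched off the reconstruction is
exact to machine precision — a property the test suite asserts. The
extrapolation-error covariance $V_t$ propagates the delayed sensory noise
plus every signal-dependent pulse injected during the delay interval, each
weighted $\alpha^2 u_k^2$ and propagated from its injection time. A Kalman
filter then fuses the extrapolated pseudo-measurement (observation matrix =
identity) with the forward-model prediction. The controller is the
finite-horizon LQR solved by backward Riccati recursion on the noise-free
problem: controller and estimator are deliberately *not* jointly optimized,
which keeps the architecture a plain composition of standard pieces.

## Why suppression falls out

$V_t$ is quadratic in the buffered commands. A saccadic burst therefore
drives $V_t$ up from the first burst command onward, and it stays elevated
until the last burst command leaves the delay buffer: movement duration
plus one delay. The Kalman weight of position feedback,
`k_pos` $= K[1,1]$, moves inversely to $V_t$, producing a suppression
window of roughly 0–150 ms re saccade onset for a 20-deg saccade (50–65 ms
movement + 100 ms delay). In stimulus time the window is shifted a full
delay earlier: the stimuli that end up down-weighted are those from 100 ms
before to 50 ms after movement onset. Right after the saccade the command
transiently undershoots the holding level, so $V_t$ dips below its fixation
value and the gain briefly *exceeds* baseline — post-saccadic enhancement.

## Parameter choices and calibrations

* **Printed defaults** ($\tau_1, \tau_2, dt, \delta t, \alpha$, noise
  scales, $R$): taken as given; `sacc_config()` collects them with
  validation (everything positive, $\delta t$ an integer multiple of $dt$).
* **Fixation cost weight `w_p = 20`** (per step, on squared eye−target
  position error). The weight is a free calibration: it shapes kinematics
  only. `w_p = 1` yields a sluggish 100 ms, 310 deg/s "saccade" with no
  antagonist braking; `w_p = 20` gives 65 ms, ≈ 460 deg/s and the
  characteristic agonist burst followed by an opposite-signed inflection,
  i.e. main-sequence-like 20-deg saccades. Chosen once, on kinematic
  grounds. An optional velocity-error weight `w_v` (default 0) exists for
  pursuit experiments.
* **Terminal cost `terminal_scale = 100`** multiplies the final-epoch cost
  matrix, standing in for fixation continuing ~0.5 s beyond the horizon.
  With a bare terminal cost the finite-horizon gains relax near the end and
  the eye drifts off target during the last ~100 ms.
* **Symmetric saccade targets.** `make_saccade_task(A)` places the targets
  at $\mp A/2$ by default. The fixation-steady gain depends on the holding
  command (at an eccentric target the muscles keep pulling, so
  signal-dependent noise never vanishes); symmetric targets give identical
  pre- and post-saccadic baselines, which is what lets the suppression
  window close back to baseline. A 0→A task (available via `from`/`to`)
  has an ~8× baseline mismatch at A = 20 and no well-defined window offset.
* **Known versus surprise target jumps.** The saccade-task target switch is
  part of the task structure (a pre-planned movement goal), so it is applied
  to the true state *and* the estimator at the movement-window start;
  leaving the estimator to discover it through the 100 ms-delayed feedback
  produces saccades that only begin mid-window and last twice too long.
  Pursuit jumps are genuine surprises and reach the estimator only through
  the delayed observation — that is what builds the 2-deg error
  ($v \cdot \delta t$) behind the catch-up saccade.

## Estimator bookkeeping decisions

* **Control noise lives in $V_t$, not in the prediction covariance**
  (`prior_control_noise = FALSE`). Putting $\alpha^2u^2B_dB_d^\top$ into
  the one-step prior as well makes the prior inflate *instantly* at burst
  onset while $V_t$ — whose most recent commands carry almost no position
  variance yet — lags, so the gain first *rises* and the dip is delayed by
  ~50 ms. Accounting for the control-dependent noise once, in the
  extrapolation variance, places the dip at saccade onset. The flag
  restores the alternative for comparison.
* **Target-block copies.** The plant has no target noise and the retina has
  no eye-independent target measurement. Two mirrored copies handle this:
  the control-dependent part of $V_t$'s eye block is added to its target
  block (`copy_target_vt`, feedback about the target shares the eye's
  uncertainty), and the estimator's process covariance mirrors the additive
  eye-block noise onto the target block (`target_noise_copy`). The second
  copy keeps the target filter stationary: without it the target posterior
  variance decays like $1/t$, the target gain collapses, and catch-up
  saccades become impossibly slow.
* **Innovation indexing.** `innovation_mode = "prior"` (default) is the
  textbook recursion: innovation = extrapolated measurement minus the
  one-step prediction. `"posterior_lagged"` references the previous
  posterior instead; at $dt = 5$ ms the two differ by well under a percent
  of the trajectory.
* **Independence approximation.** The extrapolation error and the
  prediction error share noise realizations over the delay interval but are
  treated as independent when forming the gain. This keeps the update a
  standard Kalman step; the Monte-Carlo oracle checks $V_t$ itself, not the
  joint distribution.
* **Hygiene.** Posterior and prediction covariances are symmetrized every
  step; the test suite checks symmetry and positive semi-definiteness of
  $P$ and $V_t$ over $10^4$ noisy steps.

## Numerical conventions

* Warm start: the delay buffer is pre-filled with the initial fixation
  state and holding command, and the filter covariance is the converged
  fixation steady state (fixed-point iteration to $10^{-14}$), so baselines
  are stationary from the first recorded step.
* Noise-free mode (`seed = NULL`) zeroes the realizations while the
  estimator keeps the full covariances; these deterministic mean rollouts
  are the reference simulations. Seeded runs are bitwise reproducible.
* Saccade detection: 30 deg/s velocity threshold, sub-threshold gaps
  < 10 ms merged. Suppression window: baseline = mean `k_pos` over the
  last 50 ms of pre-movement fixation; edges at a 1 % relative drop; the
  contiguous sub-baseline run containing (or nearest to) saccade onset.
  The 1 % edge tolerance is an order of magnitude above float-level wiggle
  and two orders below the dip itself.
* Pursuit contrast: because the fixation-steady gain falls with
  eccentricity, both pursuit variants' gains decline slowly as the eye
  tracks; the smooth-initiation run therefore serves as the time-matched
  reference trace, and saccade-evoked suppression is the transient drop of
  the catch-up run below it.
* Problem sizes: reference runs are 1 s (201 steps); the robustness run is
  $10^4$ steps; the covariance oracle uses $10^4$ rollouts with entrywise
  z-scores against the Monte-Carlo standard error.

## What the oracle does and does not check

`mc_covariance_oracle()` rolls the open-loop dynamics forward under a fixed
command schedule, injecting exactly the noise channels the analytic $V_t$
propagates — the multiplicative control noise and the sensory noise — and
compares covariances (max |z| < 4 at $10^4$ rollouts for both quiet and
burst schedules). The additive process noise $\xi$ is *not* part of the
analytic extrapolation covariance as formulated, and is therefore excluded
from the default comparison; `include_additive = TRUE` quantifies that
approximation (the mismatch grows like $\sqrt{n}$ in z-units, which the
suite uses as a scaling check). Inside the filter the $\xi$ term is carried
by the prediction covariance instead, so no noise source is dropped from
the loop as a whole.

## Limitations

* One-dimensional horizontal movements; no head, vergence, or 2-D gaze.
* Linear plant and quadratic costs: no main-sequence saturation at large
  amplitudes (peak velocity keeps growing linearly).
* The link from the Kalman position weight to perceptual contrast
  sensitivity is qualitative; the package does not fit psychophysical data.
* Simulations are deterministic mean rollouts plus analytically propagated
  covariances. Real data add trial-to-trial kinematic variability,
  latency jitter, and retinal processing delays (~50 ms) that would shift
  the stimulus-locked window accordingly; passing tests show internal
  consistency of the model, not fits to any particular dataset.
* Post-saccadic enhancement emerges with the right sign and timing but its
  magnitude is modest; capturing measured enhancement of pursuit responses
  would need additional mechanisms.

```{r fig-example, eval = FALSE}
cfg <- sacc_config()
traj <- run_closed_loop(make_saccade_task(20, cfg), cfg)
plot_suppression(traj)
```
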