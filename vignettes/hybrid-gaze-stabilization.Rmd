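---
title: "Modelling saccadic resets in yaw gaze stabilization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling saccadic resets in yaw gaze stabilization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridgaze)
```

## The model

Flying insects stabilize their gaze against wide-field visual rotation with
two interleaved behaviors: a smooth optomotor response that continuously
counter-rotates against background slip, and rapid saccades that discretely
re-orient the gaze. `hybridgaze` models this as a *switched hybrid system*:

* **Flow map (smooth controller).** A PI feedback loop on angular velocity.
  The velocity error $e(t) = \dot\theta_{setpoint}(t) - \dot\theta_{out}(t)$
  reaches the controller only after a sensorimotor transport delay $t_d$;
  the delayed error $e_d(t) = e(t - t_d)$ drives the torque
  $u = K_P^* e_d + K_I^* \int e_d \, dt$ applied to a first-order yaw plant
  $\ \dot v = u - C_u^* v$, where $v = \dot\theta_{out}$ is the body's
  angular velocity. All constants are normalized by the yaw inertia:
  $K_P^*$ and $C_u^*$ carry units of $s^{-1}$, $K_I^*$ of $s^{-2}$.
* **Jump map (saccadic reset).** A supervisor integrates the delayed error
  — the same integral the PI controller uses — and, when its magnitude
  reaches the switching threshold $\sigma$ (degrees), fires a saccade:
  the integrator, the plant state and the delay line are reset to zero and
  smooth flow resumes from this re-based state. The visual feedback
  interruption during the saccade plays the role of an efference copy; the
  body rotation a real saccade produces is deliberately not modelled.

The threshold interpolates between pure strategies: $\sigma = 0$ fires a
saccade at every step (a purely discrete system, heavily bounded near
zero), while $\sigma \to \infty$ never fires and leaves the purely
continuous linear loop, whose open- and closed-loop transfer functions are

$$G(s) = D(s)\,\frac{K_P^* s + K_I^*}{s^2 + C_u^* s}, \qquad
  H(s) = \frac{P^5(t_d, s)(K_P^* s + K_I^*)}
              {s^2 + C_u^* s + P^5(t_d, s)(K_P^* s + K_I^*)}$$

with the delay $D(s) = e^{-s t_d}$ represented by its 5th-order Pade
approximant $P^5$ wherever poles are needed. Because the saccadic reset
re-bases the state in finite time, the hybrid system cannot diverge for any
finite $\sigma$; its stability surrogate is the peak-to-peak response bound
$S_H = \max(\dot\theta_{out}) - \min(\dot\theta_{out})$ rather than a
Boolean.

## Parameters and defaults

| Parameter | Meaning | Units | Default | Why |
|---|---|---|---|---|
| $C_u^*$ | damping-to-inertia ratio of the yaw plant | 1/s | 4.2 | experimentally derived ratio for *D. melanogaster* |
| $K_P^*, K_I^*$ | normalized PI gains | 1/s, 1/s² | (10, 1) in examples | experimentally identified fly gain pair |
| $t_d$ | transport delay | s | 0.020 | fly visuomotor transport latency |
| Pade order | delay approximant order | — | 5 | accurate to well beyond all crossover frequencies used; configurable because sensitivity to order is worth exposing |
| $\sigma$ | switching threshold | deg | `Inf` | continuous system unless the user asks for saccades |
| stimulus | sinusoid amplitude / frequency | deg/s, Hz | 50, 0.5–3 | amplitudes flies readily stabilize; frequency band of natural yaw perturbations |
| `dt` | integration step | s | 1e-4 | two orders below every system time constant; halving it moves SAE and $S_H$ by < 0.5% |
| duration | simulated record | s | 5 | at least 2.5 periods of the slowest (0.5 Hz) stimulus |

The simulator works throughout in degrees and deg/s; the linear analyses
are unit-free ratios.

## Stability analysis choices

**Pole-based stability with an exact-delay cross-check.** `is_stable()`
declares the continuous loop stable when every pole of the Pade-5 closed
loop has real part below $-10^{-9}$; marginal poles count as unstable
(conservative). Because the Pade substitution is an approximation, the test
suite cross-checks the Boolean against the winding number of the
exact-delay Nyquist curve (`nyquist_encirclements()`, which indents the
D-contour around the open-loop pole at the origin) over a gain–delay
lattice; the two routes agree at every tested point. `nyquist_curve()`
itself always uses the exact $e^{-j\omega t_d}$, since the pure delay is
exactly evaluable on the imaginary axis.

**Bisections.** `max_stable_delay()` bisects the delay axis to $10^{-5}$ s
(the delay-free loop is provably stable for positive gains, so the
transition is bracketed); `stability_slice()` bisects the integral-gain
axis to $10^{-3}$. Both tolerances sit far below any feature of the
surfaces they trace. When a bracket never goes unstable the sentinel
(`censored` attribute, or `Inf` for the slice) marks it explicitly.

**Margins.** `gain_phase_margins()` computes classical margins from the
Pade loop — the same rational object the pole analysis uses — by locating
crossovers on a dense logarithmic grid with unwrapped phase and refining
each by root bracketing; when several crossovers exist the smallest margin
is reported, and a missing crossover returns the `Inf` sentinel. The
high-gain system at $(K_P^*, K_I^*) = (60, 700)$ sits very close to
instability, and its margins are correspondingly sensitive to the delay
constant: about 0.5 dB and 3.5° per millisecond of $t_d$. At exactly
$t_d = 20$ ms and $C_u^* = 4.2$ this package computes 1.67 dB and 13.3°
(identical through the Pade and exact-delay routes); readers comparing
against margins quoted elsewhere for similar models should check the delay
constant first, since a shift of only 1 ms moves the high-gain margins by
more than their own size while barely moving the wide margins of the
(10, 1) system.

## Simulator numerics

* **Fixed-step RK4** on the two continuous states (plant velocity,
  error integral), with the delayed error interpolated from the stored
  error history; the delay line is that history read `round(td/dt)`
  samples back, so a delay that is not an integer multiple of `dt` is
  rounded with a warning. Events and transport delays make adaptive
  solvers awkward, and the plant is at most mildly stiff, so a fixed step
  is the robust choice.
* **Event handling at sample resolution.** The threshold crossing is
  detected after each full step, and the reset (integrator, plant state,
  delay-line flush) is applied at that sample — no interpolation of the
  crossing instant. This quantizes saccade times to `dt`, which is two
  orders of magnitude below the stimulus periods studied.
* **One shared delay line.** Both the PI controller and the saccade
  trigger read the same delayed error, i.e. the trigger integrates what
  the controller integrates. Whether a biological trigger sees the delayed
  or undelayed error is not established; `flush_delay = FALSE` exposes the
  main alternative (preserving in-transit error across a saccade) for
  sensitivity analysis. At the fly gain pair the optimal-threshold results
  move by at most one grid step (0.1°) between the two conventions.
* **Instantaneous saccades.** No saccade duration or refractory period is
  imposed; the zeroed integrator provides natural refractoriness, and at
  $\sigma = 0$ the jump map legitimately fires at every step.
* **Divergence.** A state beyond $10^9$ deg/s (possible only with
  $\sigma = \infty$ and continuously unstable gains) halts the run, which
  is returned partial and flagged; `response_bound()` and `sae()` then
  report `Inf`.

## Performance metric

`sae()` is the raw sum of absolute sample-wise errors over the full
record, transient included, with no normalization — so values are
comparable only at a fixed `dt` and duration, which are attached as
attributes. A raw sum needs no linearity assumption, which is the point:
hybrid responses are compared in raw form. All optimal-threshold decisions
are argmins over a $\sigma$ grid and are therefore invariant to any
uniform rescaling of the metric. The default sweep (0–6° in 0.1° steps
plus the continuous sentinel) resolves the optima of interest; the
continuous system is declared the winner whenever the best finite
threshold improves SAE by less than 0.1% (relative), so "optimal" always
means a material improvement over pure smooth pursuit.

Two headline predictions at the fly gain pair (10, 1), 20 ms delay,
50 deg/s stimulus: the SAE-optimal threshold is ≈ 4.9° at 1.5 Hz and
≈ 3.3° at 3 Hz (saccades help only above ~1.5 Hz, and the optimal
threshold falls as frequency rises). The continuous-optimal share of the
stable gain space shrinks monotonically with frequency on the default
grids, while the high-gain corner (e.g. (60, 700)) never benefits from
saccades at any tested frequency — it buys that performance with margins
two orders of magnitude thinner.

## Problem sizes

The bundled experiments and tests run at desk scale, chosen so the whole
suite completes in minutes on one core: gain lattices of 6×5 to 8×8
points, delay grids of 3–8 points, $\sigma$ grids of 13–62 points, 5 s
records at $10^{-4}$ s steps. Every sweep cell is an independent
deterministic simulation, so grids can be scaled up freely without
changing any result at shared grid points; there is no randomness anywhere
in the pipeline (property tests draw random parameter points under fixed
seeds, but the model itself is deterministic).

## What the stability ridge looks like

The maximum-stable-delay surface over the gain plane is not monotone in
$K_P^*$: at high integral gains a ridge of enhanced delay tolerance runs
near $K_P^* \approx 35$, where the system tolerates longer delays than at
either lower or higher proportional gain. The ridge location drifts with
the integral gain — on the default pipeline it peaks at $K_P^* = 35$ for
$K_I^* = 900$, 31 for 700, and 26 for 500 — so "the ridge is at 35" should
be read as a high-$K_I^*$ statement.

## Limitations

* Saccades are pure state resets: the body rotation, its dynamics, and
  any feedback during the saccade are outside the model, as are sensory
  noise and neural implementation.
* Only velocity (gaze-stabilization) control is modelled; there is no
  parallel position/bar-tracking loop, no pitch or roll axis.
* SAE is one scalar priority; robustness, step responses and position
  errors are not folded in (the wide-margin/low-gain versus
  thin-margin/high-gain trade-off is reported, not scalarized).
* The synthetic stimuli are pure sinusoids. Passing tests show the model
  behaves correctly for such inputs; they do not show that real flies'
  broadband, noisy visual input is captured.
* Pole-based stability inherits the Pade approximation; the exact-delay
  Nyquist cross-check guards the tested lattice, not every conceivable
  parameter point.
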