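# hybridgaze

Switched hybrid control models of yaw gaze stabilization in fly flight.

Flying insects such as *Drosophila melanogaster* stabilize their gaze with
two interleaved behaviors: a smooth optomotor reflex that continuously
counter-rotates against wide-field visual slip, and rapid saccades that
discretely re-base the gaze. `hybridgaze` is for computational
neuroethologists and control engineers who want to ask *when saccades help*:
it implements the smooth reflex as a PI velocity controller with a
sensorimotor transport delay acting on a first-order yaw plant, and the
saccadic system as an integrate-and-fire supervisor that resets the
controller and plant whenever the integrated velocity error reaches a
switching threshold σ (degrees).

The continuous limit (σ = ∞) is the linear loop

    G(s) = D(s) (KP* s + KI*) / (s² + Cu* s),
    H(s) = P⁵(td, s)(KP* s + KI*) / (s² + Cu* s + P⁵(td, s)(KP* s + KI*))

with normalized gains KP* (1/s), KI* (1/s²), damping-to-inertia ratio
Cu* = 4.2 (1/s) and the delay e^(−s·td) handled by a 5th-order Pade
approximant P⁵ for pole-based work (exactly, as e^(−jωtd), for Nyquist
curves). The hybrid system (finite σ) is simulated in the time domain with
a fixed-step RK4 integrator, a delay line, and threshold-triggered reset
events; its stability surrogate is the peak-to-peak response bound
S_H = max(θ̇_out) − min(θ̇_out), and its performance metric is the
sum-absolute error (SAE) between setpoint and output angular velocity.

## Worked example

```r
library(hybridgaze)

fly  <- controller_gains(10, 1)    # experimentally identified gain pair
high <- controller_gains(60, 700)  # high-gain corner of the stable region

# Stability margins of the continuous loop at the fly's 20 ms delay
gain_phase_margins(fly)
#> <margins> gain margin: 18.19 dB at 12.91 Hz
#>           phase margin: 103.8 deg at 1.444 Hz
gain_phase_margins(high)
#> <margins> gain margin: 1.674 dB at 11.7 Hz
#>           phase margin: 13.28 deg at 9.7 Hz

# The fly pair tolerates delays an order of magnitude beyond 20 ms
max_stable_delay(fly)
#> [1] 0.2196159

# Hybrid simulation: 2 Hz, 50 deg/s stimulus, switching threshold 3 deg
r <- simulate_hybrid(system_params(fly, sigma = 3), stimulus(50, 2),
                     sim_config(duration = 2))
r
#> <sim_result> 20001 samples over 2 s; 8 saccades
response_bound(r)   # peak-to-peak output bound S_H (deg/s)
#> [1] 56.73082

# When do saccades pay off? SAE-optimal threshold at 3 Hz:
optimal_threshold(fly, f_in = 3, sigma_grid = c(seq(0, 6, 0.5), Inf))
#> [1] 3
```

The margins read the performance/robustness trade-off directly: the fly's
low-gain pair keeps margins of ~18 dB and ~104°, while the high-gain pair
that tracks best in the stable region survives on 1.7 dB and 13° — a system
that wing damage or changed aerodynamics could easily tip into instability.
The optimal threshold of ~3° at 3 Hz says the fly's saccadic system, with
its experimentally reported thresholds of a few degrees, operates near the
SAE-optimal point for its gain set.

Deterministic, file-writing versions of the standard analyses are available
as named experiments (`list_experiments()`, `run_experiment()`) and through
a thin CLI (`inst/cli/hybridgaze.R`), e.g.

```sh
Rscript inst/cli/hybridgaze.R margins --kp 60 --ki 700
Rscript inst/cli/hybridgaze.R simulate --kp 10 --ki 1 --sigma 3 --freq 2 --out out/
```

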