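# velopace

Physics-based pacing optimization for road-cycling individual time trials.

In a time trial the rider's finishing time is decided by how a finite
anaerobic reserve is spent across a course whose segments differ in grade,
heading (hence wind), and cornering geometry. `velopace` models the rider's
steady-state force balance, converts corners into friction-limited speed
caps, simulates per-segment speed strategies against an above-recovery
energy budget, and searches for the time-minimal allocation with a
real-coded genetic algorithm. It is aimed at sports scientists, coaches and
modellers who want a reproducible, inspectable pacing model rather than a
black box.

## The model

On each segment the rider's propulsive force balances

```
F_c = F_air + F_g + F_r + F_acc
    = 1/2 C rho S V_rel |V_rel|  +  m g sin(gamma)  +  mu m g cos(gamma)  +  m a
```

with `V_rel = V - V_wind cos(alpha)` the wind-relative speed (`alpha` the
angle between the segment heading and the wind direction) and, in steady
state (`a = 0`), required pedal power `P = max(F_c V, 0)`.

Riding above the recovery power `P_recover` (the power sustainable
indefinitely by aerobic metabolism, akin to FTP) drains a finite budget
`W_all` (akin to W′ of critical-power theory) at rate `P - P_recover`;
riding at or below it costs nothing. Corners are traversed on the racing
line — the largest inscribable circle, radius `R = r + d (1 - sin(theta/2))`
— at no more than the grip-limited speed `V_mb = sqrt(mu_sli g R)`
(`mu_sli` = 0.9 dry, 0.4 wet), with zero pedal power.

The optimizer searches the per-segment speed vector `V = [v_1, ..., v_n]`
(each `v_i` between the segment's recovery speed and its class/corner cap)
to minimize total time `T = sum(s_i / v_i)` subject to `W <= W_all`, using a
generational GA (binary tournament selection, extended-intermediate
recombination, Gaussian mutation, elitism, linear exterior penalty on
overspend). A brute-force grid search over the same bounds serves as an
independent oracle in the tests.

## Worked example

Optimize pacing over a 1.5 km bridge ridden as 750 m up, 750 m down
(±1.97 % grade), for a 75 kg rider with 300 W recovery power and a 10 kJ
budget:

```r
library(velopace)
crs <- make_bridge_course(mode = "up_down")
r   <- rider(energy_budget = 10000)
e   <- race_env()

base <- constant_power_baseline(crs, r, e)   # even-power reference
res  <- optimize_pacing(crs, r, e,
                        ga_params(population_size = 120,
                                  max_generations = 80, seed = 42))
sim  <- simulate_strategy(res$best, crs, r, e)
sim$segments[, c("length_m", "grade_pct", "speed_eff", "power_W",
                 "time_s", "work_J")]
#>   length_m grade_pct speed_eff power_W time_s   work_J
#> 1      750      1.97     10.54  440.48  71.19 10000.98
#> 2      750     -1.97     13.25  300.00  56.62     0.00

simulate_strategy(as.numeric(base), crs, r, e)$total_time_s  # 130.69 s
res$best_time_s                                              # 127.81 s
improvement_percent(130.69, res$best_time_s)                 # ~2.2 %
```

The optimizer spends the entire 10 kJ budget on the climb (440 W, well
above recovery) and descends at exactly recovery power — the classic
finding that time is won by pushing uphill and easing downhill. The
constant-power reference (376.5 W everywhere) is 2.2 % slower.

The same run is available from the command line:

```sh
Rscript inst/cli/velopace.R optimize --config run.json
```

where `run.json` names a course fixture (`track400`, `bridge`) or a course
table plus rider/environment/GA sections; reports (`best_strategy.csv`,
`history.csv`, `summary.json` with the full resolved configuration) land in
the configured output directory.

## Documentation

See the methods vignette (`vignettes/pacing-model.Rmd`) for the model's
assumptions, parameter choices, numerical details, and known limitations.
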