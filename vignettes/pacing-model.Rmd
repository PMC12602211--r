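---
title: "The velopace pacing model: physics, energy budget, and optimizer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The velopace pacing model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(velopace)
```

## The problem

In a road-cycling individual time trial the rider's finishing time depends
on how a finite anaerobic reserve is distributed over a course of unequal
segments: climbs, descents, straights into and out of the wind, and
corners that cap speed regardless of fitness. `velopace` implements a
steady-state model of this allocation problem and a genetic-algorithm (GA)
optimizer for it.

## Force balance and the power--speed relation

On a segment with grade angle $\gamma$ and heading $D_{seg}$, at speed $v$
and acceleration $a$, the total resistive force is

$$F_c = \tfrac12 C\rho S\, V_{rel}\lvert V_{rel}\rvert
      + m g \sin\gamma + \mu m g \cos\gamma + m a,$$

with relative wind $V_{rel} = v - V_{wind}\cos(D_{wind}-D_{seg})$. Wind
direction shares the heading convention (degrees clockwise from north) and
is the direction the wind blows *toward*, so $\alpha = 0$ is a pure
tailwind. Two deliberate choices:

* **Signed drag.** The textbook form writes $F_{air}\propto V_{rel}^2$.
  With a tailwind faster than the rider, $V_{rel}<0$, and squaring would
  make the wind push backward; we therefore use
  $V_{rel}\lvert V_{rel}\rvert$, which is identical whenever
  $V_{rel}\ge 0$ and physically correct otherwise.
* **Exact grade trigonometry.** Grades are stored as angles, so
  $\sin\gamma$ and $\cos\gamma$ are evaluated exactly rather than
  small-angle approximated. On file, grades are percentages
  ($100\tan\gamma$), the convention course data comes in.

Steady-state pedal power is $P = \max(F_c v, 0)$: a negative product (a
gravity-assisted descent) clamps to zero because the drivetrain cannot
absorb energy. `speed_at_power()` inverts this numerically with bracketed
root finding (`uniroot`, absolute tolerance $10^{-12}$, ceiling 40 m/s).
On descents where $F_c(0)<0$ the inversion first finds the coasting
terminal speed (the root of $F_c(v)=0$) and solves above it; at $P=0$ the
terminal speed itself is returned. The inversion and the forward relation
are mutual inverses to better than $10^{-6}$ relative error, which the
test suite checks on a grid of grades, winds and speeds.

## Cornering

The racing line through a junction with inner-bend radius $r$, road width
$d$ and interior intersection angle $\theta$ is the largest inscribable
arc, of radius $R = r + d\,(1-\sin(\theta/2))$; $\theta$ is measured so
that $\theta = 180^\circ$ means the road continues straight (and $R=r$).
Equating the grip limit $\mu_{sli} m g$ with the centripetal demand
$m V^2/R$ gives the safe corner speed $V_{mb} = \sqrt{\mu_{sli} g R}$
(mass cancels). The sliding coefficient is 0.9 dry and 0.4 wet, so wet
corners are slower by exactly $\sqrt{0.4/0.9} \approx 0.667$.

Because a rider cannot deliver pedal power mid-corner, corner segments are
simulated at $\min(\text{entry speed}, V_{mb})$ with $P=0$ and zero budget
charge: corners are an opportunity to recover, not to spend. Entry speed is
the previous segment's effective speed (for a first-segment corner, the
segment's own target). Braking into the corner is treated as free — the
model carries no braking dynamics, so deceleration costs neither time
beyond the capped traversal nor energy.

## Energy budget

Riding above the recovery power $P_{recover}$ (sustainable indefinitely by
aerobic metabolism) drains a finite budget $W_{all}$:

$$W = \sum_i \max(P_i - P_{recover}, 0)\, t_i \le W_{all}.$$

The unclamped form $\sum_i (P_i - P_{recover}) t_i$ would let easy segments
refill the reserve without bound, so the per-segment charge is floored at
zero. Recovery on easy ground is honored by *not charging*, not by
crediting; an optional linear recharge mode (`recharge_rate`, default off,
cumulative balance floored at zero) exists for experimentation only. At the
optimum, time minimization drives $W$ to the budget — exhausting the
reserve exactly at the line is the target, and the constant-power baseline
(`constant_power_baseline()`) finds the single power that does so by
bisection to 1 J.

Within-segment acceleration is deliberately not simulated ($a = 0$
throughout): charging the kinetic-energy difference between segments would
require a braking/acceleration model the framework does not define. The
difference is reported as the `accel_energy_J` diagnostic so its magnitude
is visible, but it never enters the budget.

## The optimizer

The decision vector is one target speed per segment,
$V = [v_1,\dots,v_n]$, real-coded. Bounds per segment: the recovery speed
below (clipped to the cap on fast descents, where the interval collapses),
and the class cap above — the elite maximum (default 20.83 m/s flat/uphill
for men, 18.06 m/s for women) or the descent cap, further reduced by
$V_{mb}$ on corners.

The GA is generational with elitism: evaluate, binary-tournament select,
extended-intermediate recombination (per-gene
$a + \beta(b-a),\ \beta\sim U[-0.25, 1.25]$, clipped), Gaussian mutation
(per-gene probability $p_m$, s.d. $0.1\times$ the bound interval, clipped),
elites carried unchanged. Default hyperparameters are the published
configuration for this problem — population 500, 200 generations,
$p_m = 0.2$, $p_c = 0.8$ — plus choices the source leaves open:

* **Objective.** The published fitness expression (a reciprocal variance)
  does not measure time; the surrounding definition of the problem does:
  minimize total time under the budget. We therefore minimize
  $T + \lambda\max(W - W_{all}, 0)$ with $\lambda = 0.01$ s/J, the
  simplest exterior penalty whose optimum satisfies the "budget exactly
  spent" condition. The variance term is available as an optional
  smoothness weight (default 0).
* **Selection** is binary tournament (scale-free, fixed pressure);
  **recombination** uses the standard extended-intermediate window
  $[-0.25, 1.25]$; the **mutation scale** $0.1$ lets one mutation explore
  about a tenth of a gene's feasible interval. None of these are specified
  by the source.
* **Feasibility by construction.** The budget-exhausting constant-power
  baseline is injected into the initial population, so a feasible member
  exists from generation zero; the result returns the best *feasible*
  strategy (budget tolerance 1 J) whenever one exists. Elitism makes the
  best penalized objective non-increasing, which the tests assert for
  every run.
* **Stopping.** 200 generations, or 30 generations without improvement
  (`stagnation_patience`, on by default) — desk-scale runtime without
  changing the reachable optimum in practice.

Runs are bit-reproducible: `optimize_pacing()` seeds R's RNG from
`ga_params(seed = ...)` and restores the previous RNG state on exit.

## Validation against a brute-force oracle

`brute_force_optimum()` enumerates the Cartesian product of equally spaced
per-segment speed grids (refusing more than $10^7$ points) and returns the
fastest budget-feasible grid point — an oracle that shares no search code
with the GA. The acceptance suite requires the GA within 1 % of the oracle
on a three-segment toy course over five seeds. The toy world uses constants
chosen for exact arithmetic ($\tfrac12 C\rho S = 0.2$, $\mu m g = 3$, so
flat-road power is $0.2v^3 + 3v$ and 230 W gives exactly 10 m/s), and its
speed bounds are kept narrow (cap 11.5 m/s, 1 % climb): a 21-point grid
then resolves the continuous budget-constrained optimum to well under the
comparison tolerance, so the comparison tests the GA rather than the grid's
discretization error. With wide bounds (e.g. a 20.83 m/s cap the budget can
never afford), the grid itself is off by 1–2 % and the comparison would be
meaningless.

## Fixtures and what a green test establishes

Two built-in fixtures mirror a standard test setting:

* `make_track_400m()` — 400 m total, two curves of inner radius 36.5 m
  summing to 231.22 m, straights splitting the remaining 168.78 m equally.
  The printed curve length is kept as an independent field: it is not
  $2\pi\times 36.5 = 229.34$ m (curve length is conventionally measured at
  a running offset from the kerb), and the radius is used only for the
  corner speed cap.
* `make_bridge_course()` — 1.5 km at 14.8 m elevation gain, mean gradient
  $100\times 14.8/1500 = 0.987\,\%$; a single constant ramp by default,
  or an up-then-down profile (`mode = "up_down"`) for descent experiments.

Randomized synthetic profiles for the segmentation tests are generated in
code (random walk in grade and heading). What these fixtures *cannot*
establish: the published experiment's absolute times (82.04/74.08 s on the
track, 284.92/266.82 s on the bridge) are not reproducible because the
experimenters' rider parameters — mass, drag area, recovery power, budget —
were never published. The rider defaults here (75 kg, $CS = 0.25$ m²,
300 W, 20 kJ) are documented placeholders, echoed into every report; the
descent cap of 25 m/s is this package's own choice (roughly the 90 km/h
speeds professionals reach only on long alpine descents, scaled back to
ordinary terrain), since only flat/uphill elite speeds are tabulated.
Improvement percentages are therefore validated on the published time
*pairs* via `improvement_percent()` — $100(t_{pre}-t_{post})/t_{pre}$,
the convention under which both published figures (9.7 %, 6.35 %) are
recovered exactly — not on re-simulated absolute times.

## Profile segmentation

`segment_profile()` reduces a dense distance/elevation/heading profile to
the piecewise-constant course the simulator needs: nearly flat stretches
become flat, small heading wiggle becomes a straight, a hill becomes one
ramp from bottom to top. An interval's grade is defined as
$\arcsin(\Delta z/\Delta s)$ with $\Delta s$ measured along the route, so
length-weighted merging conserves total length and total ascent *exactly*.
A greedy forward pass merges intervals while grade and heading stay within
the thresholds of the run's running means; a final pairwise merge pass
iterates to a fixed point, which guarantees idempotence (segmenting the
reconstruction of a segmentation reproduces it). Defaults: 0.5 % grade
tolerance, 5° heading tolerance — about the noise floor of consumer GPS
elevation and heading traces. GPX 1.1 tracks are ingested via haversine
distances and forward bearings on a 6371.0088 km sphere.

## Numerical choices and degenerate inputs

* Root finding: `uniroot` with tolerance $10^{-12}$, hard speed ceiling
  40 m/s; a grade too steep for any equilibrium below the ceiling raises a
  numerical error rather than returning a fabricated speed.
* Tournament ties break uniformly at random; degenerate bound intervals
  (lower equals upper) are legal and collapse the gene.
* The budget feasibility tolerance is 1 J everywhere (baseline bisection,
  GA feasibility bookkeeping, acceptance checks).
* Reports round percentages to two decimals; all underlying values are
  written at full precision, and course tables round-trip doubles
  bit-identically.

## Known limitations

No within-segment dynamics (acceleration, braking), no rotating-mass or
drivetrain-efficiency corrections, no crosswind stability, no lean-angle
or transition-curve cornering model, no physiological fatigue beyond the
single budget, and no in-race feedback. The energy model treats the
reserve as a strict one-way resource by default; physiological recovery of
anaerobic capacity is real but its kinetics are outside this model's
scope.
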