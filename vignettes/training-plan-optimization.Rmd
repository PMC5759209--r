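---
title: "Constrained optimization of endurance training plans: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constrained optimization of endurance training plans: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trainopt)
```

## The problem

An endurance block is planned as `M = 56` daily sessions (8 weeks), each
prescribed by an average heart rate (bpm) and a duration (minutes). The
planner's goal is to maximize the athlete's modeled performance at the end
of the block while staying clear of overtraining. `trainopt` casts this as
a 112-dimensional constrained continuous optimization problem and solves it
with a grouped, ε-constrained particle swarm.

## The physiological model

**Session load (TRIMP).** A session of duration $d$ minutes at average
heart rate $\bar{hr}$ carries the training impulse

$$w = d \cdot \mathrm{nHR} \cdot e^{y\,\mathrm{nHR}}, \qquad
\mathrm{nHR} = \frac{\bar{hr} - \mathrm{HR}_{rest}}{\mathrm{HR}_{max} - \mathrm{HR}_{rest}},$$

with $y = 1.92$ for male and $1.67$ for female athletes. The exponential
weighting makes time at high fractional heart-rate reserve disproportionately
costly: an hour at 50% reserve for the reference athlete is worth
`r round(session_trimp(120, 60, simulated_athlete()), 2)` TRIMP, an hour at
resting heart rate zero.

**Performance (fitness–fatigue impulse response).** Daily loads
$w_0, \dots, w_{M-1}$ (session $j$ occupies day $i = j-1$) drive performance
through two antagonistic first-order systems:

$$p_t = p_0
 + k_1 \sum_{i=0}^{t-1} w_i\, e^{-(t-i)/r_1}
 - k_2 \sum_{i=0}^{t-1} w_i\, e^{-(t-i)/r_2}.$$

A session therefore first affects performance the day after it is ridden.
The implementation uses the equivalent prefix recursion
$F_{t} = e^{-1/r}(F_{t-1} + k\,w_{t-1})$; the test suite checks it against a
naive term-by-term evaluation of the double sum to $10^{-9}$.

**Parameter defaults and their status.** Individual-athlete fits of
$(k_1, k_2, r_1, r_2)$ are out of scope. The shipped defaults,
$k_1 = 1, k_2 = 2, r_1 = 42$ d, $r_2 = 7$ d, encode the standard
physiological asymmetry — fatigue reacts twice as hard but fades six times
faster than fitness — using the 42/7-day time constants that the cycling
training-load literature conventionally uses for its chronic/acute load
averages. Performance is consequently in *arbitrary units*: comparisons
between plans evaluated under the same parameters are meaningful, absolute
values are not, and every fit object and CLI report echoes the parameter
set used. Atypical sets ($k_2 \le k_1$ or $r_1 \le r_2$) warn rather than
error, since real fits occasionally violate the narrative.

The scalar objective is $p_M$, the final-day performance — the block
prepares a peak at its end. `objective = "peak"` switches to
$\max_t p_t$ for users who care about the best day instead.

## The constraint suite

Three inequality constraints act on the daily TRIMP series; all are
feasible *at* their threshold:

1. **Weekly monotony** — per 7-day block, mean daily load / sample standard
   deviation, must not exceed 1.5. An all-zero (rest) week scores 0 by
   convention; a nonzero constant week has undefined (infinite) monotony and
   contributes a large finite penalty (default 10) so the aggregate stays
   arithmetic-friendly.
2. **CTL ramp rate** — the chronic training load is the EWMA
   $\mathrm{CTL}_t = \mathrm{CTL}_{t-1} + (w_t - \mathrm{CTL}_{t-1})/\tau$
   with $\tau = 42$ days, starting at 0 (an untrained state; configurable).
   Each week-over-week change $\mathrm{CTL}_{7k} - \mathrm{CTL}_{7(k-1)}$
   must not exceed 5 TRIMP/day. Negative ramps are unconstrained.
3. **Daily cap** — no single day above 450 TRIMP.

Each constraint's excess is normalized by its own threshold before
aggregation; without this, a 100-TRIMP daily-cap excess would drown a
0.1-unit monotony excess. The aggregate violation is the power sum
$\varphi = g_1^p + g_2^p + g_3^p$ with $p = 2$, and $\varphi = 0$ holds
exactly when the plan is feasible (property-tested against a brute-force
checker). Weekly excesses are summed rather than maxed (a `"max"` switch
exists) because the sum preserves gradient information for the swarm.

Starting the CTL at 0 makes the ramp constraint the binding one early on:
a constant load $L$ produces a first-week ramp of
$L(1 - (41/42)^7) \approx 0.155\,L$, so feasible first weeks average below
roughly 32 TRIMP/day and the whole block's CTL can climb to at most 40.
This is the stated world of a cautious novice progression, and it is why
optimized and benchmark plans look light compared to elite practice.

## The ε-constrained comparison

Candidates are pairs (objective, $\varphi$). With ε-level 0 (the default)
the order is lexicographic: smaller $\varphi$ wins outright; ties are
broken by larger objective. Violations at or below a nonzero ε are treated
as zero, which is the standard ε-comparison generalization; the package
keeps ε = 0, so the swarm first finds the feasible region and then climbs
performance inside it. The comparison is a total preorder (transitivity is
property-tested).

## The swarm

100 particles in 4 islands of 25 (the decomposition `N = N_g × n_g` is
enforced). Standard velocity/position updates with:

* **linearly decaying inertia** from 0.9 to 0.4 across the budget;
* cognitive/social coefficients `c1 = c2 = 2.0` — the canonical PSO
  choice, exposed as configuration since no published value governs them;
* **island topology**: the social attractor is the island's best; the
  global best is bookkeeping (a `global_social` flag restores the
  fully-connected variant). Islands limit premature consensus in the
  112-dimensional space;
* initial velocities exactly 0, positions uniform in the box
  (HR ∈ [resting, max] bpm, duration ∈ [30, 300] min per day);
* **clamp-to-bound** with velocity zeroing on the clamped component — the
  least-surprise boundary rule for a physically bounded plan;
* **adaptive per-dimension velocity limits**: limits start at the full box
  range and shrink by γ = 0.95 whenever fewer than `F_λ = 0.2` of the
  particles are currently feasible, or the incumbent has improved by less
  than the relative tolerance `F_θ = 0.05` over the last 10 iterations
  (measured on $\varphi$ while infeasible, on the objective once
  feasible), floored at $10^{-3}$ of the range. This realizes the
  "don't fly over the feasible region" idea with the two otherwise-unused
  knobs $F_\lambda$ and $F_\theta$; the exact published mechanism is not
  recoverable, so all four knobs (trigger pair, γ, floor) are
  configuration.

A particle whose evaluation fails is assigned (−∞, +∞) and the run
continues. The incumbent is the ε-best personal best ever seen, so its
(φ, −objective) pair is non-worsening along the trace — asserted on every
run in the tests. Two budgets exist (`max_iterations`, `max_evaluations`)
because published accounts of comparable experiments mix the two; when both
are set the tighter one governs.

All randomness flows from one `set.seed()` at the start of a run; two runs
with the same seed and configuration are bit-identical, and a serialized
run record (config + seed) reproduces its plan exactly.

## The synthetic benchmark

Published federation plans cannot be redistributed, so comparisons use a
*synthetic* standard plan that emulates conventional coaching structure:
a weekly template of hard/easy alternation with two rest days
(multipliers 1.5, 0.5, 1.8, 0, 1.2, 2.0, 0 of the weekly mean), 15%
week-over-week progression, every 4th week a recovery week at 0.55 of the
previous load, 5% seeded jitter. Daily TRIMP targets are converted to
(HR, duration) sessions by fixing a duration per day type (90/75/60 min
hard/moderate/easy, 30 min at resting HR for rest days) and inverting the
TRIMP formula for heart rate. The base weekly mean of 20 TRIMP/day is the
largest round value that keeps the whole schedule comfortably inside the
ramp constraint when the CTL starts at 0. The generator *verifies*
feasibility and refuses infeasible specifications, naming the violated
constraint — that verified feasibility is what makes it a meaningful
benchmark. What it does **not** emulate: real plans' zone periodization
semantics, intra-week ordering rationale, or absolute volumes of trained
athletes; a green comparison says the optimizer beats a plausible
feasible straw-plan under the same model, not that it beats any real
federation program.

Plan similarity uses dynamic time warping on the two daily-TRIMP series
(absolute-difference cost, unit steps, no window), mapped to [0, 1] by
`1 − DTW(a, b) / DTW(all-min, all-max)` — the denominator is the distance
between the least and most demanding plans expressible in the same number
of days, i.e. the "furthest apart" pair, and similarity 1 means identical
load patterns.

## Numerical choices and edge cases

* Sample (n−1) standard deviation in monotony; weeks are non-overlapping
  7-day blocks; trailing partial weeks are dropped with a warning.
* Zone boundaries are stored as percentages of FTHR and converted to bpm
  at runtime, so the zone table personalizes to any athlete; the reference
  athlete (FTHR 165) reproduces the canonical bpm table. One printed
  zone-3 row conflicts with its own percentages; the percentage-consistent
  reading is the default and the printed duplicate is available via
  `zone_table(..., zone3 = "printed")`.
* Decision variables are continuous bpm/minutes; zone quantization is an
  output-formatting concern, not a search-space one.
* Feasibility is tested as `phi == 0` exactly — the violation is built
  from `pmax(0, ·)` terms, so feasible plans produce an exact zero.
* Equality of floating traces across runs is asserted bitwise
  (`expect_identical`), which holds because the computation is
  deterministic given the seed.

## Known limitations

* Banister parameters are not fitted to data; all performance values are
  relative to the shipped defaults.
* The CTL-ramp "for < 4 weeks" qualifier seen in some training guidance is
  not modeled as a duration-dependent threshold schedule; every week faces
  the same 5-unit ceiling.
* The optimizer returns one plan per seed; it does not explore the
  feasible set's diversity, and 500-iteration runs (the tested budget)
  typically sit on the ramp-constraint boundary with monotony and daily
  load well inside theirs.
* No FIT/TCX ingestion, no GUI, no multi-objective or GA baselines.
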