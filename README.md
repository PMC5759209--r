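# trainopt

Generates 8-week (56-session) endurance cycling training plans that
maximize modeled athletic performance while respecting physiological
safety limits, and provides the evaluation tooling to audit and compare
any plan. It is aimed at exercise-physiology researchers and
training-software developers who want a reproducible, testable planner
rather than hand-tuned spreadsheets.

## The model in brief

Each session is an (average heart rate, duration) pair. A session's load
is Banister's TRIMP,

    w = d · nHR · exp(y · nHR),      nHR = (hr − HR_rest)/(HR_max − HR_rest),

with `y = 1.92` (male) / `1.67` (female). Daily loads drive the
fitness–fatigue impulse-response model of performance,

    p_t = p0 + k1 · Σ_{i<t} w_i e^{−(t−i)/r1} − k2 · Σ_{i<t} w_i e^{−(t−i)/r2},

whose final-day value `p_M` is the optimization objective. Three
inequality constraints guard against overtraining: weekly training
monotony (mean/sd of daily load) ≤ 1.5, weekly chronic-training-load ramp
(42-day EWMA, week-over-week change) ≤ 5, and daily TRIMP ≤ 450. Their
threshold-normalized excesses aggregate into a violation value
`φ = g1² + g2² + g3²`, and a grouped particle swarm (100 particles, 4
islands, linearly decaying inertia, adaptive per-dimension velocity
limits) searches the 112-dimensional plan space under the ε-constrained
order: smaller `φ` wins, ties go to higher performance. With ε = 0 the
swarm first finds the feasible region, then maximizes performance inside
it.

Default Banister parameters (`k1 = 1, k2 = 2, r1 = 42 d, r2 = 7 d`) are a
documented convention, not athlete fits — performance is in arbitrary
units and every report echoes the parameter set used. See the methods
vignette (`vignettes/training-plan-optimization.Rmd`) for the full account.

## Worked example

```r
library(trainopt)

ath <- simulated_athlete()        # resting 51, FTHR 165, max 189 bpm, male
fit <- optimize_plan(ath, swarm = swarm_config(max_iterations = 500), seed = 1)
print(fit)
#> Optimized training plan (56 sessions, seed 1)
#>   final-day performance : 941.400
#>   total violation phi   : 0  [FEASIBLE]
#>   evaluations           : 50100 (2.1 s)
#> Banister parameters: k1 = 1, k2 = 2, r1 = 42 d, r2 = 7 d

print(fit$report)
#> Constraint report
#>   weekly monotony (max 1.5): 1.036 0.918 0.838 0.628 0.716 0.871 0.875 0.555
#>   weekly CTL ramp (max 5): 5.000 5.000 4.998 5.000 4.999 4.999 5.000 -4.553
#>   daily TRIMP max (cap 450): 217.05
#>   violations g = (0, 0, 0), phi = 0  [FEASIBLE]
```

Reading this: the optimized plan is exactly feasible (`φ = 0`). The swarm
pushes the CTL ramp to its 5-unit ceiling for seven weeks — the binding
constraint when chronic load starts at 0 — then unloads in week 8
(ramp −4.55): it discovers a taper, letting the 7-day fatigue term drain
before the final day while the 42-day fitness term persists. Monotony and
daily load sit well inside their limits.

Comparison against the built-in synthetic "standard plan" (a feasible,
coach-like hard/easy progression standing in for published federation
plans, which cannot be redistributed):

```r
std <- synth_standard_plan()
plan_fitness(std, ath, banister_parameters())
#> [1] 545.8321                      # optimized plan: 941.4
dtw_similarity(trimp_series(fit$plan, ath), trimp_series(std, ath),
               athlete = ath)$similarity
#> [1] 0.9866                        # very similar daily-load pattern
```

The optimizer beats the benchmark on final-day performance while
producing a recognizably similar alternation of hard and easy days.

## Command line

```sh
Rscript -e 'trainopt::trainopt_main()' optimize --seed 7 --iterations 500 \
    --out plan.csv --trace trace.csv --record run.json
Rscript -e 'trainopt::trainopt_main()' evaluate --plan plan.csv
Rscript -e 'trainopt::trainopt_main()' compare plan.csv std.csv
Rscript -e 'trainopt::trainopt_main()' batch --runs 10 --seed 1 --iterations 500
Rscript -e 'trainopt::trainopt_main()' synth-benchmark --out std.csv
```

Plans are CSV (`day,avg_hr_bpm,duration_min`), athletes JSON
(`{"resting_hr": 51, "max_hr": 189, "fthr": 165, "sex": "male", "p0": 0}`),
configuration JSON mirroring the constructor arguments
(`banister` / `swarm` / `constraints` sections). A run record (config +
seed) reproduces its plan bit-exactly.

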