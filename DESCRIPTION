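Package: trainopt
Title: Constrained Optimization of Endurance Training Plans
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for generating and evaluating endurance (cycling) training
    plans. Implements the Banister fitness-fatigue impulse-response model of
    athletic performance driven by heart-rate based TRIMP session loads, a
    suite of physiological safety constraints (weekly training monotony,
    chronic-training-load ramp rate, daily TRIMP cap), and a grouped,
    epsilon-constrained particle swarm optimizer with linearly decaying
    inertia and adaptive per-dimension velocity limits that searches the
    space of 8-week session schedules. Includes a synthetic standard-plan
    generator, dynamic-time-warping plan similarity, batch experiment
    tooling and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
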