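#' Vectorized objective/constraint evaluator for plan optimization
#'
#' Builds the evaluator used by the swarm: for each row of a position
#' matrix (interleaved `HR1, D1, ..., HRM, DM`, see [encode_plan()]) it
#' computes the daily TRIMP series, the Banister objective
#' ([plan_fitness()]) and the aggregate constraint violation
#' ([violations()]), all in matrix form so a 100-particle swarm costs a
#' handful of matrix operations per iteration.
#'
#' @param athlete An [athlete_profile()].
#' @param params A [banister_parameters()].
#' @param cfg A [constraint_config()].
#' @param objective `"final"` (performance at the last day) or `"peak"`
#'   (maximum over days).
#' @return Function mapping an `n x 2M` matrix to
#'   `list(objective, phi, g)`.
#' @export
plan_evaluator <- function(athlete, params, cfg = constraint_config(),
                           objective = c("final", "peak")) {
  objective <- match.arg(objective)
  y <- athlete$sex_factor
  rng <- athlete$max_hr - athlete$resting_hr
  function(X) {
    M <- ncol(X) %/% 2L
    hr <- X[, seq(1L, 2L * M, by = 2L), drop = FALSE]
    dur <- X[, seq(2L, 2L * M, by = 2L), drop = FALSE]
    nh <- (hr - athlete$resting_hr) / rng
    W <- dur * nh * exp(y * nh)
    # final-day convolution weights: session j (day i = j-1) weighs
    # e^{-(M-j+1)/r} in p_M
    if (objective == "final") {
      d1 <- exp(-(M - seq_len(M) + 1) / params$r1)
      d2 <- exp(-(M - seq_len(M) + 1) / params$r2)
      obj <- athlete$p0 + params$k1 * (W %*% d1) - params$k2 * (W %*% d2)
      obj <- as.vector(obj)
    } else {
      D1 <- outer(seq_len(M), seq_len(M),
                  function(t, j) ifelse(j <= t, exp(-(t - j + 1) / params$r1), 0))
      D2 <- outer(seq_len(M), seq_len(M),
                  function(t, j) ifelse(j <= t, exp(-(t - j + 1) / params$r2), 0))
      P <- athlete$p0 + params$k1 * W %*% t(D1) - params$k2 * W %*% t(D2)
      obj <- apply(P, 1L, max)
    }
    v <- .violations_matrix(W, cfg)
    list(objective = obj, phi = v$phi, g = cbind(v$g1, v$g2, v$g3))
  }
}

#' Optimize a training plan for an athlete
#'
#' Searches the space of `n_sessions`-day plans (average heart rate within
#' the athlete's resting-to-maximum range, duration within
#' `duration_bounds`) for the plan maximizing Banister performance on the
#' final day, subject to the three physiological constraints, using the
#' grouped epsilon-constrained particle swarm ([pso_optimize()]). With the
#' default epsilon level 0 the search is lexicographic: the swarm first
#' drives the aggregate violation to zero, then maximizes performance
#' among feasible plans.
#'
#' @param athlete An [athlete_profile()].
#' @param params A [banister_parameters()].
#' @param swarm A [swarm_config()].
#' @param constraints A [constraint_config()].
#' @param n_sessions Plan length in days, default 56 (8 weeks).
#' @param duration_bounds Session duration range, minutes, default
#'   `c(30, 300)`.
#' @param seed Integer RNG seed (defaults to `swarm$seed`, else 1).
#' @param objective Passed to [plan_evaluator()].
#' @return An object of class `trainopt_fit`: list with the optimized
#'   `plan`, its `performance` series ([performance_series()]), its
#'   constraint `report` ([violations()]), the scalar `objective` value,
#'   the per-iteration `trace` (columns `iteration`, `best_performance`,
#'   `total_violation`, `g_monotony`, `g_ramp`, `g_daily`,
#'   `feasible_fraction`, `vmax_scale`), and the `athlete`, `params`,
#'   configs, `seed`, `evaluations` and `wall_time_s` that produced it.
#' @examples
#' \donttest{
#' fit <- optimize_plan(simulated_athlete(),
#'                      swarm = swarm_config(n_particles = 20, n_groups = 4,
#'                                           group_size = 5,
#'                                           max_iterations = 50),
#'                      seed = 1)
#' fit$report$feasible
#' }
#' @export
optimize_plan <- function(athlete, params = banister_parameters(),
                          swarm = swarm_config(),
                          constraints = constraint_config(),
                          n_sessions = 56, duration_bounds = c(30, 300),
                          seed = swarm$seed, objective = "final") {
  stopifnot(inherits(athlete, "athlete_profile"),
            inherits(params, "banister_parameters"))
  t0 <- proc.time()[["elapsed"]]
  bounds <- matrix(NA_real_, 2L * n_sessions, 2L)
  odd <- seq(1L, 2L * n_sessions, by = 2L)
  bounds[odd, ] <- matrix(c(athlete$resting_hr, athlete$max_hr),
                          n_sessions, 2L, byrow = TRUE)
  bounds[odd + 1L, ] <- matrix(duration_bounds, n_sessions, 2L, byrow = TRUE)
  evaluate <- plan_evaluator(athlete, params, constraints,
                             objective = objective)
  res <- pso_optimize(evaluate, bounds, swarm, seed = seed)
  plan <- decode_plan(res$best_position)
  trace <- res$trace
  names(trace) <- c("iteration", "best_performance", "total_violation",
                    "g_monotony", "g_ramp", "g_daily",
                    "feasible_fraction", "vmax_scale")
  structure(
    list(plan = plan,
         performance = performance_series(plan, athlete, params),
         report = violations(plan, athlete, constraints),
         objective = res$best_objective,
         trace = trace,
         athlete = athlete, params = params,
         swarm_config = swarm, constraint_config = constraints,
         duration_bounds = duration_bounds,
         seed = res$seed,
         evaluations = res$evaluations,
         wall_time_s = proc.time()[["elapsed"]] - t0),
    class = "trainopt_fit")
}

#' @export
print.trainopt_fit <- function(x, ...) {
  cat(sprintf("Optimized training plan (%d sessions, seed %s)\n",
              nrow(x$plan), format(x$seed)))
  cat(sprintf("  final-day performance : %.3f\n",
              x$performance$performance[nrow(x$performance)]))
  cat(sprintf("  total violation phi   : %.6g  [%s]\n", x$report$phi,
              if (x$report$feasible) "FEASIBLE" else "infeasible"))
  cat(sprintf("  evaluations           : %d (%.1f s)\n",
              x$evaluations, x$wall_time_s))
  print(x$params)
  invisible(x)
}
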