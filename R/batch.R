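#' Run a batch of independent optimizations
#'
#' Executes `n_runs` independent plan optimizations with seeds
#' `base_seed, base_seed + 1, ..., base_seed + n_runs - 1` and summarizes,
#' at each requested fitness-evaluation checkpoint, the best / worst /
#' average / standard deviation of the final-day performance and of each
#' per-constraint violation across runs. Checkpoints are given in fitness
#' evaluations (FEs) and mapped to the iteration whose cumulative
#' evaluation count first reaches them; checkpoints beyond the budget
#' snapshot the final iteration.
#'
#' @inheritParams optimize_plan
#' @param n_runs Number of independent runs, default 10.
#' @param base_seed First seed, default 1.
#' @param checkpoints Fitness-evaluation counts at which constraint
#'   violations are snapshotted, default `c(50, 500, 50000)`.
#' @return An object of class `trainopt_batch`: list with `runs` (list of
#'   `trainopt_fit`), `summary` (data frame: `checkpoint_fes`, `metric`,
#'   `best`, `worst`, `average`, `sd`), `seeds` and the configs used.
#' @export
run_batch <- function(athlete, params = banister_parameters(),
                      swarm = swarm_config(),
                      constraints = constraint_config(),
                      n_runs = 10, base_seed = 1,
                      checkpoints = c(50, 500, 50000),
                      n_sessions = 56, duration_bounds = c(30, 300)) {
  if (n_runs < 1) stop("n_runs must be >= 1", call. = FALSE)
  seeds <- base_seed + seq_len(n_runs) - 1L
  runs <- lapply(seeds, function(s)
    optimize_plan(athlete, params, swarm, constraints,
                  n_sessions = n_sessions,
                  duration_bounds = duration_bounds, seed = s))
  N <- swarm$n_particles
  snap_iter <- function(fe) {
    it <- max(0L, ceiling(fe / N) - 1L)        # iteration 0 = first N FEs
    min(it, nrow(runs[[1L]]$trace) - 1L)
  }
  metrics <- c("best_performance", "g_monotony", "g_ramp", "g_daily",
               "total_violation")
  rows <- list()
  for (fe in checkpoints) {
    it <- snap_iter(fe)
    for (m in metrics) {
      vals <- vapply(runs, function(r) r$trace[[m]][it + 1L], numeric(1L))
      rows[[length(rows) + 1L]] <- data.frame(
        checkpoint_fes = fe, iteration = it, metric = m,
        best = if (m == "best_performance") max(vals) else min(vals),
        worst = if (m == "best_performance") min(vals) else max(vals),
        average = mean(vals), sd = stats::sd(vals))
    }
  }
  structure(
    list(runs = runs,
         summary = do.call(rbind, rows),
         seeds = seeds,
         athlete = athlete, params = params,
         swarm_config = swarm, constraint_config = constraints),
    class = "trainopt_batch")
}

#' @export
print.trainopt_batch <- function(x, ...) {
  cat(sprintf("Batch of %d independent runs (seeds %s..%s)\n",
              length(x$runs), x$seeds[1L], x$seeds[length(x$seeds)]))
  feas <- vapply(x$runs, function(r) r$report$feasible, logical(1L))
  perf <- vapply(x$runs, function(r)
    r$performance$performance[nrow(r$performance)], numeric(1L))
  cat(sprintf("  feasible final plans : %d/%d\n", sum(feas), length(feas)))
  cat(sprintf("  final performance    : best %.3f / worst %.3f / mean %.3f / sd %.3f\n",
              max(perf), min(perf), mean(perf), stats::sd(perf)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Serialize / restore a run record
#'
#' A run record captures everything needed to audit and reproduce one
#' optimization: the configuration snapshot and seed (sufficient for
#' bit-exact reproduction via [optimize_plan()]), plus the final plan,
#' constraint report, performance series and wall time. Stored as JSON.
#'
#' @param fit A `trainopt_fit` from [optimize_plan()].
#' @param path JSON file path.
#' @return `write_run_record()` returns `path` invisibly;
#'   `read_run_record()` returns the parsed record as a list (with the
#'   plan restored as a [training_plan()]).
#' @export
write_run_record <- function(fit, path) {
  stopifnot(inherits(fit, "trainopt_fit"))
  rec <- list(
    seed = fit$seed,
    athlete = unclass(fit$athlete),
    banister = unclass(fit$params),
    swarm_config = unclass(fit$swarm_config),
    constraint_config = unclass(fit$constraint_config),
    duration_bounds = fit$duration_bounds,
    evaluations = fit$evaluations,
    wall_time_s = fit$wall_time_s,
    objective = fit$objective,
    plan = as.data.frame(fit$plan),
    performance = fit$performance,
    report = list(weekly_monotony = fit$report$weekly_monotony,
                  weekly_ramp_rates = fit$report$weekly_ramp_rates,
                  g = as.list(fit$report$g),
                  phi = fit$report$phi,
                  feasible = fit$report$feasible))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_run_record
#' @export
read_run_record <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  rec$plan <- training_plan(rec$plan$avg_hr_bpm, rec$plan$duration_min)
  rec
}
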