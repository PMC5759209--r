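#' Synthetic standard-plan specification
#'
#' Describes a conventional coach-designed 8-week endurance block used as a
#' comparison benchmark: alternation of hard and easy days with two weekly
#' rest days, a gentle week-over-week load progression and a reduced
#' recovery week every `recovery_week_period` weeks. It is a synthetic
#' stand-in for published federation plans (which cannot be redistributed),
#' constructed so that the generated plan is feasible under the default
#' physiological constraints.
#'
#' The `day_pattern` gives each weekday's share of the weekly load
#' (0 = rest day); its mean fixes the weekly volume and its spread keeps
#' the weekly monotony comfortably under the 1.5 ceiling (the monotony
#' ratio is scale-invariant, so it depends on the pattern only).
#'
#' @param weeks Number of weeks, default 8.
#' @param sessions_per_week Days per week, default 7.
#' @param day_pattern Relative daily-load multipliers, one per weekday.
#' @param base_weekly_mean Mean daily TRIMP in week 1, default 20 (a
#'   cautious novice start consistent with a CTL ramp starting from 0).
#' @param progression Week-over-week multiplier on the weekly mean,
#'   default 1.15.
#' @param recovery_week_period Every this-many-th week is a recovery week,
#'   default 4.
#' @param recovery_scale Load scale of a recovery week relative to the
#'   preceding week, default 0.55.
#' @param jitter Relative uniform jitter applied to daily targets,
#'   default 0.05.
#' @param seed RNG seed for the jitter, default 1.
#' @return An object of class `benchmark_spec`.
#' @export
benchmark_spec <- function(weeks = 8, sessions_per_week = 7,
                           day_pattern = c(1.5, 0.5, 1.8, 0, 1.2, 2.0, 0),
                           base_weekly_mean = 20, progression = 1.15,
                           recovery_week_period = 4, recovery_scale = 0.55,
                           jitter = 0.05, seed = 1) {
  if (length(day_pattern) != sessions_per_week)
    stop("day_pattern must have one entry per session of the week",
         call. = FALSE)
  if (any(day_pattern < 0) || all(day_pattern == 0))
    stop("day_pattern must be non-negative with at least one training day",
         call. = FALSE)
  if (weeks < 1 || base_weekly_mean <= 0 || progression <= 0)
    stop("invalid benchmark specification", call. = FALSE)
  structure(
    list(weeks = as.integer(weeks),
         sessions_per_week = as.integer(sessions_per_week),
         day_pattern = day_pattern,
         base_weekly_mean = base_weekly_mean,
         progression = progression,
         recovery_week_period = as.integer(recovery_week_period),
         recovery_scale = recovery_scale,
         jitter = jitter, seed = seed),
    class = "benchmark_spec")
}

# invert w = d * nh * exp(y * nh) for nh at fixed duration; target_frac =
# w / d must lie in [0, e^y]
.hr_for_trimp <- function(target, duration, athlete) {
  if (target <= 0) return(athlete$resting_hr)
  f <- function(nh) nh * exp(athlete$sex_factor * nh) - target / duration
  if (f(1) < 0)
    stop("daily TRIMP target unreachable within the athlete's HR range",
         call. = FALSE)
  nh <- stats::uniroot(f, c(0, 1), tol = 1e-10)$root
  athlete$resting_hr + nh * (athlete$max_hr - athlete$resting_hr)
}

#' Generate the synthetic standard training plan
#'
#' Realizes a [benchmark_spec()] as a concrete [training_plan()] for an
#' athlete: weekly mean loads follow the progression/recovery schedule,
#' daily TRIMP targets are the weekly mean times the day-pattern multiplier
#' (with a small seeded jitter), and each target is converted to an
#' (average HR, duration) session by fixing a duration per day type
#' (90 min hard, 75 min moderate, 60 min easy, 30 min rest at resting HR)
#' and solving the TRIMP formula for heart rate. The generated plan is
#' verified to be feasible; an infeasible specification raises an error
#' naming the violated constraint.
#'
#' @param spec A [benchmark_spec()].
#' @param athlete An [athlete_profile()].
#' @param cfg A [constraint_config()] used for the feasibility check.
#' @return A feasible [training_plan()] of
#'   `weeks * sessions_per_week` sessions.
#' @export
synth_standard_plan <- function(spec = benchmark_spec(),
                                athlete = simulated_athlete(),
                                cfg = constraint_config()) {
  stopifnot(inherits(spec, "benchmark_spec"),
            inherits(athlete, "athlete_profile"))
  set.seed(spec$seed)
  weekly_mean <- numeric(spec$weeks)
  run <- spec$base_weekly_mean
  for (k in seq_len(spec$weeks)) {
    if (k > 1L) run <- run * spec$progression
    weekly_mean[k] <- if (k %% spec$recovery_week_period == 0L)
      run * spec$recovery_scale else run
  }
  rel <- spec$day_pattern / mean(spec$day_pattern)
  durations <- ifelse(spec$day_pattern == 0, 30,
               ifelse(spec$day_pattern >= 1.5, 90,
               ifelse(spec$day_pattern >= 1.0, 75, 60)))
  n <- spec$weeks * spec$sessions_per_week
  jit <- 1 + spec$jitter * (2 * stats::runif(n) - 1)
  target <- as.vector(t(outer(weekly_mean, rel))) * jit
  avg_hr <- mapply(.hr_for_trimp, target,
                   rep(durations, spec$weeks),
                   MoreArgs = list(athlete = athlete))
  plan <- training_plan(avg_hr, rep(durations, spec$weeks))
  rep_ <- violations(plan, athlete, cfg)
  if (!rep_$feasible) {
    worst <- names(which.max(rep_$g))
    stop(sprintf(
      "benchmark specification generates an infeasible plan: %s constraint violated (g = %.4g)",
      worst, rep_$g[[worst]]), call. = FALSE)
  }
  plan
}

#' Dynamic time warping distance between two load series
#'
#' Classic DTW with absolute-difference local cost, unit step pattern
#' \{(1,0), (0,1), (1,1)\} and no warping window: the minimum accumulated
#' cost over all monotone alignments of the two series. Symmetric, and 0
#' exactly when the warped-aligned series coincide.
#'
#' @param a,b Non-empty numeric series (e.g. daily TRIMP values).
#' @return Accumulated alignment cost.
#' @examples
#' dtw_distance(c(0, 0), c(1, 1))  # 2
#' @export
dtw_distance <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L)
    stop("DTW requires non-empty series", call. = FALSE)
  n <- length(a); m <- length(b)
  D <- matrix(Inf, n + 1L, m + 1L)
  D[1L, 1L] <- 0
  for (i in seq_len(n)) {
    cost <- abs(a[i] - b)
    for (j in seq_len(m)) {
      D[i + 1L, j + 1L] <- cost[j] +
        min(D[i, j + 1L], D[i + 1L, j], D[i, j])
    }
  }
  D[n + 1L, m + 1L]
}

#' Bounded DTW similarity of two training plans' load series
#'
#' Maps the DTW distance into `[0, 1]` with 1 for identical series and 0
#' for maximal separation. The normalizer is the DTW distance between the
#' least and most demanding plans expressible in the same number of days:
#' the all-`load_range[1]` and all-`load_range[2]` constant series.
#' `similarity = 1 - dtw_distance(a, b) / normalizer`, clipped to `[0, 1]`.
#'
#' @inheritParams dtw_distance
#' @param load_range Length-2 numeric, the per-day load bounds defining the
#'   "furthest apart" reference plans. Defaults to `c(0, max_trimp)` where
#'   `max_trimp` is computed from `athlete` and `max_duration` when an
#'   athlete is supplied.
#' @param athlete Optional [athlete_profile()] used to derive the default
#'   upper load bound (maximum HR for `max_duration` minutes).
#' @param max_duration Session duration used for the default upper bound,
#'   minutes, default 300.
#' @return List with `dtw_distance` and `similarity`.
#' @export
dtw_similarity <- function(a, b, load_range = NULL,
                           athlete = NULL, max_duration = 300) {
  if (is.null(load_range)) {
    if (is.null(athlete))
      stop("provide load_range or an athlete to derive it from",
           call. = FALSE)
    load_range <- c(0, session_trimp(athlete$max_hr, max_duration, athlete))
  }
  if (load_range[2L] <= load_range[1L])
    stop("degenerate load_range: upper bound must exceed lower bound",
         call. = FALSE)
  norm <- dtw_distance(rep(load_range[1L], length(a)),
                       rep(load_range[2L], length(b)))
  if (norm <= 0)
    stop("degenerate normalizer: reference plans coincide", call. = FALSE)
  d <- dtw_distance(a, b)
  list(dtw_distance = d,
       similarity = min(max(1 - d / norm, 0), 1))
}
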