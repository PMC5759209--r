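#' Banister impulse-response model parameters
#'
#' The four constants of the fitness-fatigue model: gain amplitudes `k1`
#' (fitness) and `k2` (fatigue) and exponential decay time constants `r1`
#' (fitness) and `r2` (fatigue), in days. The canonical physiological
#' picture has fatigue reacting more strongly but fading faster than
#' fitness, i.e. `k2 > k1` and `r1 > r2`; a parameter set that violates this
#' triggers a warning (not an error), since fitted values for individual
#' athletes occasionally do.
#'
#' Defaults follow the cycling training-load literature's convention of a
#' 42-day fitness and 7-day fatigue time constant with a 1:2 gain ratio.
#' They are a documented stand-in for athlete-specific model fits, not
#' universal constants: every result object echoes the parameter set used.
#'
#' @param k1 Fitness gain amplitude (> 0).
#' @param k2 Fatigue gain amplitude (> 0).
#' @param r1 Fitness decay time constant, days (> 0).
#' @param r2 Fatigue decay time constant, days (> 0).
#' @return An object of class `banister_parameters`.
#' @export
banister_parameters <- function(k1 = 1, k2 = 2, r1 = 42, r2 = 7) {
  vals <- c(k1 = k1, k2 = k2, r1 = r1, r2 = r2)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all Banister parameters must be positive and finite", call. = FALSE)
  if (k2 <= k1 || r1 <= r2)
    warning("unusual parameter set: expected k2 > k1 and r1 > r2 ",
            "(fatigue reacts harder but decays faster than fitness)",
            call. = FALSE)
  structure(list(k1 = k1, k2 = k2, r1 = r1, r2 = r2),
            class = "banister_parameters")
}

#' @export
print.banister_parameters <- function(x, ...) {
  cat(sprintf(
    "Banister parameters: k1 = %g, k2 = %g, r1 = %g d, r2 = %g d\n",
    x$k1, x$k2, x$r1, x$r2))
  invisible(x)
}

#' Normalized heart rate
#'
#' Maps an average session heart rate onto the athlete's heart-rate reserve:
#' `(hr - resting) / (max - resting)`, a dimensionless fraction in `[0, 1]`
#' that is exactly 0 at resting HR and 1 at maximum HR.
#'
#' @param avg_hr Average heart rate(s), bpm; vectorized.
#' @param athlete An [athlete_profile()].
#' @return Numeric vector of fractions in `[0, 1]`.
#' @export
normalized_hr <- function(avg_hr, athlete) {
  bad <- which(avg_hr < athlete$resting_hr | avg_hr > athlete$max_hr)
  if (length(bad))
    stop(sprintf("avg_hr = %.2f bpm outside athlete range [%g, %g]",
                 avg_hr[bad[1L]], athlete$resting_hr, athlete$max_hr),
         call. = FALSE)
  (avg_hr - athlete$resting_hr) / (athlete$max_hr - athlete$resting_hr)
}

#' TRIMP load of a single session
#'
#' Banister's training impulse: `d * normHR * exp(y * normHR)` where `d` is
#' the duration in minutes, `normHR` the normalized heart rate
#' ([normalized_hr()]) and `y` the sex-specific exponent (1.92 male,
#' 1.67 female). Zero duration or resting heart rate gives a zero load;
#' the load is strictly increasing in both duration and heart rate.
#'
#' @param avg_hr Average heart rate(s), bpm; vectorized.
#' @param duration Duration(s), minutes; vectorized.
#' @inheritParams normalized_hr
#' @return TRIMP load(s), arbitrary TRIMP units.
#' @examples
#' session_trimp(120, 60, simulated_athlete())  # ~78.35
#' @export
session_trimp <- function(avg_hr, duration, athlete) {
  nh <- normalized_hr(avg_hr, athlete)
  duration * nh * exp(athlete$sex_factor * nh)
}

#' Daily TRIMP series of a plan
#'
#' @param plan A [training_plan()].
#' @param athlete An [athlete_profile()].
#' @return Numeric vector `w_1..w_M` of daily TRIMP loads.
#' @export
trimp_series <- function(plan, athlete) {
  stopifnot(inherits(plan, "training_plan"))
  session_trimp(plan$avg_hr_bpm, plan$duration_min, athlete)
}

# Fitness/fatigue convolutions for all days 1..M via the prefix recursion
# F_{t+1} = e^{-1/r} (F_t + k w_t); session j occupies day i = j - 1, so its
# first contribution (weight e^{-1/r}) appears on day j.
.banister_components <- function(w, k, r) {
  M <- length(w)
  decay <- exp(-1 / r)
  out <- numeric(M)
  acc <- 0
  for (t in seq_len(M)) {
    acc <- decay * (acc + k * w[t])
    out[t] <- acc
  }
  out
}

#' Banister performance of a plan
#'
#' Athletic performance on day `t` is the baseline plus the fitness
#' convolution minus the fatigue convolution of the daily loads:
#' `p_t = p0 + k1 * sum_{i=0}^{t-1} w_i e^{-(t-i)/r1}
#'           - k2 * sum_{i=0}^{t-1} w_i e^{-(t-i)/r2}`,
#' where session `j` of the plan sits on day `i = j - 1` and therefore
#' first affects performance on day `j`. With an all-zero load series the
#' performance equals `p0` on every day.
#'
#' @param plan A [training_plan()].
#' @param athlete An [athlete_profile()].
#' @param params A [banister_parameters()].
#' @param t Day index, `1 <= t <= M`.
#' @return Performance on day `t`, arbitrary units.
#' @seealso [performance_series()] for all days with the fitness/fatigue
#'   decomposition, [plan_fitness()] for the scalar optimization objective.
#' @export
performance <- function(plan, athlete, params, t) {
  M <- nrow(plan)
  if (length(t) != 1L || t < 1L || t > M || t != round(t))
    stop(sprintf("day index t must be an integer in 1..%d, got %s", M,
                 paste(t, collapse = ",")), call. = FALSE)
  performance_series(plan, athlete, params)$performance[t]
}

#' @rdname performance
#' @return `performance_series()` returns a data frame with columns `day`,
#'   `load`, `fitness`, `fatigue` and `performance`
#'   (`= p0 + fitness - fatigue`).
#' @export
performance_series <- function(plan, athlete, params) {
  stopifnot(inherits(plan, "training_plan"),
            inherits(params, "banister_parameters"))
  w <- trimp_series(plan, athlete)
  fit <- .banister_components(w, params$k1, params$r1)
  fat <- .banister_components(w, params$k2, params$r2)
  data.frame(day = seq_along(w), load = w, fitness = fit, fatigue = fat,
             performance = athlete$p0 + fit - fat)
}

#' Scalar objective value of a plan
#'
#' The quantity the optimizer maximizes. By default this is the Banister
#' performance on the final day of the plan (`t = M`), reflecting the goal
#' of peaking at the end of the preparation block; `objective = "peak"`
#' instead takes the maximum performance over all days.
#'
#' @inheritParams performance_series
#' @param objective `"final"` (default) or `"peak"`.
#' @return A single performance value.
#' @export
plan_fitness <- function(plan, athlete, params,
                         objective = c("final", "peak")) {
  objective <- match.arg(objective)
  p <- performance_series(plan, athlete, params)$performance
  if (objective == "final") p[length(p)] else max(p)
}
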