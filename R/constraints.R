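#' Physiological constraint configuration
#'
#' Thresholds and conventions for the three overtraining-avoidance
#' constraints applied to a plan's daily TRIMP series:
#'
#' * **weekly training monotony** (mean daily load / sd of daily load per
#'   7-day block) must not exceed `monotony_max`;
#' * **chronic-training-load (CTL) ramp rate** (week-over-week change of an
#'   exponentially weighted moving average of daily load with time constant
#'   `ctl_time_constant`) must not exceed `ramp_rate_max`;
#' * **daily load** must not exceed `daily_trimp_max` TRIMP.
#'
#' Each constraint's excess is normalized by its own threshold so the three
#' contribute on comparable scales, then raised to `violation_exponent` and
#' summed into the aggregate violation `phi` used by the epsilon-constrained
#' comparison.
#'
#' @param monotony_max Weekly monotony ceiling (dimensionless), default 1.5.
#' @param ramp_rate_max Weekly CTL ramp ceiling, TRIMP/day per week,
#'   default 5.
#' @param daily_trimp_max Daily load ceiling, TRIMP, default 450.
#' @param ctl_time_constant CTL EWMA time constant, days, default 42.
#' @param ctl_start Starting CTL before day 1, TRIMP/day, default 0
#'   (an untrained / novice starting state).
#' @param violation_exponent Power `p` in `phi = g1^p + g2^p + g3^p`,
#'   default 2.
#' @param week_length Days per monotony/ramp block, default 7.
#' @param monotony_inf_penalty Finite per-week penalty substituted when a
#'   week has nonzero constant load (zero variance, monotony formally
#'   infinite), default 10.
#' @param monotony_aggregate `"sum"` (default) adds the threshold excess of
#'   every week into `g1`; `"max"` uses only the worst week.
#' @return An object of class `constraint_config`.
#' @export
constraint_config <- function(monotony_max = 1.5, ramp_rate_max = 5,
                              daily_trimp_max = 450, ctl_time_constant = 42,
                              ctl_start = 0, violation_exponent = 2,
                              week_length = 7, monotony_inf_penalty = 10,
                              monotony_aggregate = c("sum", "max")) {
  monotony_aggregate <- match.arg(monotony_aggregate)
  thr <- c(monotony_max, ramp_rate_max, daily_trimp_max, ctl_time_constant,
           monotony_inf_penalty)
  if (any(!is.finite(thr)) || any(thr <= 0))
    stop("constraint thresholds must be positive and finite", call. = FALSE)
  if (violation_exponent < 1)
    stop("violation_exponent must be >= 1", call. = FALSE)
  if (week_length < 2 || week_length != round(week_length))
    stop("week_length must be an integer >= 2", call. = FALSE)
  if (ctl_start < 0) stop("ctl_start must be >= 0", call. = FALSE)
  structure(
    list(monotony_max = monotony_max, ramp_rate_max = ramp_rate_max,
         daily_trimp_max = daily_trimp_max,
         ctl_time_constant = ctl_time_constant, ctl_start = ctl_start,
         violation_exponent = violation_exponent,
         week_length = as.integer(week_length),
         monotony_inf_penalty = monotony_inf_penalty,
         monotony_aggregate = monotony_aggregate),
    class = "constraint_config")
}

# ---- vectorized kernels shared by the scalar API and the swarm evaluator --

# W: n x M matrix of daily loads -> n x n_weeks matrix of monotony ratios.
# All-zero week -> 0 (a rest week is not monotonous training); nonzero
# constant week -> Inf sentinel.
.monotony_matrix <- function(W, cfg) {
  wl <- cfg$week_length
  n_weeks <- floor(ncol(W) / wl)
  out <- matrix(0, nrow(W), n_weeks)
  for (k in seq_len(n_weeks)) {
    blk <- W[, ((k - 1L) * wl + 1L):(k * wl), drop = FALSE]
    m <- rowMeans(blk)
    s <- sqrt(pmax(rowSums(blk^2) - wl * m^2, 0) / (wl - 1L))
    ratio <- ifelse(rowSums(blk) == 0, 0, ifelse(s == 0, Inf, m / s))
    out[, k] <- ratio
  }
  out
}

# W: n x M loads -> n x M CTL matrix, EWMA recursion
# CTL_t = CTL_{t-1} + (w_t - CTL_{t-1}) / tau, CTL_0 = ctl_start.
.ctl_matrix <- function(W, cfg) {
  tau <- cfg$ctl_time_constant
  out <- matrix(0, nrow(W), ncol(W))
  prev <- rep(cfg$ctl_start, nrow(W))
  for (t in seq_len(ncol(W))) {
    prev <- prev + (W[, t] - prev) / tau
    out[, t] <- prev
  }
  out
}

# ctl: n x M -> n x n_weeks week-over-week CTL differences
.ramp_matrix <- function(ctl, cfg) {
  wl <- cfg$week_length
  n_weeks <- floor(ncol(ctl) / wl)
  ends <- seq_len(n_weeks) * wl
  d <- ctl[, ends, drop = FALSE]
  cbind(d[, 1L] - cfg$ctl_start,
        if (n_weeks > 1L) d[, -1L, drop = FALSE] - d[, -n_weeks, drop = FALSE])
}

# full vectorized constraint evaluation: W (n x M) -> list of g1,g2,g3,phi
.violations_matrix <- function(W, cfg) {
  mono <- .monotony_matrix(W, cfg)
  e1 <- pmax(mono - cfg$monotony_max, 0) / cfg$monotony_max
  e1[!is.finite(mono)] <- cfg$monotony_inf_penalty
  g1 <- if (cfg$monotony_aggregate == "sum") rowSums(e1) else
    apply(e1, 1L, max)
  ctl <- .ctl_matrix(W, cfg)
  ramp <- .ramp_matrix(ctl, cfg)
  g2 <- rowSums(pmax(ramp - cfg$ramp_rate_max, 0) / cfg$ramp_rate_max)
  g3 <- rowSums(pmax(W - cfg$daily_trimp_max, 0) / cfg$daily_trimp_max)
  p <- cfg$violation_exponent
  list(g1 = g1, g2 = g2, g3 = g3, phi = g1^p + g2^p + g3^p,
       monotony = mono, ctl = ctl, ramp = ramp)
}

.check_loads <- function(loads) {
  if (length(loads) == 0L) stop("empty load series", call. = FALSE)
  if (any(!is.finite(loads)) || any(loads < 0))
    stop("daily loads must be finite and non-negative", call. = FALSE)
}

.whole_weeks <- function(loads, wl) {
  n_weeks <- floor(length(loads) / wl)
  if (n_weeks == 0L)
    stop("load series shorter than one week (", wl, " days)", call. = FALSE)
  if (length(loads) %% wl != 0L)
    warning("load series length not a multiple of ", wl,
            " days; trailing partial week ignored", call. = FALSE)
  loads[seq_len(n_weeks * wl)]
}

#' Weekly training monotony
#'
#' Foster's monotony index per 7-day block: the mean of the daily loads
#' divided by their sample (n-1) standard deviation. An all-zero (rest)
#' week yields 0 by convention; a nonzero constant week has zero variance
#' and yields `Inf` (callers aggregating violations substitute a finite
#' penalty, see [constraint_config()]).
#'
#' @param loads Daily TRIMP series.
#' @param cfg A [constraint_config()].
#' @return One monotony ratio per whole week.
#' @examples
#' weekly_monotony(c(rep(100, 6), 0))  # ~2.27
#' @export
weekly_monotony <- function(loads, cfg = constraint_config()) {
  .check_loads(loads)
  loads <- .whole_weeks(loads, cfg$week_length)
  as.vector(.monotony_matrix(matrix(loads, nrow = 1L), cfg))
}

#' Chronic training load (CTL) series
#'
#' Exponentially weighted moving average of the daily load with time
#' constant `tau = ctl_time_constant` days:
#' `CTL_t = CTL_{t-1} + (w_t - CTL_{t-1}) / tau`, starting from
#' `ctl_start`. For a constant load `L` the closed form is
#' `CTL_t = L + (ctl_start - L) * ((tau - 1)/tau)^t`, converging to `L`.
#'
#' @inheritParams weekly_monotony
#' @return CTL values (TRIMP/day), same length as `loads`.
#' @export
ctl_series <- function(loads, cfg = constraint_config()) {
  .check_loads(loads)
  as.vector(.ctl_matrix(matrix(loads, nrow = 1L), cfg))
}

#' Weekly CTL ramp rates
#'
#' Week-over-week change of the CTL: for week `k`, `CTL` at day `7k` minus
#' `CTL` at day `7(k-1)` (the starting CTL for `k = 1`). Negative ramps
#' (unloading weeks) are allowed; only the upper bound is constrained.
#'
#' @param ctl A CTL series from [ctl_series()].
#' @param cfg A [constraint_config()].
#' @return One ramp rate (TRIMP/day per week) per whole week.
#' @export
weekly_ramp_rates <- function(ctl, cfg = constraint_config()) {
  if (length(ctl) == 0L) stop("empty CTL series", call. = FALSE)
  ctl <- .whole_weeks(ctl, cfg$week_length)
  as.vector(.ramp_matrix(matrix(ctl, nrow = 1L), cfg))
}

#' Constraint report of a training plan
#'
#' Evaluates the three physiological constraints on a plan and aggregates
#' their threshold-normalized excesses into the total violation
#' `phi = g1^p + g2^p + g3^p`:
#' `g1 = sum_weeks max(0, monotony - monotony_max)/monotony_max`,
#' `g2 = sum_weeks max(0, ramp - ramp_rate_max)/ramp_rate_max`,
#' `g3 = sum_days  max(0, w - daily_trimp_max)/daily_trimp_max`.
#' `phi = 0` exactly when the plan is feasible (every weekly monotony,
#' every weekly ramp and every daily load at or below its threshold).
#'
#' @param plan A [training_plan()].
#' @param athlete An [athlete_profile()].
#' @param cfg A [constraint_config()].
#' @return An object of class `constraint_report`: list with
#'   `weekly_monotony`, `ctl_series`, `weekly_ramp_rates`, `daily_trimp`,
#'   `g` (named vector: monotony, ramp, daily), `phi`, `feasible`, `config`.
#' @export
violations <- function(plan, athlete, cfg = constraint_config()) {
  stopifnot(inherits(plan, "training_plan"))
  w <- trimp_series(plan, athlete)
  .check_loads(w)
  W <- matrix(.whole_weeks(w, cfg$week_length), nrow = 1L)
  v <- .violations_matrix(W, cfg)
  structure(
    list(weekly_monotony = as.vector(v$monotony),
         ctl_series = as.vector(v$ctl),
         weekly_ramp_rates = as.vector(v$ramp),
         daily_trimp = w,
         g = c(monotony = v$g1, ramp = v$g2, daily = v$g3),
         phi = v$phi,
         feasible = v$phi == 0,
         config = cfg),
    class = "constraint_report")
}

#' @export
print.constraint_report <- function(x, ...) {
  cfg <- x$config
  cat("Constraint report\n")
  cat(sprintf("  weekly monotony (max %.3g): %s\n", cfg$monotony_max,
              paste(sprintf("%.3f", x$weekly_monotony), collapse = " ")))
  cat(sprintf("  weekly CTL ramp (max %.3g): %s\n", cfg$ramp_rate_max,
              paste(sprintf("%.3f", x$weekly_ramp_rates), collapse = " ")))
  cat(sprintf("  daily TRIMP max (cap %.4g): %.2f\n", cfg$daily_trimp_max,
              max(x$daily_trimp)))
  cat(sprintf("  violations g = (%.4g, %.4g, %.4g), phi = %.6g  [%s]\n",
              x$g[["monotony"]], x$g[["ramp"]], x$g[["daily"]], x$phi,
              if (x$feasible) "FEASIBLE" else "infeasible"))
  invisible(x)
}

# vectorized strict "a better than b" under the epsilon-lexicographic order:
# violations at or below eps count as zero; smaller violation wins, ties
# broken by larger objective.
.eps_better <- function(obj_a, phi_a, obj_b, phi_b, eps = 0) {
  pa <- ifelse(phi_a <= eps, 0, phi_a)
  pb <- ifelse(phi_b <= eps, 0, phi_b)
  (pa < pb) | (pa == pb & obj_a > obj_b)
}

#' Epsilon-constrained comparison of two candidate solutions
#'
#' Orders `(objective, violation)` pairs lexicographically with the
#' violation first: violations at or below the epsilon level are treated as
#' zero; of two unequal (effective) violations the smaller wins; at equal
#' effective violation the larger objective wins. With `eps = 0` this is
#' the pure lexicographic order in which feasibility precedes performance.
#'
#' @param a,b Candidates: numeric `c(objective, violation)` or lists with
#'   elements `objective` and `violation` (alias `phi`).
#' @param eps Epsilon level, default 0.
#' @return The better candidate (`a` on a complete tie).
#' @export
epsilon_compare <- function(a, b, eps = 0) {
  get2 <- function(x) {
    if (is.numeric(x) && length(x) == 2L) c(obj = x[1L], phi = x[2L])
    else c(obj = x$objective,
           phi = if (!is.null(x$violation)) x$violation else x$phi)
  }
  pa <- get2(a); pb <- get2(b)
  if (any(c(pa["phi"], pb["phi"]) < 0))
    stop("constraint violations must be non-negative", call. = FALSE)
  if (.eps_better(pb["obj"], pb["phi"], pa["obj"], pa["phi"], eps)) b else a
}
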