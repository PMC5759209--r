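# Independent oracles and fixture factories used across the suite. These
# deliberately re-derive each quantity from its definition by a different
# algorithm than the package implementation.

ath <- simulated_athlete()

# naive term-by-term evaluation of the impulse-response sum
# p_t = p0 + k1 sum_{i=0}^{t-1} w_i e^{-(t-i)/r1} - k2 sum ... /r2,
# with session j of the plan on day i = j - 1
oracle_performance <- function(w, p0, prm, t) {
  fit <- 0
  fat <- 0
  for (i in 0:(t - 1)) {
    fit <- fit + w[i + 1] * exp(-(t - i) / prm$r1)
    fat <- fat + w[i + 1] * exp(-(t - i) / prm$r2)
  }
  p0 + prm$k1 * fit - prm$k2 * fat
}

# exhaustive enumeration of all monotone warping paths (no DP reuse)
oracle_dtw <- function(a, b) {
  rec <- function(i, j) {
    c0 <- abs(a[i] - b[j])
    if (i == 1 && j == 1) return(c0)
    best <- Inf
    if (i > 1) best <- min(best, rec(i - 1, j))
    if (j > 1) best <- min(best, rec(i, j - 1))
    if (i > 1 && j > 1) best <- min(best, rec(i - 1, j - 1))
    c0 + best
  }
  rec(length(a), length(b))
}

# brute-force feasibility check straight from the three constraint
# statements, bypassing the violations() aggregation
oracle_feasible <- function(loads, cfg = constraint_config()) {
  wl <- cfg$week_length
  for (k in seq_len(length(loads) %/% wl)) {
    blk <- loads[((k - 1) * wl + 1):(k * wl)]
    if (any(blk > cfg$daily_trimp_max)) return(FALSE)
    if (sum(blk) > 0) {
      s <- stats::sd(blk)
      if (s == 0 || mean(blk) / s > cfg$monotony_max) return(FALSE)
    }
  }
  ctl_prev <- cfg$ctl_start
  ctl <- cfg$ctl_start
  for (k in seq_len(length(loads) %/% wl)) {
    for (t in ((k - 1) * wl + 1):(k * wl))
      ctl <- ctl + (loads[t] - ctl) / cfg$ctl_time_constant
    if (ctl - ctl_prev > cfg$ramp_rate_max) return(FALSE)
    ctl_prev <- ctl
  }
  TRUE
}

random_plan <- function(n = 56, athlete = ath, dur = c(30, 300)) {
  training_plan(stats::runif(n, athlete$resting_hr, athlete$max_hr),
                stats::runif(n, dur[1], dur[2]))
}

# small swarm configuration for fast unit tests
tiny_swarm <- function(iters = 50, ...) {
  swarm_config(n_particles = 20, n_groups = 4, group_size = 5,
               max_iterations = iters, ...)
}
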