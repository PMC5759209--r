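#' Swarm optimizer configuration
#'
#' Hyper-parameters of the grouped, epsilon-constrained particle swarm.
#' The swarm of `n_particles` is partitioned into `n_groups` islands of
#' `group_size` particles each (`n_particles = n_groups * group_size` is
#' enforced); particles are socially attracted to their island's best
#' unless `global_social = TRUE`. Inertia decays linearly from
#' `inertia_start` at iteration 0 to `inertia_end` at `max_iterations`.
#' Per-dimension maximum velocities start at the full box range and shrink
#' by `vmax_gamma` whenever the swarm looks like it is flying over the
#' feasible region: fewer than `feasible_fraction_weight` of particles are
#' currently feasible, or the incumbent has improved by less than the
#' relative tolerance `update_threshold` over the last `vmax_window`
#' iterations. Velocity limits never shrink below `vmax_floor_frac` of the
#' dimension range.
#'
#' @param n_particles Swarm size `N`, default 100.
#' @param n_groups Number of islands `N_g`, default 4.
#' @param group_size Particles per island `n_g`, default 25.
#' @param inertia_start,inertia_end Linear inertia schedule endpoints
#'   (`w0 = 0.9`, `wT = 0.4`).
#' @param c1,c2 Cognitive and social acceleration coefficients, default 2.
#' @param max_iterations Iteration budget `T`, default 5000.
#' @param max_evaluations Optional fitness-evaluation budget; when set, the
#'   effective iteration count is `floor(max_evaluations / n_particles)`
#'   capped at `max_iterations`.
#' @param eps_level Epsilon level of the constrained comparison, default 0
#'   (strict lexicographic: feasibility first).
#' @param feasible_fraction_weight Feasible-fraction trigger `F_lambda`,
#'   default 0.2.
#' @param update_threshold Relative-improvement trigger `F_theta`,
#'   default 0.05.
#' @param vmax_gamma Velocity-limit shrink factor, default 0.95.
#' @param vmax_floor_frac Velocity-limit floor as a fraction of the
#'   dimension range, default 1e-3.
#' @param vmax_window Iterations over which stagnation is measured,
#'   default 10.
#' @param global_social Use the global best (instead of island bests) as
#'   the social attractor, default `FALSE`.
#' @param seed Default RNG seed for [pso_optimize()].
#' @return An object of class `swarm_config`.
#' @export
swarm_config <- function(n_particles = 100, n_groups = 4, group_size = 25,
                         inertia_start = 0.9, inertia_end = 0.4,
                         c1 = 2, c2 = 2,
                         max_iterations = 5000, max_evaluations = NULL,
                         eps_level = 0,
                         feasible_fraction_weight = 0.2,
                         update_threshold = 0.05,
                         vmax_gamma = 0.95, vmax_floor_frac = 1e-3,
                         vmax_window = 10,
                         global_social = FALSE, seed = NULL) {
  if (n_particles != n_groups * group_size)
    stop(sprintf("n_particles (%d) must equal n_groups * group_size (%d x %d)",
                 n_particles, n_groups, group_size), call. = FALSE)
  if (!(inertia_end > 0 && inertia_end <= inertia_start))
    stop("require 0 < inertia_end <= inertia_start", call. = FALSE)
  if (max_iterations < 1) stop("max_iterations must be >= 1", call. = FALSE)
  if (eps_level < 0) stop("eps_level must be >= 0", call. = FALSE)
  if (!(vmax_gamma > 0 && vmax_gamma < 1))
    stop("vmax_gamma must be in (0, 1)", call. = FALSE)
  structure(
    list(n_particles = as.integer(n_particles),
         n_groups = as.integer(n_groups),
         group_size = as.integer(group_size),
         inertia_start = inertia_start, inertia_end = inertia_end,
         c1 = c1, c2 = c2,
         max_iterations = as.integer(max_iterations),
         max_evaluations = if (is.null(max_evaluations)) NULL else
           as.integer(max_evaluations),
         eps_level = eps_level,
         feasible_fraction_weight = feasible_fraction_weight,
         update_threshold = update_threshold,
         vmax_gamma = vmax_gamma, vmax_floor_frac = vmax_floor_frac,
         vmax_window = as.integer(vmax_window),
         global_social = isTRUE(global_social),
         seed = seed),
    class = "swarm_config")
}

#' Inertia weight at an iteration
#'
#' Linear schedule `w(r) = w0 + (wT - w0) * r / T` between the configured
#' endpoints.
#'
#' @param r Iteration counter, `0 <= r <= T`.
#' @param cfg A [swarm_config()].
#' @param T Total iterations; defaults to `cfg$max_iterations`.
#' @return Inertia weight.
#' @export
inertia_at <- function(r, cfg, T = cfg$max_iterations) {
  if (any(r < 0) || any(r > T))
    stop("iteration r must lie in [0, T]", call. = FALSE)
  cfg$inertia_start + (cfg$inertia_end - cfg$inertia_start) * r / T
}

.check_bounds <- function(bounds) {
  if (!is.matrix(bounds) || ncol(bounds) != 2L)
    stop("bounds must be a d x 2 matrix of (lower, upper) columns",
         call. = FALSE)
  if (any(bounds[, 1L] >= bounds[, 2L]))
    stop(sprintf("lower bound >= upper bound in dimension %d",
                 which(bounds[, 1L] >= bounds[, 2L])[1L]), call. = FALSE)
  invisible(bounds)
}

#' Initialize a swarm
#'
#' Positions are drawn uniformly within the per-dimension bounds, all
#' velocities start at exactly zero, and each dimension's maximum velocity
#' is initialized to its full bound range. Personal bests are unset until
#' the first evaluation. Deterministic under a fixed seed.
#'
#' @param bounds `d x 2` matrix; column 1 lower, column 2 upper bounds.
#' @param cfg A [swarm_config()].
#' @param seed Optional integer seed (seeds the session RNG).
#' @return An object of class `swarm_state`.
#' @export
initialize_swarm <- function(bounds, cfg, seed = NULL) {
  .check_bounds(bounds)
  if (!is.null(seed)) set.seed(seed)
  d <- nrow(bounds)
  N <- cfg$n_particles
  lo <- matrix(bounds[, 1L], N, d, byrow = TRUE)
  hi <- matrix(bounds[, 2L], N, d, byrow = TRUE)
  x <- lo + matrix(stats::runif(N * d), N, d) * (hi - lo)
  structure(
    list(x = x,
         v = matrix(0, N, d),
         bounds = bounds,
         group = rep(seq_len(cfg$n_groups), each = cfg$group_size),
         pbest_x = x,
         pbest_obj = rep(-Inf, N),
         pbest_phi = rep(Inf, N),
         gb_x = matrix(NA_real_, cfg$n_groups, d),
         gb_obj = rep(-Inf, cfg$n_groups),
         gb_phi = rep(Inf, cfg$n_groups),
         best_x = rep(NA_real_, d),
         best_obj = -Inf,
         best_phi = Inf,
         best_g = NULL,
         vmax = bounds[, 2L] - bounds[, 1L],
         iter = 0L,
         feasible_fraction = NA_real_,
         hist_obj = numeric(0),
         hist_phi = numeric(0),
         evaluated = FALSE),
    class = "swarm_state")
}

# sanitize an evaluator result: particles whose evaluation produced
# non-finite scores are assigned the worst possible score and the run
# continues.
.sanitize_scores <- function(res, N) {
  obj <- as.numeric(res$objective)
  phi <- as.numeric(res$phi)
  if (length(obj) != N || length(phi) != N)
    stop("evaluator must return objective and phi of length n_particles",
         call. = FALSE)
  bad <- !is.finite(obj) | !is.finite(phi) | phi < 0
  if (any(bad)) {
    obj[bad] <- -Inf
    phi[bad] <- Inf
  }
  list(objective = obj, phi = phi, g = res$g, bad = bad)
}

# refresh personal, island and global bests from freshly evaluated scores
.update_bests <- function(state, scores, cfg) {
  better <- .eps_better(scores$objective, scores$phi,
                        state$pbest_obj, state$pbest_phi, cfg$eps_level)
  state$pbest_x[better, ] <- state$x[better, , drop = FALSE]
  state$pbest_obj[better] <- scores$objective[better]
  state$pbest_phi[better] <- scores$phi[better]
  key_order <- function(obj, phi) {
    peff <- ifelse(phi <= cfg$eps_level, 0, phi)
    order(peff, -obj)
  }
  for (g in seq_len(cfg$n_groups)) {
    idx <- which(state$group == g)
    b <- idx[key_order(state$pbest_obj[idx], state$pbest_phi[idx])[1L]]
    state$gb_x[g, ] <- state$pbest_x[b, ]
    state$gb_obj[g] <- state$pbest_obj[b]
    state$gb_phi[g] <- state$pbest_phi[b]
  }
  b <- key_order(state$pbest_obj, state$pbest_phi)[1L]
  state$best_x <- state$pbest_x[b, ]
  state$best_obj <- state$pbest_obj[b]
  state$best_phi <- state$pbest_phi[b]
  if (!is.null(scores$g)) state$best_g <- scores$g[b, ]
  state$feasible_fraction <- mean(scores$phi <= cfg$eps_level)
  state$evaluated <- TRUE
  state
}

#' Advance the swarm by one iteration
#'
#' Standard PSO velocity update (linearly decaying inertia, cognitive pull
#' toward the personal best, social pull toward the island best), followed
#' by per-dimension velocity clamping to the current adaptive limit,
#' position clamping to the box bounds (with the velocity of a clamped
#' component zeroed), evaluation of the moved swarm and an
#' epsilon-constrained update of all bests. A particle whose evaluation
#' fails or returns non-finite scores is assigned the worst score
#' (`objective = -Inf`, `phi = Inf`) and the run continues.
#'
#' @param state A `swarm_state` whose initial positions have been evaluated
#'   (see [pso_optimize()], which handles iteration 0).
#' @param evaluate Function taking an `n x d` position matrix and returning
#'   `list(objective =, phi =, g = )` with numeric vectors of length `n`
#'   (`g`, an optional `n x k` matrix of per-constraint violations, is
#'   carried into the trace).
#' @param cfg A [swarm_config()].
#' @param T Iteration budget used by the inertia schedule; defaults to
#'   `cfg$max_iterations`.
#' @return The advanced `swarm_state`.
#' @export
pso_step <- function(state, evaluate, cfg, T = cfg$max_iterations) {
  stopifnot(inherits(state, "swarm_state"))
  N <- nrow(state$x); d <- ncol(state$x)
  w <- inertia_at(min(state$iter, T), cfg, T)
  social_x <- if (cfg$global_social)
    matrix(state$best_x, N, d, byrow = TRUE)
  else
    state$gb_x[state$group, , drop = FALSE]
  r1 <- matrix(stats::runif(N * d), N, d)
  r2 <- matrix(stats::runif(N * d), N, d)
  v <- w * state$v +
    cfg$c1 * r1 * (state$pbest_x - state$x) +
    cfg$c2 * r2 * (social_x - state$x)
  vm <- matrix(state$vmax, N, d, byrow = TRUE)
  v <- pmin(pmax(v, -vm), vm)
  x <- state$x + v
  lo <- matrix(state$bounds[, 1L], N, d, byrow = TRUE)
  hi <- matrix(state$bounds[, 2L], N, d, byrow = TRUE)
  clamped <- x < lo | x > hi
  x <- pmin(pmax(x, lo), hi)
  v[clamped] <- 0
  state$x <- x
  state$v <- v
  scores <- .sanitize_scores(
    tryCatch(evaluate(x),
             error = function(e) {
               list(objective = rep(-Inf, N), phi = rep(Inf, N))
             }), N)
  state <- .update_bests(state, scores, cfg)
  state$iter <- state$iter + 1L
  state$hist_obj <- c(state$hist_obj, state$best_obj)
  state$hist_phi <- c(state$hist_phi, state$best_phi)
  state
}

#' Adapt the per-dimension maximum velocity
#'
#' Called once per iteration after evaluation. Every component of the
#' velocity limit shrinks by the factor `vmax_gamma` when either trigger
#' fires: (a) the fraction of currently feasible particles is below
#' `feasible_fraction_weight`, or (b) the incumbent has improved by less
#' than the relative tolerance `update_threshold` over the last
#' `vmax_window` iterations (measured on the violation while the incumbent
#' is infeasible, on the objective once feasible). Limits never fall below
#' `vmax_floor_frac` of each dimension's range.
#'
#' @inheritParams pso_step
#' @return The state with an updated `vmax` vector.
#' @export
adapt_vmax <- function(state, cfg) {
  stopifnot(inherits(state, "swarm_state"))
  trigger <- FALSE
  if (!is.na(state$feasible_fraction) &&
      state$feasible_fraction < cfg$feasible_fraction_weight)
    trigger <- TRUE
  L <- length(state$hist_obj)
  if (!trigger && L > cfg$vmax_window) {
    then_obj <- state$hist_obj[L - cfg$vmax_window]
    then_phi <- state$hist_phi[L - cfg$vmax_window]
    improved <- if (then_phi > cfg$eps_level) {
      (then_phi - state$best_phi) / max(then_phi, 1) >= cfg$update_threshold
    } else {
      is.finite(then_obj) &&
        (state$best_obj - then_obj) / max(abs(then_obj), 1) >=
          cfg$update_threshold
    }
    trigger <- !improved
  }
  if (trigger) {
    range <- state$bounds[, 2L] - state$bounds[, 1L]
    state$vmax <- pmax(state$vmax * cfg$vmax_gamma,
                       cfg$vmax_floor_frac * range)
  }
  state
}

#' Run the grouped epsilon-constrained particle swarm optimizer
#'
#' Initializes a swarm inside the box `bounds`, evaluates it (iteration 0),
#' then alternates [pso_step()] and [adapt_vmax()] for the configured
#' budget, recording a per-iteration trace of the incumbent. The returned
#' best solution is the epsilon-lexicographically best personal best ever
#' seen, so the incumbent never worsens along the trace. Bit-identical
#' under a fixed seed and configuration.
#'
#' @param evaluate Vectorized evaluator, see [pso_step()].
#' @param bounds `d x 2` matrix of lower/upper bounds.
#' @param cfg A [swarm_config()].
#' @param seed Integer seed; defaults to `cfg$seed`.
#' @return An object of class `pso_result`: list with `best_position`,
#'   `best_objective`, `best_phi`, `best_g`, `trace` (data frame:
#'   `iteration`, `best_objective`, `best_phi`, per-constraint `g.*`
#'   columns when provided, `feasible_fraction`, `vmax_scale`),
#'   `iterations`, `evaluations`, `config`, `seed` and the final `state`.
#' @export
pso_optimize <- function(evaluate, bounds, cfg = swarm_config(),
                         seed = cfg$seed) {
  .check_bounds(bounds)
  if (is.null(seed)) seed <- 1L
  T_eff <- cfg$max_iterations
  if (!is.null(cfg$max_evaluations))
    T_eff <- min(T_eff,
                 max(0L, floor(cfg$max_evaluations / cfg$n_particles) - 1L))
  state <- initialize_swarm(bounds, cfg, seed = seed)
  scores <- .sanitize_scores(
    evaluate(state$x), cfg$n_particles)
  state <- .update_bests(state, scores, cfg)
  state$hist_obj <- state$best_obj
  state$hist_phi <- state$best_phi
  range_mean <- mean(state$bounds[, 2L] - state$bounds[, 1L])
  n_g <- if (!is.null(state$best_g)) length(state$best_g) else 0L
  trace <- vector("list", T_eff + 1L)
  snap <- function(state) {
    row <- c(iteration = state$iter,
             best_objective = state$best_obj,
             best_phi = state$best_phi)
    if (n_g > 0L) {
      g <- state$best_g
      names(g) <- paste0("g", seq_len(n_g))
      row <- c(row, g)
    }
    c(row, feasible_fraction = state$feasible_fraction,
      vmax_scale = mean(state$vmax) / range_mean)
  }
  trace[[1L]] <- snap(state)
  if (T_eff > 0L) {
    for (r in seq_len(T_eff)) {
      state <- pso_step(state, evaluate, cfg, T = T_eff)
      state <- adapt_vmax(state, cfg)
      trace[[r + 1L]] <- snap(state)
    }
  }
  trace <- as.data.frame(do.call(rbind, trace))
  structure(
    list(best_position = state$best_x,
         best_objective = state$best_obj,
         best_phi = state$best_phi,
         best_g = state$best_g,
         trace = trace,
         iterations = T_eff,
         evaluations = (T_eff + 1L) * cfg$n_particles,
         config = cfg,
         seed = seed,
         state = state),
    class = "pso_result")
}

#' Lift a single-candidate objective to a swarm evaluator
#'
#' Convenience wrapper turning a function of one position vector returning
#' `c(objective, violation)` (or a scalar objective for unconstrained
#' problems) into the row-vectorized evaluator [pso_optimize()] expects.
#'
#' @param f Function of one numeric vector.
#' @return A function of an `n x d` matrix.
#' @export
rowwise_evaluator <- function(f) {
  function(X) {
    res <- apply(X, 1L, function(row) {
      out <- f(row)
      if (length(out) == 1L) c(out, 0) else out[1:2]
    })
    list(objective = res[1L, ], phi = res[2L, ])
  }
}
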