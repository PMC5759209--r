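sphere_eval <- function(X) {
  list(objective = -rowSums(X^2), phi = rep(0, nrow(X)))
}

toy_eval <- function(X) {
  s <- rowSums(X)
  list(objective = s, phi = pmax(s - 1, 0)^2)
}

test_that("plan codec round-trips and preserves the interleaved layout", {
  expect_equal(decode_plan(c(120, 60))$avg_hr_bpm, 120)
  expect_equal(decode_plan(c(120, 60))$duration_min, 60)
  set.seed(2)
  for (i in 1:10) {
    x <- as.vector(rbind(runif(56, 51, 189), runif(56, 30, 300)))
    expect_equal(encode_plan(decode_plan(x)), x)
  }
  plan <- random_plan(56)
  expect_length(encode_plan(plan), 112)
  expect_equal(nrow(decode_plan(encode_plan(plan))), 56)
  expect_error(decode_plan(c(1, 2, 3)), "even length")
})

test_that("inertia decays linearly from 0.9 to 0.4", {
  cfg <- swarm_config()
  T <- cfg$max_iterations
  expect_equal(inertia_at(0, cfg), 0.9)
  expect_equal(inertia_at(T, cfg), 0.4)
  expect_equal(inertia_at(T / 2, cfg), 0.65)
  expect_error(inertia_at(-1, cfg), "\\[0, T\\]")
})

test_that("swarm_config enforces the group decomposition", {
  expect_error(swarm_config(n_particles = 100, n_groups = 5, group_size = 25),
               "n_groups \\* group_size")
  cfg <- swarm_config()
  expect_identical(cfg$n_particles, 100L)
  expect_identical(cfg$n_groups * cfg$group_size, cfg$n_particles)
})

test_that("initialization is uniform-in-bounds, zero-velocity, reproducible", {
  bounds <- cbind(rep(c(51, 30), 56), rep(c(189, 300), 56))
  cfg <- tiny_swarm()
  s1 <- initialize_swarm(bounds, cfg, seed = 99)
  s2 <- initialize_swarm(bounds, cfg, seed = 99)
  expect_identical(s1$x, s2$x)
  expect_equal(ncol(s1$x), 112)
  expect_true(all(s1$v == 0))
  expect_true(all(sweep(s1$x, 2, bounds[, 1], ">=")))
  expect_true(all(sweep(s1$x, 2, bounds[, 2], "<=")))
  expect_equal(s1$vmax, bounds[, 2] - bounds[, 1])
  expect_error(initialize_swarm(cbind(1, 1), cfg), "lower bound >= upper")
})

test_that("a converged swarm with no attraction is a fixed point", {
  bounds <- cbind(rep(0, 3), rep(1, 3))
  cfg <- swarm_config(n_particles = 8, n_groups = 2, group_size = 4,
                      c1 = 0, c2 = 0, max_iterations = 10)
  state <- initialize_swarm(bounds, cfg, seed = 1)
  state$x[] <- 0.5
  state$v[] <- 0
  # prime personal/group bests at the common position (iteration 0)
  state <- trainopt:::.update_bests(
    state, trainopt:::.sanitize_scores(sphere_eval(state$x), 8), cfg)
  st2 <- pso_step(state, sphere_eval, cfg)
  expect_identical(st2$x, state$x)
  expect_true(all(st2$v == 0))
})

test_that("velocity clamping and bound clamping are exact", {
  bounds <- cbind(rep(0, 2), rep(1, 2))
  cfg <- swarm_config(n_particles = 4, n_groups = 1, group_size = 4,
                      max_iterations = 10)
  state <- initialize_swarm(bounds, cfg, seed = 1)
  state <- trainopt:::.update_bests(
    state, trainopt:::.sanitize_scores(sphere_eval(state$x), 4), cfg)
  state$vmax <- c(0.05, 0.05)
  # force large attraction so that raw velocities exceed vmax
  state$pbest_x[] <- 5
  st2 <- pso_step(state, sphere_eval, cfg)
  expect_true(all(abs(st2$v) <= 0.05 + 1e-15))
  expect_true(all(st2$x >= 0 & st2$x <= 1))
})

test_that("a feasible particle dethrones an infeasible incumbent", {
  bounds <- cbind(rep(-2, 2), rep(2, 2))
  cfg <- swarm_config(n_particles = 4, n_groups = 1, group_size = 4,
                      max_iterations = 5)
  state <- initialize_swarm(bounds, cfg, seed = 8)
  ev1 <- function(X) list(objective = rep(100, nrow(X)),
                          phi = rep(3, nrow(X)))
  state <- trainopt:::.update_bests(state, trainopt:::.sanitize_scores(
    ev1(state$x), 4), cfg)
  expect_equal(state$best_phi, 3)
  ev2 <- function(X) list(objective = rep(-50, nrow(X)),
                          phi = rep(0, nrow(X)))
  state <- pso_step(state, ev2, cfg)
  expect_equal(state$best_phi, 0)
  expect_equal(state$best_obj, -50)
})

test_that("failed evaluations demote only the failing particles", {
  bounds <- cbind(rep(0, 2), rep(1, 2))
  cfg <- swarm_config(n_particles = 4, n_groups = 1, group_size = 4,
                      max_iterations = 5)
  ev <- function(X) {
    obj <- -rowSums(X^2)
    obj[2] <- NaN
    list(objective = obj, phi = c(0, NA, 0, 0))
  }
  res <- pso_optimize(ev, bounds, cfg, seed = 4)
  expect_true(is.finite(res$best_objective))
  expect_equal(res$best_phi, 0)
})

test_that("adapt_vmax shrinks on the configured triggers and respects the floor", {
  bounds <- cbind(rep(0, 2), rep(10, 2))
  cfg <- swarm_config(n_particles = 4, n_groups = 1, group_size = 4,
                      max_iterations = 5)
  state <- initialize_swarm(bounds, cfg, seed = 1)
  # no feasible particles -> shrink by gamma
  state$feasible_fraction <- 0
  st2 <- adapt_vmax(state, cfg)
  expect_equal(st2$vmax, state$vmax * cfg$vmax_gamma)
  # plenty feasible and recent improvement -> unchanged
  state$feasible_fraction <- 1
  state$best_obj <- 2
  state$best_phi <- 0
  state$hist_obj <- c(1, rep(2, cfg$vmax_window))
  state$hist_phi <- rep(0, cfg$vmax_window + 1)
  expect_equal(adapt_vmax(state, cfg)$vmax, state$vmax)
  # stagnation -> shrink
  state$hist_obj <- rep(2, cfg$vmax_window + 1)
  expect_equal(adapt_vmax(state, cfg)$vmax, state$vmax * cfg$vmax_gamma)
  # repeated shrinking never passes the floor
  state$feasible_fraction <- 0
  for (i in 1:500) state <- adapt_vmax(state, cfg)
  expect_equal(state$vmax, cfg$vmax_floor_frac * (bounds[, 2] - bounds[, 1]))
})

test_that("optimization is elitist, deterministic and bound-safe", {
  bounds <- cbind(rep(-5, 6), rep(5, 6))
  cfg <- tiny_swarm(iters = 60)
  r1 <- pso_optimize(sphere_eval, bounds, cfg, seed = 17)
  r2 <- pso_optimize(sphere_eval, bounds, cfg, seed = 17)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$best_position, r2$best_position)
  # global best objective never worsens on an unconstrained problem
  expect_true(all(diff(r1$trace$best_objective) >= 0))
  expect_true(all(r1$best_position >= -5 & r1$best_position <= 5))
  # T = 0 returns the best of the evaluated initial swarm
  cfg0 <- swarm_config(n_particles = 20, n_groups = 4, group_size = 5,
                       max_iterations = 1, max_evaluations = 20)
  r0 <- pso_optimize(sphere_eval, bounds, cfg0, seed = 3)
  expect_equal(r0$iterations, 0)
  expect_equal(nrow(r0$trace), 1)
})

test_that("the incumbent never worsens under the epsilon order (constrained)", {
  bounds <- cbind(rep(-2, 2), rep(2, 2))
  res <- pso_optimize(toy_eval, bounds, tiny_swarm(iters = 100), seed = 5)
  tr <- res$trace
  key_phi <- tr$best_phi
  for (i in seq_len(nrow(tr) - 1)) {
    expect_true(key_phi[i + 1] <= key_phi[i])
    if (key_phi[i + 1] == key_phi[i])
      expect_true(tr$best_objective[i + 1] >= tr$best_objective[i])
  }
})

test_that("the toy constrained problem converges to its known optimum", {
  bounds <- cbind(rep(-2, 2), rep(2, 2))
  res <- pso_optimize(toy_eval, bounds, tiny_swarm(iters = 300), seed = 1)
  expect_true(res$best_phi <= 1e-6)
  expect_equal(res$best_objective, 1, tolerance = 1e-2)
})

test_that("rowwise_evaluator lifts scalar objectives", {
  ev <- rowwise_evaluator(function(x) sum(x))
  out <- ev(rbind(c(1, 2), c(3, 4)))
  expect_equal(out$objective, c(3, 7))
  expect_equal(out$phi, c(0, 0))
})

test_that("optimize_plan returns a coherent fit object", {
  fit <- optimize_plan(ath, swarm = tiny_swarm(iters = 40), seed = 2)
  expect_s3_class(fit$plan, "training_plan")
  expect_equal(nrow(fit$plan), 56)
  expect_true(all(fit$plan$avg_hr_bpm >= 51 & fit$plan$avg_hr_bpm <= 189))
  expect_true(all(fit$plan$duration_min >= 30 & fit$plan$duration_min <= 300))
  # reported objective equals the decoded plan's recomputed fitness
  expect_equal(fit$objective,
               plan_fitness(fit$plan, ath, fit$params), tolerance = 1e-9)
  # trace carries the documented columns
  expect_named(fit$trace,
               c("iteration", "best_performance", "total_violation",
                 "g_monotony", "g_ramp", "g_daily", "feasible_fraction",
                 "vmax_scale"))
  # bit-identical reproduction from config + seed
  fit2 <- optimize_plan(ath, swarm = tiny_swarm(iters = 40), seed = 2)
  expect_identical(fit$plan, fit2$plan)
  expect_identical(fit$trace, fit2$trace)
})
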