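# The actor-critic agent: reward functions, advantage, Polyak averaging,
# network updates and the compiled training loop.

test_that("the tracking reward is a calibrated similarity in (0, 1]", {
  x <- c(0.2, 0.3, 0.1, 0.4)
  expect_equal(reward_tracking(x, x, eta = 5), 1)
  expect_equal(reward_tracking(x, x + 1, eta = 0), 1)
  # eta = 1 with squared distance 0.25
  expect_equal(reward_tracking(c(0, 0), c(0.3, 0.4), eta = 1), exp(-0.25))
  expect_error(reward_tracking(c(1, 2), c(1, 2, 3), eta = 1), "shape")

  set.seed(2)
  for (i in 1:20) {
    r <- reward_tracking(runif(4), runif(4), eta = runif(1, 0, 100))
    expect_gt(r, 0); expect_lte(r, 1)
  }
})

test_that("the sparse reward charges -1 per unhealed step", {
  expect_equal(reward_sparse(0.2, 0.95), -1)
  expect_equal(reward_sparse(0.99, 0.95), 0)

  # rollout oracle: the undiscounted return is minus the unhealed steps
  env <- wound_env(default_stage_model(), act_base = rate_constants(0, 0, 0))
  z <- stage_vector(1, 0, 0, 0)
  total <- 0; unhealed <- 0
  for (s in 1:240) {
    z <- env_step(env, z, 0, 0, render = FALSE)$z
    r <- reward_sparse(z[[4]], env$model$heal_threshold)
    total <- total + r
    unhealed <- unhealed + (z[[4]] < env$model$heal_threshold)
  }
  expect_equal(total, -unhealed)
})

test_that("advantage implements the bootstrapped TD form", {
  expect_equal(advantage(0, v_next = 0.7, v = 0.7, gamma = 1), 0)
  expect_equal(advantage(1, v_next = 0.5, v = 0.2, gamma = 1), 1.3)
  expect_equal(advantage(1, v_next = 0.5, v = 0.2, gamma = 1,
                         terminal = TRUE), 0.8)
  expect_equal(advantage(0.3, v_next = 2, v = 1, gamma = 0.5), 0.3)
})

test_that("Polyak averaging is the exact post-burn-in arithmetic mean", {
  expect_equal(polyak_average(c(2, 4), n0 = 0), 3)
  expect_equal(polyak_average(c(10, 2, 4), n0 = 1), 3)
  expect_equal(polyak_average(list(rep(5, 3), rep(5, 3)), n0 = 0), rep(5, 3))
  mats <- list(matrix(1, 2, 2), matrix(3, 2, 2), matrix(5, 2, 2))
  expect_equal(polyak_average(mats, n0 = 1), matrix(4, 2, 2))
  expect_error(polyak_average(c(1, 2), n0 = 2), "n0")
})

test_that("the softmax policy head yields a valid distribution", {
  actor <- init_mlp(c(4, 16, 16, 9), seed = 1)
  set.seed(4)
  for (i in 1:10) {
    pr <- policy_probs(actor, as.numeric(random_stage_vector()))
    expect_equal(sum(pr), 1, tolerance = 1e-12)
    expect_true(all(pr > 0))
  }
})

test_that("network updates follow the advantage-weighted gradient", {
  cfg <- a2c_config(gamma = 1, entropy_coef = 0, lr_actor = 1e-3,
                    lr_critic = 1e-3, episodes = 10)
  agent <- list(actor = init_mlp(c(4, 16, 16, 6), seed = 1),
                critic = init_mlp(c(4, 16, 16, 1), seed = 2))
  obs <- c(0.4, 0.3, 0.2, 0.1)

  # zero advantage: r = 0 and v_next = v leave the actor untouched
  batch0 <- list(list(obs = obs, action = 2L, reward = 0, obs_next = obs,
                      terminal = FALSE))
  out0 <- update_networks(agent, batch0, cfg)
  expect_equal(out0$actor, agent$actor)
  expect_equal(out0$diagnostics$advantage, 0)

  # a positive-advantage transition raises its action's probability
  batch1 <- list(list(obs = obs, action = 3L, reward = 5, obs_next = obs,
                      terminal = TRUE))
  out1 <- update_networks(agent, batch1, cfg)
  expect_gt(policy_probs(out1$actor, obs)[3], policy_probs(agent$actor, obs)[3])

  # the critic overfits a fixed batch
  batch2 <- list(list(obs = obs, action = 1L, reward = 2, obs_next = obs,
                      terminal = TRUE))
  ag <- agent
  losses <- numeric(100)
  for (i in 1:100) {
    ag <- update_networks(ag, batch2, a2c_config(lr_critic = 0.05,
                                                 entropy_coef = 0,
                                                 episodes = 10))
    losses[i] <- ag$diagnostics$critic_loss
  }
  expect_lt(losses[100], losses[1])
  expect_error(update_networks(agent, list(), cfg), "non-empty")
})

test_that("compiled training is reproducible and its env matches the R env", {
  env <- default_env()
  cfg <- a2c_config(episodes = 60, seed = 7)
  ag1 <- train_agent(env, cfg)
  ag2 <- train_agent(env, cfg)
  expect_identical(ag1$returns, ag2$returns)
  expect_identical(ag1$actor, ag2$actor)
  expect_equal(nrow(ag1$evals), 1L)   # one evaluation row per 50 episodes

  # greedy evaluation cross-check: an R-side rollout over env_step must
  # reproduce the compiled rollout exactly
  h_cpp <- evaluate_agent(ag1, env)
  z <- stage_vector(1, 0, 0, 0)
  t <- 0; h_r <- NA
  for (s in 1:round(30 / env$model$dt)) {
    a <- greedy_action(ag1, as.numeric(z))
    z2 <- env_step(env, z, a$e, a$d, render = FALSE)$z
    if (z2[[4]] >= env$model$heal_threshold) {
      h_r <- t + env$model$dt * (env$model$heal_threshold - z[[4]]) /
        (z2[[4]] - z[[4]])
      break
    }
    z <- z2; t <- t + env$model$dt
  }
  expect_equal(h_r, h_cpp, tolerance = 1e-10)
})

test_that("a degenerate no-treatment action space recovers natural healing", {
  m <- default_stage_model()
  env0 <- wound_env(m, act_base = rate_constants(0, 0, 0))
  ag <- train_agent(env0, a2c_config(episodes = 20, seed = 1, n_levels = 1L,
                                     max_level = 0))
  nat <- healing_time(simulate_stages(m, horizon = 30))
  expect_equal(evaluate_agent(ag, env0), nat, tolerance = 1e-10)
})
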