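#' Train an advantage actor-critic treatment agent
#'
#' Runs the full training loop on the latent stage simulator: at every step
#' the agent observes the stage vector, samples a treatment action
#' `(e, d)` from its softmax policy, the environment advances under the
#' treatment-effect modulation, and the networks take one temporal-difference
#' update. With the `"tracking"` reward the agent is paid
#' `exp(-eta * ||z*_{k+1} - z_{k+1}||^2)` for steering the wound towards the
#' LQR-generated reference next state (the leader-follower strategy); with
#' the `"sparse"` reward it is charged -1 for every step the wound remains
#' unhealed. The greedy policy is evaluated every `eval_every` episodes and
#' the final policy is the Polyak-Ruppert average of the actor parameters
#' over the post-burn-in episodes.
#'
#' @param env A [wound_env()]. Only latent-state observations are used here
#'   (the scaled-down observation mode); images are re-renderable from the
#'   logged states.
#' @param config An [a2c_config()].
#' @param reward `"tracking"` (leader-follower, the default) or `"sparse"`.
#' @param ref_model Stage model supplying the LQR reference; defaults to the
#'   environment's model (solved on demand).
#' @return An object of class `a2c_agent`: the Polyak-averaged `actor`, the
#'   last-iterate `actor_final`, the `critic`, a per-episode `returns`
#'   tibble, an `evals` tibble (`episode, eval_healing_days`), the config and
#'   reward mode.
#' @examples
#' \donttest{
#' env <- wound_env(default_stage_model())
#' ag <- train_agent(env, a2c_config(episodes = 100, seed = 1))
#' evaluate_agent(ag, env)
#' }
#' @export
train_agent <- function(env, config = a2c_config(),
                        reward = c("tracking", "sparse"),
                        ref_model = NULL) {
  reward <- match.arg(reward)
  if (config$observation != "stage") {
    abort("only the stage-vector observation mode is implemented in the compiled trainer")
  }
  ref_model <- ref_model %||% env$model
  if (is.null(ref_model$K)) ref_model <- solve_lqr(ref_model)
  m_ref <- build_generator(ref_model$natural) -
    build_generator(ref_model$actuated) %*% ref_model$K

  grid <- treatment_grid(config$n_levels, config$max_level, config$channels)
  steps <- round(config$horizon_days / env$model$dt)
  n_actions <- nrow(grid)

  actor <- init_mlp(c(4L, config$hidden, config$hidden, n_actions),
                    seed = config$seed + 1L)
  critic <- init_mlp(c(4L, config$hidden, config$hidden, 1L),
                     seed = config$seed + 2L)

  res <- with_seed(config$seed, .a2c_train_cpp(
    actor, critic,
    kn = as.numeric(env$model$natural), kab = as.numeric(env$act_base),
    dt = env$model$dt, thr = env$model$heal_threshold,
    Mref = m_ref, grid_e = grid$e, grid_d = grid$d,
    reward_mode = if (reward == "tracking") 1L else 0L,
    eta = config$eta, gamma = config$gamma,
    lr_actor = config$lr_actor, lr_critic = config$lr_critic,
    entropy_coef = config$entropy_coef,
    entropy_anneal = config$entropy_anneal,
    episodes = config$episodes, steps = steps, n_step = config$n_step,
    eval_every = config$eval_every, eval_rollouts = config$eval_rollouts,
    burn_in = config$burn_in
  ))

  structure(
    list(
      actor = res$actor, actor_final = res$actor_final, critic = res$critic,
      returns = tibble::tibble(
        episode = seq_len(config$episodes),
        return_mean = as.numeric(res$episode_return),
        seed = config$seed
      ),
      evals = tibble::tibble(
        episode = as.numeric(res$eval_episode),
        eval_healing_days = as.numeric(res$eval_healing_days),
        seed = config$seed
      ),
      grid = grid, config = config, reward = reward,
      ref_matrix = m_ref
    ),
    class = "a2c_agent"
  )
}

#' Healing time achieved by a trained agent's greedy policy
#'
#' Rolls out the greedy (argmax) policy on the environment and returns the
#' interpolated healing time in days (`NA` if the wound does not heal within
#' the horizon).
#'
#' @param agent An `a2c_agent` from [train_agent()].
#' @param env A [wound_env()].
#' @param policy `"polyak"` (the Polyak-averaged actor, default) or
#'   `"final"` (the last training iterate).
#' @param horizon_days Rollout cap in days.
#' @return Healing time in days.
#' @export
evaluate_agent <- function(agent, env, policy = c("polyak", "final"),
                           horizon_days = agent$config$horizon_days) {
  policy <- match.arg(policy)
  actor <- if (policy == "polyak") agent$actor else agent$actor_final
  .a2c_eval_cpp(
    actor,
    kn = as.numeric(env$model$natural), kab = as.numeric(env$act_base),
    dt = env$model$dt, thr = env$model$heal_threshold,
    grid_e = agent$grid$e, grid_d = agent$grid$d,
    max_steps = round(horizon_days / env$model$dt)
  )
}

#' Greedy action of a trained agent at a stage vector
#'
#' @param agent An `a2c_agent`.
#' @param z Stage vector observation.
#' @return One row of the agent's action grid (`action_id`, `e`, `d`).
#' @export
greedy_action <- function(agent, z) {
  pr <- policy_probs(agent$actor, as.numeric(z))
  agent$grid[which.max(pr), ]
}

#' @export
print.a2c_agent <- function(x, ...) {
  cat(sprintf(
    "<a2c_agent> reward = %s, %d episodes (seed %d)\n",
    x$reward, x$config$episodes, x$config$seed
  ))
  if (nrow(x$evals)) {
    cat(sprintf("  last eval healing: %.2f days\n",
                tail(x$evals$eval_healing_days, 1)))
  }
  invisible(x)
}
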