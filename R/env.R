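#' The synthetic nonlinear wound environment
#'
#' Bundles everything the simulated wound needs: the natural rates driving
#' the latent stage dynamics, the base actuated rates the device contributes
#' when it is active, the treatment-effect modulation, and the renderer that
#' produces the observed image. The agent never sees the latent dynamics --
#' the environment plays the role of the unknown nonlinear plant.
#'
#' When the device is active with action `(e, d)`, the actuated rates are
#' modulated by the treatment-effect model ([modulated_rates()]) and add to
#' the natural transition velocities, i.e. the latent state advances under
#' the combined generator `G_nat + G_act(k_hat)` (unit-gain state actuation).
#' With zero base actuated rates and action `(0, 0)` the step is exactly the
#' natural step.
#'
#' @param model A [stage_model()] supplying the natural rates, `dt` and the
#'   healing threshold.
#' @param act_base Base actuated [rate_constants()] of the device channel.
#'   Default `(0.1, 0.1, 0.1)`/day, the amplitude of the sine modulation.
#' @param params [render_params()] for the observation renderer.
#' @return A list of class `wound_env`.
#' @export
wound_env <- function(model = default_stage_model(),
                      act_base = rate_constants(0.1, 0.1, 0.1),
                      params = render_params()) {
  if (!inherits(act_base, "rate_constants")) act_base <- do.call(rate_constants, as.list(act_base))
  if (model$dt * max(model$natural + c(act_base) + 0.1) > 1 + 1e-12) {
    abort("Euler positivity bound violated for natural + modulated actuated rates")
  }
  structure(list(model = model, act_base = act_base, params = params),
            class = "wound_env")
}

#' Step the wound environment under a treatment action
#'
#' Applies the treatment-effect modulation to the actuated base rates at the
#' current maturation level, advances the latent stage vector one Euler step
#' under the combined generator, and renders the next observation.
#'
#' @param env A [wound_env()].
#' @param z Current latent stage vector.
#' @param e,d Treatment action levels.
#' @param render Render the next image (default `TRUE`; latent-only rollouts
#'   can skip rendering for speed).
#' @param seed Seed forwarded to the renderer noise.
#' @return A list with `z` (next stage vector) and `image` (a `wound_image`,
#'   or `NULL` if `render = FALSE`).
#' @examples
#' env <- wound_env(default_stage_model(), act_base = rate_constants(0, 0, 0))
#' out <- env_step(env, stage_vector(1, 0, 0, 0), e = 0, d = 0, render = FALSE)
#' out$z
#' @export
env_step <- function(env, z, e, d, render = TRUE, seed = env$params$seed) {
  if (!inherits(z, "stage_vector")) z <- as_stage_vector(z)
  k_hat <- modulated_rates(env$act_base, e, d, m = z[[4]])
  g_eff <- build_generator(env$model$natural) + build_generator(k_hat)
  z2 <- as.numeric(z) + env$model$dt * as.numeric(g_eff %*% as.numeric(z))
  z2 <- structure(setNames(project_simplex(z2), stage_names), class = "stage_vector")
  img <- if (render) render_wound(z2, env$params, seed = seed) else NULL
  list(z = z2, image = img)
}

#' Simulate the environment under a treatment policy
#'
#' Latent-space rollout of the environment (no rendering) under a policy
#' mapping the stage vector to an action.
#'
#' @param env A [wound_env()].
#' @param policy Function `function(z)` returning `c(e, d)`, or `NULL` for
#'   the no-treatment device action `(0, 0)`.
#' @param z0 Initial stage vector.
#' @param horizon Days to simulate.
#' @return A `stage_trajectory` tibble (see [simulate_stages()]).
#' @export
simulate_env <- function(env, policy = NULL, z0 = stage_vector(1, 0, 0, 0),
                         horizon = 30) {
  n_steps <- round(horizon / env$model$dt)
  out <- matrix(NA_real_, n_steps + 1L, 4L)
  out[1L, ] <- as.numeric(z0)
  z <- z0
  for (s in seq_len(n_steps)) {
    a <- if (is.null(policy)) c(0, 0) else policy(z)
    z <- env_step(env, z, a[1], a[2], render = FALSE)$z
    out[s + 1L, ] <- as.numeric(z)
  }
  res <- tibble::tibble(
    time_days = seq(0, by = env$model$dt, length.out = n_steps + 1L),
    H = out[, 1], I = out[, 2], P = out[, 3], M = out[, 4]
  )
  attr(res, "heal_threshold") <- env$model$heal_threshold
  class(res) <- c("stage_trajectory", class(res))
  res
}
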