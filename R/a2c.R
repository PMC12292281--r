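#' Configuration of the advantage actor-critic agent
#'
#' @param gamma Discount factor in (0, 1\]. Default 0.99.
#' @param eta Tracking-reward scale: `reward = exp(-eta * ||x_ref - x||^2)`.
#'   Default 3000, sized so that per-step squared stage-vector tracking
#'   distances (1e-4 to 1e-3 in the late healing phase) map to a usable
#'   reward spread.
#' @param hidden Hidden layer width of the actor and critic networks (two
#'   hidden layers each). Default 64.
#' @param lr_actor,lr_critic Adam learning rates.
#' @param entropy_coef Entropy-bonus coefficient (0 disables exploration
#'   pressure). Default 0.01.
#' @param entropy_anneal Linearly anneal the entropy coefficient to zero
#'   across training so the policy can commit once exploration has paid off.
#'   Default `TRUE`.
#' @param n_step Length of the rollout window of the n-step advantage
#'   estimator (one batched update per window). Default 24 steps (two
#'   simulated days at the default cadence).
#' @param episodes Training episodes. Default 2000.
#' @param burn_in Episodes discarded before Polyak averaging of the actor
#'   parameters; default half of `episodes`.
#' @param horizon_days Episode length in days (episodes run the full horizon;
#'   see the package vignette for why tracking episodes are not truncated at
#'   healing). Default 30.
#' @param eval_every Evaluate the greedy policy every this many episodes.
#'   Default 50.
#' @param eval_rollouts Rollouts averaged per evaluation. Default 5.
#' @param n_levels,max_level,channels Action grid, see [treatment_grid()].
#' @param observation Observation mode: `"stage"` (the encoded stage vector;
#'   the scaled-down default) or `"image"`.
#' @param seed RNG seed for training.
#' @return A list of class `a2c_config`.
#' @export
a2c_config <- function(gamma = 0.99, eta = 3000, hidden = 64L,
                       lr_actor = 5e-3, lr_critic = 2e-2,
                       entropy_coef = 0.01, entropy_anneal = TRUE,
                       n_step = 24L, episodes = 2000L,
                       burn_in = NULL, horizon_days = 30,
                       eval_every = 50L, eval_rollouts = 5L,
                       n_levels = 6L, max_level = 0.25,
                       channels = "joint",
                       observation = c("stage", "image"), seed = 0L) {
  check_number(gamma, "gamma", lower = 1e-9, upper = 1)
  check_number(eta, "eta", lower = 0)
  observation <- match.arg(observation)
  burn_in <- burn_in %||% (episodes %/% 2L)
  if (burn_in >= episodes) abort("`burn_in` must be smaller than `episodes`")
  structure(
    list(gamma = gamma, eta = eta, hidden = as.integer(hidden),
         lr_actor = lr_actor, lr_critic = lr_critic,
         entropy_coef = entropy_coef, entropy_anneal = isTRUE(entropy_anneal),
         n_step = as.integer(n_step),
         episodes = as.integer(episodes),
         burn_in = as.integer(burn_in), horizon_days = horizon_days,
         eval_every = as.integer(eval_every),
         eval_rollouts = as.integer(eval_rollouts),
         n_levels = as.integer(n_levels), max_level = max_level,
         channels = channels, observation = observation,
         seed = as.integer(seed)),
    class = "a2c_config"
  )
}

#' Reference-tracking reward
#'
#' `exp(-eta * ||x_ref_next - x_next||^2)`: 1 when the realised next
#' observation equals the reference exactly, decaying with the squared
#' Euclidean distance. Works on any pair of equally-shaped numeric arrays
#' (stage vectors or images).
#'
#' @param x_ref_next Reference next observation (the decoded LQR target).
#' @param x_next Realised next observation.
#' @param eta Reward scale, `>= 0`.
#' @return A scalar in (0, 1\].
#' @examples
#' reward_tracking(c(0, 0, 0, 1), c(0, 0, 0.1, 0.9), eta = 10)
#' @export
reward_tracking <- function(x_ref_next, x_next, eta) {
  a <- if (inherits(x_ref_next, "wound_image")) x_ref_next$pixels else unclass(x_ref_next)
  b <- if (inherits(x_next, "wound_image")) x_next$pixels else unclass(x_next)
  if (!identical(dim(a) %||% length(a), dim(b) %||% length(b))) {
    abort("`x_ref_next` and `x_next` must have identical shape")
  }
  check_number(eta, "eta", lower = 0)
  exp(-eta * sum((as.numeric(a) - as.numeric(b))^2))
}

#' Sparse healing reward
#'
#' The baseline reward without the leader-follower strategy: -1 for every
#' step the wound is still unhealed, 0 once maturation has reached the
#' threshold. The episode return is minus the number of unhealed steps.
#'
#' @param m Maturation fraction.
#' @param heal_threshold Healing threshold. Default 0.95.
#' @return -1 or 0.
#' @export
reward_sparse <- function(m, heal_threshold = 0.95) {
  if (m < heal_threshold) -1 else 0
}

#' One-step advantage estimate
#'
#' `A = r + gamma * v_next * (1 - terminal) - v`: the temporal-difference
#' advantage with the critic's bootstrap cut at terminal transitions.
#'
#' @param r Reward.
#' @param v_next Critic value of the next observation.
#' @param v Critic value of the current observation.
#' @param gamma Discount factor.
#' @param terminal Is the transition terminal?
#' @return The scalar advantage.
#' @export
advantage <- function(r, v_next, v, gamma = 0.99, terminal = FALSE) {
  r + gamma * v_next * (1 - as.numeric(terminal)) - v
}

#' Polyak-Ruppert average of parameter snapshots
#'
#' Arithmetic mean of parameter snapshots after a burn-in: given snapshots
#' `omega_1 ... omega_N`, returns the mean of `omega_(n0+1) ... omega_N`.
#'
#' @param snapshots A list of equally-shaped numeric vectors/matrices, or a
#'   numeric vector of scalar snapshots.
#' @param n0 Burn-in count: snapshots `1..n0` are discarded. `n0 = 0` gives
#'   the plain mean.
#' @return The averaged parameters (same shape as one snapshot).
#' @examples
#' polyak_average(c(2, 4), n0 = 0)   # 3
#' @export
polyak_average <- function(snapshots, n0 = 0L) {
  if (is.numeric(snapshots)) snapshots <- as.list(snapshots)
  n <- length(snapshots)
  if (n0 < 0 || n0 >= n) abort("`n0` must satisfy 0 <= n0 < number of snapshots")
  kept <- snapshots[(n0 + 1L):n]
  Reduce(`+`, kept) / length(kept)
}

# ---- minimal MLP machinery (reference implementation; the training loop
# ---- itself runs in compiled code) ----

#' Initialise a small multilayer perceptron
#'
#' Fully-connected network with ReLU hidden activations and a linear output
#' layer, weights drawn from scaled Gaussians (He-style fan-in scaling).
#'
#' @param sizes Integer vector of layer sizes, input first, output last.
#' @param seed RNG seed for the initial weights.
#' @return A list with elements `W` (list of weight matrices, in x out) and
#'   `b` (list of bias vectors).
#' @export
init_mlp <- function(sizes, seed = 0L) {
  with_seed(seed, {
    W <- list(); b <- list()
    for (l in seq_len(length(sizes) - 1L)) {
      W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1L], sd = sqrt(2 / sizes[l])),
                       sizes[l], sizes[l + 1L])
      b[[l]] <- rep(0, sizes[l + 1L])
    }
    list(W = W, b = b)
  })
}

# forward pass returning activations (for backprop)
mlp_forward <- function(net, x) {
  a <- list(matrix(x, nrow = 1))
  n_layers <- length(net$W)
  for (l in seq_len(n_layers)) {
    z <- a[[l]] %*% net$W[[l]] + matrix(net$b[[l]], 1)
    a[[l + 1L]] <- if (l < n_layers) pmax(z, 0) else z
  }
  a
}

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

#' Action probabilities of the actor network
#'
#' @param actor An [init_mlp()] network whose output layer has one logit per
#'   action.
#' @param obs Observation vector.
#' @return A probability vector (softmax of the logits); strictly positive,
#'   summing to 1.
#' @export
policy_probs <- function(actor, obs) {
  logits <- mlp_forward(actor, obs)[[length(actor$W) + 1L]]
  as.numeric(softmax(as.numeric(logits)))
}

#' Critic value of an observation
#'
#' @param critic An [init_mlp()] network with a single output.
#' @param obs Observation vector.
#' @return The scalar state value.
#' @export
state_value <- function(critic, obs) {
  as.numeric(mlp_forward(critic, obs)[[length(critic$W) + 1L]])
}

# backprop of dL/d(output) through the MLP; returns gradient lists
mlp_backward <- function(net, acts, dout) {
  n_layers <- length(net$W)
  gW <- vector("list", n_layers)
  gb <- vector("list", n_layers)
  delta <- matrix(dout, nrow = 1)
  for (l in rev(seq_len(n_layers))) {
    gW[[l]] <- crossprod(acts[[l]], delta)
    gb[[l]] <- as.numeric(delta)
    if (l > 1L) {
      delta <- (delta %*% t(net$W[[l]])) * (acts[[l]] > 0)
    }
  }
  list(W = gW, b = gb)
}

#' One actor-critic update from a batch of transitions
#'
#' Reference implementation of the A2C update: the critic takes a gradient
#' step on the squared Bellman error towards `reward + gamma * v_next`, and the
#' actor ascends the advantage-weighted log-probability gradient (the
#' advantage is treated as a constant in the actor update) plus an entropy
#' bonus. Plain SGD with the configured learning rates.
#'
#' @param agent A list with elements `actor` and `critic` ([init_mlp()]
#'   networks).
#' @param batch A list of transitions, each a list with `obs`, `action`
#'   (1-based index), `reward`, `obs_next`, `terminal`.
#' @param config An [a2c_config()].
#' @return The updated agent, with `diagnostics` (actor loss, critic loss,
#'   mean entropy, mean advantage) attached.
#' @export
update_networks <- function(agent, batch, config = a2c_config()) {
  if (length(batch) == 0L) abort("`batch` must be non-empty")
  n <- length(batch)
  acc_actor <- NULL; acc_critic <- NULL
  actor_loss <- 0; critic_loss <- 0; ent_sum <- 0; adv_sum <- 0
  for (tr in batch) {
    v <- state_value(agent$critic, tr$obs)
    v_next <- if (tr$terminal) 0 else state_value(agent$critic, tr$obs_next)
    adv <- advantage(tr$reward, v_next, v, gamma = config$gamma,
                     terminal = tr$terminal)
    target <- tr$reward + config$gamma * v_next * (1 - as.numeric(tr$terminal))

    # critic: d/dv of (v - target)^2
    c_acts <- mlp_forward(agent$critic, tr$obs)
    g_c <- mlp_backward(agent$critic, c_acts, 2 * (v - target))

    # actor: d/dlogits of -(log pi(a) * adv + entropy_coef * H(pi))
    a_acts <- mlp_forward(agent$actor, tr$obs)
    logits <- as.numeric(a_acts[[length(agent$actor$W) + 1L]])
    pr <- softmax(logits)
    onehot <- rep(0, length(pr)); onehot[tr$action] <- 1
    dlogp <- onehot - pr
    ent <- -sum(pr * log(pr))
    dent <- -pr * (log(pr) + 1) + pr * sum(pr * (log(pr) + 1))
    dlogits <- -(dlogp * adv + config$entropy_coef * dent)
    g_a <- mlp_backward(agent$actor, a_acts, dlogits)

    if (!any(is.finite(unlist(g_a$b))) || !any(is.finite(unlist(g_c$b)))) {
      abort("non-finite gradients in update_networks")
    }
    acc_actor <- if (is.null(acc_actor)) g_a else
      list(W = purrr::map2(acc_actor$W, g_a$W, `+`),
           b = purrr::map2(acc_actor$b, g_a$b, `+`))
    acc_critic <- if (is.null(acc_critic)) g_c else
      list(W = purrr::map2(acc_critic$W, g_c$W, `+`),
           b = purrr::map2(acc_critic$b, g_c$b, `+`))
    actor_loss <- actor_loss - log(pr[tr$action]) * adv
    critic_loss <- critic_loss + (v - target)^2
    ent_sum <- ent_sum + ent
    adv_sum <- adv_sum + adv
  }
  for (l in seq_along(agent$actor$W)) {
    agent$actor$W[[l]] <- agent$actor$W[[l]] - config$lr_actor * acc_actor$W[[l]] / n
    agent$actor$b[[l]] <- agent$actor$b[[l]] - config$lr_actor * acc_actor$b[[l]] / n
  }
  for (l in seq_along(agent$critic$W)) {
    agent$critic$W[[l]] <- agent$critic$W[[l]] - config$lr_critic * acc_critic$W[[l]] / n
    agent$critic$b[[l]] <- agent$critic$b[[l]] - config$lr_critic * acc_critic$b[[l]] / n
  }
  agent$diagnostics <- list(
    actor_loss = actor_loss / n, critic_loss = critic_loss / n,
    entropy = ent_sum / n, advantage = adv_sum / n
  )
  agent
}
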