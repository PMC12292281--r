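#' Treatment-modality switch rule
#'
#' Decides which treatment channel is active: electric-field (EF) therapy is
#' applied first; once the inflammation fraction has reached the switch
#' threshold (default 40%) and its smoothed trajectory has started to
#' decrease, control latches to fluoxetine (Flx) delivery for the rest of
#' the episode.
#'
#' "Started to decrease" is judged on a centred moving average of the
#' inflammation history (window `smooth`, default 3 points) to avoid
#' switching on single-frame noise.
#'
#' @param stage_history A data frame with an `I` column (one row per
#'   observation, temporal order) or a numeric vector of inflammation
#'   fractions.
#' @param threshold Inflammation fraction that arms the switch. Default 0.4.
#' @param smooth Moving-average window (points). Default 3.
#' @return `"EF"` or `"Flx"` (the modality for the present time), with the
#'   1-based index of the first Flx step in `attr(, "switch_index")` (NA if
#'   never switched).
#' @examples
#' switch_rule(c(0.2, 0.45, 0.42, 0.38))
#' @export
switch_rule <- function(stage_history, threshold = 0.4, smooth = 3L) {
  i_path <- if (is.data.frame(stage_history)) stage_history$I else as.numeric(stage_history)
  if (length(i_path) == 0L) abort("`stage_history` is empty")
  path <- modality_path(i_path, threshold, smooth)
  out <- path[length(path)]
  attr(out, "switch_index") <- if (any(path == "Flx")) which(path == "Flx")[1] else NA_integer_
  out
}

# full EF/Flx sequence for an inflammation path; latches at the first
# smoothed decrease after the threshold has been reached
modality_path <- function(i_path, threshold = 0.4, smooth = 3L) {
  n <- length(i_path)
  sm <- numeric(n)
  half <- (smooth - 1L) %/% 2L
  for (t in seq_len(n)) {
    lo <- max(1L, t - half)
    hi <- min(n, t + half)
    sm[t] <- mean(i_path[lo:hi])
  }
  out <- rep("EF", n)
  armed <- FALSE
  for (t in seq_len(n)) {
    if (sm[t] >= threshold) armed <- TRUE
    if (armed && t > 1L && sm[t] < sm[t - 1L]) {
      out[t:n] <- "Flx"
      break
    }
  }
  out
}

#' Iontophoretic dose parameters
#'
#' Constants of the electrochemical pump: delivered drug mass per unit
#' charge is `pump_efficiency * mol_weight / faraday` grams per coulomb.
#'
#' @param pump_efficiency Pump efficiency (fraction). Default 0.022 (2.2%).
#' @param faraday Faraday constant in C/mol. Default 96485.3321.
#' @param mol_weight Molecular weight of the drug in g/mol. Default 309.33
#'   (fluoxetine).
#' @return A list of class `dose_params`.
#' @export
dose_params <- function(pump_efficiency = 0.022, faraday = 96485.3321,
                        mol_weight = 309.33) {
  check_number(pump_efficiency, "pump_efficiency", lower = 1e-12)
  check_number(faraday, "faraday", lower = 1e-12)
  check_number(mol_weight, "mol_weight", lower = 1e-12)
  structure(list(pump_efficiency = pump_efficiency, faraday = faraday,
                 mol_weight = mol_weight), class = "dose_params")
}

#' Cumulative drug dose from a delivery-current series
#'
#' Trapezoidal integration of
#' `dose(t) = integral eta * (g / F) * i(t) dt`: with the current in mA and
#' time in seconds the result is in mg (the milli prefix carries through
#' linearly). Dose is non-decreasing in time and linear in the current.
#'
#' @param current_mA Non-negative current samples in mA.
#' @param dt_s Sampling interval in seconds (scalar).
#' @param params [dose_params()].
#' @return A tibble with columns `time_s`, `current_mA`, `dose_mg`
#'   (cumulative; first row at time 0).
#' @examples
#' dose_from_current(rep(1, 61), dt_s = 60)   # 1 mA for an hour
#' @export
dose_from_current <- function(current_mA, dt_s, params = dose_params()) {
  if (any(current_mA < 0)) abort("currents must be non-negative")
  check_number(dt_s, "dt_s", lower = 1e-12)
  rate <- params$pump_efficiency * params$mol_weight / params$faraday  # mg per mA*s
  n <- length(current_mA)
  dose <- numeric(n)
  if (n > 1L) {
    inc <- (current_mA[-n] + current_mA[-1]) / 2 * dt_s * rate
    dose <- c(0, cumsum(inc))
  }
  tibble::tibble(
    time_s = (seq_len(n) - 1) * dt_s,
    current_mA = current_mA,
    dose_mg = dose
  )
}

#' Run the full closed control loop on the simulated wound
#'
#' One episode of the sense-map-reference-act loop: at each step the current
#' wound image is encoded to a stage vector (via the mapper, or read
#' directly from the simulator when no mapper is supplied), the LQR
#' reference next state is computed, the switch rule picks the active
#' modality, the active agent's greedy policy selects the treatment level
#' (EF phase: `e` channel, Flx phase: `d` channel), the environment steps,
#' and the tracking reward plus the delivered dose are logged.
#'
#' @param env A [wound_env()].
#' @param agent A trained [train_agent()] agent (its greedy policy is used;
#'   the inactive channel of its action is forced to zero by the switch
#'   rule).
#' @param mapper Optional trained `deep_mapper`; when supplied, each step
#'   renders the wound image and encodes it (sense through pixels), and the
#'   renderer's noise is active. Without a mapper the latent state is
#'   observed directly.
#' @param config List of loop options: `horizon_days` (default 30),
#'   `switch_threshold` (0.4), `smooth` (3), `i_max_mA` (1, current at the
#'   maximum action level), `eta` (tracking-reward scale, default the
#'   agent's), `dose` ([dose_params()]).
#' @param seed Seed for the rendering noise.
#' @return An `episode_log` tibble: `time_days, H, I, P, M, H_ref, I_ref,
#'   P_ref, M_ref, modality, action_level, current_mA, reward, dose_mg`.
#' @export
run_closed_loop <- function(env, agent, mapper = NULL, config = list(),
                            seed = 0L) {
  horizon <- config$horizon_days %||% 30
  thr_sw <- config$switch_threshold %||% 0.4
  smooth <- config$smooth %||% 3L
  i_max <- config$i_max_mA %||% 1
  eta <- config$eta %||% agent$config$eta
  dp <- config$dose %||% dose_params()
  model <- env$model
  if (is.null(model$K)) model <- solve_lqr(model)

  dt_s <- model$dt * 86400
  rate_mg <- dp$pump_efficiency * dp$mol_weight / dp$faraday
  n_steps <- round(horizon / model$dt)

  z <- config$z0 %||% stage_vector(1, 0, 0, 0)
  if (!inherits(z, "stage_vector")) z <- as_stage_vector(z)
  obs <- if (is.null(mapper)) z else {
    encode_stages(mapper, render_wound(z, env$params, seed = seed))
  }
  if (z[[4]] >= model$heal_threshold) {
    # already healed: a single observation row, no treatment applied
    log <- tibble::tibble(
      time_days = 0, H = z[[1]], I = z[[2]], P = z[[3]], M = z[[4]],
      H_ref = z[[1]], I_ref = z[[2]], P_ref = z[[3]], M_ref = z[[4]],
      modality = "EF", action_level = NA_real_, current_mA = 0,
      reward = NA_real_, dose_mg = 0
    )
    attr(log, "healed") <- TRUE
    attr(log, "healing_days") <- 0
    class(log) <- c("episode_log", class(log))
    return(log)
  }
  i_hist <- obs[[2]]
  rows <- vector("list", n_steps)
  dose <- 0
  healed <- FALSE
  for (s in seq_len(n_steps)) {
    zref <- reference_next(obs, model)
    modality <- tail(modality_path(i_hist, thr_sw, smooth), 1)
    act <- greedy_action(agent, as.numeric(obs))
    level <- if (modality == "EF") act$e else act$d
    e <- if (modality == "EF") act$e else 0
    d <- if (modality == "EF") 0 else act$d
    step <- env_step(env, z, e, d, render = !is.null(mapper), seed = seed + s)
    z2 <- step$z
    obs2 <- if (is.null(mapper)) z2 else encode_stages(mapper, step$image)
    reward <- reward_tracking(as.numeric(zref), as.numeric(obs2), eta)
    current <- level / agent$config$max_level * i_max
    dose <- dose + current * dt_s * rate_mg
    rows[[s]] <- tibble::tibble(
      time_days = s * model$dt,
      H = z2[[1]], I = z2[[2]], P = z2[[3]], M = z2[[4]],
      H_ref = zref[[1]], I_ref = zref[[2]], P_ref = zref[[3]], M_ref = zref[[4]],
      modality = modality, action_level = level, current_mA = current,
      reward = reward, dose_mg = dose
    )
    z <- z2
    obs <- obs2
    i_hist <- c(i_hist, obs[[2]])
    if (z2[[4]] >= model$heal_threshold) {
      healed <- TRUE
      break
    }
  }
  log <- dplyr::bind_rows(rows)
  attr(log, "healed") <- healed
  attr(log, "healing_days") <- if (healed) log$time_days[nrow(log)] else NA_real_
  class(log) <- c("episode_log", class(log))
  log
}
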