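#' Advance the stage vector by one Euler step
#'
#' Forward-Euler step of the linear stage dynamics,
#' `z' = z + dt * (G_nat %*% z + G_act %*% nu)`. With `nu = 0` the step
#' conserves the simplex exactly. A control that pushes a component negative
#' is handled by clipping to zero and renormalising (counted in
#' `getOption("woundloop.simplex_clips")`).
#'
#' @param z Stage vector (see [stage_vector()]) or numeric length 4.
#' @param nu Control 4-vector entering through the actuated generator.
#' @param model A [stage_model()].
#' @return The next stage vector (named numeric, class `stage_vector`).
#' @examples
#' m <- stage_model(rate_constants(0.5, 0.3, 0.2))
#' step_stage(stage_vector(1, 0, 0, 0), model = m)
#' @export
step_stage <- function(z, nu = rep(0, 4), model) {
  if (!inherits(z, "stage_vector")) z <- as_stage_vector(z)
  g_nat <- build_generator(model$natural)
  g_act <- build_generator(model$actuated)
  z2 <- as.numeric(z) + model$dt * as.numeric(g_nat %*% as.numeric(z) + g_act %*% nu)
  structure(setNames(project_simplex(z2), stage_names), class = "stage_vector")
}

#' Simulate a stage trajectory
#'
#' Iterates [step_stage()] from `z0` for `horizon` days and returns the
#' trajectory as a tibble, one row per time point.
#'
#' @param model A [stage_model()].
#' @param z0 Initial stage vector; defaults to the fresh wound `c(1,0,0,0)`.
#' @param policy Control schedule: `NULL` for no control, the string `"lqr"`
#'   for the closed-loop optimal feedback `nu = -K %*% z` (requires a solved
#'   gain, see [solve_lqr()]), or a function `function(z, t)` returning a
#'   control 4-vector.
#' @param horizon Length of the simulation in days.
#' @return A tibble of class `stage_trajectory` with columns
#'   `time_days, H, I, P, M`.
#' @examples
#' m <- default_stage_model()
#' traj <- simulate_stages(m, horizon = 15)
#' healing_time(traj)
#' @export
simulate_stages <- function(model, z0 = stage_vector(1, 0, 0, 0),
                            policy = NULL, horizon = 30) {
  if (horizon < 0) abort("`horizon` must be non-negative")
  if (!inherits(z0, "stage_vector")) z0 <- as_stage_vector(z0)
  n_steps <- round(horizon / model$dt)
  out <- matrix(NA_real_, nrow = n_steps + 1L, ncol = 4L)
  out[1L, ] <- as.numeric(z0)
  use_lqr <- identical(policy, "lqr")
  if (use_lqr && is.null(model$K)) {
    abort("policy = \"lqr\" needs a solved gain; call solve_lqr() first")
  }
  g_nat <- build_generator(model$natural)
  g_act <- build_generator(model$actuated)
  z <- as.numeric(z0)
  t <- 0
  if (n_steps > 0) {
    for (s in seq_len(n_steps)) {
      nu <-
        if (is.null(policy)) NULL
        else if (use_lqr) as.numeric(-model$K %*% z)
        else policy(as_stage_vector(z), t)
      dz <- g_nat %*% z
      if (!is.null(nu)) dz <- dz + g_act %*% nu
      z <- z + model$dt * as.numeric(dz)
      if (any(z < 0)) z <- project_simplex(z) else z <- z / sum(z)
      t <- t + model$dt
      out[s + 1L, ] <- z
    }
  }
  res <- tibble::tibble(
    time_days = seq(0, by = model$dt, length.out = n_steps + 1L),
    H = out[, 1], I = out[, 2], P = out[, 3], M = out[, 4]
  )
  attr(res, "heal_threshold") <- model$heal_threshold
  class(res) <- c("stage_trajectory", class(res))
  res
}

#' Healing time of a stage trajectory
#'
#' The first time at which the maturation fraction reaches the healing
#' threshold, linearly interpolated between trajectory points. Returns
#' `NA_real_` if the threshold is never reached ("not healed").
#'
#' @param trajectory A `stage_trajectory` tibble (or any data frame with
#'   `time_days` and `M` columns).
#' @param heal_threshold Maturation threshold; defaults to the threshold
#'   stored on the trajectory, else 0.95.
#' @return Healing time in days, or `NA_real_`.
#' @export
healing_time <- function(trajectory, heal_threshold = NULL) {
  if (nrow(trajectory) == 0L) abort("`trajectory` is empty")
  thr <- heal_threshold %||% attr(trajectory, "heal_threshold") %||% 0.95
  first_crossing(trajectory$time_days, trajectory$M, thr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Calibrate natural rates to a target untreated healing time
#'
#' Scales the base rates by a single positive factor `s`, found by bisection,
#' so that the untreated trajectory from the fresh wound heals in
#' `target_days` days (within `tol`). Healing time is strictly decreasing in
#' `s`, so the bisection is well posed whenever the bracket straddles the
#' target.
#'
#' @param base Base [rate_constants()], scaled jointly.
#' @param target_days Target untreated healing time in days.
#' @param heal_threshold Maturation threshold defining "healed".
#' @param dt Integration step in days.
#' @param bracket Multiplicative search bracket for the scale factor.
#' @param tol Tolerance on the achieved healing time, in days.
#' @param max_iter Bisection iteration cap.
#' @return Calibrated `rate_constants`, with the scale factor in
#'   `attr(, "scale")`.
#' @examples
#' calibrate_natural_rates(rate_constants(0.9, 0.6, 0.4), target_days = 10.33)
#' @export
calibrate_natural_rates <- function(base, target_days,
                                    heal_threshold = 0.95, dt = 1 / 12,
                                    bracket = c(0.1, 10), tol = 0.01,
                                    max_iter = 60L) {
  if (!inherits(base, "rate_constants")) base <- do.call(rate_constants, as.list(base))
  check_number(target_days, "target_days", lower = 0)
  # unscaled healing time sizes the horizon: healing scales like 1/s
  ht1 <- local({
    m1 <- stage_model(natural = base, dt = dt, heal_threshold = heal_threshold)
    horizon <- 30
    repeat {
      ht <- healing_time(simulate_stages(m1, horizon = horizon))
      if (!is.na(ht) || horizon > 5000) break
      horizon <- horizon * 4
    }
    ht
  })
  if (is.na(ht1)) abort("base rates do not heal within 5000 days; cannot calibrate")
  ht_of <- function(s) {
    m <- stage_model(
      natural = rate_constants(base[[1]] * s, base[[2]] * s, base[[3]] * s),
      dt = dt, heal_threshold = heal_threshold
    )
    healing_time(simulate_stages(m, horizon = ceiling(3 * ht1 / s) + 5))
  }
  lo <- bracket[1]; hi <- bracket[2]
  f_lo <- ht_of(lo); f_hi <- ht_of(hi)
  if (is.na(f_lo) || is.na(f_hi) || (f_lo - target_days) * (f_hi - target_days) > 0) {
    abort(sprintf(
      "target %.2f days not bracketed: healing(s=%.2f) = %.2f, healing(s=%.2f) = %.2f",
      target_days, lo, f_lo, hi, f_hi
    ))
  }
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    f_mid <- ht_of(mid)
    if (!is.na(f_mid) && abs(f_mid - target_days) < tol / 4) break
    # healing time decreases with the scale factor
    if (is.na(f_mid) || f_mid > target_days) lo <- mid else hi <- mid
  }
  out <- rate_constants(base[[1]] * mid, base[[2]] * mid, base[[3]] * mid)
  attr(out, "scale") <- mid
  achieved <- ht_of(mid)
  if (is.na(achieved) || abs(achieved - target_days) > tol) {
    abort(sprintf("calibration missed target: achieved %.4f vs %.4f days", achieved, target_days))
  }
  attr(out, "achieved_days") <- achieved
  out
}
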