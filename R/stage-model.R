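#' Construct a wound-stage vector
#'
#' A stage vector is a point on the 4-simplex giving the fractions of the four
#' canonical wound-healing stages: hemostasis (H), inflammation (I),
#' proliferation (P) and maturation (M). A fresh wound is `c(1, 0, 0, 0)`; a
#' fully healed wound is the equilibrium `c(0, 0, 0, 1)`.
#'
#' @param h,i,p,m Stage fractions, each in \[0, 1\], summing to 1.
#' @return A named numeric vector of length 4 with class `stage_vector`.
#' @examples
#' stage_vector(1, 0, 0, 0)      # fresh wound
#' stage_vector(0, 0, 0, 1)      # healed equilibrium
#' @export
stage_vector <- function(h, i, p, m) {
  z <- c(h, i, p, m)
  if (any(z < -1e-12)) abort("stage fractions must be non-negative")
  if (abs(sum(z) - 1) > 1e-9) {
    abort(sprintf("stage fractions must sum to 1 (got %.12f)", sum(z)))
  }
  structure(setNames(pmax(z, 0), stage_names), class = "stage_vector")
}

#' @rdname stage_vector
#' @param x A numeric vector of length 4 (H, I, P, M order).
#' @export
as_stage_vector <- function(x) {
  if (length(x) != 4L) abort("a stage vector has exactly 4 components")
  stage_vector(x[[1]], x[[2]], x[[3]], x[[4]])
}

#' Construct stage-transition rate constants
#'
#' Rates (per day) of the sequential transitions H -> I (`k_h`), I -> P
#' (`k_i`) and P -> M (`k_p`). Rates are the velocities of the compartmental
#' chain; all must be non-negative.
#'
#' @param k_h,k_i,k_p Transition rates in per-day units, each `>= 0`.
#' @return A named numeric vector of length 3 with class `rate_constants`.
#' @examples
#' rate_constants(0.9, 0.6, 0.4)
#' @export
rate_constants <- function(k_h, k_i, k_p) {
  k <- c(k_h = k_h, k_i = k_i, k_p = k_p)
  if (any(!is.finite(k))) abort("rates must be finite")
  if (any(k < 0)) abort("rates must be non-negative")
  structure(k, class = "rate_constants")
}

#' Build the compartmental generator matrix of the stage chain
#'
#' The generator of the linear stage dynamics is a lower-bidiagonal 4x4 matrix
#' moving mass along H -> I -> P -> M at the given rates. Every column sums to
#' zero, so the dynamics conserve total stage mass.
#'
#' @param rates A [rate_constants()] object (or numeric length-3 vector).
#' @return A 4x4 matrix with zero column sums.
#' @examples
#' build_generator(rate_constants(0.3, 0.2, 0.1))
#' @export
build_generator <- function(rates) {
  if (!inherits(rates, "rate_constants")) rates <- rate_constants(rates[[1]], rates[[2]], rates[[3]])
  g <- matrix(0, 4, 4, dimnames = list(stage_names, stage_names))
  g[1, 1] <- -rates[[1]]
  g[2, 1] <- rates[[1]]
  g[2, 2] <- -rates[[2]]
  g[3, 2] <- rates[[2]]
  g[3, 3] <- -rates[[3]]
  g[4, 3] <- rates[[3]]
  g
}

#' Construct a linear 4-stage healing model
#'
#' Bundles the natural and actuated rate constants with the integration time
#' step, the LQR cost matrices and the healing threshold. The discrete
#' dynamics advance by forward Euler on the generators:
#' `z' = z + dt * (G_nat %*% z + G_act %*% nu)`, where `nu` is the control.
#'
#' The default cost matrices are `Q = diag(c(1, 1, 1, 0))` (no penalty on the
#' healed maturation component) and `R = diag(4)`.
#'
#' @param natural,actuated [rate_constants()] for the natural dynamics and the
#'   actuation channel.
#' @param dt Integration step in days. Default `1/12` day (a 2-hour cadence).
#'   Must satisfy the Euler positivity bound `dt * max(rates) <= 1` for the
#'   combined natural + actuated rates.
#' @param lqr_dt Discretisation step (days) used when solving the LQR gain.
#'   Defaults to 1 day, the cadence at which the latent daily dynamics are
#'   identified from once-daily images.
#' @param Q,R State- and input-cost matrices of the quadratic objective.
#' @param heal_threshold Maturation fraction at which the wound counts as
#'   healed. Default 0.95.
#' @return An object of class `stage_model`. The LQR gain `K` is `NULL` until
#'   [solve_lqr()] is called.
#' @seealso [default_stage_model()], [solve_lqr()], [simulate_stages()]
#' @export
stage_model <- function(natural,
                        actuated = rate_constants(0, 0, 0),
                        dt = 1 / 12,
                        lqr_dt = 1,
                        Q = diag(c(1, 1, 1, 0)),
                        R = diag(4),
                        heal_threshold = 0.95) {
  if (!inherits(natural, "rate_constants")) natural <- do.call(rate_constants, as.list(natural))
  if (!inherits(actuated, "rate_constants")) actuated <- do.call(rate_constants, as.list(actuated))
  check_number(dt, "dt", lower = 1e-9)
  check_number(lqr_dt, "lqr_dt", lower = 1e-9)
  check_number(heal_threshold, "heal_threshold", lower = 1e-9, upper = 1 - 1e-9)
  combined <- max(natural + actuated, natural, actuated)
  if (dt * combined > 1 + 1e-12) {
    abort(sprintf(
      "Euler positivity bound violated: dt * max combined rate = %.3f > 1",
      dt * combined
    ))
  }
  stopifnot(identical(dim(Q), c(4L, 4L)), identical(dim(R), c(4L, 4L)))
  structure(
    list(
      natural = natural, actuated = actuated,
      dt = dt, lqr_dt = lqr_dt, Q = Q, R = R,
      heal_threshold = heal_threshold, K = NULL
    ),
    class = "stage_model"
  )
}

#' @export
print.stage_model <- function(x, ...) {
  cat("<stage_model>\n")
  cat(sprintf("  natural rates  : %.4f %.4f %.4f (per day)\n",
              x$natural[1], x$natural[2], x$natural[3]))
  cat(sprintf("  actuated rates : %.4f %.4f %.4f (per day)\n",
              x$actuated[1], x$actuated[2], x$actuated[3]))
  cat(sprintf("  dt = %.4f d, lqr_dt = %.2f d, heal threshold = %.2f\n",
              x$dt, x$lqr_dt, x$heal_threshold))
  cat(if (is.null(x$K)) "  LQR gain: not solved\n" else "  LQR gain: solved\n")
  invisible(x)
}

# cache for the calibrated default model (computed once per session)
.woundloop_cache <- new.env(parent = emptyenv())

#' The default calibrated stage model
#'
#' Returns the package's reference parameterisation: base natural rates
#' (0.9, 0.6, 0.4)/day scaled by a single bisection-calibrated factor so that
#' the untreated wound (from `z0 = c(1,0,0,0)`, threshold 0.95, dt = 1/12 day)
#' heals in exactly `target_days` days. The actuated rates of the model --
#' used to build the LQR reference, never applied to the simulated wound --
#' default to the calibrated natural rates, giving the reference controller
#' authority comparable to the natural transition velocities.
#'
#' @param target_days Untreated healing time the calibration pins, in days.
#' @param solve Solve the LQR gain as part of construction (default `TRUE`).
#' @return A `stage_model` with calibrated rates (and gain `K` if `solve`).
#' @examples
#' m <- default_stage_model()
#' healing_time(simulate_stages(m, horizon = 30))
#' @export
default_stage_model <- function(target_days = 10.33, solve = TRUE) {
  key <- sprintf("default_%.6f_%d", target_days, solve)
  if (!is.null(.woundloop_cache[[key]])) return(.woundloop_cache[[key]])
  base <- rate_constants(0.9, 0.6, 0.4)
  nat <- calibrate_natural_rates(base, target_days = target_days)
  model <- stage_model(natural = nat, actuated = nat)
  if (solve) model <- solve_lqr(model)
  .woundloop_cache[[key]] <- model
  model
}
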