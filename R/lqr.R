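#' Solve a discrete algebraic Riccati equation
#'
#' Fixed-point iteration of the DARE
#' `P = Q + A'PA - A'PB (R + B'PB)^{-1} B'PA`, returning the stabilising
#' solution and the optimal feedback gain `K = (R + B'PB)^{-1} B'PA`.
#'
#' @param A,B State and input matrices of the discrete pair.
#' @param Q,R State- and input-cost matrices (`Q >= 0`, `R > 0`).
#' @param tol Convergence tolerance on the iterates (max abs difference).
#' @param max_iter Iteration cap.
#' @return A list with elements `P`, `K`, `residual` (Frobenius norm of the
#'   DARE residual) and `spectral_radius` (of the closed loop `A - B K`).
#' @examples
#' # scalar chain: closed-form root of r k^2 + (r + q a^2 ... ) available
#' solve_dare(matrix(0.9), matrix(1), matrix(1), matrix(1))
#' @export
solve_dare <- function(A, B, Q, R, tol = 1e-13, max_iter = 100000L) {
  P <- Q
  for (it in seq_len(max_iter)) {
    BtP <- crossprod(B, P)
    G <- solve(R + BtP %*% B, BtP %*% A)
    Pn <- Q + crossprod(A, P %*% A) - crossprod(A, P %*% B) %*% G
    Pn <- (Pn + t(Pn)) / 2
    if (max(abs(Pn - P)) < tol) {
      P <- Pn
      break
    }
    P <- Pn
    if (it == max_iter) abort("DARE iteration did not converge")
  }
  BtP <- crossprod(B, P)
  K <- solve(R + BtP %*% B, BtP %*% A)
  resid <- Q + crossprod(A, P %*% A) - crossprod(A, P %*% B) %*% K - P
  cl <- A - B %*% K
  list(
    P = P, K = K,
    residual = norm(resid, "F"),
    spectral_radius = max(Mod(eigen(cl, only.values = TRUE)$values))
  )
}

#' Solve the LQR gain of a stage model
#'
#' Computes the optimal state feedback `nu* = -K %*% z` for the quadratic cost
#' `sum(z'Qz + nu'Rnu)` on the Euler-discretised pair at the model's design
#' cadence `lqr_dt`.
#'
#' Mass conservation makes the full 4x4 pair structurally marginally stable:
#' the columns of the discrete `A` sum to one and those of `B` to zero, so the
#' healed equilibrium always carries a unit eigenvalue. Since the printed cost
#' `Q = diag(c(1,1,1,0))` does not penalise maturation, the regulator is
#' solved on the transient `(h, i, p)` subsystem (where `m = 1 - h - i - p`),
#' which is stabilisable; the resulting 3x3 gain is embedded as a 4x4 gain
#' with a zero column for `m`. The stability and residual contracts are
#' checked on the reduced closed loop.
#'
#' @param model A [stage_model()]. Its `actuated` rates define the control
#'   authority `B`.
#' @return The model with gain `K` (4x4) attached, plus attributes
#'   `dare_residual` and `closed_loop_radius` (both for the reduced system).
#' @examples
#' m <- solve_lqr(default_stage_model(solve = FALSE))
#' attr(m, "closed_loop_radius") < 1
#' @export
solve_lqr <- function(model) {
  g_nat <- build_generator(model$natural)
  g_act <- build_generator(model$actuated)
  if (all(g_act == 0) && any(diag(model$Q) != 0)) {
    abort("actuated rates are all zero: the pair is uncontrollable")
  }
  A3 <- (diag(4) + model$lqr_dt * g_nat)[1:3, 1:3]
  B3 <- (model$lqr_dt * g_act)[1:3, 1:3]
  Q3 <- model$Q[1:3, 1:3]
  R3 <- model$R[1:3, 1:3]
  sol <- tryCatch(
    solve_dare(A3, B3, Q3, R3),
    error = function(e) {
      abort(sprintf(
        "LQR solve failed (%s); A3 = [%s], B3 = [%s]",
        conditionMessage(e),
        paste(signif(A3, 4), collapse = " "),
        paste(signif(B3, 4), collapse = " ")
      ))
    }
  )
  K <- matrix(0, 4, 4)
  K[1:3, 1:3] <- sol$K
  model$K <- K
  attr(model, "dare_P") <- sol$P
  attr(model, "dare_residual") <- sol$residual
  attr(model, "closed_loop_radius") <- sol$spectral_radius
  model
}

#' One step of the LQR-closed-loop reference trajectory
#'
#' Advances the latent state under the optimal feedback `nu* = -K %*% z`,
#' i.e. `z* = z + dt * (G_nat - G_act K) %*% z`, projected back to the
#' simplex. This is the "leader" state the tracking agent is rewarded for
#' steering the wound towards.
#'
#' @param z Current stage vector.
#' @param model A [stage_model()] with solved gain.
#' @return The reference next stage vector.
#' @export
reference_next <- function(z, model) {
  if (is.null(model$K)) abort("model has no LQR gain; call solve_lqr() first")
  if (!inherits(z, "stage_vector")) z <- as_stage_vector(z)
  nu <- as.numeric(-model$K %*% as.numeric(z))
  step_stage(z, nu, model)
}

#' Quadratic regulation cost of a constant-gain policy
#'
#' Accumulates `sum(z'Qz + nu'Rnu)` over `steps` Euler steps under the
#' feedback `nu = -K %*% z` (with simplex projection, matching the simulated
#' dynamics). Used to spot-check LQR optimality against random gains.
#'
#' @param model A [stage_model()].
#' @param K Feedback gain (4x4 matrix).
#' @param z0 Initial state.
#' @param steps Number of steps to accumulate.
#' @return The accumulated cost (scalar).
#' @export
lqr_cost <- function(model, K, z0 = stage_vector(1, 0, 0, 0), steps = 200L) {
  z <- as.numeric(z0)
  cost <- 0
  for (s in seq_len(steps)) {
    nu <- as.numeric(-K %*% z)
    cost <- cost + sum(z * (model$Q %*% z)) + sum(nu * (model$R %*% nu))
    z <- as.numeric(step_stage(z, nu, model))
  }
  cost
}
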