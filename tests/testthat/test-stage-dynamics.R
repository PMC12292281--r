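# The linear 4-stage model: generators, Euler stepping, healing-time
# computation, calibration and the LQR reference controller.

test_that("generator matrices have the sequential-chain structure", {
  expect_equal(build_generator(rate_constants(0, 0, 0)), matrix(0, 4, 4),
               ignore_attr = TRUE)

  # direct element-by-element placement oracle
  g <- build_generator(rate_constants(0.3, 0.2, 0.1))
  expected <- matrix(0, 4, 4)
  expected[1, 1] <- -0.3; expected[2, 1] <- 0.3
  expected[2, 2] <- -0.2; expected[3, 2] <- 0.2
  expected[3, 3] <- -0.1; expected[4, 3] <- 0.1
  expect_equal(unname(g), expected)

  # mass conservation: every column sums to zero, for arbitrary rates
  set.seed(11)
  for (i in 1:20) {
    g <- build_generator(rate_constants(runif(1, 0, 2), runif(1, 0, 2),
                                        runif(1, 0, 2)))
    expect_equal(colSums(g), rep(0, 4), ignore_attr = TRUE)
  }

  expect_error(rate_constants(-0.1, 0, 0), "non-negative")
})

test_that("the Euler step conserves the simplex and fixes the equilibrium", {
  m <- tiny_model()
  ze <- stage_vector(0, 0, 0, 1)
  expect_equal(as.numeric(step_stage(ze, model = m)), c(0, 0, 0, 1))

  # zero rates: the step is the identity
  m0 <- stage_model(rate_constants(0, 0, 0))
  z <- random_stage_vector()
  expect_equal(as.numeric(step_stage(z, model = m0)), as.numeric(z))

  # one-step hand computation: z = e1, k_h = 0.5, dt = 1
  m1 <- stage_model(rate_constants(0.5, 0.3, 0.2), dt = 1)
  expect_equal(as.numeric(step_stage(stage_vector(1, 0, 0, 0), model = m1)),
               c(0.5, 0.5, 0, 0))

  # conservation along random uncontrolled steps
  set.seed(7)
  for (i in 1:50) {
    z <- random_stage_vector()
    z2 <- step_stage(z, model = tiny_model())
    expect_lt(abs(sum(z2) - 1), 1e-12)
    expect_true(all(z2 >= 0))
  }

  # positivity bound is enforced at model construction
  expect_error(stage_model(rate_constants(2, 0.1, 0.1), dt = 1), "positivity")
})

test_that("uncontrolled trajectories are conservative with monotone maturation", {
  m <- tiny_model()
  traj0 <- simulate_stages(m, horizon = 0)
  expect_equal(nrow(traj0), 1L)

  traj <- simulate_stages(m, horizon = 10)
  expect_equal(nrow(traj), round(10 / m$dt) + 1L)
  expect_true(all(abs(rowSums(traj[, c("H", "I", "P", "M")]) - 1) < 1e-12))

  set.seed(21)
  for (i in 1:10) {
    mm <- stage_model(rate_constants(runif(1, 0, 1), runif(1, 0, 1),
                                     runif(1, 0, 1)))
    tr <- simulate_stages(mm, horizon = 8)
    expect_true(all(diff(tr$M) >= -1e-13))
  }
})

test_that("healing time interpolates the threshold crossing", {
  # hand-built trajectory: M crosses 0.95 between t = 2 and t = 3 at
  # 2 + (0.95 - 0.9) / (0.98 - 0.9) = 2.625
  tr <- tibble::tibble(time_days = 0:3, M = c(0, 0.5, 0.9, 0.98))
  expect_equal(healing_time(tr, 0.95), 2.625)

  # already healed at the start
  tr0 <- tibble::tibble(time_days = 0:1, M = c(0.97, 0.99))
  expect_equal(healing_time(tr0, 0.95), 0)

  # never healed
  trn <- tibble::tibble(time_days = 0:1, M = c(0.1, 0.2))
  expect_true(is.na(healing_time(trn, 0.95)))

  # doubling all natural rates strictly shortens healing
  set.seed(5)
  for (i in 1:20) {
    k <- runif(3, 0.2, 0.9)
    m1 <- stage_model(rate_constants(k[1], k[2], k[3]))
    m2 <- stage_model(rate_constants(2 * k[1], 2 * k[2], 2 * k[3]))
    h1 <- healing_time(simulate_stages(m1, horizon = 100))
    h2 <- healing_time(simulate_stages(m2, horizon = 100))
    expect_lt(h2, h1)
  }
})

test_that("rate calibration pins the untreated healing time", {
  base <- rate_constants(0.9, 0.6, 0.4)
  cal <- calibrate_natural_rates(base, target_days = 10.33)
  m <- stage_model(cal)
  expect_equal(healing_time(simulate_stages(m, horizon = 30)), 10.33,
               tolerance = 0.01 / 10.33)

  # a base that already achieves the target returns scale ~ 1
  cal2 <- calibrate_natural_rates(cal, target_days = 10.33)
  expect_equal(attr(cal2, "scale"), 1, tolerance = 1e-3)

  # the scale factor is monotone decreasing in the target
  scales <- vapply(c(7, 10.33, 14), function(td) {
    attr(calibrate_natural_rates(base, target_days = td), "scale")
  }, numeric(1))
  expect_true(all(diff(scales) < 0))

  expect_error(calibrate_natural_rates(base, target_days = 1e5),
               "not bracketed")
})

test_that("the DARE solver matches the scalar closed form", {
  a <- 0.9; b <- 1; q <- 1; r <- 1
  sol <- solve_dare(matrix(a), matrix(b), matrix(q), matrix(r))
  # scalar DARE root: b^2 P^2 + (r - q b^2 - a^2 r) P - q r = 0
  c1 <- r - q * b^2 - a^2 * r
  P <- (-c1 + sqrt(c1^2 + 4 * b^2 * q * r)) / (2 * b^2)
  K <- a * b * P / (r + b^2 * P)
  expect_equal(as.numeric(sol$P), P, tolerance = 1e-10)
  expect_equal(as.numeric(sol$K), K, tolerance = 1e-10)

  # no state cost: the optimal gain vanishes
  m0 <- tiny_model()
  m0$Q <- matrix(0, 4, 4)
  expect_equal(solve_lqr(m0)$K, matrix(0, 4, 4), tolerance = 1e-9)
})

test_that("the LQR gain stabilises the transient subsystem", {
  m <- default_stage_model()
  expect_lt(attr(m, "dare_residual"), 1e-8)
  expect_lt(attr(m, "closed_loop_radius"), 1)
  expect_equal(m$K[, 4], rep(0, 4))   # no feedback from the healed mass

  # contract over random admissible models
  set.seed(31)
  for (i in 1:50) {
    mm <- stage_model(rate_constants(runif(1, 0.2, 1), runif(1, 0.2, 1),
                                     runif(1, 0.2, 1)),
                      actuated = rate_constants(runif(1, 0.05, 0.5),
                                                runif(1, 0.05, 0.5),
                                                runif(1, 0.05, 0.5)))
    mm <- solve_lqr(mm)
    expect_lt(attr(mm, "dare_residual"), 1e-8)
    expect_lt(attr(mm, "closed_loop_radius"), 1)
  }
})

test_that("the LQR policy beats random constant gains on the quadratic cost", {
  m <- default_stage_model()
  j_lqr <- lqr_cost(m, m$K, steps = 200)
  set.seed(41)
  for (i in 1:100) {
    K_rand <- matrix(rnorm(16, sd = 0.2), 4, 4)
    expect_lte(j_lqr, lqr_cost(m, K_rand, steps = 200) + 1e-9)
  }
})

test_that("the closed-loop reference fixes the equilibrium and heals faster", {
  m <- default_stage_model()
  ze <- stage_vector(0, 0, 0, 1)
  expect_equal(as.numeric(reference_next(ze, m)), c(0, 0, 0, 1),
               tolerance = 1e-10)

  # zero gain reduces to the natural step
  m0 <- m; m0$K <- matrix(0, 4, 4)
  z <- random_stage_vector()
  expect_equal(as.numeric(reference_next(z, m0)),
               as.numeric(step_stage(z, model = m)))

  expect_error(reference_next(z, stage_model(rate_constants(0.5, 0.3, 0.2))),
               "gain")

  # closed-loop healing time is no slower than natural
  nat <- healing_time(simulate_stages(m, horizon = 30))
  z <- stage_vector(1, 0, 0, 0)
  t <- 0; ht <- NA
  for (s in 1:round(30 / m$dt)) {
    z2 <- reference_next(z, m)
    if (z2[[4]] >= m$heal_threshold) {
      ht <- t + m$dt * (m$heal_threshold - z[[4]]) / (z2[[4]] - z[[4]])
      break
    }
    z <- z2; t <- t + m$dt
  }
  expect_lte(ht, nat)
})

test_that("models and trajectories survive a round trip through text files", {
  m <- default_stage_model()
  path <- withr::local_tempfile(fileext = ".txt")
  write_stage_model(m, path)
  m2 <- read_stage_model(path)
  expect_equal(as.numeric(m2$natural), as.numeric(m$natural))
  expect_equal(m2$K, m$K)

  tr <- simulate_stages(m, horizon = 2)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, csv)
  tr2 <- read_trajectory(csv)
  expect_equal(tr2$M, tr$M, tolerance = 1e-12)
  expect_equal(healing_time(tr2, 0.5), healing_time(tr, 0.5))
})
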