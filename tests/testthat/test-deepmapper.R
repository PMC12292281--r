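# The image-to-stage mapper: encoder/decoder contracts, the three losses,
# gradient correctness and the training loop.

test_that("encoder outputs live on the stage simplex, deterministically", {
  mp <- mapper_init(tiny_mapper_config())
  set.seed(3)
  imgs <- replicate(5, array(runif(32 * 32 * 3), dim = c(32, 32, 3)),
                    simplify = FALSE)
  Z <- encode_stages(mp, imgs)
  expect_true(all(abs(rowSums(as.matrix(Z)) - 1) < 1e-6))
  expect_true(all(as.matrix(Z) >= 0))
  expect_identical(encode_stages(mp, imgs[[1]]), encode_stages(mp, imgs[[1]]))
  expect_error(encode_stages(mp, array(0, dim = c(16, 16, 3))), "mismatch")
})

test_that("decoder respects the pixel range and rejects off-simplex input", {
  mp <- mapper_init(tiny_mapper_config())
  img <- decode_stage(mp, stage_vector(0.25, 0.25, 0.25, 0.25))
  expect_true(all(img$pixels >= 0 & img$pixels <= 1))
  expect_equal(dim(img$pixels), c(32L, 32L, 3L))
  expect_error(decode_stage(mp, c(0.5, 0.5, 0.5, -0.5)), "simplex")
})

test_that("the latent step operator composes substeps and differentiates", {
  nat <- rate_constants(0.6, 0.4, 0.3)
  act <- rate_constants(0.1, 0.2, 0.1)
  K <- matrix(c(0.1, 0, 0, 0, 0, 0.1, 0, 0, 0, 0, 0.1, 0, 0, 0, 0, 0), 4, 4)
  op <- woundloop:::latent_step_operator(nat, act, K, dt_obs = 1,
                                         substeps = 12, with_grads = TRUE)
  M <- diag(4) + (1 / 12) * (build_generator(nat) - build_generator(act) %*% K)
  A_expected <- Reduce(`%*%`, replicate(12, M, simplify = FALSE))
  expect_equal(op$A, A_expected, tolerance = 1e-12, ignore_attr = TRUE)

  # finite-difference check of every rate derivative
  eps <- 1e-7
  for (i in 1:3) {
    nat2 <- nat; nat2[i] <- nat2[i] + eps
    A2 <- woundloop:::latent_step_operator(nat2, act, K, 1, 12)$A
    expect_equal(op$dA[[i]], (A2 - op$A) / eps, tolerance = 1e-5,
                 ignore_attr = TRUE)
    act2 <- act; act2[i] <- act2[i] + eps
    A2 <- woundloop:::latent_step_operator(nat, act2, K, 1, 12)$A
    expect_equal(op$dA[[3 + i]], (A2 - op$A) / eps, tolerance = 1e-5,
                 ignore_attr = TRUE)
  }
})

test_that("loss components obey their algebra", {
  mp <- mapper_init(tiny_mapper_config())
  set.seed(8)
  xs <- replicate(4, array(runif(32 * 32 * 3), dim = c(32, 32, 3)),
                  simplify = FALSE)
  xs1 <- replicate(4, array(runif(32 * 32 * 3), dim = c(32, 32, 3)),
                   simplify = FALSE)
  L1 <- loss_reconstruction(mp, xs)
  L2 <- loss_prediction(mp, xs, xs1)
  L3 <- loss_linearity(mp, xs, xs1)
  expect_gte(L1, 0); expect_gte(L2, 0); expect_gte(L3, 0)

  # batch order does not matter
  expect_equal(loss_reconstruction(mp, rev(xs)), L1)

  # the linearity loss ignores the decoder entirely
  mp2 <- mp
  mp2$Wd2 <- mp2$Wd2 * 0
  expect_equal(loss_linearity(mp2, xs, xs1), L3)
  expect_false(isTRUE(all.equal(loss_prediction(mp2, xs, xs1), L2)))

  # the total is the exact convex combination and lies between the parts
  total <- loss_total(mp, xs, xs1, weights = c(1 / 3, 1 / 3, 1 / 3))
  expect_equal(total, (L1 + L2 + L3) / 3, tolerance = 1e-12)
  expect_gte(total, min(L1, L2, L3))
  expect_lte(total, max(L1, L2, L3))
  expect_equal(loss_total(mp, xs, xs1, weights = c(1, 0, 0)), L1)
  expect_error(loss_total(mp, xs, xs1, weights = c(0.5, 0.5, 0.5)), "sum to 1")
})

test_that("backpropagated gradients match finite differences", {
  cfg <- mapper_config(size = 32, hidden = 8, seed = 3)
  mp <- mapper_init(cfg)
  set.seed(9)
  Xk <- matrix(runif(2 * 32 * 32 * 3), 2)
  Xk1 <- matrix(runif(2 * 32 * 32 * 3), 2)
  op <- woundloop:::latent_step_operator(mp$natural, mp$actuated,
                                         matrix(0, 4, 4), 1, 12,
                                         with_grads = TRUE)
  w <- c(0.4, 0.3, 0.3)
  bg <- woundloop:::mapper_batch_grads(mp, Xk, Xk1, op$A, w)
  lossfun <- function(mp2) {
    e <- woundloop:::encoder_forward(mp2, Xk)
    e1 <- woundloop:::encoder_forward(mp2, Xk1)
    Zp <- e$Z %*% t(op$A)
    d1 <- woundloop:::decoder_forward(mp2, e$Z)
    d2 <- woundloop:::decoder_forward(mp2, Zp)
    w[1] * mean(rowMeans((d1$Y - Xk)^2)) +
      w[2] * mean(rowMeans((d2$Y - Xk1)^2)) +
      w[3] * mean(rowMeans((e1$Z - Zp)^2))
  }
  eps <- 1e-6
  for (nm in c("We1", "We2", "Wd1", "Wd2", "be1", "bd2")) {
    mp2 <- mp
    if (is.matrix(mp[[nm]])) mp2[[nm]][2, 1] <- mp[[nm]][2, 1] + eps
    else mp2[[nm]][2] <- mp[[nm]][2] + eps
    num <- (lossfun(mp2) - lossfun(mp)) / eps
    ana <- unname(if (is.matrix(mp[[nm]])) bg$grads[[nm]][2, 1] else bg$grads[[nm]][2])
    expect_equal(ana, num, tolerance = 1e-3,
                 label = sprintf("analytic gradient of %s", nm))
  }
})

test_that("training reduces the loss deterministically per seed", {
  co <- tiny_cohort()
  mp_a <- fit_mapper(mapper_init(tiny_mapper_config()), co)
  # compare the reconstruction loss, which is defined identically in the
  # warmup and main phases
  expect_lt(tail(mp_a$loss_curve$L1, 1), mp_a$loss_curve$L1[1])

  mp_b <- fit_mapper(mapper_init(tiny_mapper_config()), co)
  expect_identical(mp_a$loss_curve, mp_b$loss_curve)

  # reconstruction-only weights leave the rate constants untouched
  mp_c <- fit_mapper(mapper_init(tiny_mapper_config(
    weights = c(1, 0, 0), warmup_weights = c(1, 0, 0)
  )), co)
  expect_equal(as.numeric(mp_c$natural), c(0.5, 0.5, 0.5))

  # too little data for the update window
  co_small <- generate_cohort(2, 1, 3, params = render_params(size = 32),
                              seed = 5, test_fraction = 0.45)
  expect_error(fit_mapper(mapper_init(tiny_mapper_config()), co_small),
               "too small")
})

test_that("stage prediction returns simplex rows plus the linear rollout", {
  co <- tiny_cohort()
  mp <- fit_mapper(mapper_init(tiny_mapper_config()), co)
  ids <- co$manifest$image_id[co$manifest$subject == 1 &
                                co$manifest$wound == 1]
  pred <- predict_stages(mp, co$images[ids])
  expect_equal(nrow(pred), length(ids))
  expect_true(all(abs(rowSums(pred[, c("H", "I", "P", "M")]) - 1) < 1e-6))
  # the linear solution starts at the first encoded frame
  expect_equal(as.numeric(pred[1, c("H_lin", "I_lin", "P_lin", "M_lin")]),
               as.numeric(pred[1, c("H", "I", "P", "M")]))

  # a constant series encodes to constant stages
  pred_const <- predict_stages(mp, co$images[rep(ids[1], 4)])
  expect_equal(max(abs(apply(as.matrix(pred_const[, c("H", "I", "P", "M")]),
                             2, diff))), 0)
})

test_that("a trained mapper aligns with the fixture's stage semantics", {
  # deeper check on a moderate budget: component identities are pinned
  # (fresh wound encodes hemostasis-dominant) and the learned chain moves
  # the transition rates towards the generating values
  co <- tiny_cohort()
  mp <- cached("mapper_mid", function() {
    fit_mapper(mapper_init(mapper_config(size = 32, epochs = 60, seed = 0)), co)
  })
  first_id <- co$manifest$image_id[co$manifest$day == 1][1]
  z1 <- encode_stages(mp, co$images[[first_id]])
  expect_gt(z1[[1]], 0.8)
  # decoded healed wound shows a smaller disc than the decoded fresh wound
  img_fresh <- decode_stage(mp, stage_vector(1, 0, 0, 0))
  img_healed <- decode_stage(mp, stage_vector(0, 0, 0, 1))
  expect_lt(woundloop:::wound_disc_pixels(img_healed),
            woundloop:::wound_disc_pixels(img_fresh))
})
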