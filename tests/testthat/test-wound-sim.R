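# The synthetic wound environment: action grid, treatment-effect
# modulation, renderer, environment stepping and cohort generation.

test_that("the treatment grid covers both channels including no-treatment", {
  g <- treatment_grid()
  expect_equal(nrow(g), 36L)
  expect_true(any(g$e == 0 & g$d == 0))
  expect_true(any(g$e == 0.25 & g$d == 0.25))
  expect_equal(nrow(treatment_grid(channels = "ef")), 6L)
  expect_true(all(treatment_grid(channels = "flx")$e == 0))
})

test_that("the sine modulation matches its printed formula and bound", {
  act <- rate_constants(0.1, 0.1, 0.1)
  expect_equal(as.numeric(modulated_rates(act, 0, 0, m = 0.2)),
               as.numeric(act))
  # maximal effect on the rising branch while m <= 0.5: sin(pi/2) = 1
  expect_equal(modulated_rates(act, e = 0.25, d = 0, m = 0.3)[[2]], 0.2)
  # after m > 0.5 the sign flips; with base 0.1 the clip lands exactly at 0
  expect_equal(modulated_rates(act, e = 0.25, d = 0, m = 0.7)[[2]], 0)
  # the H->I rate is never modulated
  expect_equal(modulated_rates(act, 0.2, 0.2, 0.4)[[1]], 0.1)

  set.seed(13)
  for (i in 1:50) {
    k <- modulated_rates(act, runif(1, 0, 0.25), runif(1, 0, 0.25), runif(1))
    expect_true(all(abs(as.numeric(k) - as.numeric(act)) <= 0.1 + 1e-12))
    expect_true(all(k >= 0))
  }
})

test_that("the renderer is deterministic and anchored at the extremes", {
  p <- render_params(size = 32, noise_sd = 0.02)
  z <- stage_vector(0.3, 0.3, 0.2, 0.2)
  expect_identical(render_wound(z, p, seed = 5)$pixels,
                   render_wound(z, p, seed = 5)$pixels)

  p0 <- render_params(size = 32, noise_sd = 0)
  healed <- render_wound(stage_vector(0, 0, 0, 1), p0)
  expect_equal(woundloop:::wound_disc_pixels(healed), 0L)
  fresh <- render_wound(stage_vector(1, 0, 0, 0), p0)
  expect_gt(woundloop:::wound_disc_pixels(fresh), 0.5 * 32^2 * pi * 0.45^2)
  expect_true(all(fresh$pixels >= 0 & fresh$pixels <= 1))
})

test_that("wound-disc area shrinks monotonically with maturation", {
  p0 <- render_params(size = 48, noise_sd = 0)
  set.seed(17)
  zs <- replicate(100, as.numeric(random_stage_vector()))
  counts <- apply(zs, 2, function(z) {
    woundloop:::wound_disc_pixels(render_wound(as_stage_vector(z), p0))
  })
  ord <- order(zs[4, ])
  expect_true(all(diff(counts[ord]) <= 0))
})

test_that("radius and redness linearly decode maturation and inflammation", {
  # brute-force identifiability oracle: the autoencoder's task is well posed
  p0 <- render_params(size = 64, noise_sd = 0)
  set.seed(19)
  feats <- t(replicate(50, {
    z <- as.numeric(random_stage_vector())
    img <- render_wound(as_stage_vector(z), p0)$pixels
    disc <- abs(img[, , 1] - 0.80) + abs(img[, , 2] - 0.62) +
      abs(img[, , 3] - 0.52) > 0.12
    radius_hat <- sqrt(sum(disc) / pi) / (64 / 2)
    redness <- mean((img[, , 1] - img[, , 2])[disc])
    c(radius_hat, redness, 1 - z[4], z[2])
  }))
  r2 <- function(y, x) summary(stats::lm(y ~ x))$r.squared
  expect_gt(r2(feats[, 3], feats[, 1]), 0.99)   # 1 - m from the radius
  expect_gt(r2(feats[, 4], feats[, 2]), 0.99)   # i from the redness
})

test_that("environment steps reduce to natural dynamics without actuation", {
  m <- default_stage_model()
  env0 <- wound_env(m, act_base = rate_constants(0, 0, 0))
  z <- random_stage_vector()
  expect_equal(as.numeric(env_step(env0, z, 0, 0, render = FALSE)$z),
               as.numeric(step_stage(z, model = m)))

  # maturation is non-decreasing along random treated rollouts
  env <- default_env()
  set.seed(23)
  z <- stage_vector(1, 0, 0, 0)
  for (s in 1:150) {
    z2 <- env_step(env, z, runif(1, 0, 0.25), runif(1, 0, 0.25),
                   render = FALSE)$z
    expect_gte(z2[[4]], z[[4]] - 1e-13)
    z <- z2
  }

  # full early treatment heals no slower than the untreated wound
  nat <- healing_time(simulate_stages(m, horizon = 30))
  treated <- healing_time(simulate_env(env, policy = function(z) {
    if (z[[4]] <= 0.5) c(0.25, 0.25) else c(0, 0)
  }))
  expect_lte(treated, nat)
})

test_that("cohort generation hits the documented counts and split", {
  co <- cached("acc_cohort", function() {
    generate_cohort(8, 2, 16, params = render_params(), seed = 1)
  })
  expect_equal(length(co$images), 256L)
  expect_equal(sum(co$manifest$split == "train"), 224L)
  expect_equal(sum(co$manifest$split == "test"), 32L)
  # split is disjoint and exhaustive by subject
  split_by_subject <- table(co$manifest$subject, co$manifest$split)
  expect_true(all(rowSums(split_by_subject > 0) == 1))

  co_small <- generate_cohort(3, 1, 4, params = render_params(size = 32),
                              seed = 9)
  expect_equal(length(co_small$images), 12L)

  # determinism: identical seed, identical cohort
  co2 <- generate_cohort(3, 1, 4, params = render_params(size = 32), seed = 9)
  expect_identical(co_small$images, co2$images)
  expect_identical(co_small$latent, co2$latent)

  expect_error(generate_cohort(2, 1, 4, test_fraction = 1.5), "between 0 and 1")
})

test_that("augmentation adds rotated noisy copies of training images only", {
  co <- generate_cohort(3, 1, 4, params = render_params(size = 32), seed = 9,
                        test_fraction = 1 / 3)
  n_train <- sum(co$manifest$split == "train")
  aug <- augment_cohort(co)
  expect_equal(sum(aug$manifest$augmented), n_train)
  expect_true(all(aug$manifest$split[aug$manifest$augmented] == "train"))
  px <- aug$images[[length(aug$images)]]
  expect_true(all(px >= 0 & px <= 1))
})

test_that("cohorts round-trip to PNG plus CSV on disk", {
  co <- generate_cohort(2, 1, 3, params = render_params(size = 32), seed = 4,
                        test_fraction = 0.45)
  dir <- withr::local_tempdir()
  man <- write_cohort(co, dir)
  expect_true(all(file.exists(man$path)))
  back <- png::readPNG(man$path[1])
  expect_equal(dim(back), dim(co$images[[1]]))
  expect_equal(max(abs(back - co$images[[1]])), 0, tolerance = 1 / 255)
  lat <- read.csv(file.path(dir, "latent.csv"))
  expect_equal(nrow(lat), 6L)
})
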