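# Training of the image-to-stage mapper: joint backpropagation through the
# encoder, decoder and latent step operator, with the slow-natural /
# fast-actuated rate update cadence.

# Adam state helper (R side; the mapper trains in R since each epoch is a
# handful of BLAS-bound matrix products)
adam_new <- function(dim) list(m = array(0, dim), v = array(0, dim), t = 0)
adam_step <- function(state, param, grad, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  state$m <- b1 * state$m + (1 - b1) * grad
  state$v <- b2 * state$v + (1 - b2) * grad^2
  mhat <- state$m / (1 - b1^state$t)
  vhat <- state$v / (1 - b2^state$t)
  list(state = state, param = param - lr * mhat / (sqrt(vhat) + eps))
}

# forward + backward over one batch of consecutive pairs; returns losses,
# parameter gradients and the gradient with respect to the step operator A
mapper_batch_grads <- function(mapper, Xk, Xk1, A, w, anchor_rows = NULL,
                               Xj0 = NULL, Xjj = NULL, jlag = 1L) {
  B <- nrow(Xk); D <- ncol(Xk)
  enc <- encoder_forward(mapper, Xk)
  enc1 <- encoder_forward(mapper, Xk1)
  Z <- enc$Z; Z1 <- enc1$Z
  Zp <- Z %*% t(A)
  dec1 <- decoder_forward(mapper, Z)
  dec2 <- decoder_forward(mapper, Zp)

  L1 <- mean(rowMeans((dec1$Y - Xk)^2))
  L2 <- mean(rowMeans((dec2$Y - Xk1)^2))
  L3 <- mean(rowMeans((Z1 - Zp)^2))

  g <- list(We1 = 0, be1 = 0, We2 = 0, be2 = 0,
            Wd1 = 0, bd1 = 0, Wd2 = 0, bd2 = 0)

  dec_back <- function(Zin, dec, dY) {
    dpre <- dY * dec$Y * (1 - dec$Y)
    g$Wd2 <<- g$Wd2 + crossprod(dec$H, dpre)
    g$bd2 <<- g$bd2 + colSums(dpre)
    dH <- (dpre %*% t(mapper$Wd2)) * (dec$H > 0)
    g$Wd1 <<- g$Wd1 + crossprod(Zin, dH)
    g$bd1 <<- g$bd1 + colSums(dH)
    dH %*% t(mapper$Wd1)
  }
  enc_back <- function(e, dZ) {
    if (identical(mapper$config$head %||% "softmax", "sparsemax")) {
      # Jacobian of the simplex projection: centre within the support set
      supp <- e$Z > 0
      dlogits <- (dZ - rowSums(dZ * supp) / pmax(rowSums(supp), 1)) * supp
    } else {
      dlogits <- (dZ - rowSums(dZ * e$Z)) * e$Z
    }
    # logit shrinkage: prevents softmax saturation at the simplex vertices
    ld <- mapper$config$logit_decay %||% 0
    if (ld > 0) dlogits <- dlogits + ld * 2 * e$logits / (B * 4)
    g$We2 <<- g$We2 + crossprod(e$H, dlogits)
    g$be2 <<- g$be2 + colSums(dlogits)
    dH <- (dlogits %*% t(mapper$We2)) * (e$H > 0)
    g$We1 <<- g$We1 + crossprod(e$P, dH)
    g$be1 <<- g$be1 + colSums(dH)
    invisible(NULL)
  }

  dZ <- matrix(0, B, 4)
  if (w[1] > 0) {
    dZ <- dZ + dec_back(Z, dec1, w[1] * 2 * (dec1$Y - Xk) / (B * D))
  }
  # initial-condition anchor: fresh wounds sit at the hemostasis vertex
  w0 <- mapper$config$anchor_weight %||% 0
  if (w0 > 0 && !is.null(anchor_rows) && any(anchor_rows)) {
    z0 <- c(1, 0, 0, 0)
    dZ[anchor_rows, ] <- dZ[anchor_rows, ] +
      w0 * 2 * sweep(Z[anchor_rows, , drop = FALSE], 2, z0) / (sum(anchor_rows) * 4)
  }
  dZp <- matrix(0, B, 4)
  if (w[2] > 0) {
    dZp <- dZp + dec_back(Zp, dec2, w[2] * 2 * (dec2$Y - Xk1) / (B * D))
  }
  if (w[3] > 0) {
    dE <- w[3] * 2 * (Z1 - Zp) / (B * 4)
    enc_back(enc1, dE)
    dZp <- dZp - dE
  }
  dA <- crossprod(dZp, Z)
  dZ <- dZ + dZp %*% A
  enc_back(enc, dZ)

  # stochastic multi-step linearity consistency at lag jlag
  L3m <- NA_real_
  if (w[3] > 0 && !is.null(Xj0) && nrow(Xj0) > 0) {
    Bj <- nrow(Xj0)
    encj0 <- encoder_forward(mapper, Xj0)
    encjj <- encoder_forward(mapper, Xjj)
    Aj <- diag(4)
    Apow <- vector("list", jlag)      # A^l, l = 0..jlag-1
    for (l in seq_len(jlag)) {
      Apow[[l]] <- Aj
      Aj <- A %*% Aj
    }
    Zpj <- encj0$Z %*% t(Aj)
    Ej <- encjj$Z - Zpj
    L3m <- mean(rowMeans(Ej^2))
    dEj <- w[3] * 2 * Ej / (Bj * 4)
    enc_back(encjj, dEj)
    dZpj <- -dEj
    dAj <- crossprod(dZpj, encj0$Z)
    for (l in seq_len(jlag)) {
      dA <- dA + t(Apow[[l]]) %*% dAj %*% t(Apow[[jlag + 1 - l]])
    }
    enc_back(encj0, dZpj %*% Aj)
  }

  list(L1 = L1, L2 = L2, L3 = L3, L3m = L3m, grads = g, dA = dA)
}

#' Fit the mapper to a wound-image cohort
#'
#' Trains the autoencoder and the latent rate constants jointly on
#' consecutive-frame pairs from the cohort's training split, minimising the
#' weighted loss `w1*L1 + w2*L2 + w3*L3`. Network weights take an Adam step
#' per batch. The rate constants follow the slow/fast cadence: natural-rate
#' gradients are accumulated and applied only every N-th optimizer step,
#' while actuated-rate gradients are re-weighted every step by a softmax
#' over recency across the last N steps (a lightweight stand-in for a
#' windowed attention mechanism) and applied immediately. With a zero gain
#' the actuated rates receive no gradient (untreated data carries no
#' actuation signal).
#'
#' @param mapper A `deep_mapper` from [mapper_init()].
#' @param cohort A `wound_cohort` (or any list with `images` and a
#'   `manifest` with `subject`, `wound`, `day`, `split`, `augmented`).
#' @param gain LQR gain K of the closed-loop operator `A = A_nat - A_act K`;
#'   zero by default (untreated cohort).
#' @param refresh_lqr Re-solve the gain from the current learned rates every
#'   N optimizer steps (uses the default cost matrices). Default `FALSE`.
#' @param verbose Print per-epoch losses.
#' @return The trained mapper with a `loss_curve` tibble
#'   (`epoch, L1, L2, L3, total`) attached.
#' @export
fit_mapper <- function(mapper, cohort, gain = matrix(0, 4, 4),
                       refresh_lqr = FALSE, verbose = FALSE) {
  cfg <- mapper$config
  man <- cohort$manifest
  train <- man[man$split == "train" & !man$augmented, ]
  train <- train[order(train$subject, train$wound, train$day), ]
  # consecutive-frame pairs within each wound
  key <- paste(train$subject, train$wound)
  pk <- which(key[-nrow(train)] == key[-1] &
                diff(train$day) == 1L)
  pairs <- cbind(train$image_id[pk], train$image_id[pk + 1L])
  first_frame <- train$day[pk] == min(train$day)
  # lagged frame pools for the multi-step consistency term
  J <- max(1L, cfg$multi_step %||% 1L)
  lag_pairs <- lapply(seq_len(J), function(j) {
    if (j >= nrow(train)) return(matrix(integer(0), 0, 2))
    ok <- which(key[seq_len(nrow(train) - j)] == key[(1 + j):nrow(train)] &
                  (train$day[(1 + j):nrow(train)] - train$day[seq_len(nrow(train) - j)]) == j)
    cbind(train$image_id[ok], train$image_id[ok + j])
  })
  if (nrow(pairs) < cfg$window) {
    abort(sprintf("dataset too small: %d pairs < window N = %d",
                  nrow(pairs), cfg$window))
  }
  X_all <- as_image_matrix(cohort$images, cfg$size)

  # optimizer state
  st <- lapply(list(We1 = mapper$We1, be1 = mapper$be1, We2 = mapper$We2,
                    be2 = mapper$be2, Wd1 = mapper$Wd1, bd1 = mapper$bd1,
                    Wd2 = mapper$Wd2, bd2 = mapper$bd2),
               function(p) adam_new(dim(p) %||% length(p)))
  st_nat <- adam_new(3L)
  st_act <- adam_new(3L)
  nat_acc <- rep(0, 3)
  nat_acc_n <- 0L
  act_window <- matrix(0, cfg$window, 3L)
  act_filled <- 0L
  step_idx <- 0L
  curve <- vector("list", cfg$epochs)
  K <- gain

  with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(nrow(pairs))
      n_batches <- ceiling(nrow(pairs) / cfg$batch_size)
      ep_loss <- c(L1 = 0, L2 = 0, L3 = 0)
      in_warmup <- ep <= (cfg$warmup %||% 0L)
      w_ep <- if (in_warmup) cfg$warmup_weights else cfg$weights
      # logit shrinkage is a scaffolding regularizer: full strength while the
      # latent assignment is forming, released for the final fine-tune so the
      # encoder can saturate towards the simplex vertices
      mapper$config$logit_decay <- if (ep <= 0.6 * cfg$epochs) cfg$logit_decay else 0
      for (bi in seq_len(n_batches)) {
        rows <- ord[((bi - 1L) * cfg$batch_size + 1L):min(bi * cfg$batch_size, nrow(pairs))]
        Xk <- X_all[pairs[rows, 1L], , drop = FALSE]
        Xk1 <- X_all[pairs[rows, 2L], , drop = FALSE]
        step_idx <- step_idx + 1L

        if (refresh_lqr && step_idx %% cfg$window == 1L) {
          sm <- stage_model(mapper$natural, mapper$actuated, dt = cfg$dt_obs / cfg$substeps,
                            lqr_dt = cfg$dt_obs)
          K <- tryCatch(solve_lqr(sm)$K, error = function(e) K)
        }

        op <- latent_step_operator(mapper$natural, mapper$actuated, K,
                                   cfg$dt_obs, cfg$substeps, with_grads = TRUE)
        jlag <- if (J > 1L) sample(2:J, 1L) else 1L
        Xj0 <- NULL; Xjj <- NULL
        if (J > 1L && w_ep[3] > 0 && nrow(lag_pairs[[jlag]]) > 0) {
          jr <- sample.int(nrow(lag_pairs[[jlag]]),
                           min(cfg$batch_size, nrow(lag_pairs[[jlag]])))
          Xj0 <- X_all[lag_pairs[[jlag]][jr, 1L], , drop = FALSE]
          Xjj <- X_all[lag_pairs[[jlag]][jr, 2L], , drop = FALSE]
        }
        bg <- mapper_batch_grads(mapper, Xk, Xk1, op$A, w_ep,
                                 anchor_rows = first_frame[rows],
                                 Xj0 = Xj0, Xjj = Xjj, jlag = jlag)
        ep_loss <- ep_loss + c(bg$L1, bg$L2, bg$L3) / n_batches

        # network weights: one Adam step per batch
        for (nm in names(bg$grads)) {
          upd <- adam_step(st[[nm]], mapper[[nm]], bg$grads[[nm]], cfg$lr)
          st[[nm]] <- upd$state
          mapper[[nm]] <- upd$param
        }

        # rates are frozen during warmup (anchor chain), learned afterwards
        g_rates <- if (in_warmup) rep(0, 6) else
          vapply(op$dA, function(dAk) sum(bg$dA * dAk), numeric(1))
        nat_acc <- nat_acc + g_rates[1:3]
        nat_acc_n <- nat_acc_n + 1L
        if (!in_warmup && step_idx %% cfg$window == 0L) {
          upd <- adam_step(st_nat, as.numeric(mapper$natural),
                           nat_acc / nat_acc_n, cfg$lr_rates)
          st_nat <- upd$state
          mapper$natural <- rate_constants(max(0, upd$param[1]),
                                           max(0, upd$param[2]),
                                           max(0, upd$param[3]))
          nat_acc <- rep(0, 3)
          nat_acc_n <- 0L
        }
        # actuated rates: fast cadence with recency-softmax window weighting
        act_window[(step_idx - 1L) %% cfg$window + 1L, ] <- g_rates[4:6]
        act_filled <- min(act_filled + 1L, cfg$window)
        if (!in_warmup && any(act_window != 0)) {
          ages <- (step_idx - 1L) %% cfg$window + 1L - seq_len(cfg$window)
          ages <- ifelse(ages < 0, ages + cfg$window, ages)
          wts <- exp(-ages)
          wts[seq_len(cfg$window) > act_filled & ages >= act_filled] <- 0
          wts <- wts / sum(wts)
          g_act <- colSums(act_window * wts)
          upd <- adam_step(st_act, as.numeric(mapper$actuated), g_act, cfg$lr_rates)
          st_act <- upd$state
          mapper$actuated <- rate_constants(max(0, upd$param[1]),
                                            max(0, upd$param[2]),
                                            max(0, upd$param[3]))
        }
      }
      curve[[ep]] <- tibble::tibble(epoch = ep, L1 = ep_loss[1], L2 = ep_loss[2],
                                    L3 = ep_loss[3],
                                    total = sum(cfg$weights * ep_loss))
      if (verbose) {
        message(sprintf("epoch %3d  L1 %.5f  L2 %.5f  L3 %.6f  total %.5f",
                        ep, ep_loss[1], ep_loss[2], ep_loss[3],
                        sum(cfg$weights * ep_loss)))
      }
    }
  })
  mapper$loss_curve <- dplyr::bind_rows(curve)
  mapper$gain <- K
  mapper
}

#' Predict stage trajectories from an image series
#'
#' Encodes every frame of a series and, alongside, rolls the learned latent
#' linear dynamics forward from the first encoded frame. The two curve
#' families can be compared to judge how linear the observed healing is in
#' the learned coordinates.
#'
#' @param mapper A trained `deep_mapper`.
#' @param images List of frames of one wound, in temporal order.
#' @param gain Gain of the closed-loop operator (default zero).
#' @return A tibble with columns `frame, H, I, P, M` (encoded) and
#'   `H_lin, I_lin, P_lin, M_lin` (latent-dynamics solution).
#' @export
predict_stages <- function(mapper, images, gain = matrix(0, 4, 4)) {
  enc <- encode_stages(mapper, images)
  A <- latent_step_operator(mapper$natural, mapper$actuated, gain,
                            mapper$config$dt_obs, mapper$config$substeps)$A
  n <- nrow(enc)
  lin <- matrix(0, n, 4)
  lin[1, ] <- as.numeric(enc[1, ])
  if (n > 1) {
    for (t in 2:n) lin[t, ] <- as.numeric(A %*% lin[t - 1, ])
  }
  dplyr::bind_cols(
    tibble::tibble(frame = seq_len(n)),
    enc,
    tibble::tibble(H_lin = lin[, 1], I_lin = lin[, 2],
                   P_lin = lin[, 3], M_lin = lin[, 4])
  )
}
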