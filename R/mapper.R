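#' Configuration of the image-to-stage mapper
#'
#' The mapper is an autoencoder linking wound images to the 4-dimensional
#' stage space: an encoder `h` (one ReLU hidden layer on the flattened
#' full-resolution pixels, softmax head onto the stage simplex), a decoder
#' `h^-1` (ReLU hidden layer, sigmoid pixel output), and a learned latent
#' linear dynamic parameterised by the six stage rate constants (three
#' natural, three actuated) rather than a free 4x4 matrix, which keeps the
#' learned dynamics identifiable and interpretable.
#'
#' The latent step operator over one observation interval is composed of
#' `substeps` Euler substeps, matching the simulator's internal integration
#' (daily frames integrated at dt = 1/12 day use `substeps = 12`).
#'
#' @param size Image side in pixels. Default 64.
#' @param hidden Hidden width of encoder and decoder. Default 64.
#' @param weights Loss weights `c(w1, w2, w3)` of the reconstruction,
#'   prediction and linearity losses; must be non-negative and sum to 1.
#' @param window Window size N of the slow/fast update cadence: natural
#'   rates are updated every N optimizer steps, actuated rates every step
#'   from a recency-softmax-weighted window of the last N per-step
#'   gradients. Default 8.
#' @param epochs,batch_size,lr Training schedule of the network weights.
#' @param warmup Number of initial epochs during which the rate constants
#'   stay frozen at their initial values and the loss uses the warmup
#'   weights. Anchoring the encoder to a fixed, plausible stage chain first
#'   breaks the permutation symmetry of the latent components and blocks the
#'   degenerate solution (static latent, zero rates) of the linearity loss;
#'   the rates are released afterwards. Default 15.
#' @param warmup_weights Loss weights used during the warmup epochs.
#'   Default `c(0.7, 0, 0.3)` (reconstruction plus linearity on the frozen
#'   chain).
#' @param anchor_weight Weight of the initial-condition anchor: first-frame
#'   images of each wound are pulled towards the fresh-wound state
#'   `c(1, 0, 0, 0)`. A freshly created wound is in hemostasis by
#'   definition, so this uses only frame metadata, never latent ground
#'   truth; it pins the identity of the latent components, which the
#'   reconstruction and linearity losses alone leave permutation-ambiguous.
#'   Default 0.2.
#' @param logit_decay L2 penalty on the encoder logits. Keeps the softmax
#'   head away from full saturation, where the simplex attractor of the
#'   linearity loss (the healed equilibrium) would otherwise capture the
#'   whole batch and kill the reconstruction gradients. Default 1e-4.
#' @param lr_rates Adam learning rate of the rate constants. Default 0.02.
#' @param dt_obs Observation interval in days (1 for daily frames).
#' @param substeps Euler substeps composing the latent step operator.
#' @param head Simplex head of the encoder: `"softmax"` (default) or
#'   `"sparsemax"` (Euclidean projection; reaches vertices exactly but is
#'   prone to dead supports on this task).
#' @param multi_step Longest horizon J of the stochastic multi-step
#'   linearity consistency term: each batch adds one linearity penalty
#'   `||h(x_(k+j)) - A^j h(x_k)||^2` at a random lag `j` in `2..J`.
#'   Long-horizon consistency amplifies rate errors through `A^j` and pulls
#'   the encoded late phase onto the dynamics' reach, which one-step terms
#'   barely constrain. Set to 1 to disable. Default 6.
#' @param init_natural,init_actuated Initial rate constants.
#' @param seed Seed controlling initialisation and batch shuffling.
#' @return A list of class `mapper_config`.
#' @export
mapper_config <- function(size = 64L, hidden = 64L,
                          weights = c(0.4, 0.3, 0.3), window = 8L,
                          epochs = 100L, batch_size = 16L, lr = 1e-3,
                          logit_decay = 1e-4, warmup = 15L,
                          warmup_weights = c(0.7, 0, 0.3),
                          anchor_weight = 0.2,
                          lr_rates = 0.02, dt_obs = 1, substeps = 12L,
                          head = c("softmax", "sparsemax"),
                          multi_step = 6L,
                          init_natural = c(0.5, 0.5, 0.5),
                          init_actuated = c(0.1, 0.1, 0.1), seed = 0L) {
  if (length(weights) != 3L || any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
    abort("loss `weights` must be three non-negative values summing to 1")
  }
  if (epochs < 1L) abort("`epochs` must be >= 1")
  structure(
    list(size = as.integer(size), hidden = as.integer(hidden),
         weights = weights, window = as.integer(window),
         epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         lr = lr, logit_decay = logit_decay, warmup = as.integer(warmup),
         warmup_weights = warmup_weights, anchor_weight = anchor_weight,
         head = match.arg(head), multi_step = as.integer(multi_step),
         lr_rates = lr_rates, dt_obs = dt_obs,
         substeps = as.integer(substeps),
         init_natural = init_natural, init_actuated = init_actuated,
         seed = as.integer(seed)),
    class = "mapper_config"
  )
}

#' Initialise an untrained mapper
#'
#' @param config A [mapper_config()].
#' @return A list of class `deep_mapper` holding the encoder and decoder
#'   weights, the learned rate constants and the config.
#' @export
mapper_init <- function(config = mapper_config()) {
  d_out <- config$size^2 * 3L
  d_in <- config$size^2 * 3L
  h <- config$hidden
  with_seed(config$seed, {
    mapper <- list(
      We1 = matrix(rnorm(d_in * h, sd = sqrt(2 / d_in)), d_in, h),
      be1 = rep(0, h),
      We2 = matrix(rnorm(h * 4L, sd = sqrt(2 / h)), h, 4L),
      be2 = rep(0, 4L),
      Wd1 = matrix(rnorm(4L * h, sd = sqrt(2 / 4)), 4L, h),
      bd1 = rep(0, h),
      Wd2 = matrix(rnorm(h * d_out, sd = sqrt(1 / h)), h, d_out),
      bd2 = rep(0, d_out),
      natural = rate_constants(config$init_natural[1], config$init_natural[2],
                               config$init_natural[3]),
      actuated = rate_constants(config$init_actuated[1], config$init_actuated[2],
                                config$init_actuated[3]),
      config = config
    )
    class(mapper) <- "deep_mapper"
    mapper
  })
}

#' @export
print.deep_mapper <- function(x, ...) {
  cat(sprintf("<deep_mapper> %dx%d images, hidden %d\n",
              x$config$size, x$config$size, x$config$hidden))
  cat(sprintf("  learned natural rates : %.3f %.3f %.3f /day\n",
              x$natural[1], x$natural[2], x$natural[3]))
  cat(sprintf("  learned actuated rates: %.3f %.3f %.3f /day\n",
              x$actuated[1], x$actuated[2], x$actuated[3]))
  if (!is.null(x$loss_curve)) {
    cat(sprintf("  trained %d epochs, final loss %.5f\n",
                nrow(x$loss_curve), tail(x$loss_curve$total, 1)))
  }
  invisible(x)
}

# ---- internal: batch plumbing ----

# accepts a single image (array or wound_image), a list of them, or a cohort
# subset; returns a B x (size^2*3) matrix of flattened pixels
as_image_matrix <- function(images, size) {
  if (inherits(images, "wound_image")) images <- list(images$pixels)
  if (is.array(images) && length(dim(images)) == 3L) images <- list(images)
  px <- lapply(images, function(im) {
    if (inherits(im, "wound_image")) im <- im$pixels
    d <- dim(im)
    if (is.null(d) || length(d) != 3L || d[1] != size || d[2] != size || d[3] != 3L) {
      abort(sprintf("image shape mismatch: expected %d x %d x 3", size, size))
    }
    as.numeric(im)
  })
  do.call(rbind, px)
}

relu <- function(x) pmax(x, 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

# rowwise Euclidean projection onto the probability simplex (sparsemax)
sparsemax_rows <- function(V) {
  Z <- V
  for (b in seq_len(nrow(V))) {
    v <- V[b, ]
    u <- sort(v, decreasing = TRUE)
    css <- cumsum(u)
    k <- max(which(1 + seq_along(u) * u > css))
    tau <- (css[k] - 1) / k
    Z[b, ] <- pmax(v - tau, 0)
  }
  Z
}

# encoder forward on a flattened pixel batch; returns list(P, H, Z)
encoder_forward <- function(mapper, X) {
  P <- X
  H <- relu(sweep(P %*% mapper$We1, 2, mapper$be1, `+`))
  logits <- sweep(H %*% mapper$We2, 2, mapper$be2, `+`)
  if (identical(mapper$config$head %||% "softmax", "sparsemax")) {
    Z <- sparsemax_rows(logits)
  } else {
    expl <- exp(logits - apply(logits, 1, max))
    Z <- expl / rowSums(expl)
  }
  list(P = P, H = H, Z = Z, logits = logits)
}

# decoder forward on a latent batch; returns list(H, Y)
decoder_forward <- function(mapper, Z) {
  H <- relu(sweep(Z %*% mapper$Wd1, 2, mapper$bd1, `+`))
  Y <- sigmoid(sweep(H %*% mapper$Wd2, 2, mapper$bd2, `+`))
  list(H = H, Y = Y)
}

#' Encode wound images to stage vectors
#'
#' Applies the encoder `h` to one or more images. The softmax head
#' guarantees the output lies on the stage simplex.
#'
#' @param mapper A `deep_mapper`.
#' @param images A single image (array or `wound_image`) or a list of them.
#' @return For a single image, a [stage_vector()]; for a list, a tibble with
#'   columns `H, I, P, M`, one row per image.
#' @export
encode_stages <- function(mapper, images) {
  single <- inherits(images, "wound_image") ||
    (is.array(images) && length(dim(images)) == 3L)
  X <- as_image_matrix(images, mapper$config$size)
  Z <- encoder_forward(mapper, X)$Z
  if (single) return(as_stage_vector(as.numeric(Z[1, ])))
  tibble::tibble(H = Z[, 1], I = Z[, 2], P = Z[, 3], M = Z[, 4])
}

#' Decode a stage vector to a wound image
#'
#' Applies the decoder `h^-1`. The sigmoid output keeps every pixel in
#' \[0, 1\].
#'
#' @param mapper A `deep_mapper`.
#' @param z A stage vector (must lie on the simplex within 1e-6).
#' @return A `wound_image`.
#' @export
decode_stage <- function(mapper, z) {
  z <- as.numeric(z)
  if (length(z) != 4L || any(z < -1e-6) || abs(sum(z) - 1) > 1e-6) {
    abort("`z` must lie on the 4-simplex (within 1e-6)")
  }
  Y <- decoder_forward(mapper, matrix(z, 1))$Y
  s <- mapper$config$size
  structure(list(pixels = array(Y[1, ], dim = c(s, s, 3L)),
                 meta = list(source = "decoded")),
            class = "wound_image")
}

# latent one-observation-step operator A and its derivatives with respect to
# the six rates. A = prod_j (I + h * G) with G = G_nat - G_act %*% K.
latent_step_operator <- function(natural, actuated, K = matrix(0, 4, 4),
                                 dt_obs = 1, substeps = 12L,
                                 with_grads = FALSE) {
  h <- dt_obs / substeps
  G <- build_generator(natural) - build_generator(actuated) %*% K
  M <- diag(4) + h * G
  A <- diag(4)
  lefts <- vector("list", substeps)   # prefix products
  for (j in seq_len(substeps)) {
    lefts[[j]] <- A
    A <- M %*% A
  }
  if (!with_grads) return(list(A = A))
  # elementary generators of the three chain rates
  E <- lapply(1:3, function(i) {
    e <- matrix(0, 4, 4)
    e[i, i] <- -1
    e[i + 1, i] <- 1
    e
  })
  dG <- c(E, lapply(E, function(e) -e %*% K))     # natural then actuated
  rights <- vector("list", substeps)              # suffix products
  Acc <- diag(4)
  for (j in rev(seq_len(substeps))) {
    rights[[j]] <- Acc
    Acc <- Acc %*% M
  }
  dA <- lapply(dG, function(g) {
    out <- matrix(0, 4, 4)
    for (j in seq_len(substeps)) {
      out <- out + rights[[j]] %*% (h * g) %*% lefts[[j]]
    }
    out
  })
  list(A = A, dA = dA)
}

# ---- the three losses (Eq.-style definitions; mean over dimension then
# ---- over examples) ----

#' Reconstruction loss of the mapper
#'
#' Mean squared reconstruction error `mean((x - h^-1(h(x)))^2)`, averaged
#' over pixels/channels then over the batch.
#'
#' @param mapper A `deep_mapper`.
#' @param images Batch of images (list, single array or `wound_image`).
#' @return A non-negative scalar; zero iff the autoencoder reproduces every
#'   image exactly.
#' @export
loss_reconstruction <- function(mapper, images) {
  X <- as_image_matrix(images, mapper$config$size)
  Z <- encoder_forward(mapper, X)$Z
  Y <- decoder_forward(mapper, Z)$Y
  mean(rowMeans((Y - X)^2))
}

#' Prediction loss of the mapper
#'
#' Mean squared error between the next frame and the decoded latent
#' one-step prediction, `mean((x_next - h^-1(A h(x)))^2)`, with `A` the
#' closed-loop latent step operator built from the learned rates and the
#' supplied gain.
#'
#' @param mapper A `deep_mapper`.
#' @param images,images_next Consecutive-frame batches of equal length.
#' @param gain LQR gain K entering `A = A_nat - A_act K`; defaults to zero
#'   (untreated data).
#' @return A non-negative scalar.
#' @export
loss_prediction <- function(mapper, images, images_next,
                            gain = matrix(0, 4, 4)) {
  X <- as_image_matrix(images, mapper$config$size)
  X1 <- as_image_matrix(images_next, mapper$config$size)
  if (nrow(X) != nrow(X1)) abort("frame batches must have equal length")
  A <- latent_step_operator(mapper$natural, mapper$actuated, gain,
                            mapper$config$dt_obs, mapper$config$substeps)$A
  Z <- encoder_forward(mapper, X)$Z
  Y <- decoder_forward(mapper, Z %*% t(A))$Y
  mean(rowMeans((Y - X1)^2))
}

#' Linearity loss of the mapper
#'
#' Latent-space prediction error `mean((h(x_next) - A h(x))^2)`, averaged
#' over the four stage dimensions then the batch. Depends only on the
#' encoder and the learned dynamics, never on the decoder.
#'
#' @inheritParams loss_prediction
#' @return A non-negative scalar.
#' @export
loss_linearity <- function(mapper, images, images_next,
                           gain = matrix(0, 4, 4)) {
  X <- as_image_matrix(images, mapper$config$size)
  X1 <- as_image_matrix(images_next, mapper$config$size)
  if (nrow(X) != nrow(X1)) abort("frame batches must have equal length")
  A <- latent_step_operator(mapper$natural, mapper$actuated, gain,
                            mapper$config$dt_obs, mapper$config$substeps)$A
  Z <- encoder_forward(mapper, X)$Z
  Z1 <- encoder_forward(mapper, X1)$Z
  mean(rowMeans((Z1 - Z %*% t(A))^2))
}

#' Total weighted mapper loss
#'
#' The convex combination `w1 * L1 + w2 * L2 + w3 * L3` of the
#' reconstruction, prediction and linearity losses.
#'
#' @inheritParams loss_prediction
#' @param weights Loss weights; default from the mapper's config. Must sum
#'   to 1.
#' @return A scalar between `min(L1, L2, L3)` and `max(L1, L2, L3)`.
#' @export
loss_total <- function(mapper, images, images_next,
                       gain = matrix(0, 4, 4),
                       weights = mapper$config$weights) {
  if (abs(sum(weights) - 1) > 1e-9 || any(weights < 0)) {
    abort("loss `weights` must be non-negative and sum to 1")
  }
  weights[1] * loss_reconstruction(mapper, images) +
    weights[2] * loss_prediction(mapper, images, images_next, gain) +
    weights[3] * loss_linearity(mapper, images, images_next, gain)
}
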