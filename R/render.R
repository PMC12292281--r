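#' Rendering parameters for the synthetic wound camera
#'
#' Controls the procedural renderer that turns a latent stage vector into an
#' RGB wound photograph. The renderer is a stand-in for a real camera: a
#' circular wound disc of radius proportional to `1 - m` on a skin-tone
#' background, with blood-dark shading and a clot core tracking hemostasis
#' `h`, disc redness increasing linearly in inflammation `i`, and granulation tissue
#' whose blue-channel depletion and texture shimmer track proliferation
#' `p`. Every stage coordinate therefore has a first-order pixel signature,
#' which keeps the image-to-stage inverse problem well posed.
#'
#' @param size Image side in pixels (square). Default 64.
#' @param base_radius Radius of the fresh wound as a fraction of the image
#'   half-width. Default 0.9.
#' @param redness_gain Slope of the red channel in `i`. Default 0.5.
#' @param granulation_gain Texture amplitude per unit `p`. Default 0.25.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise.
#'   Default 0.02 (set to 0 for noiseless fixtures).
#' @param seed Base seed for the pixel noise.
#' @return A list of class `render_params`.
#' @export
render_params <- function(size = 64L, base_radius = 0.9, redness_gain = 0.5,
                          granulation_gain = 0.25, noise_sd = 0.02,
                          seed = 0L) {
  if (size < 16L) abort("`size` must be >= 16")
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(base_radius, "base_radius", lower = 0, upper = 1)
  structure(
    list(
      size = as.integer(size), base_radius = base_radius,
      redness_gain = redness_gain, granulation_gain = granulation_gain,
      noise_sd = noise_sd, seed = as.integer(seed)
    ),
    class = "render_params"
  )
}

# skin-tone background and wound palette (values on [0,1])
.skin <- c(0.80, 0.62, 0.52)

#' Render a wound image from a stage vector
#'
#' Deterministic given `(z, params, seed)`: the same inputs produce
#' bit-identical rasters. At the healed equilibrium `z = c(0,0,0,1)` the
#' wound radius is zero and the image is pure background (plus noise).
#'
#' @param z Stage vector.
#' @param params A [render_params()] object.
#' @param seed Seed for the additive pixel noise; defaults to `params$seed`.
#' @param meta Optional named list of metadata (subject, wound, day, source)
#'   attached to the result.
#' @return A `wound_image`: list with `pixels` (size x size x 3 array in
#'   \[0,1\]) and `meta`.
#' @examples
#' img <- render_wound(stage_vector(0.2, 0.5, 0.2, 0.1), render_params(size = 32))
#' range(img$pixels)
#' @export
render_wound <- function(z, params = render_params(), seed = params$seed,
                         meta = list()) {
  if (!inherits(z, "stage_vector")) z <- as_stage_vector(z)
  s <- params$size
  ax <- seq(-1, 1, length.out = s)
  xg <- matrix(ax, s, s)            # x varies down rows
  yg <- matrix(ax, s, s, byrow = TRUE)
  r2 <- xg^2 + yg^2

  h <- z[[1]]; i <- z[[2]]; p <- z[[3]]; m <- z[[4]]
  radius <- params$base_radius * (1 - m)
  disc <- r2 <= radius^2
  core <- r2 <= (radius * sqrt(h))^2   # clot core area = h * disc area

  R <- matrix(.skin[1], s, s)
  G <- matrix(.skin[2], s, s)
  B <- matrix(.skin[3], s, s)

  if (any(disc)) {
    # wound bed: redness linear in inflammation (R - G = 0.15 + gain * i
    # everywhere inside the disc, preserved by texture and core shading)
    # wound bed: uniform blood-dark shading proportional to hemostasis h
    # (equal R/G subtraction keeps R - G = 0.15 + gain * i exactly, so
    # inflammation stays linearly decodable everywhere in the disc)
    R[disc] <- 0.45 + params$redness_gain * i - 0.2 * h
    G[disc] <- 0.30 - 0.2 * h
    B[disc] <- 0.28 - 0.2 * p - 0.2 * h
    tex <- params$granulation_gain * p * sin(9 * pi * xg) * sin(9 * pi * yg)
    R[disc] <- R[disc] + tex[disc]
    G[disc] <- G[disc] + tex[disc]
    if (any(core)) {
      R[core] <- R[core] - 0.1
      G[core] <- G[core] - 0.1
      B[core] <- B[core] - 0.08
    }
  }

  px <- array(c(R, G, B), dim = c(s, s, 3))
  if (params$noise_sd > 0) {
    noise <- with_seed(seed, rnorm(length(px), sd = params$noise_sd))
    px <- px + array(noise, dim = dim(px))
  }
  px[px < 0] <- 0
  px[px > 1] <- 1
  structure(list(pixels = px, meta = meta), class = "wound_image")
}

#' @export
print.wound_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<wound_image> %dx%dx%d", d[1], d[2], d[3]))
  if (length(x$meta)) {
    cat(" |", paste(names(x$meta), unlist(x$meta), sep = "=", collapse = " "))
  }
  cat("\n")
  invisible(x)
}

# Pixels inside the wound disc, detected as departure from the flat background.
# Used by tests and diagnostics; tolerant to additive noise well below the
# skin/wound contrast.
wound_disc_pixels <- function(img, tol = 0.12) {
  px <- if (inherits(img, "wound_image")) img$pixels else img
  dev <- abs(px[, , 1] - .skin[1]) + abs(px[, , 2] - .skin[2]) + abs(px[, , 3] - .skin[3])
  sum(dev > tol)
}
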