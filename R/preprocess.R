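#' Device-image preprocessing configuration
#'
#' The bioelectronic device camera produces images with a strong red cast
#' and wound-edge hardware in frame; the preprocessing chain subtracts fixed
#' per-channel offsets (on the 0-255 scale), resamples to a square target
#' with a Lanczos kernel, and rescales intensities.
#'
#' @param offsets Per-channel (R, G, B) offsets subtracted on the 0-255
#'   scale. Default `c(108.16, 61.49, 55.44)`.
#' @param size Target side in pixels. Default 128.
#' @param a Lanczos kernel order. Default 3.
#' @param normalization `"range"` (min-max rescale to \[0,1\], the default)
#'   or `"center"` (range rescale followed by per-channel mean removal;
#'   zero-mean output, values no longer confined to \[0,1\]).
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(offsets = c(108.16, 61.49, 55.44),
                              size = 128L, a = 3L,
                              normalization = c("range", "center")) {
  if (length(offsets) != 3L || any(offsets < 0)) {
    abort("`offsets` must be three non-negative values")
  }
  if (size < 16L) abort("`size` must be >= 16")
  structure(
    list(offsets = offsets, size = as.integer(size), a = as.integer(a),
         normalization = match.arg(normalization)),
    class = "preprocess_config"
  )
}

# separable Lanczos-a resampling weights from n_in source pixels to n_out
lanczos_weights <- function(n_in, n_out, a = 3L) {
  scale <- n_in / n_out
  W <- matrix(0, n_out, n_in)
  for (j in seq_len(n_out)) {
    centre <- (j - 0.5) * scale + 0.5   # source coordinate of target centre
    support <- a * max(1, scale)
    lo <- max(1L, floor(centre - support))
    hi <- min(n_in, ceiling(centre + support))
    x <- (seq(lo, hi) - centre) / max(1, scale)
    w <- ifelse(abs(x) < 1e-12, 1,
                ifelse(abs(x) < a,
                       a * sin(pi * x) * sin(pi * x / a) / (pi^2 * x^2), 0))
    if (sum(w) == 0) w[which.min(abs(x))] <- 1
    W[j, lo:hi] <- w / sum(w)
  }
  W
}

#' Preprocess a raw device image
#'
#' Pipeline: per-channel offset subtraction (clipped at zero) on the 0-255
#' scale, Lanczos resampling to `size x size`, then intensity
#' normalization. A constant image (no dynamic range after the offsets)
#' yields an all-zero raster with a warning.
#'
#' @param raw An RGB raster: `height x width x 3` array with values on the
#'   0-255 scale.
#' @param config A [preprocess_config()].
#' @return A `size x size x 3` numeric array; in `"range"` mode all values
#'   lie in \[0, 1\].
#' @examples
#' raw <- array(runif(48 * 48 * 3, 0, 255), dim = c(48, 48, 3))
#' dim(preprocess_device_image(raw))
#' @export
preprocess_device_image <- function(raw, config = preprocess_config()) {
  d <- dim(raw)
  if (is.null(d) || length(d) != 3L || d[3] != 3L) {
    abort("`raw` must be a height x width x 3 RGB array")
  }
  out <- array(0, dim = c(config$size, config$size, 3L))
  Wr <- lanczos_weights(d[1], config$size, config$a)
  Wc <- lanczos_weights(d[2], config$size, config$a)
  for (ch in 1:3) {
    plane <- pmax(raw[, , ch] - config$offsets[ch], 0)
    out[, , ch] <- Wr %*% plane %*% t(Wc)
  }
  rng <- range(out)
  if (diff(rng) < 1e-12) {
    warn("constant image after offset subtraction; returning zeros")
    return(array(0, dim = dim(out)))
  }
  out <- (out - rng[1]) / diff(rng)
  if (config$normalization == "center") {
    for (ch in 1:3) out[, , ch] <- out[, , ch] - mean(out[, , ch])
  }
  out
}

#' Select the sharpest image of a timepoint
#'
#' Device acquisitions come in bursts (several frames per timepoint); the
#' frame with the largest Laplacian variance (a standard focus measure) is
#' kept. Ties break by acquisition order.
#'
#' @param images A non-empty list of RGB rasters (or `wound_image`s).
#' @param method `"sharpest"` (default) or `"first"` (keep the first frame).
#' @return The selected raster, with the winning index in
#'   `attr(, "selected")`.
#' @export
select_timepoint_image <- function(images, method = c("sharpest", "first")) {
  method <- match.arg(method)
  if (length(images) == 0L) abort("`images` is empty")
  px <- lapply(images, function(im) if (inherits(im, "wound_image")) im$pixels else im)
  if (method == "first") {
    out <- px[[1]]
    attr(out, "selected") <- 1L
    return(out)
  }
  sharp <- vapply(px, function(im) {
    g <- (im[, , 1] + im[, , 2] + im[, , 3]) / 3
    n <- nrow(g); m <- ncol(g)
    lap <- 4 * g[2:(n - 1), 2:(m - 1)] -
      g[1:(n - 2), 2:(m - 1)] - g[3:n, 2:(m - 1)] -
      g[2:(n - 1), 1:(m - 2)] - g[2:(n - 1), 3:m]
    stats::var(as.numeric(lap))
  }, numeric(1))
  k <- which.max(sharp)
  out <- px[[k]]
  attr(out, "selected") <- k
  out
}
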