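#' Generate a synthetic mouse-style wound-image cohort
#'
#' Emulates a cohort of untreated wounds photographed once per day: per
#' wound, a latent stage trajectory starts at the fresh wound
#' `c(1, 0, 0, 0)` and evolves under the natural dynamics with
#' subject-specific rate heterogeneity (a lognormal multiplier per subject),
#' integrated internally at the model `dt` and observed at day resolution.
#' Each observation is rendered into an image. The default configuration
#' (8 subjects x 2 wounds x 16 days) yields 256 images split 224/32 by
#' holding out whole subjects.
#'
#' @param n_subjects,wounds_per_subject,n_days Cohort dimensions, all `>= 1`.
#' @param obs_per_day Frames per day (1 = daily imaging, the mouse-style
#'   default; 12 = the 2-hour device cadence).
#' @param params [render_params()] for the image renderer.
#' @param seed Master seed: fixes the subject rate multipliers, image noise
#'   and augmentation draws.
#' @param model [stage_model()] supplying natural rates and `dt`.
#' @param jitter_sd Standard deviation of the per-subject lognormal rate
#'   multiplier. Default 0.1.
#' @param test_fraction Fraction of subjects held out for testing (rounded to
#'   at least one subject). Default `1/8`.
#' @param augment Add one augmented copy (right-angle rotation plus Gaussian
#'   noise, sd `augment_noise_sd`) of every training image. Default `FALSE`.
#' @param augment_noise_sd Noise level of the augmentation pass.
#' @return A list of class `wound_cohort` with elements `images` (list of
#'   size x size x 3 arrays), `manifest` (tibble: `image_id, subject, wound,
#'   day, split, augmented`), `latent` (tibble: `subject, wound, day, H, I,
#'   P, M`), `params`, `seed`.
#' @examples
#' co <- generate_cohort(2, 1, 4, params = render_params(size = 32), seed = 1)
#' nrow(co$manifest)
#' @export
generate_cohort <- function(n_subjects = 8L, wounds_per_subject = 2L,
                            n_days = 16L, obs_per_day = 1L,
                            params = render_params(),
                            seed = 1L, model = default_stage_model(solve = FALSE),
                            jitter_sd = 0.1, test_fraction = 1 / 8,
                            augment = FALSE, augment_noise_sd = 0.01) {
  if (n_subjects < 1L || wounds_per_subject < 1L || n_days < 1L) {
    abort("all cohort counts must be >= 1")
  }
  if (test_fraction <= 0 || test_fraction >= 1) {
    abort("`test_fraction` must be strictly between 0 and 1")
  }
  n_test_subjects <- max(1L, round(test_fraction * n_subjects))
  if (n_test_subjects >= n_subjects) abort("`test_fraction` leaves no training subjects")
  test_subjects <- seq_len(n_subjects) > (n_subjects - n_test_subjects)

  multipliers <- with_seed(seed, exp(rnorm(n_subjects, mean = 0, sd = jitter_sd)))

  images <- list()
  manifest <- list()
  latent <- list()
  idx <- 0L
  for (s in seq_len(n_subjects)) {
    rates_s <- rate_constants(
      model$natural[[1]] * multipliers[s],
      model$natural[[2]] * multipliers[s],
      model$natural[[3]] * multipliers[s]
    )
    model_s <- stage_model(rates_s, dt = model$dt,
                           heal_threshold = model$heal_threshold)
    for (w in seq_len(wounds_per_subject)) {
      traj <- simulate_stages(model_s, horizon = n_days - 1)
      n_frames <- (n_days - 1L) * obs_per_day + 1L
      times <- (seq_len(n_frames) - 1L) / obs_per_day
      obs_rows <- 1L + round(times / model$dt)
      for (d in seq_len(n_frames)) {
        z <- as_stage_vector(as.numeric(traj[obs_rows[d], c("H", "I", "P", "M")]))
        idx <- idx + 1L
        img_seed <- seed + 7919L * s + 379L * w + d
        images[[idx]] <- render_wound(
          z, params, seed = img_seed,
          meta = list(subject = s, wound = w, day = d, source = "synthetic-mouse")
        )$pixels
        manifest[[idx]] <- tibble::tibble(
          image_id = idx, subject = s, wound = w, day = d,
          split = if (test_subjects[s]) "test" else "train",
          augmented = FALSE
        )
        latent[[idx]] <- tibble::tibble(
          subject = s, wound = w, day = d, time_days = times[d],
          H = z[[1]], I = z[[2]], P = z[[3]], M = z[[4]]
        )
      }
    }
  }
  manifest <- dplyr::bind_rows(manifest)
  latent <- dplyr::bind_rows(latent)

  cohort <- structure(
    list(images = images, manifest = manifest, latent = latent,
         params = params, seed = seed),
    class = "wound_cohort"
  )
  if (augment) cohort <- augment_cohort(cohort, noise_sd = augment_noise_sd)
  cohort
}

# Right-angle rotation of an (s, s, 3) raster, k in {1, 2, 3} quarter-turns.
rotate_raster <- function(px, k) {
  for (j in seq_len(k)) {
    px <- aperm(px, c(2, 1, 3))
    px <- px[dim(px)[1]:1, , , drop = FALSE]
  }
  px
}

#' Augment the training images of a cohort
#'
#' Appends one augmented copy of every training image: a random right-angle
#' rotation (90/180/270 degrees, avoiding interpolation artifacts) plus
#' additive Gaussian noise. Test images are never augmented.
#'
#' @param cohort A `wound_cohort`.
#' @param noise_sd Gaussian noise sd of the augmentation pass.
#' @param seed Seed of the augmentation draws; defaults to the cohort seed.
#' @return The cohort with augmented images appended (marked
#'   `augmented = TRUE` in the manifest).
#' @export
augment_cohort <- function(cohort, noise_sd = 0.01, seed = cohort$seed + 1L) {
  train_ids <- cohort$manifest$image_id[
    cohort$manifest$split == "train" & !cohort$manifest$augmented
  ]
  rots <- with_seed(seed, sample(1:3, length(train_ids), replace = TRUE))
  idx <- length(cohort$images)
  new_rows <- list()
  for (j in seq_along(train_ids)) {
    id <- train_ids[j]
    px <- rotate_raster(cohort$images[[id]], rots[j])
    noise <- with_seed(seed + j, rnorm(length(px), sd = noise_sd))
    px <- px + array(noise, dim = dim(px))
    px[px < 0] <- 0
    px[px > 1] <- 1
    idx <- idx + 1L
    cohort$images[[idx]] <- px
    row <- cohort$manifest[cohort$manifest$image_id == id, ]
    row$image_id <- idx
    row$augmented <- TRUE
    new_rows[[j]] <- row
  }
  cohort$manifest <- dplyr::bind_rows(cohort$manifest, new_rows)
  cohort
}

#' Write a cohort to disk as PNG images plus CSV tables
#'
#' @param cohort A `wound_cohort`.
#' @param dir Output directory (created if missing). Images are written as
#'   `img_<id>.png`; the manifest (with a `path` column) and the latent
#'   ground-truth table as CSV.
#' @return Invisibly, the manifest with paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, sprintf("img_%04d.png", cohort$manifest$image_id))
  for (j in seq_along(paths)) {
    png::writePNG(cohort$images[[cohort$manifest$image_id[j]]], paths[j])
  }
  manifest <- dplyr::mutate(cohort$manifest, path = paths)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  write.csv(cohort$latent, file.path(dir, "latent.csv"), row.names = FALSE)
  invisible(manifest)
}

#' @export
print.wound_cohort <- function(x, ...) {
  n <- nrow(x$manifest)
  cat(sprintf(
    "<wound_cohort> %d images (%d train / %d test), %d augmented\n",
    n, sum(x$manifest$split == "train"), sum(x$manifest$split == "test"),
    sum(x$manifest$augmented)
  ))
  invisible(x)
}
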