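# Synthetic radiograph phantoms.
#
# Each identity is a set of geometric parameters (thorax outline, rib
# pattern, cardiac silhouette, clavicles, spine) that stays fixed across all
# of that person's images; each acquisition adds the variation a repeat exam
# would: small rotation/translation, brightness/contrast jitter and additive
# Gaussian noise. This minimally realises the statistical structure the
# embedding method assumes - identity-stable anatomy plus per-acquisition
# nuisance variation - without attempting photorealism.

#' Sample the anatomy parameters of one synthetic identity
#'
#' All geometry is expressed in unit coordinates (`[-1, 1]` across the
#' image). Parameter ranges are fixed so every phantom renders in frame.
#'
#' @param identity_seed integer seed; phantoms with different seeds differ
#'   in essentially all parameters.
#' @return an `identity_phantom` list.
#' @export
identity_phantom <- function(identity_seed) {
  withr::with_seed(identity_seed, {
    structure(list(
      thorax_a = stats::runif(1, 0.55, 0.75),      # semi-axis, horizontal
      thorax_b = stats::runif(1, 0.65, 0.85),      # semi-axis, vertical
      rib_count = sample(6:9, 1),
      rib_start = stats::runif(1, -0.68, -0.58),
      rib_spacing = stats::runif(1, 0.13, 0.18),
      rib_curvature = stats::runif(1, 0.15, 0.45),
      rib_width = stats::runif(1, 0.015, 0.03),
      cardiac_width_fraction = stats::runif(1, 0.25, 0.4),
      cardiac_height = stats::runif(1, 0.3, 0.45),
      cardiac_offset = stats::runif(1, 0.05, 0.2),
      clavicle_angle = stats::runif(1, 5, 20),     # degrees
      spine_offset = stats::runif(1, -0.06, 0.06),
      spine_width = 0.07,
      identity_seed = as.integer(identity_seed)
    ), class = "identity_phantom")
  })
}

#' Sample per-acquisition nuisance parameters
#'
#' Jitter bounds are fixed small enough that the anatomy stays in frame:
#' rotation within `max_rotation` degrees, translation within
#' `max_translation` of the image width, multiplicative contrast within
#' `1 +/- contrast_jitter` and additive brightness within
#' `+/- brightness_jitter`.
#'
#' @param acquisition_seed integer seed; also drives the pixel noise.
#' @param noise_sd standard deviation of the additive Gaussian pixel noise
#'   on the `[0, 1]` intensity scale (default 0.04, about 10 grey levels of
#'   an 8-bit detector).
#' @param brightness_jitter,contrast_jitter,max_rotation,max_translation
#'   jitter bounds as described above.
#' @return an `acquisition_params` list.
#' @export
acquisition_params <- function(acquisition_seed, noise_sd = 0.04,
                               brightness_jitter = 0.06, contrast_jitter = 0.1,
                               max_rotation = 3, max_translation = 0.03) {
  withr::with_seed(acquisition_seed, {
    structure(list(
      noise_sd = noise_sd,
      brightness = stats::runif(1, -brightness_jitter, brightness_jitter),
      contrast = stats::runif(1, 1 - contrast_jitter, 1 + contrast_jitter),
      rotation = stats::runif(1, -max_rotation, max_rotation),
      translation = stats::runif(2, -max_translation, max_translation),
      acquisition_seed = as.integer(acquisition_seed)
    ), class = "acquisition_params")
  })
}

#' Acquisition with no noise and no jitter (for deterministic geometry)
#' @param acquisition_seed integer seed (kept for bookkeeping only).
#' @export
clean_acquisition <- function(acquisition_seed = 0L) {
  structure(list(noise_sd = 0, brightness = 0, contrast = 1, rotation = 0,
                 translation = c(0, 0),
                 acquisition_seed = as.integer(acquisition_seed)),
            class = "acquisition_params")
}

soft_band <- function(dist, halfwidth, edge = 0.01) {
  clamp01((halfwidth - dist) / edge + 1)
}

#' Render a synthetic radiograph
#'
#' Deterministic given the phantom and acquisition parameters: the same pair
#' always yields the bit-identical image.
#'
#' @param phantom an [identity_phantom()].
#' @param acq an [acquisition_params()].
#' @param size image side length in pixels (default 200).
#' @return a `size x size` matrix of intensities in `[0, 1]`.
#' @export
render_radiograph <- function(phantom, acq, size = 200L) {
  stop_if_not_scalar_count(size, "size")
  p <- phantom
  # pixel grid in unit coordinates, then inverse view transform
  ax <- seq(-1, 1, length.out = size)
  u0 <- matrix(ax, size, size, byrow = TRUE)   # horizontal coordinate
  v0 <- matrix(ax, size, size)                 # vertical coordinate (down)
  th <- acq$rotation * pi / 180
  u <- cos(th) * (u0 - acq$translation[1]) + sin(th) * (v0 - acq$translation[2])
  v <- -sin(th) * (u0 - acq$translation[1]) + cos(th) * (v0 - acq$translation[2])

  img <- matrix(0.08, size, size)
  if (p$thorax_a > 0 && p$thorax_b > 0) {
    e <- (u / p$thorax_a)^2 + (v / p$thorax_b)^2
    thorax <- clamp01((1 - e) / 0.08)
    img <- img + 0.2 * thorax
    # spine: bright vertical band
    img <- img + 0.22 * thorax * soft_band(abs(u - p$spine_offset), p$spine_width)
    # ribs: curved horizontal bands following v = y_i + curvature * u^2
    for (i in seq_len(p$rib_count)) {
      yi <- p$rib_start + (i - 1) * p$rib_spacing
      img <- img + 0.3 * thorax * soft_band(abs(v - (yi + p$rib_curvature * u^2)),
                                            p$rib_width)
    }
    # cardiac silhouette: ellipse displaced toward the (anatomical) left
    cw <- p$cardiac_width_fraction * p$thorax_a * 2
    ec <- ((u - p$cardiac_offset) / cw)^2 + ((v - 0.25) / p$cardiac_height)^2
    img <- img + 0.18 * clamp01((1 - ec) / 0.15)
    # clavicles: two oblique bands near the apex
    vtop <- -0.72 * p$thorax_b
    slope <- tan(p$clavicle_angle * pi / 180)
    wing <- clamp01((0.9 * p$thorax_a - abs(u)) / 0.05) * clamp01((abs(u) - 0.05) / 0.05)
    img <- img + 0.25 * wing * soft_band(abs(v - (vtop + slope * abs(u))), 0.018)
  }
  img <- 0.5 + acq$contrast * (img - 0.5) + acq$brightness
  if (acq$noise_sd > 0) {
    noise <- withr::with_seed(acq$acquisition_seed,
                              stats::rnorm(size * size, sd = acq$noise_sd))
    img <- img + matrix(noise, size, size)
  }
  clamp01(img)
}

#' Generate a synthetic identity-labelled radiograph dataset
#'
#' Produces `n_identities * images_per_identity` images plus a metadata
#' table in the NIH naming dialect (columns `Image Index` and `Patient ID`).
#' When `out_dir` is given, 8-bit grayscale PNGs and `metadata.csv` are
#' written there; images are always returned in memory as well.
#'
#' @param n_identities number of synthetic patients (at least 2).
#' @param images_per_identity images rendered per patient.
#' @param size image side length in pixels.
#' @param seed integer seed; the whole dataset (parameters, noise, file
#'   bytes) is reproducible from it.
#' @param out_dir optional output directory.
#' @param ... jitter/noise overrides forwarded to [acquisition_params()].
#' @return list with `metadata` (data frame), `images` (named list of
#'   matrices), `phantoms`, and `dir` (or `NULL`).
#' @export
generate_dataset <- function(n_identities, images_per_identity, size = 200L,
                             seed = 1L, out_dir = NULL, ...) {
  stop_if_not_scalar_count(n_identities, "n_identities")
  stop_if_not_scalar_count(images_per_identity, "images_per_identity")
  if (n_identities < 2) stop("`n_identities` must be at least 2")
  seeds <- withr::with_seed(seed, {
    matrix(sample.int(2^30, n_identities * (images_per_identity + 1L)),
           nrow = n_identities)
  })
  images <- list()
  phantoms <- vector("list", n_identities)
  meta <- vector("list", n_identities * images_per_identity)
  k <- 0L
  for (i in seq_len(n_identities)) {
    phantoms[[i]] <- identity_phantom(seeds[i, 1L])
    pid <- sprintf("%05d", i)
    for (j in seq_len(images_per_identity)) {
      acq <- acquisition_params(seeds[i, j + 1L], ...)
      img <- render_radiograph(phantoms[[i]], acq, size = size)
      name <- sprintf("%s_%03d.png", pid, j)
      images[[name]] <- img
      k <- k + 1L
      meta[[k]] <- data.frame(`Image Index` = name, `Patient ID` = pid,
                              check.names = FALSE, stringsAsFactors = FALSE)
    }
  }
  metadata <- do.call(rbind, meta)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) {
      ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      if (!ok) stop(sprintf("cannot create output directory '%s'", out_dir))
    }
    for (name in names(images)) {
      png::writePNG(images[[name]], file.path(out_dir, name))
    }
    utils::write.csv(metadata, file.path(out_dir, "metadata.csv"), row.names = FALSE)
  }
  list(metadata = metadata, images = images, phantoms = phantoms, dir = out_dir)
}
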