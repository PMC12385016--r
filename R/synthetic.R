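#' Configuration for the synthetic radiograph generator
#'
#' The generator emulates the structure of periapical radiographs at the
#' level a texture-analysis pipeline cares about: a bright, elongated
#' root-like structure on a noisy mid-gray background, where lesion-class
#' images additionally carry a darker elliptical region at the root apex
#' with elevated intensity heterogeneity. Effect sizes are explicit knobs:
#' `lesion_contrast` is the mean-intensity drop inside the lesion and
#' `lesion_texture_sd` the extra noise standard deviation, so the planted
#' signal can be scaled from zero (classes identically distributed) to
#' strong. The default class balance of 0.52 mirrors a realistic
#' lesion-heavy clinical archive.
#'
#' @param n_images number of images to generate (>= 2).
#' @param lesion_fraction proportion of lesion-class images in `[0, 1]`.
#'   Class counts are `round(n * fraction)` lesioned and the rest healthy.
#' @param image_size side length in pixels (square images, >= 32).
#' @param lesion_contrast mean intensity drop inside the lesion, in `[0, 1]`.
#' @param lesion_texture_sd extra noise SD inside the lesion; interior
#'   noise SD is `background_noise_sd + lesion_texture_sd`.
#' @param background_noise_sd global Gaussian noise SD.
#' @param seed integer seed; one seeded generator drives all draws, with
#'   per-image substreams derived by counter offset so any subset of the
#'   dataset is reproducible in isolation.
#'
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_images = 100,
                             lesion_fraction = 0.52,
                             image_size = 128,
                             lesion_contrast = 0.30,
                             lesion_texture_sd = 0.15,
                             background_noise_sd = 0.10,
                             seed = 1L) {
  n_images <- assert_count(n_images, "n_images", min = 2L)
  assert_number(lesion_fraction, "lesion_fraction", 0, 1)
  image_size <- assert_count(image_size, "image_size", min = 32L)
  assert_number(lesion_contrast, "lesion_contrast", 0, 1)
  assert_number(lesion_texture_sd, "lesion_texture_sd", min = 0)
  assert_number(background_noise_sd, "background_noise_sd", min = 0)
  seed <- assert_count(seed, "seed", min = 0L)
  n_lesion <- round(n_images * lesion_fraction)
  if (lesion_fraction > 0 && lesion_fraction < 1 &&
      (n_lesion < 1L || n_lesion > n_images - 1L))
    abort_config("config must yield at least one image per class")
  structure(
    list(n_images = n_images, lesion_fraction = lesion_fraction,
         image_size = image_size, lesion_contrast = lesion_contrast,
         lesion_texture_sd = lesion_texture_sd,
         background_noise_sd = background_noise_sd, seed = seed),
    class = "synthetic_config"
  )
}

#' Generate a labeled synthetic radiograph dataset
#'
#' Deterministic given the config seed: the same config yields bit-identical
#' pixel arrays on every run. Lesion position, axes and orientation are
#' jittered per image; the planted lesion geometry is recorded in the
#' `lesion` attribute of each lesion-class sample so that tests can measure
#' the signal inside the true region.
#'
#' @param config a [synthetic_config()].
#' @return A list of [radiograph_sample()] objects with the config attached
#'   as attribute `config`.
#' @export
#' @examples
#' ds <- generate_dataset(synthetic_config(n_images = 4, image_size = 32))
#' sample_manifest(ds)
generate_dataset <- function(config) {
  if (!inherits(config, "synthetic_config"))
    abort_config("`config` must come from synthetic_config()")
  n <- config$n_images
  n_lesion <- round(n * config$lesion_fraction)
  labels <- c(rep(1L, n_lesion), rep(0L, n - n_lesion))
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    samples[[i]] <- with_seed(
      substream_seed(config$seed, i),
      synth_one_image(config, id = sprintf("img_%04d", i), label = labels[i])
    )
  }
  attr(samples, "config") <- config
  samples
}

## One image: bright root capsule on noisy background, plus (label 1) a
## darker ellipse at the root apex with inflated noise SD.
synth_one_image <- function(config, id, label) {
  s <- config$image_size
  rr <- matrix(seq_len(s), nrow = s, ncol = s)
  cc <- matrix(seq_len(s), nrow = s, ncol = s, byrow = TRUE)

  apex_r <- s * (0.66 + runif(1, -0.06, 0.06))
  apex_c <- s * (0.50 + runif(1, -0.08, 0.08))
  width <- s * (0.10 + runif(1, -0.015, 0.015))

  ## distance to the root axis: vertical segment from top to the apex point
  dr <- pmax(rr - apex_r, 0)              # 0 above the apex
  dc <- cc - apex_c
  dist_axis <- sqrt(dr^2 + dc^2)
  mu <- 0.45 + 0.30 * exp(-0.5 * (dist_axis / width)^2)

  inside <- matrix(FALSE, s, s)
  lesion <- NULL
  if (label == 1L) {
    ctr_r <- apex_r + s * runif(1, 0.02, 0.06)
    ctr_c <- apex_c + s * runif(1, -0.03, 0.03)
    ax_a <- s * (0.090 + runif(1, -0.015, 0.015))
    ax_b <- s * (0.070 + runif(1, -0.015, 0.015))
    phi <- runif(1, 0, pi)
    u <- (rr - ctr_r) * cos(phi) + (cc - ctr_c) * sin(phi)
    v <- -(rr - ctr_r) * sin(phi) + (cc - ctr_c) * cos(phi)
    inside <- (u / ax_a)^2 + (v / ax_b)^2 <= 1
    mu[inside] <- mu[inside] - config$lesion_contrast
    lesion <- list(center = c(ctr_r, ctr_c), axes = c(ax_a, ax_b), angle = phi)
  }

  noise <- matrix(rnorm(s * s, sd = config$background_noise_sd), s, s)
  if (any(inside)) {
    sd_in <- config$background_noise_sd + config$lesion_texture_sd
    noise[inside] <- rnorm(sum(inside), sd = sd_in)
  }
  px <- clip01(mu + noise)
  out <- radiograph_sample(id = id, pixels = px, label = label)
  attr(out, "lesion") <- lesion
  out
}

#' Write a dataset to disk as 8-bit images plus a manifest CSV
#'
#' Intensities are generated in `[0, 1]` and quantized to 8 bits on write.
#'
#' @param samples list of [radiograph_sample()] objects.
#' @param dir output directory (created if missing).
#' @param format `"tiff"` (default) or `"png"`.
#' @param split optional named character vector id -> split, written into
#'   the manifest.
#' @return A tibble manifest with columns `id`, `path`, `label`, `split`,
#'   also written to `manifest.csv` in `dir`.
#' @export
write_dataset <- function(samples, dir, format = c("tiff", "png"), split = NULL) {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ext <- if (format == "tiff") "tiff" else "png"
  paths <- character(length(samples))
  for (i in seq_along(samples)) {
    sm <- samples[[i]]
    paths[i] <- file.path(dir, paste0(sm$id, ".", ext))
    if (format == "tiff") {
      tiff::writeTIFF(sm$pixels, paths[i], bits.per.sample = 8L)
    } else {
      png::writePNG(sm$pixels, paths[i])
    }
  }
  man <- sample_manifest(samples)
  man <- tibble::tibble(
    id = man$id, path = paths, label = man$label,
    split = if (is.null(split)) NA_character_ else unname(split[man$id])
  )
  readr::write_csv(man, file.path(dir, "manifest.csv"))
  man
}
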