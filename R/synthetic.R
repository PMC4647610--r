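#' Map a latent degradation score to generator parameters
#'
#' Encodes the documented visual correlates of reef degradation as
#' monotone parameter maps over the impact-score scale `[0, 50]`:
#' thriving low-score reefs get many distinct hue palettes, large and
#' numerous discernable objects, bright saturated colour and crisp
#' texture; degraded high-score reefs get few hues, small sparse objects,
#' dimmer colour and heavy smoothing (the amorphous-slime proxy) that
#' obscures the underlying texture.
#'
#' @param latent_score impact-style score in `[0, 50]`.
#' @return A list of class `generator_params`: `color_diversity`
#'   (distinct hue palettes, decreasing), `object_count` (blobs per
#'   image, decreasing), `object_scale` (mean blob radius in px at a
#'   128-px reference side, decreasing), `blur_sigma` (Gaussian smoothing
#'   width in px, increasing), `noise_sd`, `brightness` and `saturation`
#'   (both decreasing), plus the score itself.
#' @export
generator_params <- function(latent_score) {
  if (latent_score < 0 || latent_score > 50)
    stop("`latent_score` must lie in [0, 50]")
  u <- latent_score / 50
  structure(list(
    latent_score = latent_score,
    color_diversity = max(1L, as.integer(round(6 - 5 * u))),
    object_count = as.integer(round(25 - 18 * u)),
    object_scale = 12 - 8 * u,
    blur_sigma = 0.5 + 3.5 * u,
    noise_sd = 0.03,
    brightness = 0.8 - 0.45 * u,
    saturation = 0.85 - 0.55 * u
  ), class = "generator_params")
}

# Hue palettes of the synthetic reef fauna, ordered so that the first
# palettes are kept as colour diversity shrinks: coral pink, orange,
# yellow, purple, green, cyan-blue.
reef_hues <- c(0.93, 0.07, 0.14, 0.78, 0.33, 0.52)

# Separable Gaussian blur with edge-replicating borders; sigma in px.
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  blur1 <- function(x) {   # along rows of x
    n <- nrow(x)
    out <- matrix(0, n, ncol(x))
    for (d in -r:r) {
      idx <- pmin(pmax(seq_len(n) + d, 1L), n)
      out <- out + k[d + r + 1L] * x[idx, , drop = FALSE]
    }
    out
  }
  t(blur1(t(blur1(m))))
}

#' Generate one synthetic reefscape image
#'
#' Layered composition: a vertical bluish background gradient, elliptical
#' coloured blobs (the discernable objects) with hues drawn from the
#' palettes the score still allows, Gaussian smoothing, and clipped
#' additive noise. Deterministic for a given `(params, h, w, seed)`.
#'
#' @param params a [generator_params()] list.
#' @param h,w image dimensions (at least 16).
#' @param seed RNG seed.
#' @return A [raster_image].
#' @export
generate_reef_image <- function(params, h = 128L, w = 128L, seed = 1L) {
  scale_px <- params$object_scale * min(h, w) / 128
  if (scale_px * 4 > min(h, w))
    stop("object scale too large for a ", h, " x ", w, " image")
  with_seed(seed, {
    hues <- reef_hues[seq_len(params$color_diversity)]
    # background: flat dim blue-gray water tone
    bg <- t(grDevices::col2rgb(grDevices::hsv(0.58, 0.35 * params$saturation / 0.85,
                                              min(params$brightness, 1)))) / 255
    img <- array(0, c(h, w, 3L))
    for (k in 1:3) img[, , k] <- matrix(bg[k], h, w)
    rows <- matrix(seq_len(h), h, w)
    cols <- matrix(seq_len(w), h, w, byrow = TRUE)
    n_obj <- params$object_count
    if (n_obj > 0L) {
      for (i in seq_len(n_obj)) {
        cy <- stats::runif(1L, 1, h); cx <- stats::runif(1L, 1, w)
        a <- scale_px * exp(stats::rnorm(1L, 0, 0.3))
        b <- a * stats::runif(1L, 0.6, 1)
        th <- stats::runif(1L, 0, pi)
        hue <- sample(hues, 1L)
        sat <- stats::runif(1L, 0.75, 1) * params$saturation
        val <- stats::runif(1L, 0.8, 1.15) * params$brightness
        rgb1 <- t(grDevices::col2rgb(grDevices::hsv(hue, min(sat, 1),
                                                    min(val, 1)))) / 255
        dy <- rows - cy; dx <- cols - cx
        u <- cos(th) * dx + sin(th) * dy
        v <- -sin(th) * dx + cos(th) * dy
        mask <- (u / a)^2 + (v / b)^2 <= 1
        if (any(mask))
          for (k in 1:3) {
            ch <- img[, , k]
            ch[mask] <- rgb1[k]
            img[, , k] <- ch
          }
      }
    }
    for (k in 1:3) img[, , k] <- gaussian_blur(img[, , k], params$blur_sigma)
    if (params$noise_sd > 0)
      img <- img + array(stats::rnorm(length(img), 0, params$noise_sd),
                         dim(img))
    raster_image(pmin(pmax(img, 0), 1))
  })
}

#' Planted driver features of the synthetic generator
#'
#' The registry features that read the generator parameters out globally
#' and unambiguously: `brightness` drives the arithmetic and logarithmic
#' brightness averages and the mean value channel, and colour diversity
#' plus saturation drive the opponent-space colourfulness. These are the
#' planted signals a feature-importance analysis on synthetic surveys is
#' expected to recover near the top of the ranking. The saturation
#' parameter is also planted, but its readout is shared between the
#' global mean and the per-segment saturation means (the largest
#' connected region is typically water background, whose saturation the
#' generator sets directly), so no single saturation feature is the
#' canonical driver; the remaining features respond only indirectly,
#' through blur, fragmentation and palette side effects.
#'
#' @return Character vector of registry feature names.
#' @export
generator_driver_features <- function() {
  c("brightness_arith", "brightness_log", "mean_v", "colorfulness")
}

#' Site specification for the synthetic survey
#'
#' @param site_id unique site label.
#' @param latent_score site-level degradation score in `[0, 50]`; recorded
#'   as the site's target score in the manifest.
#' @param n_images images generated for the site.
#' @param seed site RNG seed (per-image seeds are derived as
#'   `seed + image index`).
#' @return A list of class `site_spec`.
#' @export
site_spec <- function(site_id, latent_score, n_images, seed) {
  stopifnot(latent_score >= 0, latent_score <= 50, n_images >= 1)
  structure(list(site_id = as.character(site_id),
                 latent_score = latent_score,
                 n_images = as.integer(n_images), seed = as.integer(seed)),
            class = "site_spec")
}

#' Generate a synthetic site-grouped image dataset
#'
#' Generates every image of every site specification and assembles the
#' manifest (`image_path`/`image_id`, `site_id`, `site_score`). When
#' `dir` is given the images are written as PNG files and the manifest as
#' `manifest.csv` inside it; regeneration with the same seeds is
#' byte-identical.
#'
#' @param specs list of [site_spec()] objects with distinct site ids and
#'   at least two distinct latent scores.
#' @param h,w image dimensions.
#' @param dir optional output directory (created if missing).
#' @return List with `images` (list of [raster_image]), `manifest`
#'   (data.frame) and `dir`.
#' @export
generate_reef_dataset <- function(specs, h = 128L, w = 128L, dir = NULL) {
  ids <- vapply(specs, `[[`, character(1L), "site_id")
  if (anyDuplicated(ids))
    stop("duplicate site id(s): ", paste(unique(ids[duplicated(ids)]),
                                         collapse = ", "))
  scores <- vapply(specs, `[[`, numeric(1L), "latent_score")
  if (length(unique(scores)) < 2L)
    stop("need at least two sites with distinct latent scores")
  images <- list()
  rows <- list()
  for (sp in specs) {
    pars <- generator_params(sp$latent_score)
    for (i in seq_len(sp$n_images)) {
      img <- generate_reef_image(pars, h, w, seed = sp$seed + i)
      images[[length(images) + 1L]] <- img
      rows[[length(rows) + 1L]] <- data.frame(
        image_id = sprintf("%s_%03d.png", sp$site_id, i),
        site_id = sp$site_id, site_score = sp$latent_score,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    manifest$image_path <- file.path(dir, manifest$image_id)
    for (i in seq_along(images)) save_image(images[[i]], manifest$image_path[i])
    utils::write.csv(manifest[, c("image_path", "site_id", "site_score")],
                     file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  list(images = images, manifest = manifest, dir = dir)
}

#' Simulate the desk-scale synthetic reef survey
#'
#' The package's default study conditions: `n_sites` sites with latent
#' scores evenly spread over the impact range observed across real survey
#' sites (about 2 to 45), `images_per_site` images each, at
#' `h` x `w` = 128 x 128 px.
#'
#' @param n_sites number of sites.
#' @param images_per_site images per site.
#' @param h,w image dimensions.
#' @param seed master seed; site seeds are derived deterministically.
#' @param dir optional output directory (PNG + manifest.csv).
#' @return As [generate_reef_dataset()].
#' @export
simulate_reef_survey <- function(n_sites = 11L, images_per_site = 30L,
                                 h = 128L, w = 128L, seed = 1L, dir = NULL) {
  scores <- round(seq(2, 45, length.out = n_sites), 2L)
  specs <- lapply(seq_len(n_sites), function(i) {
    site_spec(sprintf("site%02d", i), scores[i], images_per_site,
              seed = seed * 1000L + i * 101L)
  })
  generate_reef_dataset(specs, h, w, dir = dir)
}
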