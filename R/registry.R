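# Means and standard deviations of the six basic channels (R,G,B,H,S,V).
channel_moments <- function(img, hsv = NULL) {
  img <- as_raster_image(img)
  if (is.null(hsv)) hsv <- rgb_to_hsv_image(img)
  p <- img$pixels
  chans <- list(r = p[, , 1L], g = p[, , 2L], b = p[, , 3L],
                h = hsv$h, s = hsv$s, v = hsv$v)
  mns <- vapply(chans, mean, numeric(1L))
  sds <- vapply(chans, function(m) stats::sd(as.vector(m)), numeric(1L))
  names(mns) <- paste0("mean_", names(chans))
  names(sds) <- paste0("sd_", names(chans))
  c(mns, sds)
}

# Mean value-channel brightness of each cell of the 3 x 3 thirds grid,
# in reading order (top-left .. bottom-right).
thirds_grid_means <- function(img) {
  v <- if (is.matrix(img)) img else value_channel(img)
  h <- nrow(v); w <- ncol(v)
  rb <- floor(h * (0:3) / 3); cb <- floor(w * (0:3) / 3)
  out <- numeric(9L)
  k <- 0L
  for (i in 1:3) for (j in 1:3) {
    k <- k + 1L
    out[k] <- mean(v[(rb[i] + 1L):rb[i + 1L], (cb[j] + 1L):cb[j + 1L]])
  }
  names(out) <- paste0("grid_v_", rep(1:3, each = 3L), rep(1:3, 3L))
  out
}

#' Feature-extraction configuration
#'
#' Bundles every tunable parameter of the 109-feature extractor so that a
#' run is reproducible from its configuration and seed alone.
#'
#' @param K k-means cluster count for the segmentation features.
#' @param margin focus-region widening `mu`.
#' @param mass histogram mass for the brightness-contrast window.
#' @param wavelet wavelet family for the texture energies.
#' @param wavelet_levels decomposition depth.
#' @param range_windows odd window sides for the local texture range.
#' @param edge_fractions energy fractions for the edge-energy bounding
#'   boxes.
#' @param profile_grid side of the edge-profile comparison grid.
#' @param top_segments number of connected regions described individually.
#' @param connectivity 4 or 8 adjacency for connected components.
#' @param hue_bins,hue_sat_min,hue_val_min,hue_alpha hue-count parameters.
#' @param color_models reference colour-model registry
#'   (default [default_color_models()]).
#' @param edge_profiles reference edge profiles
#'   (default [default_edge_profiles()] on `profile_grid`).
#' @param seed RNG seed for the seeded sub-steps (k-means initialisation).
#' @param pre_resize optional `c(h, w)`: resize every image to a common
#'   resolution before extraction (off by default; features are otherwise
#'   computed at native resolution).
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(K = 2L, margin = 0.1, mass = 0.98,
                           wavelet = "db1", wavelet_levels = 3L,
                           range_windows = c(3L, 5L, 7L),
                           edge_fractions = c(0.81, 0.9604),
                           profile_grid = 100L, top_segments = 5L,
                           connectivity = 8L, hue_bins = 20L,
                           hue_sat_min = 0.2, hue_val_min = 0.15,
                           hue_alpha = 0.05,
                           color_models = default_color_models(),
                           edge_profiles = default_edge_profiles(profile_grid),
                           seed = 1L, pre_resize = NULL) {
  structure(as.list(environment()), class = "feature_config")
}

#' The 109-feature registry
#'
#' Single source of truth for the aesthetic feature vector: feature ids
#' `f1..f109`, stable names, the group each feature belongs to (`color`,
#' `texture` or `objects`), the package operation that computes it and a
#' short parameter note. [extract_features()] emits values in exactly this
#' order.
#'
#' @return A data.frame with 109 rows and columns `id`, `name`, `group`,
#'   `operation`, `parameters`.
#' @export
feature_registry <- function() {
  row <- function(name, group, operation, parameters = "") {
    data.frame(name = name, group = group, operation = operation,
               parameters = parameters, stringsAsFactors = FALSE)
  }
  rows <- list(
    # -- colour and brightness of the whole image ------------------------
    row(paste0("mean_", c("r", "g", "b")), "color", "channel_moments"),
    row(paste0("sd_", c("r", "g", "b")), "color", "channel_moments"),
    row(paste0("entropy_", c("r", "g", "b")), "color", "channel_entropy",
        "256 bins"),
    row(paste0("mean_", c("h", "s", "v")), "color", "channel_moments"),
    row(paste0("sd_", c("h", "s", "v")), "color", "channel_moments"),
    row(paste0("entropy_", c("h", "s", "v")), "color", "channel_entropy",
        "256 bins"),
    row("brightness_arith", "color", "brightness_means"),
    row("brightness_log", "color", "brightness_means", "delta = 1/255"),
    row("brightness_contrast", "color", "brightness_contrast",
        "mass = 0.98, 0-255 scale"),
    row("colorfulness", "color", "colorfulness", "opponent-space"),
    row("hue_count", "color", "hue_count", "20 bins, alpha = 0.05"),
    row("hue_modal_fraction", "color", "hue_modal_fraction", "20 bins"),
    row("entropy_gray", "color", "channel_entropy", "luminance"),
    row("color_model_index", "color", "color_model_match", "L1, 4x4x4"),
    row("color_model_score", "color", "color_model_match", "L1, 4x4x4"),
    # -- texture of the whole image --------------------------------------
    row(as.vector(t(outer(c("h", "s", "v"), c("l1", "l2", "l3", "sum"),
                          function(a, b) paste0("w_", a, "_", b)))),
        "texture", "wavelet_features", "Haar, 3 levels"),
    row(c("tex_range_mean_w3", "tex_range_sd_w3"), "texture",
        "texture_range", "window 3"),
    row(c("tex_range_mean_w5", "tex_range_sd_w5"), "texture",
        "texture_range", "window 5"),
    row(c("tex_range_mean_w7", "tex_range_sd_w7"), "texture",
        "texture_range", "window 7"),
    row("smoothness", "texture", "smoothness"),
    row("laplacian_sd", "texture", "laplacian_edge_map", "sd of |lap|"),
    # -- discernable objects and composition -----------------------------
    row("edge_energy_mean", "objects", "laplacian_edge_map", "mean |lap|"),
    row("edge_similarity", "objects", "edge_distribution_similarity",
        "100x100 grid"),
    row(c("edge_box_area_81", "edge_box_area_96"), "objects",
        "edge_energy_box", "fractions 0.81, 0.9604"),
    row(c("focus_mean_v", "focus_mean_s", "focus_mean_h", "focus_sd_v"),
        "objects", "focus_region_stats", "margin mu = 0.1"),
    row("n_components", "objects", "connected_components", "8-adjacency"),
    row("n_clusters", "objects", "kmeans_segment", "K = 2"),
    row(paste0("cluster", rep(1:2, each = 4L), "_",
               rep(c("size", "r", "g", "b"), 2L)),
        "objects", "kmeans_segment", "K = 2"),
    row(paste0("seg", rep(1:5, each = 7L), "_",
               rep(c("rel_area", "centroid_r", "centroid_c",
                     "mean_h", "mean_s", "mean_v", "brightness_log"), 5L)),
        "objects", "segment_statistics", "top 5 regions"),
    row(paste0("grid_v_", rep(1:3, each = 3L), rep(1:3, 3L)),
        "objects", "thirds_grid_means", "3x3 thirds grid")
  )
  out <- do.call(rbind, rows)
  out <- cbind(id = paste0("f", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}

#' Extract the full aesthetic feature vector
#'
#' Computes all 109 registry features for one image. The result is
#' deterministic given the image, the configuration and its seed, and
#' every value is finite: degenerate inputs fall back to documented
#' defaults (a featureless all-zero edge map yields bounding-box area 1
#' and edge similarity 0; regions beyond those present are zero-padded).
#'
#' @param img a [raster_image] (or array accepted by [raster_image()]).
#' @param config a [feature_config()].
#' @return Named numeric vector of length 109 (names and order from
#'   [feature_registry()]), with a `groups` attribute carrying the group
#'   tag of each entry.
#' @export
extract_features <- function(img, config = feature_config()) {
  img <- as_raster_image(img)
  if (!is.null(config$pre_resize))
    img <- as_raster_image(resize_image(img, config$pre_resize[1L],
                                        config$pre_resize[2L]))
  hsv <- rgb_to_hsv_image(img)
  vch <- hsv$v

  mom <- channel_moments(img, hsv)
  ent <- vapply(c("R", "G", "B"), function(ch) channel_entropy(img, ch),
                numeric(1L))
  ent_hsv <- vapply(c("h", "s", "v"),
                    function(ch) channel_entropy(hsv[[ch]]), numeric(1L))
  bm <- brightness_means(img)
  cm <- color_model_match(img, config$color_models)

  col_feats <- c(
    mom[c("mean_r", "mean_g", "mean_b")],
    mom[c("sd_r", "sd_g", "sd_b")],
    entropy_r = ent[["R"]], entropy_g = ent[["G"]], entropy_b = ent[["B"]],
    mom[c("mean_h", "mean_s", "mean_v")],
    mom[c("sd_h", "sd_s", "sd_v")],
    entropy_h = ent_hsv[[1L]], entropy_s = ent_hsv[[2L]],
    entropy_v = ent_hsv[[3L]],
    brightness_arith = bm[["arith"]], brightness_log = bm[["log"]],
    brightness_contrast = brightness_contrast(img, config$mass),
    colorfulness = colorfulness(img),
    hue_count = hue_count(hsv, config$hue_sat_min, config$hue_val_min,
                          config$hue_bins, config$hue_alpha),
    hue_modal_fraction = hue_modal_fraction(hsv, config$hue_sat_min,
                                            config$hue_val_min,
                                            config$hue_bins),
    entropy_gray = channel_entropy(gray_channel(img)),
    color_model_index = cm$index, color_model_score = cm$score
  )

  wav <- wavelet_features(hsv, config$wavelet_levels, config$wavelet)
  tex <- unlist(lapply(config$range_windows, function(w) {
    tr <- texture_range(vch, w)
    stats::setNames(tr, paste0("tex_range_", c("mean", "sd"), "_w", w))
  }))
  edges <- laplacian_edge_map(vch)
  tex_feats <- c(wav, tex, smoothness = 1 - mean(edges),
                 laplacian_sd = stats::sd(as.vector(edges)))

  has_energy <- sum(edges) > 0
  box_areas <- vapply(config$edge_fractions, function(f) {
    if (has_energy) edge_energy_box(edges, f)$area_fraction else 1.0
  }, numeric(1L))
  sim <- if (has_energy)
    edge_distribution_similarity(edges, config$edge_profiles,
                                 config$profile_grid) else 0.0

  region <- thirds_focus_region(img$height, img$width, config$margin)
  foc <- focus_region_stats(img, region, hsv)

  seg <- kmeans_segment(img, K = config$K, seed = config$seed)
  ncomp <- connected_components(seg, config$connectivity)
  cl <- matrix(0, 2L, 4L)
  for (i in seq_len(min(2L, seg$K)))
    cl[i, ] <- c(seg$sizes[i] / (img$height * img$width), seg$centers[i, ])
  segstats <- segment_statistics(img, seg, config$top_segments,
                                 config$connectivity)

  obj_feats <- c(
    edge_energy_mean = mean(edges),
    edge_similarity = sim,
    edge_box_area_81 = box_areas[1L], edge_box_area_96 = box_areas[2L],
    focus_mean_v = foc[["mean_v"]], focus_mean_s = foc[["mean_s"]],
    focus_mean_h = foc[["mean_h"]], focus_sd_v = foc[["sd_v"]],
    n_components = ncomp, n_clusters = seg$K,
    stats::setNames(as.vector(t(cl)),
                    paste0("cluster", rep(1:2, each = 4L), "_",
                           rep(c("size", "r", "g", "b"), 2L))),
    stats::setNames(as.vector(t(as.matrix(segstats))),
                    paste0("seg", rep(1:5, each = 7L), "_",
                           rep(colnames(segstats), 5L))),
    thirds_grid_means(vch)
  )

  reg <- feature_registry()
  out <- c(col_feats, tex_feats, obj_feats)
  if (!identical(unname(names(out)), reg$name))
    stop("internal error: extracted features do not match the registry")
  if (!all(is.finite(out)))
    stop("non-finite feature value(s): ",
         paste(names(out)[!is.finite(out)], collapse = ", "))
  attr(out, "groups") <- reg$group
  out
}

#' Extract a feature matrix for a set of images
#'
#' Runs [extract_features()] over a manifest of images (or an in-memory
#' list) and returns a feature matrix with one row per image, the 109
#' registry columns, and the site metadata used by the calibration step.
#'
#' @param x either a data.frame manifest with columns `image_path`,
#'   `site_id`, `site_score`, or a list of [raster_image] objects.
#' @param config a [feature_config()].
#' @param site_id,site_score site metadata, required when `x` is a list.
#' @return A data.frame: columns `image_id`, `site_id`, `site_score`
#'   followed by the 109 features.
#' @export
extract_feature_matrix <- function(x, config = feature_config(),
                                   site_id = NULL, site_score = NULL) {
  if (is.data.frame(x)) {
    need <- c("image_path", "site_id", "site_score")
    if (!all(need %in% names(x)))
      stop("manifest must have columns ", paste(need, collapse = ", "))
    imgs <- lapply(x$image_path, load_image)
    ids <- basename(x$image_path)
    site_id <- x$site_id
    site_score <- x$site_score
  } else {
    imgs <- lapply(x, as_raster_image)
    ids <- sprintf("img%04d", seq_along(imgs))
    if (is.null(site_id) || is.null(site_score))
      stop("`site_id` and `site_score` are required for image lists")
  }
  feats <- t(vapply(imgs, extract_features, numeric(109L), config = config))
  cbind(
    data.frame(image_id = ids, site_id = as.character(site_id),
               site_score = as.numeric(site_score),
               stringsAsFactors = FALSE),
    as.data.frame(feats)
  )
}

# Split a feature-matrix data.frame into metadata and the numeric
# 109-column feature block (column order enforced by the registry).
feature_columns <- function(fm) {
  reg <- feature_registry()
  missing <- setdiff(reg$name, names(fm))
  if (length(missing) > 0L)
    stop("feature matrix lacks registry column(s): ",
         paste(utils::head(missing, 5L), collapse = ", "))
  as.matrix(fm[, reg$name, drop = FALSE])
}

#' Export the registry as JSON
#'
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_registry_json <- function(path) {
  jsonlite::write_json(feature_registry(), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
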