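#' Arithmetic and logarithmic average brightness
#'
#' Brightness is the HSV value channel. The logarithmic (geometric-style)
#' average is computed as `exp(mean(log(V + delta))) - delta` with a small
#' guard `delta = 1/255` against `log(0)`; by the AM-GM inequality it never
#' exceeds the arithmetic mean.
#'
#' @param img a [raster_image].
#' @param delta guard added inside the logarithm; default `1/255`
#'   (one 8-bit quantisation step).
#' @return Named numeric vector with elements `arith` and `log`, both in
#'   `[0, 1]`.
#' @export
brightness_means <- function(img, delta = 1 / 255) {
  v <- value_channel(img)
  c(arith = mean(v), log = exp(mean(log(v + delta))) - delta)
}

# 256-bin histogram of a [0,1] channel quantised to 8-bit levels 0..255.
quantize256 <- function(channel) {
  lev <- as.integer(round(channel * 255))
  tabulate(lev + 1L, nbins = 256L)
}

#' Brightness contrast (histogram-mass width)
#'
#' Width, in 0--255 gray levels, of the smallest contiguous window of the
#' 256-bin value-channel histogram that holds at least `mass` of the pixel
#' count. A constant image scores 0; an image split between black and white
#' scores 255. Reported on the 8-bit scale to match the conventional
#' magnitudes of this statistic.
#'
#' @param img a [raster_image].
#' @param mass fraction of pixel mass the window must contain, in `(0, 1]`.
#' @return Integer-valued width in `[0, 255]`.
#' @export
brightness_contrast <- function(img, mass = 0.98) {
  if (mass <= 0 || mass > 1) stop("`mass` must lie in (0, 1]")
  h <- quantize256(value_channel(img))
  need <- mass * sum(h)
  # two-pointer scan over contiguous windows
  best <- 255L
  lo <- 1L
  acc <- 0
  for (hi in 1:256) {
    acc <- acc + h[hi]
    while (acc - h[lo] >= need && lo < hi) {
      acc <- acc - h[lo]
      lo <- lo + 1L
    }
    if (acc >= need) best <- min(best, hi - lo)
  }
  as.integer(best)
}

#' Channel means of an HSV image
#'
#' Arithmetic means of the hue, saturation and value channels. Hue is
#' averaged arithmetically on `[0, 1)` (not circularly), following the
#' convention of the photographic-aesthetics feature sets this package
#' implements; see the methods vignette for the caveat.
#'
#' @param hsv an `hsv_image` (see [rgb_to_hsv_image()]) or a
#'   [raster_image], converted on the fly.
#' @return Named numeric vector `c(h = , s = , v = )` in `[0, 1]`.
#' @export
hsv_means <- function(hsv) {
  hsv <- as_hsv_image(hsv)
  c(h = mean(hsv$h), s = mean(hsv$s), v = mean(hsv$v))
}

#' Shannon entropy of an intensity channel
#'
#' Entropy in bits of the 256-bin histogram of the selected channel
#' (`0 log 0 = 0`), between 0 (constant) and 8 (uniform over all levels).
#' The blue-channel entropy is one of the most informative colour features
#' for reef imagery: clear water scatters a wide range of blues.
#'
#' @param img a [raster_image] (for `"R"`, `"G"`, `"B"`) and/or an object
#'   accepted by [rgb_to_hsv_image()] (for `"H"`, `"S"`, `"V"`); a plain
#'   matrix in `[0,1]` may be passed with `channel = "gray"`.
#' @param channel one of `"R"`, `"G"`, `"B"`, `"H"`, `"S"`, `"V"`, `"gray"`.
#' @return Entropy in bits, in `[0, 8]`.
#' @export
channel_entropy <- function(img, channel = "B") {
  ch <- if (is.matrix(img) || channel == "gray") {
    if (is.matrix(img)) img else gray_channel(img)
  } else if (channel %in% c("R", "G", "B")) {
    as_raster_image(img)$pixels[, , match(channel, c("R", "G", "B"))]
  } else if (channel %in% c("H", "S", "V")) {
    as_hsv_image(img)[[tolower(channel)]]
  } else {
    stop("unknown channel '", channel, "'")
  }
  p <- quantize256(ch)
  p <- p[p > 0] / sum(p)
  -sum(p * log2(p))
}

gray_channel <- function(img) {
  p <- as_raster_image(img)$pixels
  0.299 * p[, , 1L] + 0.587 * p[, , 2L] + 0.114 * p[, , 3L]
}

#' Opponent-space colourfulness
#'
#' Dispersion-based colourfulness of Hasler and Suesstrunk: with opponent
#' channels `rg = R - G` and `yb = (R + G)/2 - B`,
#' `C = sqrt(sd(rg)^2 + sd(yb)^2) + 0.3 * sqrt(mean(rg)^2 + mean(yb)^2)`
#' (population standard deviations). Any gray image scores exactly 0.
#'
#' @param img a [raster_image].
#' @return Non-negative colourfulness score (channels on `[0, 1]`).
#' @export
colorfulness <- function(img) {
  p <- as_raster_image(img)$pixels
  rg <- p[, , 1L] - p[, , 2L]
  yb <- (p[, , 1L] + p[, , 2L]) / 2 - p[, , 3L]
  pop_var <- function(x) mean((x - mean(x))^2)
  sqrt(pop_var(rg) + pop_var(yb)) + 0.3 * sqrt(mean(rg)^2 + mean(yb)^2)
}

# Hue histogram over sufficiently saturated, sufficiently bright pixels.
hue_histogram <- function(hsv, sat_min, val_min, bin_count) {
  keep <- hsv$s > sat_min & hsv$v > val_min
  if (!any(keep)) return(integer(bin_count))
  bins <- pmin(floor(hsv$h[keep] * bin_count), bin_count - 1L)
  tabulate(bins + 1L, nbins = bin_count)
}

#' Number of distinct hues
#'
#' Counts bins of the hue histogram (over pixels passing saturation and
#' value thresholds) whose count exceeds `alpha` times the maximal bin
#' count — a standard measure of colour diversity. Returns 0 when no pixel
#' is chromatic enough.
#'
#' @param hsv an `hsv_image` or [raster_image].
#' @param sat_min,val_min thresholds a pixel must exceed to be counted.
#' @param bin_count number of hue bins.
#' @param alpha fraction of the modal bin a bin must exceed to count.
#' @return Integer hue count in `[0, bin_count]`.
#' @export
hue_count <- function(hsv, sat_min = 0.2, val_min = 0.15, bin_count = 20L,
                      alpha = 0.05) {
  hsv <- as_hsv_image(hsv)
  hh <- hue_histogram(hsv, sat_min, val_min, bin_count)
  if (sum(hh) == 0L) return(0L)
  sum(hh > alpha * max(hh))
}

# Fraction of chromatic pixels falling in the modal hue bin (0 if none).
hue_modal_fraction <- function(hsv, sat_min = 0.2, val_min = 0.15,
                               bin_count = 20L) {
  hsv <- as_hsv_image(hsv)
  hh <- hue_histogram(hsv, sat_min, val_min, bin_count)
  if (sum(hh) == 0L) return(0) else max(hh) / sum(hh)
}

#' Quantised RGB histogram
#'
#' Normalised histogram over a `bins^3` quantisation of RGB space (default
#' 4 x 4 x 4 = 64 cells), the representation used to compare images against
#' reference colour models.
#'
#' @param img a [raster_image].
#' @param bins quantisation level per channel.
#' @return Numeric vector of length `bins^3` summing to 1; cell order is
#'   R fastest, then G, then B.
#' @export
rgb_histogram <- function(img, bins = 4L) {
  p <- as_raster_image(img)$pixels
  q <- function(ch) pmin(floor(ch * bins), bins - 1L)
  idx <- q(p[, , 1L]) + bins * q(p[, , 2L]) + bins^2 * q(p[, , 3L])
  h <- tabulate(as.integer(idx) + 1L, nbins = bins^3)
  h / sum(h)
}

#' Match an image against reference colour models
#'
#' Compares the image's quantised RGB histogram against each model
#' histogram by L1 distance and returns the best (smallest-distance) model.
#' Ties are broken toward the lowest index. The reference models are a
#' user-supplied registry (see [default_color_models()] for the synthetic
#' palettes shipped with the package, and [read_color_models()] /
#' [write_color_models()] for the JSON exchange format).
#'
#' @param img a [raster_image].
#' @param models a list of colour models, each a list with elements
#'   `name`, `histogram` (numeric, one value per RGB cell, summing to 1)
#'   and optional `metadata`.
#' @return List with `index` (1-based model index), `name`, and `score`
#'   (the L1 distance; 0 for a perfect match).
#' @export
color_model_match <- function(img, models) {
  if (length(models) == 0L) stop("`models` must contain at least one model")
  hist_img <- rgb_histogram(img, bins = round(length(models[[1L]]$histogram)^(1 / 3)))
  d <- vapply(models, function(m) {
    if (length(m$histogram) != length(hist_img))
      stop("model '", m$name, "' histogram length mismatch")
    sum(abs(m$histogram - hist_img))
  }, numeric(1L))
  i <- which.min(d)   # which.min takes the first minimum: lowest index wins
  list(index = i, name = models[[i]]$name, score = d[i])
}

#' Default reference colour models
#'
#' A small registry of synthetic reference palettes constructed in code
#' (the original reference models are not distributable): a blue/brown/pink
#' weighted "healthy reef" palette, a green/gray "turf and sediment"
#' palette, and a dark low-chroma "degraded" palette. Each model is built
#' by histogramming a constructed palette image, so the histograms are
#' valid distributions by construction. The `metadata$reference_score`
#' field is user-editable metadata, not a calibrated quantity.
#'
#' @param bins RGB quantisation per channel.
#' @return A list of colour models suitable for [color_model_match()].
#' @export
default_color_models <- function(bins = 4L) {
  palette_hist <- function(colors, weights) {
    # weights: relative area of each colour patch
    n <- pmax(1L, round(weights / sum(weights) * 4096))
    rgbm <- t(grDevices::col2rgb(rep(colors, n))) / 255
    q <- function(ch) pmin(floor(ch * bins), bins - 1L)
    idx <- q(rgbm[, 1L]) + bins * q(rgbm[, 2L]) + bins^2 * q(rgbm[, 3L])
    h <- tabulate(as.integer(idx) + 1L, nbins = bins^3)
    h / sum(h)
  }
  list(
    list(name = "healthy_reef",
         histogram = palette_hist(
           c("#1060B0", "#2080D0", "#8B5A2B", "#E890B0", "#F0C040"),
           c(3, 3, 2, 1.5, 0.5)),
         metadata = list(synthetic = TRUE, reference_score = 5)),
    list(name = "turf_sediment",
         histogram = palette_hist(
           c("#4E6B3A", "#6E7B5A", "#909080", "#607048"),
           c(3, 3, 2, 2)),
         metadata = list(synthetic = TRUE, reference_score = 30)),
    list(name = "degraded_dark",
         histogram = palette_hist(
           c("#303830", "#404840", "#585850", "#282830"),
           c(3, 3, 2, 2)),
         metadata = list(synthetic = TRUE, reference_score = 45))
  )
}

#' Read / write a colour-model registry (JSON)
#'
#' @param path JSON file holding a list of `{name, histogram, metadata}`
#'   records.
#' @return `read_color_models()` returns the model list;
#'   `write_color_models()` returns `path` invisibly.
#' @export
read_color_models <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  lapply(raw, function(m) {
    m$histogram <- as.numeric(m$histogram)
    m
  })
}

#' @rdname read_color_models
#' @param models a colour-model list.
#' @export
write_color_models <- function(models, path) {
  jsonlite::write_json(models, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
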