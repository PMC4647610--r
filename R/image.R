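#' Raster image container
#'
#' All feature extractors in reefscore consume a `raster_image`: an
#' `H x W x 3` numeric array of RGB intensities on `[0, 1]`. Images must be
#' at least 16 x 16 pixels so that the three-level wavelet decomposition and
#' the rule-of-thirds grid are well defined.
#'
#' @param pixels numeric array, either `H x W x 3` (RGB), `H x W` or
#'   `H x W x 1` (grayscale, replicated to three channels), or `H x W x 4`
#'   (RGBA; the alpha channel is dropped).
#' @param source_path optional character path recording where the pixels
#'   came from.
#' @return An object of class `raster_image`: a list with elements
#'   `pixels` (`H x W x 3` array in `[0,1]`), `height`, `width` and
#'   `source_path`.
#' @examples
#' img <- raster_image(array(runif(32 * 32 * 3), c(32, 32, 3)))
#' img
#' @export
raster_image <- function(pixels, source_path = NULL) {
  if (is.matrix(pixels)) pixels <- array(pixels, c(dim(pixels), 1L))
  if (!is.array(pixels) || length(dim(pixels)) != 3L)
    stop("`pixels` must be an H x W x C array or an H x W matrix")
  nc <- dim(pixels)[3L]
  if (nc == 1L) {
    pixels <- array(rep(pixels, 3L), c(dim(pixels)[1:2], 3L))
  } else if (nc == 4L) {
    pixels <- pixels[, , 1:3, drop = FALSE]
  } else if (nc != 3L) {
    stop("unsupported channel count: ", nc)
  }
  if (!all(is.finite(pixels)))
    stop("image intensities must be finite")
  if (min(pixels) < 0 || max(pixels) > 1)
    stop("image intensities must lie in [0, 1]")
  h <- dim(pixels)[1L]; w <- dim(pixels)[2L]
  if (h < 16L || w < 16L)
    stop("image too small: need at least 16 x 16 pixels, got ", h, " x ", w)
  structure(
    list(pixels = pixels, height = h, width = w,
         source_path = source_path),
    class = "raster_image"
  )
}

#' @export
print.raster_image <- function(x, ...) {
  cat(sprintf("<raster_image %d x %d px", x$height, x$width))
  if (!is.null(x$source_path)) cat(", ", x$source_path, sep = "")
  cat(">\n")
  invisible(x)
}

#' @export
dim.raster_image <- function(x) c(x$height, x$width, 3L)

as_raster_image <- function(x) {
  if (inherits(x, "raster_image")) x else raster_image(x)
}

#' Load a raster image from disk
#'
#' Reads an 8-bit RGB raster (PNG, JPEG or TIFF, chosen by file extension)
#' and scales intensities to `[0, 1]` (8-bit values are divided by 255).
#' Grayscale images are replicated to three channels and alpha channels are
#' dropped.
#'
#' @param path path to a `.png`, `.jpg`/`.jpeg`, `.tif`/`.tiff` file.
#' @return A [raster_image].
#' @seealso [save_image()] for the PNG writer used for fixtures.
#' @export
load_image <- function(path) {
  if (!is.character(path) || length(path) != 1L)
    stop("`path` must be a single file path")
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png  = png::readPNG(path),
    jpg  = ,
    jpeg = jpeg::readJPEG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '.", ext,
         "': expected png, jpeg or tiff")
  )
  if (!is.numeric(px)) stop("could not decode raster data from ", path)
  raster_image(px, source_path = path)
}

#' Write an image as PNG
#'
#' @param img a [raster_image] (or bare array accepted by [raster_image()]).
#' @param path output path; the containing directory must exist.
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path) {
  img <- as_raster_image(img)
  png::writePNG(img$pixels, target = path)
  invisible(path)
}

#' Convert RGB to HSV
#'
#' Standard hexcone transform. Hue is normalised to `[0, 1)` and defined as
#' 0 for achromatic pixels; saturation and value lie in `[0, 1]`. The value
#' channel `V = max(R, G, B)` is the brightness surface used throughout the
#' texture and composition features.
#'
#' @param img a [raster_image].
#' @return An object of class `hsv_image`: a list of three `H x W`
#'   matrices `h`, `s`, `v`.
#' @export
rgb_to_hsv_image <- function(img) {
  img <- as_raster_image(img)
  p <- img$pixels
  m <- grDevices::rgb2hsv(
    rbind(as.vector(p[, , 1L]), as.vector(p[, , 2L]), as.vector(p[, , 3L])),
    maxColorValue = 1
  )
  shape <- c(img$height, img$width)
  structure(
    list(h = matrix(m[1L, ], shape[1L], shape[2L]) %% 1,
         s = matrix(m[2L, ], shape[1L], shape[2L]),
         v = matrix(m[3L, ], shape[1L], shape[2L])),
    class = "hsv_image"
  )
}

#' @export
print.hsv_image <- function(x, ...) {
  cat(sprintf("<hsv_image %d x %d px>\n", nrow(x$v), ncol(x$v)))
  invisible(x)
}

as_hsv_image <- function(x) {
  if (inherits(x, "hsv_image")) x else rgb_to_hsv_image(x)
}

# Value (brightness) channel of an image: max over RGB.
value_channel <- function(img) {
  p <- as_raster_image(img)$pixels
  pmax(p[, , 1L], p[, , 2L], p[, , 3L])
}

# Bilinear 1-D interpolation matrix mapping n_src samples to n_dst, using
# the half-pixel-centre convention (dst centre i+0.5 maps to
# src coordinate (i+0.5)*n_src/n_dst, clamped to the sample range).
bilinear_matrix <- function(n_src, n_dst) {
  ctr <- ((seq_len(n_dst) - 0.5) * n_src / n_dst) - 0.5
  ctr <- pmin(pmax(ctr, 0), n_src - 1)
  lo <- floor(ctr)
  hi <- pmin(lo + 1, n_src - 1)
  whi <- ctr - lo
  A <- matrix(0, n_dst, n_src)
  idx <- seq_len(n_dst)
  A[cbind(idx, lo + 1)] <- A[cbind(idx, lo + 1)] + (1 - whi)
  A[cbind(idx, hi + 1)] <- A[cbind(idx, hi + 1)] + whi
  A
}

#' Resize an image with bilinear interpolation
#'
#' Uses the half-pixel-centre sampling convention, so an aligned 2x
#' downscale averages 2x2 blocks exactly. Used internally to bring the
#' Laplacian edge map onto the fixed comparison grid.
#'
#' @param img a [raster_image] or a plain matrix (single channel).
#' @param target_h,target_w positive integer output dimensions.
#' @return A resized object of the same kind as the input (`raster_image`
#'   in, `raster_image` out; matrix in, matrix out). Note a resized
#'   `raster_image` below 16 px a side is returned as a bare array.
#' @export
resize_image <- function(img, target_h, target_w) {
  if (target_h < 1 || target_w < 1)
    stop("target dimensions must be positive")
  resize1 <- function(m) {
    A <- bilinear_matrix(nrow(m), target_h)
    B <- bilinear_matrix(ncol(m), target_w)
    A %*% m %*% t(B)
  }
  if (is.matrix(img)) return(resize1(img))
  img <- as_raster_image(img)
  out <- array(0, c(target_h, target_w, 3L))
  for (k in 1:3) out[, , k] <- resize1(img$pixels[, , k])
  out <- pmin(pmax(out, 0), 1)
  if (target_h >= 16 && target_w >= 16) raster_image(out) else out
}
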