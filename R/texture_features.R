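# One level of the 2-D orthonormal Haar transform. Odd dimensions are
# symmetrically padded (last row/column repeated) before pairing.
haar_level <- function(m) {
  if (nrow(m) %% 2L == 1L) m <- rbind(m, m[nrow(m), ])
  if (ncol(m) %% 2L == 1L) m <- cbind(m, m[, ncol(m)])
  ro <- m[seq(1L, nrow(m), 2L), , drop = FALSE]
  re <- m[seq(2L, nrow(m), 2L), , drop = FALSE]
  rl <- (ro + re) / sqrt(2)   # row lowpass
  rh <- (ro - re) / sqrt(2)   # row highpass
  cl <- function(x) (x[, seq(1L, ncol(x), 2L), drop = FALSE] +
                     x[, seq(2L, ncol(x), 2L), drop = FALSE]) / sqrt(2)
  ch <- function(x) (x[, seq(1L, ncol(x), 2L), drop = FALSE] -
                     x[, seq(2L, ncol(x), 2L), drop = FALSE]) / sqrt(2)
  list(cA = cl(rl), cH = ch(rl), cV = cl(rh), cD = ch(rh))
}

#' Multi-level wavelet detail energies
#'
#' Three-level 2-D Haar (db1) decomposition of each HSV channel. The
#' level-k feature is the mean absolute detail coefficient over the three
#' orientation subbands at that level,
#' `(sum|cH| + sum|cV| + sum|cD|) / n_coefficients`; per-channel sums
#' across levels are appended. All twelve values are non-negative, zero
#' for a constant image, and scale linearly with channel contrast.
#'
#' @param hsv an `hsv_image` (see [rgb_to_hsv_image()]) or an object
#'   convertible to one.
#' @param levels decomposition depth; image sides must be at least
#'   `2^levels`.
#' @param wavelet wavelet family; only the Haar wavelet (`"db1"`/
#'   `"haar"`), the default of the aesthetics feature sets this package
#'   follows, is provided.
#' @return Named numeric vector of length `4 * 3`: `w_<ch>_l<k>` for
#'   channels `h`, `s`, `v` and levels 1..`levels`, plus `w_<ch>_sum`.
#' @export
wavelet_features <- function(hsv, levels = 3L, wavelet = "db1") {
  if (!wavelet %in% c("db1", "haar"))
    stop("only the Haar ('db1') wavelet is implemented")
  hsv <- as_hsv_image(hsv)
  if (min(nrow(hsv$v), ncol(hsv$v)) < 2^levels)
    stop("image too small for a ", levels, "-level wavelet decomposition")
  out <- numeric(0)
  for (ch in c("h", "s", "v")) {
    m <- hsv[[ch]]
    vals <- numeric(levels)
    for (k in seq_len(levels)) {
      d <- haar_level(m)
      vals[k] <- (sum(abs(d$cH)) + sum(abs(d$cV)) + sum(abs(d$cD))) /
        (3 * length(d$cH))
      m <- d$cA
    }
    v <- c(vals, sum(vals))
    names(v) <- c(paste0("w_", ch, "_l", seq_len(levels)),
                  paste0("w_", ch, "_sum"))
    out <- c(out, v)
  }
  out
}

#' Local texture range
#'
#' Per-pixel local range (max - min) of the value channel over a sliding
#' odd-sided window with edge-replicating borders, summarised by its mean
#' and standard deviation. Smooth, biofilm-covered surfaces score near 0;
#' crisp structured textures score high.
#'
#' @param img a [raster_image] or a `[0,1]` matrix.
#' @param window odd window side, at least 3.
#' @return Named numeric vector `c(mean = , sd = )`.
#' @export
texture_range <- function(img, window = 3L) {
  if (window < 3L || window %% 2L == 0L)
    stop("`window` must be an odd integer >= 3")
  v <- if (is.matrix(img)) img else value_channel(img)
  r <- (window - 1L) %/% 2L
  h <- nrow(v); w <- ncol(v)
  pad_idx <- function(n) pmin(pmax(seq(1L - r, n + r), 1L), n)
  vp <- v[pad_idx(h), pad_idx(w)]
  mx <- matrix(-Inf, h, w); mn <- matrix(Inf, h, w)
  for (dr in 0:(window - 1L)) {
    for (dc in 0:(window - 1L)) {
      blk <- vp[dr + seq_len(h), dc + seq_len(w)]
      mx <- pmax(mx, blk); mn <- pmin(mn, blk)
    }
  }
  rng <- mx - mn
  c(mean = mean(rng), sd = stats::sd(as.vector(rng)))
}

#' Surface smoothness
#'
#' `1 - mean(|Laplacian|)` of the value channel: close to 1 for smooth
#' (possibly degraded, slime-covered) surfaces, lower for images rich in
#' fine boundaries.
#'
#' @param img a [raster_image] or a `[0,1]` matrix.
#' @return Smoothness, at most 1.
#' @export
smoothness <- function(img) {
  1 - mean(laplacian_edge_map(img))
}
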