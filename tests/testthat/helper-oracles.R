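# Independent brute-force oracles. These deliberately use naive loops and
# constructions distinct from the package's vectorised implementations.

# Shannon entropy (bits) of an 8-bit-quantised [0,1] channel.
oracle_entropy <- function(channel) {
  lev <- as.integer(round(as.vector(channel) * 255))
  counts <- rep(0L, 256L)
  for (l in lev) counts[l + 1L] <- counts[l + 1L] + 1L
  p <- counts[counts > 0L] / length(lev)
  e <- 0
  for (pi in p) e <- e - pi * log2(pi)
  e
}

# Smallest contiguous 256-bin histogram window holding >= mass of the
# pixels, by exhaustive search over window widths via cumulative sums.
oracle_contrast <- function(vchannel, mass = 0.98) {
  lev <- as.integer(round(as.vector(vchannel) * 255))
  h <- rep(0L, 256L)
  for (l in lev) h[l + 1L] <- h[l + 1L] + 1L
  need <- mass * length(lev)
  S <- c(0, cumsum(h))
  for (width in 0:255) {
    starts <- 1:(256 - width)
    sums <- S[starts + width + 1L] - S[starts]
    if (max(sums) >= need) return(width)
  }
  255L
}

# Per-pixel hexcone RGB -> HSV.
oracle_hsv_pixel <- function(r, g, b) {
  mx <- max(r, g, b); mn <- min(r, g, b); d <- mx - mn
  v <- mx
  s <- if (mx > 0) d / mx else 0
  h <- if (d == 0) 0
  else if (mx == r) ((g - b) / d) %% 6
  else if (mx == g) (b - r) / d + 2
  else (r - g) / d + 4
  c(h = (h / 6) %% 1, s = s, v = v)
}

# Hexcone HSV -> RGB (used to check inverse recovery).
oracle_hsv_to_rgb <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  c <- v * s
  x <- c * (1 - abs(h6 %% 2 - 1))
  m <- v - c
  rgb <- if (h6 < 1) c(c, x, 0) else if (h6 < 2) c(x, c, 0) else
    if (h6 < 3) c(0, c, x) else if (h6 < 4) c(0, x, c) else
      if (h6 < 5) c(x, 0, c) else c(c, 0, x)
  rgb + m
}

# Flood-fill (BFS) connected-component count of an integer label matrix.
oracle_components <- function(labels, connectivity = 8L) {
  h <- nrow(labels); w <- ncol(labels)
  seen <- matrix(FALSE, h, w)
  moves <- if (connectivity == 4L)
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  else
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  n <- 0L
  for (r0 in seq_len(h)) for (c0 in seq_len(w)) {
    if (seen[r0, c0]) next
    n <- n + 1L
    lab <- labels[r0, c0]
    queue <- list(c(r0, c0))
    seen[r0, c0] <- TRUE
    while (length(queue) > 0L) {
      cur <- queue[[1L]]; queue <- queue[-1L]
      for (mv in moves) {
        rr <- cur[1L] + mv[1L]; cc <- cur[2L] + mv[2L]
        if (rr >= 1L && rr <= h && cc >= 1L && cc <= w &&
            !seen[rr, cc] && labels[rr, cc] == lab) {
          seen[rr, cc] <- TRUE
          queue[[length(queue) + 1L]] <- c(rr, cc)
        }
      }
    }
  }
  n
}

# Naive 3x3 four-neighbour Laplacian with edge-replicating borders.
oracle_laplacian <- function(v) {
  h <- nrow(v); w <- ncol(v)
  at <- function(r, c) v[min(max(r, 1L), h), min(max(c, 1L), w)]
  out <- matrix(0, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    out[r, c] <- abs(at(r - 1L, c) + at(r + 1L, c) +
                     at(r, c - 1L) + at(r, c + 1L) - 4 * v[r, c])
  }
  out
}

# Naive sliding-window local range with edge-replicating borders.
oracle_texture_range <- function(v, window) {
  h <- nrow(v); w <- ncol(v); r <- (window - 1L) %/% 2L
  rng <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    rr <- max(1L, i - r):min(h, i + r)
    cc <- max(1L, j - r):min(w, j + r)
    # replicate-padded window: out-of-range samples duplicate edge values,
    # which never change the max or min of the clamped window
    rng[i, j] <- max(v[rr, cc]) - min(v[rr, cc])
  }
  c(mean = mean(rng), sd = stats::sd(as.vector(rng)))
}

# Haar detail energies per level by explicit 2x2 block arithmetic.
oracle_haar_features <- function(m, levels = 3L) {
  vals <- numeric(levels)
  for (k in seq_len(levels)) {
    if (nrow(m) %% 2L == 1L) m <- rbind(m, m[nrow(m), ])
    if (ncol(m) %% 2L == 1L) m <- cbind(m, m[, ncol(m)])
    hh <- nrow(m) %/% 2L; ww <- ncol(m) %/% 2L
    cA <- matrix(0, hh, ww)
    tot <- 0
    for (i in seq_len(hh)) for (j in seq_len(ww)) {
      a <- m[2L * i - 1L, 2L * j - 1L]; b <- m[2L * i - 1L, 2L * j]
      cc <- m[2L * i, 2L * j - 1L]; d <- m[2L * i, 2L * j]
      cA[i, j] <- (a + b + cc + d) / 2
      cH <- (a - b + cc - d) / 2
      cV <- (a + b - cc - d) / 2
      cD <- (a - b - cc + d) / 2
      tot <- tot + abs(cH) + abs(cV) + abs(cD)
    }
    vals[k] <- tot / (3 * hh * ww)
    m <- cA
  }
  vals
}

# Cumulative-marginal check of an edge-energy box: recompute the per-side
# trims directly from marginal cumulative sums.
oracle_box_trims <- function(edges, fraction) {
  tot <- sum(edges)
  slack <- (1 - fraction) / 2 * tot
  bounds <- function(mar) {
    cs <- cumsum(mar)
    lo <- 1L
    while (lo < length(mar) && cs[lo] <= slack) lo <- lo + 1L
    cs_rev <- cumsum(rev(mar))
    hi <- length(mar)
    k <- 1L
    while (hi > lo && cs_rev[k] <= slack) { hi <- hi - 1L; k <- k + 1L }
    c(lo, hi)
  }
  list(rows = bounds(rowSums(edges)), cols = bounds(colSums(edges)))
}

# Random test image helpers.
rand_img <- function(h = 24L, w = 24L, seed = 1L) {
  set.seed(seed)
  raster_image(array(runif(h * w * 3L), c(h, w, 3L)))
}

rand_gray_matrix <- function(h = 8L, w = 8L, seed = 1L) {
  set.seed(seed)
  matrix(runif(h * w), h, w)
}

constant_img <- function(value = 0.5, h = 32L, w = 32L) {
  raster_image(array(value, c(h, w, 3L)))
}
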