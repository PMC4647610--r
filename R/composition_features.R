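# Run expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Rule-of-thirds focus region
#'
#' The central cell of the 3 x 3 thirds grid, optionally widened by a
#' margin `mu` (a fraction of the image side on each edge). With
#' `margin = 0` the region is exactly the central ninth. Bounds are
#' computed as `floor(h * (1/3 - margin))` to `floor(h * (2/3 + margin))`
#' (half-open, 0-based), evaluated with an epsilon guard so the exact
#' rational values are honoured rather than floating-point floor artifacts.
#'
#' @param h,w image dimensions in pixels (at least 3).
#' @param margin widening fraction `mu` in `[0, 1/3)`.
#' @return A `focus_region`: list with 0-based half-open `rows = c(r0, r1)`
#'   and `cols = c(c0, c1)`, and the `margin` used.
#' @export
thirds_focus_region <- function(h, w, margin = 0) {
  if (h < 3 || w < 3) stop("image must be at least 3 x 3 for a thirds grid")
  if (margin < 0 || margin >= 1 / 3)
    stop("`margin` must lie in [0, 1/3): the region would exceed the image")
  eps <- 1e-9
  f <- function(n) c(floor(n * (1 / 3 - margin) + eps),
                     floor(n * (2 / 3 + margin) + eps))
  structure(list(rows = f(h), cols = f(w), margin = margin),
            class = "focus_region")
}

# 1-based row/col index vectors of a focus_region.
region_rows <- function(region) (region$rows[1L] + 1L):region$rows[2L]
region_cols <- function(region) (region$cols[1L] + 1L):region$cols[2L]

#' Brightness of the focus region
#'
#' Mean of the HSV value channel over a [thirds_focus_region()].
#'
#' @param img a [raster_image].
#' @param region a `focus_region`; defaults to the central ninth.
#' @return Mean brightness in `[0, 1]`.
#' @export
focus_brightness <- function(img, region = NULL) {
  img <- as_raster_image(img)
  if (is.null(region)) region <- thirds_focus_region(img$height, img$width)
  mean(value_channel(img)[region_rows(region), region_cols(region)])
}

# Mean hue/saturation/value and value spread inside the focus region.
focus_region_stats <- function(img, region, hsv = NULL) {
  img <- as_raster_image(img)
  if (is.null(hsv)) hsv <- rgb_to_hsv_image(img)
  r <- region_rows(region); cc <- region_cols(region)
  v <- hsv$v[r, cc]
  c(mean_h = mean(hsv$h[r, cc]), mean_s = mean(hsv$s[r, cc]),
    mean_v = mean(v), sd_v = stats::sd(as.vector(v)))
}

# Seeded k-means++ initial centers (Arthur & Vassilvitskii) on an n x d
# matrix; returns k x d matrix of starting centers.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  centers[1L, ] <- x[sample.int(n, 1L), ]
  if (k > 1L) {
    d2 <- rowSums(sweep(x, 2L, centers[1L, ])^2)
    for (j in 2:k) {
      p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[j, ] <- x[sample.int(n, 1L, prob = p), ]
      d2 <- pmin(d2, rowSums(sweep(x, 2L, centers[j, ])^2))
    }
  }
  centers
}

#' K-means colour segmentation
#'
#' Lloyd's algorithm in RGB space with one seeded k-means++
#' initialisation (restarts configurable). Cluster labels are re-ordered
#' by descending cluster size, ties broken toward the darker centre, so
#' downstream per-cluster features are stable under label permutation.
#' If the image has fewer distinct colours than `K`, the occupied
#' clusters are returned without error.
#'
#' @param img a [raster_image].
#' @param K number of clusters (reef scenes segment well with the
#'   default `K = 2`, figure/ground).
#' @param max_iter Lloyd iteration cap.
#' @param seed RNG seed controlling the initialisation.
#' @param nstart number of k-means++ restarts.
#' @return A `segment_map`: list with `labels` (`H x W` integer matrix,
#'   values `1..K`), `K` (occupied cluster count), `centers`
#'   (`K x 3` RGB), `sizes` (pixel counts, non-increasing).
#' @export
kmeans_segment <- function(img, K = 2L, max_iter = 50L, seed = 1L,
                           nstart = 1L) {
  img <- as_raster_image(img)
  p <- img$pixels
  x <- cbind(as.vector(p[, , 1L]), as.vector(p[, , 2L]), as.vector(p[, , 3L]))
  ux <- unique(x)
  if (nrow(ux) <= K) {
    # fewer distinct colours than clusters: each colour is its own cluster
    lab <- match(
      paste(x[, 1L], x[, 2L], x[, 3L]),
      paste(ux[, 1L], ux[, 2L], ux[, 3L])
    )
    centers <- ux
  } else {
    fit <- with_seed(seed, {
      best <- NULL
      for (r in seq_len(nstart)) {
        init <- kmeanspp_init(x, K)
        f <- tryCatch(
          suppressWarnings(stats::kmeans(x, centers = init,
                                         iter.max = max_iter,
                                         algorithm = "Lloyd")),
          error = function(e) NULL
        )
        if (!is.null(f) && (is.null(best) || f$tot.withinss < best$tot.withinss))
          best <- f
      }
      if (is.null(best))  # degenerate data: fall back to distinct colours
        best <- suppressWarnings(stats::kmeans(x, centers = ux[seq_len(K), ],
                                               iter.max = max_iter,
                                               algorithm = "Lloyd"))
      best
    })
    lab <- fit$cluster
    centers <- fit$centers
  }
  sizes <- tabulate(lab, nbins = nrow(centers))
  keep <- which(sizes > 0L)
  # order: descending size, tie -> darker centre first
  ord <- keep[order(-sizes[keep], rowSums(centers)[keep])]
  relab <- integer(nrow(centers))
  relab[ord] <- seq_along(ord)
  structure(
    list(labels = matrix(relab[lab], img$height, img$width),
         K = length(ord),
         centers = centers[ord, , drop = FALSE],
         sizes = sizes[ord]),
    class = "segment_map"
  )
}

#' @export
print.segment_map <- function(x, ...) {
  cat(sprintf("<segment_map %d x %d px, %d occupied cluster(s)>\n",
              nrow(x$labels), ncol(x$labels), x$K))
  invisible(x)
}

# Connected-region labelling of an integer label matrix. Pixels with equal
# labels joined by 4- or 8-adjacency form one region. Returns an H x W
# integer matrix of region ids 1..n_regions.
label_components <- function(labels, connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  h <- nrow(labels); w <- ncol(labels)
  id <- matrix(seq_len(h * w), h, w)
  pair_if_equal <- function(a, b, la, lb) {
    eq <- la == lb
    cbind(a[eq], b[eq])
  }
  edges <- list(
    pair_if_equal(id[, -w, drop = FALSE], id[, -1L, drop = FALSE],
                  labels[, -w, drop = FALSE], labels[, -1L, drop = FALSE]),
    pair_if_equal(id[-h, , drop = FALSE], id[-1L, , drop = FALSE],
                  labels[-h, , drop = FALSE], labels[-1L, , drop = FALSE])
  )
  if (connectivity == 8L && h > 1L && w > 1L) {
    edges <- c(edges, list(
      pair_if_equal(id[-h, -w, drop = FALSE], id[-1L, -1L, drop = FALSE],
                    labels[-h, -w, drop = FALSE], labels[-1L, -1L, drop = FALSE]),
      pair_if_equal(id[-1L, -w, drop = FALSE], id[-h, -1L, drop = FALSE],
                    labels[-1L, -w, drop = FALSE], labels[-h, -1L, drop = FALSE])
    ))
  }
  e <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = h * w, directed = FALSE)
  if (nrow(e) > 0L) g <- igraph::add_edges(g, as.vector(t(e)))
  memb <- igraph::components(g)$membership
  matrix(as.integer(memb), h, w)
}

#' Count connected components of a segmentation
#'
#' Total number of maximal same-label connected regions across all labels
#' of a [kmeans_segment()] map — a measure of object fragmentation: intact
#' reef scenes break into fewer, larger pieces than turf- or
#' sediment-dominated ones.
#'
#' @param seg a `segment_map`, or a bare integer label matrix.
#' @param connectivity 4 (rook) or 8 (queen, default) adjacency.
#' @return Integer count, at least 1.
#' @export
connected_components <- function(seg, connectivity = 8L) {
  labels <- if (inherits(seg, "segment_map")) seg$labels else seg
  max(label_components(labels, connectivity))
}

#' Statistics of the largest connected regions
#'
#' Describes the `top_n` largest connected regions of a segmentation:
#' relative area, normalised centroid, mean hue/saturation/value and
#' logarithmic-average brightness. Entries are zero-padded when fewer
#' regions exist, so the feature block has fixed width.
#'
#' @param img a [raster_image].
#' @param seg a `segment_map` for `img`.
#' @param top_n number of regions reported.
#' @param connectivity adjacency passed to the region labelling.
#' @return A data.frame with `top_n` rows and columns `rel_area`,
#'   `centroid_r`, `centroid_c` (in `[0,1]`), `mean_h`, `mean_s`,
#'   `mean_v`, `brightness_log`; attribute `n_regions` carries the total
#'   region count.
#' @export
segment_statistics <- function(img, seg, top_n = 5L, connectivity = 8L) {
  img <- as_raster_image(img)
  memb <- label_components(seg$labels, connectivity)
  n <- max(memb)
  sizes <- tabulate(memb, nbins = n)
  ord <- order(-sizes, seq_len(n))[seq_len(min(top_n, n))]
  hsv <- rgb_to_hsv_image(img)
  h <- img$height; w <- img$width
  rows <- row(memb); cols <- col(memb)
  out <- matrix(0, top_n, 7L,
                dimnames = list(NULL, c("rel_area", "centroid_r", "centroid_c",
                                        "mean_h", "mean_s", "mean_v",
                                        "brightness_log")))
  delta <- 1 / 255
  for (i in seq_along(ord)) {
    m <- memb == ord[i]
    v <- hsv$v[m]
    out[i, ] <- c(sizes[ord[i]] / (h * w),
                  (mean(rows[m]) - 0.5) / h,
                  (mean(cols[m]) - 0.5) / w,
                  mean(hsv$h[m]), mean(hsv$s[m]), mean(v),
                  exp(mean(log(v + delta))) - delta)
  }
  structure(as.data.frame(out), n_regions = n)
}

# Edge-replicating (symmetric) 1-pixel pad used by the 3 x 3 filters.
shift_up    <- function(m) m[c(1L, seq_len(nrow(m) - 1L)), , drop = FALSE]
shift_down  <- function(m) m[c(seq_len(nrow(m))[-1L], nrow(m)), , drop = FALSE]
shift_left  <- function(m) m[, c(1L, seq_len(ncol(m) - 1L)), drop = FALSE]
shift_right <- function(m) m[, c(seq_len(ncol(m))[-1L], ncol(m)), drop = FALSE]

#' Laplacian edge-energy map
#'
#' Absolute response of the 3 x 3 four-neighbour Laplacian kernel applied
#' to the HSV value channel, with edge-replicating borders. The map is
#' everywhere non-negative, zero for constant images, and invariant under
#' a global intensity offset.
#'
#' @param img a [raster_image], or a plain `[0,1]` matrix treated as the
#'   value channel.
#' @return `H x W` non-negative matrix of edge energy.
#' @export
laplacian_edge_map <- function(img) {
  v <- if (is.matrix(img)) img else value_channel(img)
  abs(shift_up(v) + shift_down(v) + shift_left(v) + shift_right(v) - 4 * v)
}

#' Bounding box holding a fraction of the edge energy
#'
#' Finds an axis-aligned box containing at least `energy_fraction` of the
#' total edge energy by the marginal-trim construction: from each of the
#' four margins, rows/columns are trimmed while their cumulative marginal
#' energy stays within `(1 - energy_fraction)/2` per side; if the
#' intersection of the row and column bands falls short of the requested
#' fraction, the box is grown back one row/column at a time on the side
#' recovering the most energy. The area of this box, as a fraction of the
#' image, summarises how concentrated the high-frequency content is.
#'
#' @param edges an edge-energy matrix (see [laplacian_edge_map()]).
#' @param energy_fraction required energy fraction in `(0, 1]`.
#' @return List with `rows`, `cols` (1-based inclusive bounds),
#'   `area_fraction`, and `energy_fraction` actually contained.
#' @export
edge_energy_box <- function(edges, energy_fraction = 0.81) {
  if (energy_fraction <= 0 || energy_fraction > 1)
    stop("`energy_fraction` must lie in (0, 1]")
  tot <- sum(edges)
  if (tot <= 0) stop("edge map has zero total energy")
  h <- nrow(edges); w <- ncol(edges)
  rmar <- rowSums(edges); cmar <- colSums(edges)
  slack <- (1 - energy_fraction) / 2 * tot
  trim <- function(mar) {
    lo <- 1L
    acc <- 0
    while (lo < length(mar) && acc + mar[lo] <= slack) {
      acc <- acc + mar[lo]; lo <- lo + 1L
    }
    hi <- length(mar)
    acc <- 0
    while (hi > lo && acc + mar[hi] <= slack) {
      acc <- acc + mar[hi]; hi <- hi - 1L
    }
    c(lo, hi)
  }
  rb <- trim(rmar); cb <- trim(cmar)
  contained <- function(rb, cb) sum(edges[rb[1L]:rb[2L], cb[1L]:cb[2L]])
  # guarantee the requested fraction: grow back greedily, deterministic
  # preference top > bottom > left > right on exact ties
  while (contained(rb, cb) < energy_fraction * tot) {
    gain <- c(
      top    = if (rb[1L] > 1L) sum(edges[rb[1L] - 1L, cb[1L]:cb[2L]]) else -Inf,
      bottom = if (rb[2L] < h)  sum(edges[rb[2L] + 1L, cb[1L]:cb[2L]]) else -Inf,
      left   = if (cb[1L] > 1L) sum(edges[rb[1L]:rb[2L], cb[1L] - 1L]) else -Inf,
      right  = if (cb[2L] < w)  sum(edges[rb[1L]:rb[2L], cb[2L] + 1L]) else -Inf
    )
    side <- which.max(gain)
    switch(side,
           rb[1L] <- rb[1L] - 1L,
           rb[2L] <- rb[2L] + 1L,
           cb[1L] <- cb[1L] - 1L,
           cb[2L] <- cb[2L] + 1L)
  }
  area <- (rb[2L] - rb[1L] + 1L) * (cb[2L] - cb[1L] + 1L) / (h * w)
  list(rows = rb, cols = cb, area_fraction = area,
       energy_fraction = contained(rb, cb) / tot)
}

#' Similarity of the edge-energy distribution to reference profiles
#'
#' Resizes the edge map onto a fixed grid, normalises it to unit mass and
#' compares it against each reference profile with total-variation
#' similarity `1 - L1/2`, returning the best match in `[0, 1]`.
#'
#' @param edges an edge-energy matrix.
#' @param profiles list of reference profiles, each a non-negative
#'   `grid x grid` matrix summing to 1 (see [default_edge_profiles()]).
#' @param grid side of the comparison grid.
#' @return Maximum similarity across profiles, in `[0, 1]`.
#' @export
edge_distribution_similarity <- function(edges, profiles, grid = 100L) {
  if (length(profiles) == 0L) stop("`profiles` must contain at least one profile")
  tot <- sum(edges)
  if (tot <= 0) stop("edge map has zero total energy")
  e <- resize_image(edges, grid, grid)
  e <- pmax(e, 0)
  e <- e / sum(e)
  max(vapply(profiles, function(p) {
    if (!all(dim(p) == c(grid, grid)))
      stop("profile dimensions must match the comparison grid")
    1 - sum(abs(e - p)) / 2
  }, numeric(1L)))
}

#' Default reference edge profiles
#'
#' Three synthetic, constructed-in-code spatial profiles of edge energy on
#' the comparison grid: a centre-weighted Gaussian (subject in the middle),
#' a rule-of-thirds profile concentrating energy along the third lines,
#' and a uniform profile (edges everywhere, typical of busy benthic
#' scenes). Each sums to 1.
#'
#' @param grid side of the profile grid.
#' @return Named list of `grid x grid` matrices.
#' @export
default_edge_profiles <- function(grid = 100L) {
  u <- (seq_len(grid) - 0.5) / grid
  gauss <- outer(stats::dnorm(u, 0.5, 0.18), stats::dnorm(u, 0.5, 0.18))
  thirds <- outer(stats::dnorm(u, 1 / 3, 0.05) + stats::dnorm(u, 2 / 3, 0.05),
                  stats::dnorm(u, 1 / 3, 0.05) + stats::dnorm(u, 2 / 3, 0.05))
  unif <- matrix(1, grid, grid)
  lapply(list(center = gauss, thirds = thirds, uniform = unif),
         function(m) m / sum(m))
}
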