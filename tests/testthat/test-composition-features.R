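test_that("thirds focus region follows the exact thirds arithmetic", {
  r <- thirds_focus_region(9, 9, margin = 0)
  expect_equal(r$rows, c(3, 6))
  expect_equal(r$cols, c(3, 6))

  expect_error(thirds_focus_region(9, 9, margin = 1 / 3), "1/3")

  r2 <- thirds_focus_region(300, 600, margin = 0.1)
  expect_equal(r2$rows, c(70, 230))
  expect_equal(r2$cols, c(140, 460))
})

test_that("focus brightness isolates the region", {
  expect_equal(focus_brightness(constant_img(0.7, 18, 18)), 0.7)

  px <- array(0, c(18, 18, 3))
  px[7:12, 7:12, ] <- 1    # exactly the central ninth of an 18x18 image
  expect_equal(focus_brightness(raster_image(px)), 1)

  img <- rand_img(20, 26, seed = 4)
  reg <- thirds_focus_region(20, 26, margin = 0.1)
  v <- pmax(img$pixels[, , 1], img$pixels[, , 2], img$pixels[, , 3])
  mask <- matrix(FALSE, 20, 26)
  mask[(reg$rows[1] + 1):reg$rows[2], (reg$cols[1] + 1):reg$cols[2]] <- TRUE
  expect_equal(focus_brightness(img, reg), sum(v[mask]) / sum(mask),
               tolerance = 1e-12)
})

test_that("k-means segmentation separates tones and is seed-stable", {
  px <- array(0, c(16, 16, 3))
  px[, 9:16, ] <- 1
  seg <- kmeans_segment(raster_image(px), K = 2, seed = 1)
  expect_equal(seg$K, 2L)
  expect_equal(length(unique(as.vector(seg$labels[, 1:8]))), 1L)
  expect_equal(length(unique(as.vector(seg$labels[, 9:16]))), 1L)
  expect_false(seg$labels[1, 1] == seg$labels[1, 16])

  seg_const <- kmeans_segment(constant_img(0.5), K = 2, seed = 1)
  expect_equal(seg_const$K, 1L)

  img <- rand_img(16, 16, seed = 21)
  s1 <- kmeans_segment(img, K = 3, seed = 9)
  s2 <- kmeans_segment(img, K = 3, seed = 9)
  expect_identical(s1$labels, s2$labels)
  expect_identical(s1$centers, s2$centers)

  # Lloyd fixed point: every pixel sits with its nearest centre
  x <- cbind(as.vector(img$pixels[, , 1]), as.vector(img$pixels[, , 2]),
             as.vector(img$pixels[, , 3]))
  d <- sapply(seq_len(s1$K), function(k)
    colSums((t(x) - s1$centers[k, ])^2))
  expect_equal(as.vector(s1$labels), unname(apply(d, 1, which.min)))

  # labels ordered by descending cluster size
  expect_true(all(diff(s1$sizes) <= 0))
})

test_that("connected components match a flood-fill oracle", {
  expect_equal(connected_components(matrix(1L, 8, 8)), 1L)

  checker2 <- matrix(c(1L, 2L, 2L, 1L), 2, 2)
  expect_equal(connected_components(checker2, connectivity = 4), 4L)
  expect_equal(connected_components(checker2, connectivity = 8), 2L)

  for (s in 1:10) {
    set.seed(300 + s)
    labels <- matrix(sample(1:2, 32 * 32, replace = TRUE), 32, 32)
    for (conn in c(4L, 8L)) {
      expect_identical(connected_components(labels, conn),
                       oracle_components(labels, conn))
    }
  }
})

test_that("component count is at least the number of occupied labels", {
  for (s in 1:5) {
    set.seed(400 + s)
    labels <- matrix(sample(1:3, 20 * 20, replace = TRUE), 20, 20)
    expect_gte(connected_components(labels), length(unique(as.vector(labels))))
  }
})

test_that("segment statistics enumerate regions correctly", {
  img <- constant_img(0.6, 16, 16)
  seg <- kmeans_segment(img, K = 2, seed = 1)
  st <- segment_statistics(img, seg)
  expect_equal(st$rel_area[1], 1)
  expect_equal(st$centroid_r[1], 0.5)
  expect_equal(st$centroid_c[1], 0.5)
  expect_equal(st$rel_area[2:5], rep(0, 4))

  px <- array(0.2, c(16, 16, 3))
  px[, 9:16, ] <- 0.9
  img2 <- raster_image(px)
  seg2 <- kmeans_segment(img2, K = 2, seed = 1)
  st2 <- segment_statistics(img2, seg2)
  expect_equal(sort(st2$rel_area[1:2]), c(0.5, 0.5))
  expect_equal(sort(st2$centroid_c[1:2]), c(0.25, 0.75))

  # areas across ALL regions form a partition of the image
  set.seed(5)
  labels <- matrix(sample(1:2, 16 * 16, replace = TRUE), 16, 16)
  seg3 <- list(labels = labels, K = 2L)
  img3 <- rand_img(16, 16, seed = 6)
  st3 <- segment_statistics(img3, seg3, top_n = 5)
  n_regions <- attr(st3, "n_regions")
  expect_gte(n_regions, 2)
  # enumerate regions independently and compare the largest one
  memb <- reefscore:::label_components(labels, 8L)
  sizes <- tabulate(memb)
  expect_equal(st3$rel_area[1], max(sizes) / 256, tolerance = 1e-12)
  big <- memb == which.max(sizes)
  hsv <- rgb_to_hsv_image(img3)
  expect_equal(st3$mean_v[1], mean(hsv$v[big]), tolerance = 1e-12)
  expect_equal(st3$centroid_r[1], (mean(row(memb)[big]) - 0.5) / 16,
               tolerance = 1e-12)
})

test_that("Laplacian edge map matches naive convolution and kills offsets", {
  expect_true(all(laplacian_edge_map(constant_img(0.8)) == 0))

  impulse <- matrix(0, 9, 9)
  impulse[5, 5] <- 1
  le <- laplacian_edge_map(impulse)
  expect_true(all(le[abs(row(le) - 5) > 1 | abs(col(le) - 5) > 1] == 0))
  expect_gt(sum(le), 0)

  for (s in 1:6) {
    v <- rand_gray_matrix(8, 8, seed = 500 + s)
    expect_equal(laplacian_edge_map(v), oracle_laplacian(v),
                 tolerance = 1e-12)
  }

  v <- rand_gray_matrix(10, 10, seed = 77) * 0.5
  expect_equal(laplacian_edge_map(v), laplacian_edge_map(v + 0.3),
               tolerance = 1e-12)
})

test_that("edge-energy box honours containment and the marginal trims", {
  # uniform energy on the central quarter, full fraction -> exact support
  e <- matrix(0, 16, 16)
  e[5:12, 5:12] <- 1
  box <- edge_energy_box(e, 1.0)
  expect_equal(box$area_fraction, 0.25)
  expect_equal(box$rows, c(5, 12))
  expect_equal(box$cols, c(5, 12))

  # fraction 1 spans the whole nonzero support
  set.seed(13)
  e2 <- matrix(0, 12, 12)
  e2[cbind(sample(2:11, 6), sample(2:11, 6))] <- runif(6)
  box2 <- edge_energy_box(e2, 1.0)
  nz <- which(e2 > 0, arr.ind = TRUE)
  expect_equal(box2$rows, range(nz[, 1]))
  expect_equal(box2$cols, range(nz[, 2]))

  for (s in 1:10) {
    set.seed(600 + s)
    e3 <- matrix(0, 20, 20)
    pick <- sample(400, 30)
    e3[pick] <- runif(30)
    for (f in c(0.81, 0.9604)) {
      b <- edge_energy_box(e3, f)
      expect_gte(b$energy_fraction, f - 1e-12)
      tr <- oracle_box_trims(e3, f)
      expect_lte(b$rows[1], tr$rows[1])   # growth only widens the trims
      expect_gte(b$rows[2], tr$rows[2])
      expect_lte(b$cols[1], tr$cols[1])
      expect_gte(b$cols[2], tr$cols[2])
      expect_equal(b$area_fraction,
                   diff(b$rows + c(-1, 0)) * diff(b$cols + c(-1, 0)) / 400,
                   tolerance = 1e-12)
    }
    # area monotone in the requested fraction
    areas <- vapply(c(0.5, 0.7, 0.81, 0.9, 0.9604, 1),
                    function(f) edge_energy_box(e3, f)$area_fraction,
                    numeric(1))
    expect_true(all(diff(areas) >= -1e-12))
  }

  expect_error(edge_energy_box(matrix(0, 8, 8), 0.8), "zero total energy")
})

test_that("edge-distribution similarity is a bounded L1 match", {
  set.seed(19)
  e <- matrix(runif(32 * 32), 32, 32)
  self <- resize_image(e, 100, 100)
  self <- pmax(self, 0); self <- self / sum(self)
  expect_equal(edge_distribution_similarity(e, list(self)), 1.0,
               tolerance = 1e-12)

  # support disjoint from the resized left-half map (which bleeds one
  # bilinear pixel past column 50 on the comparison grid)
  right <- matrix(0, 100, 100); right[, 60:100] <- 1 / (100 * 41)
  e_left <- matrix(0, 32, 32); e_left[, 1:16] <- 1
  sim <- edge_distribution_similarity(e_left, list(right))
  expect_equal(sim, 0.0, tolerance = 1e-9)

  profs <- lapply(1:3, function(i) {
    set.seed(i); p <- matrix(runif(1e4), 100, 100); p / sum(p)
  })
  got <- edge_distribution_similarity(e, profs)
  en <- resize_image(e, 100, 100); en <- pmax(en, 0); en <- en / sum(en)
  want <- max(vapply(profs, function(p) 1 - sum(abs(en - p)) / 2, numeric(1)))
  expect_equal(got, want, tolerance = 1e-12)

  expect_error(edge_distribution_similarity(e, list()), "at least one")
})

test_that("default edge profiles are normalised distributions", {
  profs <- default_edge_profiles()
  expect_named(profs, c("center", "thirds", "uniform"))
  for (p in profs) {
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0))
  }
})
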