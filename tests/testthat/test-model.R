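# Small synthetic feature matrices for model tests: random features with a
# controlled relationship to the target.
toy_matrix <- function(n, seed, signal_col = 7L, noise_sd = 0) {
  set.seed(seed)
  x <- matrix(runif(n * 109), n, 109,
              dimnames = list(NULL, feature_registry()$name))
  y <- 10 + 20 * x[, signal_col] + rnorm(n, 0, noise_sd)
  list(x = x, y = y)
}

test_that("site-stratified splitting reproduces the holdout design", {
  fm <- data.frame(site_id = rep(sprintf("s%02d", 1:11), each = 30),
                   site_score = rep(seq(2, 45, length.out = 11), each = 30))
  sp <- split_dataset(fm, holdout_per_site = 20, seed = 1)
  expect_equal(sum(sp$split == "holdout"), 220L)
  expect_true(all(table(sp$site_id[sp$split == "holdout"]) == 20L))

  sp0 <- split_dataset(fm, holdout_per_site = 0)
  expect_true(all(sp0$split == "train_pool"))

  expect_identical(split_dataset(fm, 5, seed = 7)$split,
                   split_dataset(fm, 5, seed = 7)$split)
  expect_error(split_dataset(fm, 30, seed = 1), "s01")
})

test_that("constant targets give a constant predictor with a warning", {
  d <- toy_matrix(40, seed = 1)
  expect_warning(m <- aesthetic_train(d$x, rep(7, 40), seed = 1),
                 "constant")
  expect_equal(predict(m, d$x), rep(7, 40), tolerance = 1e-6)
})

test_that("a noise-free linear signal is recovered on held-out rows", {
  d <- toy_matrix(600, seed = 2)
  m <- aesthetic_train(d$x, d$y, seed = 3, hidden = 2)
  fresh <- toy_matrix(80, seed = 99)
  rms <- rms_error(predict(m, fresh$x), fresh$y)
  expect_lt(rms, 0.05 * stats::sd(fresh$y))
})

test_that("training is deterministic given the seed", {
  d <- toy_matrix(60, seed = 4)
  m1 <- aesthetic_train(d$x, d$y, seed = 5, decay_grid = 0.1,
                        max_chunks = 5)
  m2 <- aesthetic_train(d$x, d$y, seed = 5, decay_grid = 0.1,
                        max_chunks = 5)
  expect_identical(m1$wts, m2$wts)
  expect_identical(predict(m1, d$x), predict(m2, d$x))
})

test_that("prediction is the standardise-affine-logistic-affine pass", {
  # hand-built 3-feature, 2-hidden-unit model
  wts <- c(0.1, 0.5, -0.2, 0.3,   # hidden 1: bias, w1..w3
           -0.4, 0.2, 0.6, -0.1,  # hidden 2
           0.05, 1.5, -2.0)       # output: bias, v1, v2
  m <- structure(list(wts = wts, p = 3L, hidden = 2L,
                      center = c(0.2, 0.4, 0.6), scale = c(1, 2, 0.5)),
                 class = "aesthetic_model")
  xnew <- c(0.7, 0.1, 0.9)
  z <- (xnew - m$center) / m$scale
  h1 <- 1 / (1 + exp(-(0.1 + sum(c(0.5, -0.2, 0.3) * z))))
  h2 <- 1 / (1 + exp(-(-0.4 + sum(c(0.2, 0.6, -0.1) * z))))
  expect_equal(predict(m, matrix(xnew, 1)), 0.05 + 1.5 * h1 - 2.0 * h2,
               tolerance = 1e-12)

  # identical inputs give identical predictions; shape errors are caught
  X <- rbind(xnew, xnew)
  expect_equal(predict(m, X)[1], predict(m, X)[2])
  expect_error(predict(m, matrix(0.5, 1, 4)), "does not match")
})

test_that("standardisation never sees the holdout rows", {
  d <- toy_matrix(120, seed = 6)
  fm <- cbind(data.frame(site_id = rep(c("a", "b", "c"), each = 40),
                         site_score = d$y), as.data.frame(d$x))
  fm <- split_dataset(fm, holdout_per_site = 10, seed = 1)
  m1 <- aesthetic_train(fm, seed = 2, decay_grid = 0.1, max_chunks = 3)
  fm2 <- fm
  ho <- fm2$split == "holdout"
  fm2[ho, feature_registry()$name] <- 0.5   # perturb holdout features
  m2 <- aesthetic_train(fm2, seed = 2, decay_grid = 0.1, max_chunks = 3)
  expect_identical(m1$center, m2$center)
  expect_identical(m1$scale, m2$scale)
  expect_identical(m1$wts, m2$wts)
})

test_that("models survive a JSON round trip exactly", {
  d <- toy_matrix(60, seed = 8)
  m <- aesthetic_train(d$x, d$y, seed = 1, decay_grid = 0.1, max_chunks = 3)
  path <- withr::local_tempfile(fileext = ".json")
  save_aesthetic_model(m, path)
  back <- load_aesthetic_model(path)
  expect_equal(predict(back, d$x), predict(m, d$x), tolerance = 1e-12)
})

test_that("model accessors expose the fit", {
  d <- toy_matrix(60, seed = 9)
  m <- aesthetic_train(d$x, d$y, seed = 1, decay_grid = 0.1, max_chunks = 3)
  expect_length(fitted(m), 60)
  expect_equal(residuals(m), d$y - fitted(m))
  cf <- coef(m)
  expect_equal(dim(cf$W1), c(10L, 109L))
  expect_output(print(m), "feed-forward net")
  expect_output(summary(m), "subdivision")
})

test_that("aggregation and rms follow their closed forms", {
  expect_equal(aggregate_score(c(5, 5, 5), 3), 5)
  expect_equal(aggregate_score(c(0, 10), 2), 5)
  expect_error(aggregate_score(numeric(0)), "non-empty")
  expect_error(aggregate_score(c(1, 2), 3), "between")

  expect_equal(rms_error(c(1, 2), c(1, 2)), 0)
  expect_equal(rms_error(c(0, 2), c(0, 0)), sqrt(2))
  set.seed(10)
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(rms_error(a, b), sqrt(sum((a - b)^2) / 50), tolerance = 1e-12)
  expect_error(rms_error(1:3, 1:2), "equal")
})

test_that("random-forest importance recovers a planted signal", {
  d <- toy_matrix(150, seed = 11)
  imp <- feature_importance(d$x, d$y, n_trees = 300, seed = 1)
  expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
  expect_true(all(imp$importance >= 0))
  expect_equal(names(which.max(imp$importance)),
               feature_registry()$name[7])
  # group sums are a partition of the total importance
  reg <- feature_registry()
  for (g in c("color", "objects", "texture")) {
    expect_equal(unname(imp$groups[g]),
                 sum(imp$importance[reg$name[reg$group == g]]),
                 tolerance = 1e-12)
  }
  expect_error(feature_importance(d$x, rep(1, 150)), "constant")
})

test_that("site comparison flags planted shifts and only those", {
  set.seed(12)
  # identical distributions: no significance expected
  v0 <- rnorm(60)
  s0 <- rep(c("a", "b", "c"), each = 20)
  res0 <- site_comparison(v0, s0)
  expect_gt(res0$anova_p, 0.01)
  expect_true(all(res0$letters == res0$letters[1]))

  # two sites ten standard deviations apart
  v1 <- c(rnorm(20), rnorm(20, 10))
  res1 <- site_comparison(v1, rep(c("a", "b"), each = 20))
  expect_lt(res1$anova_p, 0.001)

  # two identical groups plus one shifted: exactly the shifted pairs flag
  v2 <- c(rnorm(20), rnorm(20), rnorm(20, 8))
  res2 <- site_comparison(v2, rep(c("a", "b", "c"), each = 20))
  sig <- res2$tukey$p_adj < 0.05
  flagged <- sort(res2$tukey$pair[sig])
  expect_identical(flagged, c("c-a", "c-b"))
  expect_identical(unname(res2$letters["c"] == res2$letters["a"]), FALSE)
  expect_identical(unname(res2$letters["a"] == res2$letters["b"]), TRUE)

  expect_error(site_comparison(1:3, c("a", "a", "b")), "fewer than two")
})

test_that("regression_fit matches the normal equations", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(regression_fit(x, 2 * x + 1)[c("slope", "intercept", "r_squared")],
               list(slope = 2, intercept = 1, r_squared = 1),
               tolerance = 1e-12)

  set.seed(13)
  x5 <- c(0.3, 1.2, 2.7, 3.1, 4.9)
  y5 <- c(2.2, 0.8, 3.9, 2.5, 5.1)
  fit <- regression_fit(x5, y5)
  # closed-form normal equations
  b <- sum((x5 - mean(x5)) * (y5 - mean(y5))) / sum((x5 - mean(x5))^2)
  a <- mean(y5) - b * mean(x5)
  r2 <- 1 - sum((y5 - a - b * x5)^2) / sum((y5 - mean(y5))^2)
  expect_equal(fit$slope, b, tolerance = 1e-12)
  expect_equal(fit$intercept, a, tolerance = 1e-12)
  expect_equal(fit$r_squared, r2, tolerance = 1e-12)

  # independent x and y: slope p-values behave like a null test
  set.seed(14)
  fitn <- regression_fit(rnorm(500), rnorm(500))
  expect_lt(fitn$r_squared, 0.05)

  expect_error(regression_fit(rep(1, 5), 1:5), "variance")
})
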