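#' Site-stratified holdout split
#'
#' Marks `holdout_per_site` randomly chosen images of every site as
#' holdout, the rest as training pool. With 11 sites and 20 holdout images
#' each this reproduces the 220-image site-stratified test batch design.
#'
#' @param fm a feature-matrix data.frame (see [extract_feature_matrix()]),
#'   or any data.frame with a `site_id` column.
#' @param holdout_per_site images withheld per site.
#' @param seed RNG seed.
#' @return `fm` with an added character column `split`
#'   (`"train_pool"` / `"holdout"`).
#' @export
split_dataset <- function(fm, holdout_per_site, seed = 1L) {
  stopifnot(is.data.frame(fm), "site_id" %in% names(fm))
  split <- rep("train_pool", nrow(fm))
  if (holdout_per_site > 0L) {
    idx_by_site <- base::split(seq_len(nrow(fm)), fm$site_id)
    too_small <- names(idx_by_site)[
      lengths(idx_by_site) <= holdout_per_site]
    if (length(too_small) > 0L)
      stop("site(s) too small for holdout of ", holdout_per_site, ": ",
           paste(too_small, collapse = ", "))
    with_seed(seed, {
      for (idx in idx_by_site)
        split[sample(idx, holdout_per_site)] <- "holdout"
    })
  }
  fm$split <- split
  fm
}

# Parse an nnet weight vector (no skip layer) into explicit matrices.
unpack_weights <- function(wts, p, size) {
  W1 <- matrix(0, size, p); b1 <- numeric(size)
  k <- 0L
  for (j in seq_len(size)) {
    b1[j] <- wts[k + 1L]
    W1[j, ] <- wts[k + 1L + seq_len(p)]
    k <- k + 1L + p
  }
  b2 <- wts[k + 1L]
  W2 <- wts[k + 1L + seq_len(size)]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

# Forward pass: standardize -> affine -> logistic -> affine (linear output).
forward_pass <- function(wts, p, size, X) {
  u <- unpack_weights(wts, p, size)
  H <- 1 / (1 + exp(-(X %*% t(u$W1) + matrix(u$b1, nrow(X), size,
                                             byrow = TRUE))))
  as.numeric(H %*% u$W2 + u$b2)
}

#' Calibrate aesthetic values against site scores
#'
#' Fits the coral-reef aesthetic model: a single-hidden-layer feed-forward
#' neural network regressing the 109 aesthetic features on the site-level
#' impact score. The training pool is subdivided 70/15/15 into training,
#' validation and internal-test subsets; features are standardised with
#' constants computed from the training subset only; the network is
#' optimised in chunks with early stopping on validation error, and the
#' weight-decay penalty is selected on the validation subset from a small
#' grid. The fit is deterministic given the data and `seed`.
#'
#' @param x feature matrix: either a numeric matrix with one row per image
#'   and the 109 registry columns, or a feature-matrix data.frame from
#'   [extract_feature_matrix()] (then `y` defaults to its `site_score`).
#'   If a `split` column is present, only `"train_pool"` rows are used.
#' @param y numeric target score per image.
#' @param hidden hidden-layer width.
#' @param seed RNG seed controlling the subdivision and initial weights.
#' @param decay_grid weight-decay values scored on the validation subset.
#' @param val_frac,test_frac validation / internal-test fractions.
#' @param chunk_iters optimiser iterations per early-stopping check.
#' @param max_chunks cap on optimisation chunks per decay value.
#' @param patience chunks without validation improvement before stopping.
#' @return An object of class `aesthetic_model` with `print`, `summary`,
#'   `coef`, `predict`, `fitted`, `residuals` and `plot` methods.
#' @export
aesthetic_train <- function(x, y = NULL, hidden = 10L, seed = 1L,
                            decay_grid = c(0.01, 0.1, 1),
                            val_frac = 0.15, test_frac = 0.15,
                            chunk_iters = 100L, max_chunks = 30L,
                            patience = 20L) {
  if (is.data.frame(x)) {
    if (is.null(y)) y <- x$site_score
    if ("split" %in% names(x)) {
      keep <- x$split == "train_pool"
      y <- y[keep]
      x <- x[keep, , drop = FALSE]
    }
    x <- feature_columns(x)
  }
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y), nrow(x) >= 3L)
  n <- nrow(x); p <- ncol(x)

  # 70/15/15 subdivision of the training pool
  sub <- with_seed(seed, {
    idx <- sample.int(n)
    n_val <- max(1L, round(val_frac * n))
    n_test <- max(1L, round(test_frac * n))
    s <- rep("train", n)
    s[idx[seq_len(n_val)]] <- "val"
    s[idx[n_val + seq_len(n_test)]] <- "test"
    s
  })
  tr <- sub == "train"; va <- sub == "val"; te <- sub == "test"

  center <- colMeans(x[tr, , drop = FALSE])
  scale <- apply(x[tr, , drop = FALSE], 2L, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  Z <- sweep(sweep(x, 2L, center), 2L, scale, "/")

  obj <- list(feature_names = colnames(x), hidden = hidden, p = p,
              center = center, scale = scale, seed = seed,
              subdivision = sub, y = y)

  if (stats::sd(y) == 0) {
    warning("all target scores identical: fitting a constant predictor")
    obj$constant <- unname(y[1L])
    obj$log <- data.frame()
    obj$val_rmse <- 0; obj$test_rmse <- 0; obj$decay <- NA_real_
    class(obj) <- "aesthetic_model"
    obj$fitted_pool <- rep(obj$constant, n)
    return(obj)
  }

  rms_on <- function(wts, mask) {
    if (!any(mask)) return(NA_real_)
    rms_error(forward_pass(wts, p, hidden, Z[mask, , drop = FALSE]), y[mask])
  }

  best <- NULL
  log_rows <- list()
  for (decay in decay_grid) {
    wts <- NULL
    best_d <- NULL
    wait <- 0L
    with_seed(seed, {
      for (chunk in seq_len(max_chunks)) {
        fit <- if (is.null(wts)) {
          nnet::nnet(x = Z[tr, , drop = FALSE], y = y[tr], size = hidden,
                     linout = TRUE, decay = decay, maxit = chunk_iters,
                     trace = FALSE, MaxNWts = 10000L)
        } else {
          nnet::nnet(x = Z[tr, , drop = FALSE], y = y[tr], size = hidden,
                     linout = TRUE, decay = decay, maxit = chunk_iters,
                     trace = FALSE, MaxNWts = 10000L, Wts = wts)
        }
        wts <- fit$wts
        vr <- rms_on(wts, va)
        log_rows[[length(log_rows) + 1L]] <-
          data.frame(decay = decay, chunk = chunk, train_rmse = rms_on(wts, tr),
                     val_rmse = vr)
        if (is.null(best_d) || vr < best_d$val_rmse - 1e-10) {
          best_d <- list(wts = wts, val_rmse = vr, decay = decay)
          wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= patience) break
        }
      }
    })
    if (is.null(best) || best_d$val_rmse < best$val_rmse) best <- best_d
  }

  obj$constant <- NULL
  obj$wts <- best$wts
  obj$decay <- best$decay
  obj$val_rmse <- best$val_rmse
  obj$test_rmse <- rms_on(best$wts, te)
  obj$log <- do.call(rbind, log_rows)
  obj$fitted_pool <- forward_pass(best$wts, p, hidden, Z)
  class(obj) <- "aesthetic_model"
  obj
}

#' Predict aesthetic values
#'
#' @param object an `aesthetic_model`.
#' @param newdata feature matrix (numeric matrix, single named feature
#'   vector, or feature-matrix data.frame).
#' @param ... unused.
#' @return Numeric vector of continuous aesthetic values on the target
#'   (impact-score) scale; predictions are not clipped to the observed
#'   score range.
#' @export
predict.aesthetic_model <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) newdata <- feature_columns(newdata)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, 1L,
                                               dimnames = list(NULL, names(newdata)))
  if (ncol(newdata) != object$p)
    stop("feature vector length ", ncol(newdata),
         " does not match the model (", object$p, ")")
  if (!is.null(object$constant)) return(rep(object$constant, nrow(newdata)))
  Z <- sweep(sweep(as.matrix(newdata), 2L, object$center), 2L,
             object$scale, "/")
  forward_pass(object$wts, object$p, object$hidden, Z)
}

#' @export
print.aesthetic_model <- function(x, ...) {
  cat("Coral reef aesthetic model\n")
  if (!is.null(x$constant)) {
    cat(sprintf("  constant predictor: %.4g\n", x$constant))
  } else {
    cat(sprintf("  feed-forward net: %d features -> %d logistic hidden units -> 1 linear output\n",
                x$p, x$hidden))
    cat(sprintf("  weight decay %.3g (validation-selected), validation rms %.3f, internal test rms %.3f\n",
                x$decay, x$val_rmse, x$test_rmse))
  }
  invisible(x)
}

#' @export
summary.aesthetic_model <- function(object, ...) {
  print(object)
  tab <- table(object$subdivision)
  cat("  training-pool subdivision:",
      paste(names(tab), tab, sep = " = ", collapse = ", "), "\n")
  if (is.null(object$constant)) {
    cat(sprintf("  optimisation: %d chunk(s) logged across the decay grid\n",
                nrow(object$log)))
  }
  invisible(object)
}

#' @export
coef.aesthetic_model <- function(object, ...) {
  if (!is.null(object$constant)) return(list(constant = object$constant))
  unpack_weights(object$wts, object$p, object$hidden)
}

#' @export
fitted.aesthetic_model <- function(object, ...) object$fitted_pool

#' @export
residuals.aesthetic_model <- function(object, ...)
  object$y - object$fitted_pool

#' @export
plot.aesthetic_model <- function(x, ...) {
  graphics::plot(x$y, x$fitted_pool,
                 xlab = "site impact score",
                 ylab = "predicted aesthetic value",
                 col = c(train = "grey40", val = "orange",
                         test = "red")[x$subdivision], ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Save / load an aesthetic model (JSON)
#'
#' Persists the standardisation constants, architecture and flat weight
#' vector as JSON, sufficient to reproduce predictions exactly.
#'
#' @param model an `aesthetic_model`.
#' @param path JSON file path.
#' @return `save_aesthetic_model()` returns `path` invisibly;
#'   `load_aesthetic_model()` returns the model.
#' @export
save_aesthetic_model <- function(model, path) {
  keep <- model[intersect(names(model),
                          c("feature_names", "hidden", "p", "center",
                            "scale", "seed", "wts", "decay", "val_rmse",
                            "test_rmse", "constant"))]
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_aesthetic_model
#' @export
load_aesthetic_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$center <- as.numeric(m$center); m$scale <- as.numeric(m$scale)
  if (!is.null(m$wts)) m$wts <- as.numeric(m$wts)
  class(m) <- "aesthetic_model"
  m
}

#' Root-mean-squared error
#'
#' @param pred,target numeric vectors of equal length.
#' @return `sqrt(mean((pred - target)^2))`.
#' @export
rms_error <- function(pred, target) {
  if (length(pred) != length(target) || length(pred) < 1L)
    stop("`pred` and `target` must have equal positive length")
  sqrt(mean((pred - target)^2))
}

#' Aggregate per-image predictions
#'
#' Arithmetic mean of `N` per-image aesthetic values from the same locale;
#' averaging several images sharply reduces the per-image motive noise.
#'
#' @param predictions numeric vector of per-image values.
#' @param N number of images to average (first `N` are used).
#' @return The aggregated aesthetic value.
#' @export
aggregate_score <- function(predictions, N = length(predictions)) {
  if (length(predictions) < 1L) stop("`predictions` must be non-empty")
  if (N < 1L || N > length(predictions))
    stop("`N` must lie between 1 and length(predictions)")
  mean(predictions[seq_len(N)])
}

#' Holdout rms of N-image aggregated predictions
#'
#' For every site in the holdout, draws `resamples` seeded subsets of `N`
#' images, averages their predicted values and measures the rms error of
#' these site-level aggregates against the site scores.
#'
#' @param model an `aesthetic_model`.
#' @param fm a feature-matrix data.frame with a `split` column.
#' @param N images aggregated per site.
#' @param seed RNG seed for the resampling.
#' @param resamples resampled subsets per site.
#' @return rms error of the aggregated predictions.
#' @export
holdout_rms <- function(model, fm, N = 1L, seed = 1L, resamples = 20L) {
  ho <- fm[fm$split == "holdout", , drop = FALSE]
  if (nrow(ho) == 0L) stop("no holdout rows in `fm`")
  pred <- predict(model, ho)
  by_site <- base::split(seq_len(nrow(ho)), ho$site_id)
  with_seed(seed, {
    errs <- unlist(lapply(by_site, function(idx) {
      target <- ho$site_score[idx[1L]]
      vapply(seq_len(resamples), function(r) {
        pick <- if (length(idx) <= N) idx else sample(idx, N)
        mean(pred[pick]) - target
      }, numeric(1L))
    }))
    sqrt(mean(errs^2))
  })
}

#' Random-forest feature importance
#'
#' Impurity-based (node-purity-increase) importances from a seeded random
#' forest regressing the target score on all 109 features, normalised to
#' sum to one, with roll-ups over the three feature groups.
#'
#' @param x feature matrix (matrix or feature-matrix data.frame).
#' @param y target scores (defaults to `site_score` for data.frames).
#' @param n_trees number of trees.
#' @param seed RNG seed.
#' @return List with `importance` (named, sums to 1), `groups`
#'   (summed importance of color / objects / texture), and `ranking`
#'   (feature names, most important first).
#' @export
feature_importance <- function(x, y = NULL, n_trees = 500L, seed = 1L) {
  if (is.data.frame(x)) {
    if (is.null(y)) y <- x$site_score
    x <- feature_columns(x)
  }
  if (length(unique(y)) < 2L)
    stop("importances undefined for a constant target")
  rf <- with_seed(seed,
    randomForest::randomForest(x = as.matrix(x), y = y, ntree = n_trees))
  imp <- rf$importance[, 1L]
  imp <- pmax(imp, 0)
  imp <- imp / sum(imp)
  reg <- feature_registry()
  grp <- tapply(imp[reg$name], reg$group, sum)
  list(importance = imp,
       groups = grp[c("color", "objects", "texture")],
       ranking = names(sort(imp, decreasing = TRUE)))
}

# Piepho-style insert-and-absorb connecting letters from a logical
# "significantly different" matrix over groups (ordered as `groups`).
connecting_letters <- function(groups, signif_pairs) {
  sets <- list(seq_along(groups))
  for (pr in signif_pairs) {
    i <- pr[1L]; j <- pr[2L]
    new_sets <- list()
    for (s in sets) {
      if (i %in% s && j %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, i)), list(setdiff(s, j)))
      } else {
        new_sets <- c(new_sets, list(s))
      }
    }
    # absorb: drop sets contained in another set
    keep <- rep(TRUE, length(new_sets))
    for (a in seq_along(new_sets)) for (b in seq_along(new_sets)) {
      if (a != b && keep[a] && keep[b] &&
          all(new_sets[[a]] %in% new_sets[[b]]) &&
          (length(new_sets[[a]]) < length(new_sets[[b]]) || a > b))
        keep[a] <- FALSE
    }
    sets <- new_sets[keep]
  }
  # letter sets ordered by their best-ranked member for stable output
  sets <- sets[order(vapply(sets, min, numeric(1L)))]
  out <- vapply(seq_along(groups), function(g) {
    paste0(letters[which(vapply(sets, function(s) g %in% s, logical(1L)))],
           collapse = "")
  }, character(1L))
  stats::setNames(out, groups)
}

#' Compare aesthetic values across sites
#'
#' One-way ANOVA over sites followed by Tukey's honest significant
#' difference test on all site pairs, with a connecting-letters report
#' (sites sharing a letter do not differ significantly at `alpha`).
#'
#' @param values numeric aesthetic values.
#' @param site site label per value.
#' @param alpha family-wise significance level for the letters.
#' @return List with `anova_p`, `tukey` (data.frame: pair, diff, lwr,
#'   upr, p_adj), and `letters` (named by site, ordered by decreasing
#'   site mean).
#' @export
site_comparison <- function(values, site, alpha = 0.05) {
  site <- as.character(site)
  counts <- table(site)
  if (length(counts) < 2L) stop("need at least two sites")
  if (any(counts < 2L))
    stop("site(s) with fewer than two values: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  d <- data.frame(v = values, site = factor(site))
  fit <- stats::aov(v ~ site, data = d)
  p <- summary(fit)[[1L]][["Pr(>F)"]][1L]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$site
  tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL)
  means <- sort(tapply(values, site, mean), decreasing = TRUE)
  grp <- names(means)
  sig <- list()
  for (r in seq_len(nrow(tukey))) {
    if (!is.na(tukey$p_adj[r]) && tukey$p_adj[r] < alpha) {
      gg <- strsplit(tukey$pair[r], "-", fixed = TRUE)[[1L]]
      sig <- c(sig, list(match(gg, grp)))
    }
  }
  list(anova_p = p, tukey = tukey,
       letters = connecting_letters(grp, sig))
}

#' Ordinary least-squares fit of aesthetic values against scores
#'
#' @param x,y numeric vectors (length at least 3).
#' @return List with `slope`, `intercept`, `r_squared` and the two-sided
#'   t-test `p` for the slope.
#' @export
regression_fit <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("`x` and `y` must have equal length >= 3")
  if (stats::sd(x) == 0) stop("zero variance in `x`")
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = s$r.squared,
       p = unname(s$coefficients[2L, 4L]))
}
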