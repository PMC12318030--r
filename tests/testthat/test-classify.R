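test_that("the lehmer mean follows its closed form", {
  expect_equal(lehmer_mean(c(2, 2), 2), 2)
  expect_equal(lehmer_mean(c(1, 2, 3), 2), 14 / 6)
  withr::with_seed(15L, {
    x <- stats::runif(20)
    expect_equal(lehmer_mean(x, 1), mean(x))
  })
  expect_warning(m <- lehmer_mean(c(-1, 1), 2))
  expect_equal(m, 0) # arithmetic-mean fallback
  expect_error(lehmer_mean(numeric(0)))
})

test_that("gaussian normalization maps the fitted statistics as specified", {
  withr::with_seed(16L, {
    X <- matrix(stats::rnorm(200, mean = 3, sd = 0.5), 50, 4)
    prm <- fit_gaussian_normalization(X)
    # centre -> 0.5, +3 sigma -> 1
    mid <- gaussian_normalize(matrix(prm$mu_L, 1), prm)
    expect_equal(as.vector(mid), rep(0.5, 4), tolerance = 1e-12)
    hi <- gaussian_normalize(matrix(prm$mu_L + 3 * prm$sigma, 1), prm)
    expect_equal(as.vector(hi), rep(1, 4), tolerance = 1e-12)
    lo <- gaussian_normalize(matrix(prm$mu_L - 6 * prm$sigma, 1), prm)
    expect_equal(as.vector(lo), rep(0, 4)) # clipped from -0.5
    prm_noclip <- fit_gaussian_normalization(X, clip = FALSE)
    lo2 <- gaussian_normalize(matrix(prm_noclip$mu_L - 6 * prm_noclip$sigma, 1),
                              prm_noclip)
    expect_equal(as.vector(lo2), rep(-0.5, 4), tolerance = 1e-12)
    # per-feature training Lehmer mean lands at 0.5
    Z <- gaussian_normalize(X, prm)
    expect_equal(apply(X, 2, lehmer_mean), prm$mu_L, tolerance = 1e-12)
    expect_error(gaussian_normalize(X, list()))
  })
})

test_that("min pooling equals the negated max pool and handles windows", {
  expect_equal(min_pool(matrix(c(1, 3, 2, 4), 2, 2), 2), matrix(1, 1, 1))
  expect_equal(min_pool(matrix(5, 4, 4), 2), matrix(5, 2, 2))
  withr::with_seed(17L, {
    g <- matrix(stats::rnorm(36), 6, 6)
    mx <- function(m, k) { # independent max pool
      out <- matrix(0, nrow(m) / k, ncol(m) / k)
      for (i in seq_len(nrow(out))) for (j in seq_len(ncol(out)))
        out[i, j] <- max(m[(i - 1) * k + 1:k, (j - 1) * k + 1:k])
      out
    }
    expect_equal(min_pool(g, 2), -mx(-g, 2))
    expect_equal(min_pool(g, 3), -mx(-g, 3))
  })
  expect_error(min_pool(matrix(0, 5, 5), 2))
})

test_that("maxout dominates its pieces and recovers the absolute value", {
  x <- seq(-3, 3, by = 0.5)
  expect_equal(maxout(x, c(1, -1)), abs(x))
  expect_equal(maxout(x, c(0.3, 0.3), c(1, 1)), 0.3 * x + 1) # identical pieces
  withr::with_seed(18L, {
    w <- stats::rnorm(3); b <- stats::rnorm(3)
    mo <- maxout(x, w, b)
    for (p in 1:3) expect_true(all(mo >= w[p] * x + b[p] - 1e-12))
  })
  expect_error(maxout(x, 1))
})

test_that("classifier forwards produce valid probability rows", {
  cfg <- classifier_config(input_size = 32L, seed = 4L)
  iln <- build_iln_tl(cfg)
  imgs <- lapply(1:3, function(s) fixture_image(32, seed = s))
  p <- iln$predict(imgs)
  expect_equal(dim(p), c(3L, 2L))
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-6)
  dm <- build_deep_maxout(cfg, n_features = 20L)
  X <- matrix(stats::runif(100), 5, 20)
  q <- dm$predict(X)
  expect_equal(rowSums(q), rep(1, 5), tolerance = 1e-6)
  dm2 <- build_deep_maxout(cfg, n_features = 20L)
  expect_identical(q, dm2$predict(X))
})

test_that("the separable convolution stage saves parameters over a full convolution", {
  cfg <- classifier_config(input_size = 32L, seed = 4L)
  iln <- build_iln_tl(cfg)
  C <- iln$trunk$out_channels; k <- cfg$iln$dw_kernel
  sep <- sum(vapply(iln$dw$par, length, 1L)) + sum(vapply(iln$pw$par, length, 1L))
  full <- k^2 * C * C + C # equivalent dense convolution of same kernel/channels
  expect_lt(sep, full)
  # closed-form comparison of the weight counts (bias aside)
  expect_lt(k^2 * C + C * C, k^2 * C * C)
})

test_that("the maxout classifier overfits a small separable problem", {
  withr::with_seed(19L, {
    X <- rbind(matrix(stats::rnorm(8 * 12, mean = -1), 8, 12),
               matrix(stats::rnorm(8 * 12, mean = 1), 8, 12))
    y <- rep(c(0L, 1L), each = 8)
    cfg <- classifier_config(dm = list(epochs = 200L, batch_size = 8L),
                             seed = 20L)
    dm <- build_deep_maxout(cfg, n_features = 12L)
    noduleCT:::train_classifier(
      dm, NULL, y, epochs = cfg$dm$epochs, batch_size = cfg$dm$batch_size,
      lr = cfg$dm$learning_rate, seed = 21L,
      forward = function(idx) dm$forward(X[idx, , drop = FALSE], TRUE),
      backward = dm$backward, layers = dm$layers())
    pred <- apply(dm$predict(X), 1, which.max) - 1L
    expect_equal(pred, y)
  })
})

test_that("ensemble training freezes the trunk, holds out validation and reproduces", {
  ds <- generate_dataset(20, 0.5, tiny_spec(), seed = 30L)
  imgs <- lapply(ds$items, function(it) it$image * it$mask)
  withr::with_seed(31L, feats <- matrix(stats::runif(20 * 16), 20, 16))
  feats[, 1] <- ds$labels + 0.2 * feats[, 1] # make the problem learnable
  cfg <- classifier_config(iln = list(epochs = 4L, batch_size = 8L),
                           dm = list(epochs = 4L, batch_size = 8L),
                           input_size = 32L, seed = 32L)
  ens <- suppressWarnings(train_ensemble(imgs, feats, ds$labels, cfg))
  expect_length(ens$history$iln, 4L)
  expect_length(ens$history$dm, 4L)
  expect_lt(ens$history$dm[4], ens$history$dm[1])
  expect_equal(length(ens$validation_index), round(0.2 * 20))
  # trunk untouched by training
  fresh <- build_iln_tl(cfg)
  expect_equal(noduleCT:::nn_params_digest(fresh$trunk$layers),
               noduleCT:::nn_params_digest(ens$iln$trunk$layers))
  ens2 <- suppressWarnings(train_ensemble(imgs, feats, ds$labels, cfg))
  expect_equal(noduleCT:::nn_params_digest(ens$iln$head_layers()),
               noduleCT:::nn_params_digest(ens2$iln$head_layers()))
  expect_equal(noduleCT:::nn_params_digest(ens$dm$layers()),
               noduleCT:::nn_params_digest(ens2$dm$layers()))
  expect_error(train_ensemble(imgs, feats, rep(0L, 20), cfg))
  pred <- predict_ensemble(ens, imgs[1:3], feats[1:3, ])
  expect_setequal(names(pred), c("p_iln_0", "p_iln_1", "p_dm_0", "p_dm_1",
                                 "p_fused_0", "p_fused_1", "label"))
  expect_equal(pred$p_fused_0 + pred$p_fused_1, rep(1, 3), tolerance = 1e-9)
})

test_that("soft voting fuses rows as a weighted average with ties to class 0", {
  v <- soft_vote(rbind(c(0.6, 0.4), c(0.3, 0.7)), c(0.5, 0.5))
  expect_equal(v$probabilities, c(0.45, 0.55))
  expect_equal(v$label, 1L)
  expect_equal(soft_vote(rbind(c(0.6, 0.4), c(0.3, 0.7)), c(1, 0))$label, 0L)
  expect_equal(soft_vote(rbind(c(0.2, 0.8), c(0.2, 0.8)))$probabilities,
               c(0.2, 0.8))
  expect_equal(soft_vote(rbind(c(0.5, 0.5), c(0.5, 0.5)))$label, 0L) # tie
  expect_error(soft_vote(rbind(c(0.9, 0.4), c(0.3, 0.7))))
  expect_error(soft_vote(rbind(c(0.6, 0.4), c(0.3, 0.7)), c(0.9, 0.5)))
  expect_error(soft_vote(rbind(c(0.6, 0.4), c(0.3, 0.7)), 1))
})
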