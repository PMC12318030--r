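test_that("attention and residual modules preserve tensor shape", {
  withr::with_seed(2L, {
    for (k in 1:5) {
      H <- sample(c(4L, 8L), 1); C <- sample(c(2L, 3L, 5L), 1)
      N <- sample(1:3, 1)
      x <- array(stats::rnorm(H * H * C * N), c(H, H, C, N))
      rb <- noduleCT:::module_resblock(C, C + 1L)
      expect_equal(dim(rb$forward(x, FALSE)), c(H, H, C + 1L, N))
      at <- noduleCT:::module_rdcab(C)
      expect_equal(dim(at$forward(x, FALSE)), dim(x))
    }
  })
})

test_that("attention-block backprop matches finite differences", {
  withr::with_seed(7L, {
    x <- array(stats::rnorm(4 * 4 * 2 * 2), c(4, 4, 2, 2))
    at <- noduleCT:::module_rdcab(2L)
    R <- array(stats::rnorm(length(x)), dim(x))
    at$forward(x, TRUE)
    dx <- at$backward(R)
    eps <- 1e-5
    idx <- sample(length(x), 10)
    num <- vapply(idx, function(k) {
      x1 <- x; x1[k] <- x1[k] + eps
      x2 <- x; x2[k] <- x2[k] - eps
      (sum(at$forward(x1, FALSE) * R) - sum(at$forward(x2, FALSE) * R)) / (2 * eps)
    }, 1)
    expect_equal(dx[idx], num, tolerance = 1e-5)
  })
})

test_that("the u-net forward keeps shape, stays in (0,1) and counts parameters deterministically", {
  cfg <- seg_config(depth = 2L, base_channels = 4L, input_size = 16L, seed = 3L)
  m1 <- build_p_resunet(cfg)
  m2 <- build_p_resunet(cfg)
  expect_equal(m1$param_count(), m2$param_count())
  expect_equal(noduleCT:::nn_params_digest(m1$layers()),
               noduleCT:::nn_params_digest(m2$layers()))
  x <- array(fixture_image(16, seed = 4L), c(16, 16, 1, 1))
  p <- m1$forward(x, train = FALSE)
  expect_equal(dim(p), c(16, 16, 1, 1))
  expect_true(all(p > 0 & p < 1))
  # the plain residual u-net ablation drops the attention parameters
  m0 <- build_p_resunet(seg_config(depth = 2L, base_channels = 4L,
                                   input_size = 16L, attention_enabled = FALSE))
  expect_lt(m0$param_count(), m1$param_count())
  expect_error(seg_config(depth = 3L, input_size = 30L))
})

test_that("training reduces the loss and is seed-reproducible", {
  ds <- fixture_dataset(n = 6L, size = 32L)
  cfg <- seg_config(input_size = 32L, epochs = 6L, batch_size = 2L, seed = 5L)
  fit <- train_segmenter(ds, cfg)
  expect_length(fit$history, 6L)
  expect_lt(fit$history[6], fit$history[1])
  fit2 <- train_segmenter(ds, cfg)
  expect_identical(fit$history, fit2$history)
  expect_equal(noduleCT:::nn_params_digest(fit$model$layers()),
               noduleCT:::nn_params_digest(fit2$model$layers()))
  # empty and all-negative datasets are rejected
  neg <- generate_dataset(2, 0, phantom_spec(image_size = 32L), seed = 1L)
  expect_error(train_segmenter(neg, cfg))
})

test_that("segmentation masks are binary and shrink monotonically with the threshold", {
  ds <- fixture_dataset(n = 4L, size = 32L)
  cfg <- seg_config(input_size = 32L, epochs = 2L, batch_size = 2L, seed = 6L)
  fit <- train_segmenter(ds, cfg)
  img <- ds$items[[1]]$image
  m <- segment(img, fit$model)
  expect_true(all(m %in% c(0L, 1L)))
  prev <- sum(segment(img, fit$model, threshold = 0.1))
  for (th in c(0.3, 0.5, 0.7, 0.9)) {
    cur <- sum(segment(img, fit$model, threshold = th))
    expect_lte(cur, prev)
    prev <- cur
  }
  # sigmoid outputs are strictly inside (0,1): extremes saturate the mask
  expect_equal(sum(segment(img, fit$model, threshold = 0)), 32L * 32L)
  expect_equal(sum(segment(img, fit$model, threshold = 1)), 0L)
  expect_error(segment(matrix(0.5, 16, 16), fit$model))
})

test_that("overlap metrics satisfy their identities and conventions", {
  a <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_equal(seg_metrics(a, a),
               list(dice = 1, jaccard = 1, segmentation_accuracy = 1))
  b <- matrix(c(0, 0, 1, 1), 2, 2)
  m <- seg_metrics(a, b)
  expect_equal(m$dice, 0)
  expect_equal(m$jaccard, 0)
  z <- matrix(0, 3, 3)
  expect_equal(seg_metrics(z, z),
               list(dice = 1, jaccard = 1, segmentation_accuracy = 1))
  # dice = 2J / (1 + J) on random mask pairs
  withr::with_seed(8L, {
    for (k in 1:100) {
      p <- matrix(stats::rbinom(64, 1, stats::runif(1, 0.1, 0.9)), 8, 8)
      t <- matrix(stats::rbinom(64, 1, stats::runif(1, 0.1, 0.9)), 8, 8)
      mm <- seg_metrics(p, t)
      expect_lt(abs(mm$dice - 2 * mm$jaccard / (1 + mm$jaccard)), 1e-12)
      expect_true(mm$dice >= 0 && mm$dice <= 1)
      expect_true(mm$jaccard >= 0 && mm$jaccard <= 1)
    }
  })
  expect_error(seg_metrics(a, matrix(0, 3, 3)))
})
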