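#' Lehmer mean
#'
#' `sum(x^Q) / sum(x^(Q-1))`. With `Q = 1` this is the arithmetic mean;
#' `Q = 2` (the default used by the normalization layer) weights larger
#' values more heavily. If the denominator is within `1e-8` of zero the
#' function falls back to the arithmetic mean with a warning.
#'
#' @param values Non-empty numeric vector.
#' @param Q Exponent.
#' @return Scalar mean.
#' @export
lehmer_mean <- function(values, Q = 2) {
  if (length(values) == 0L) stop("`values` must be non-empty", call. = FALSE)
  den <- sum(values^(Q - 1))
  if (abs(den) < 1e-8) {
    warning("degenerate Lehmer denominator; falling back to arithmetic mean")
    return(mean(values))
  }
  sum(values^Q) / den
}

#' Fit / apply Lehmer-centred Gaussian feature normalization
#'
#' Per feature, `N_Z = ((X - mu_L) / (3 * sigma) + 1) / 2` where `mu_L` is
#' the Lehmer mean and `sigma` the standard deviation of the training
#' values, so the training Lehmer mean maps to 0.5 and +/-3 sigma to 1/0.
#' Statistics are frozen at fit time.
#'
#' @param X Training feature matrix (samples x features) for the fit;
#'   any matrix/vector with matching feature count for the transform.
#' @param Q Lehmer exponent (2 by default).
#' @param clip Clip the transformed values to `[0, 1]`.
#' @return `fit_gaussian_normalization` returns a `gaussian_norm` parameter
#'   object; `gaussian_normalize` returns the normalized matrix.
#' @export
fit_gaussian_normalization <- function(X, Q = 2, clip = TRUE) {
  X <- as.matrix(X)
  den <- colSums(X^(Q - 1)); num <- colSums(X^Q)
  deg <- abs(den) < 1e-8
  mu <- ifelse(deg, colMeans(X), num / pmax(abs(den), 1e-12) * sign(den))
  if (any(deg))
    warning(sprintf("%d feature(s) had a degenerate Lehmer denominator; using arithmetic mean there", sum(deg)))
  sigma <- pmax(apply(X, 2, stats::sd), 1e-8)
  structure(list(mu_L = mu, sigma = sigma, Q = Q, clip = isTRUE(clip)),
            class = "gaussian_norm")
}

#' @rdname fit_gaussian_normalization
#' @param params A fitted `gaussian_norm` object.
#' @export
gaussian_normalize <- function(X, params) {
  if (!inherits(params, "gaussian_norm"))
    stop("`params` must come from fit_gaussian_normalization()", call. = FALSE)
  X <- if (is.matrix(X)) X else matrix(X, nrow = 1)
  Z <- (sweep(sweep(X, 2, params$mu_L), 2, 3 * params$sigma, `/`) + 1) / 2
  if (params$clip) Z <- clip01(Z)
  Z
}

#' Minimum pooling of a matrix
#'
#' Per non-overlapping `k x k` window minimum; equal to the negated max
#' pool of the negated input.
#'
#' @param grid Numeric matrix with dimensions divisible by `k`.
#' @param k Window size.
#' @return Matrix of size `dim(grid) / k`.
#' @export
min_pool <- function(grid, k = 2L) {
  if (nrow(grid) %% k != 0L || ncol(grid) %% k != 0L)
    stop("grid dimensions must be divisible by k", call. = FALSE)
  a <- array(grid, c(k, nrow(grid) %/% k, k, ncol(grid) %/% k))
  apply(a, c(2, 4), min)
}

#' Maxout activation over affine pieces
#'
#' Elementwise maximum of `k` affine maps `w[p] * x + b[p]`, giving a
#' piecewise-linear activation with non-zero slope on both sides (e.g.
#' `w = c(1, -1), b = c(0, 0)` yields `abs(x)`).
#'
#' @param x Numeric vector/matrix.
#' @param w Slopes, one per piece (k >= 2).
#' @param b Intercepts, one per piece (default zeros).
#' @return Same shape as `x`.
#' @export
maxout <- function(x, w, b = numeric(length(w))) {
  if (length(w) < 2L) stop("need at least 2 pieces", call. = FALSE)
  Reduce(pmax, Map(function(wp, bp) wp * x + bp, w, b))
}

#' Classifier ensemble configuration
#'
#' Defaults mirror the training regimen of the two classifiers: the
#' transfer-learning LeNet head (`iln`) uses hidden_neurons = 128, relu,
#' adam, learning_rate = 0.001, batch_size = 64, validation_split = 0.2,
#' epochs = 50 and a 5x5 depthwise separable kernel; the maxout network
#' (`dm`) uses batch_size = 32, learning_rate = 0.01, pool size 2 and
#' epochs = 50.
#'
#' @param iln,dm Named lists overriding individual classifier settings.
#' @param trunk `"mini"` (4-layer VGG-style trunk, the desk-scale default
#'   that needs no downloads) or `"vgg16"` (full 13-conv trunk,
#'   seed-initialized). The trunk is frozen in both cases.
#' @param input_size Image side length fed to the trunk.
#' @param seed Integer seed for initialization, splits and batch order.
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(iln = list(), dm = list(), trunk = c("mini", "vgg16"),
                              input_size = 64L, seed = 1L) {
  trunk <- match.arg(trunk)
  iln_def <- list(hidden_neurons = 128L, activation = "relu", optimizer = "adam",
                  learning_rate = 0.001, batch_size = 64L, validation_split = 0.2,
                  epochs = 50L, dw_kernel = 5L, dropout = 0.3)
  dm_def <- list(batch_size = 32L, learning_rate = 0.01, pool_k = 2L,
                 epochs = 50L, maxout_pieces = 3L, conv_channels = 16L,
                 conv_kernel = 3L, maxout_units = 64L)
  iln <- utils::modifyList(iln_def, iln)
  dm <- utils::modifyList(dm_def, dm)
  if (iln$validation_split <= 0 || iln$validation_split >= 1)
    stop("`validation_split` must lie in (0, 1)", call. = FALSE)
  stopifnot(iln$epochs > 0, dm$epochs > 0, iln$learning_rate > 0,
            dm$learning_rate > 0, dm$maxout_pieces >= 2)
  structure(list(iln = iln, dm = dm, trunk = trunk,
                 input_size = as.integer(input_size), seed = as.integer(seed)),
            class = "classifier_config")
}

# frozen feature trunk; built under the current RNG state
build_trunk <- function(kind, input_size) {
  plan <- if (kind == "mini") {
    list(c(1L, 8L), "P", c(8L, 16L), "P", c(16L, 32L), "P", c(32L, 32L), "P")
  } else {
    list(c(1L, 64L), c(64L, 64L), "P", c(64L, 128L), c(128L, 128L), "P",
         c(128L, 256L), c(256L, 256L), c(256L, 256L), "P",
         c(256L, 512L), c(512L, 512L), c(512L, 512L), "P",
         c(512L, 512L), c(512L, 512L), c(512L, 512L), "P")
  }
  layers <- list(); s <- input_size; c_out <- 1L
  for (p in plan) {
    if (identical(p, "P")) {
      layers <- c(layers, list(nn_pool2("max"))); s <- s %/% 2L
    } else {
      l <- nn_conv2d(p[1], p[2], 3L); l$frozen <- TRUE
      layers <- c(layers, list(l, nn_act("relu")))
      c_out <- p[2]
    }
  }
  list(layers = layers, out_size = s, out_channels = c_out)
}

trunk_forward <- function(trunk, x) {
  h <- x
  for (l in trunk$layers) h <- l$forward(h, train = FALSE)
  h
}

# stack a list of matrices into (H, W, 1, N)
stack_images <- function(images, size) {
  N <- length(images)
  X <- array(0, c(size, size, 1L, N))
  for (n in seq_len(N)) {
    im <- images[[n]]
    if (!all(dim(im) == size)) im <- resize_bilinear(im, size)
    X[, , 1L, n] <- im
  }
  X
}

#' Build the transfer-learning LeNet-style image classifier
#'
#' A frozen VGG-style convolutional trunk feeds a head of: Lehmer-centred
#' Gaussian feature normalization, a 5x5 depthwise separable convolution,
#' relu, max pooling, min pooling, two dense(128, relu) + dropout stages
#' and a 2-way softmax. The normalization statistics are fitted on the
#' training trunk features by [train_ensemble()].
#'
#' @param config A [classifier_config()].
#' @return An `iln_tl` model environment.
#' @export
build_iln_tl <- function(config = classifier_config()) {
  stopifnot(inherits(config, "classifier_config"))
  withr::with_seed(config$seed, {
    self <- new.env(parent = emptyenv())
    self$config <- config
    self$trunk <- build_trunk(config$trunk, config$input_size)
    s <- self$trunk$out_size; C <- self$trunk$out_channels
    self$dw <- nn_dwconv2d(C, config$iln$dw_kernel)
    self$pw <- nn_conv2d(C, C, 1L) # pointwise stage of the separable conv
    self$act_dw <- nn_act("relu")
    self$do_maxpool <- s >= 2L; if (self$do_maxpool) s <- s %/% 2L
    self$do_minpool <- s >= 2L; if (self$do_minpool) s <- s %/% 2L
    self$maxp <- nn_pool2("max"); self$minp <- nn_pool2("min")
    self$flat <- nn_flatten()
    d_in <- s * s * C
    hn <- config$iln$hidden_neurons
    self$dense1 <- nn_dense(d_in, hn); self$act1 <- nn_act("relu")
    self$drop1 <- nn_dropout(config$iln$dropout)
    self$dense2 <- nn_dense(hn, hn); self$act2 <- nn_act("relu")
    self$drop2 <- nn_dropout(config$iln$dropout)
    self$dense3 <- nn_dense(hn, 2L)
    self$norm <- NULL # fitted on training trunk features

    self$head_layers <- function()
      list(self$dw, self$pw, self$act_dw, self$maxp, self$minp, self$flat,
           self$dense1, self$act1, self$drop1, self$dense2, self$act2,
           self$drop2, self$dense3)
    self$layers <- function() c(self$trunk$layers, self$head_layers())

    # fmap: trunk output (s, s, C, N); returns logits N x 2
    self$forward_head <- function(fmap, train = TRUE) {
      d <- dim(fmap)
      if (!is.null(self$norm)) {
        flatf <- t(matrix(fmap, prod(d[1:3]), d[4]))
        fmap <- array(t(gaussian_normalize(flatf, self$norm)), d)
      }
      h <- self$pw$forward(self$dw$forward(fmap, train), train)
      h <- self$act_dw$forward(h, train)
      if (self$do_maxpool) h <- self$maxp$forward(h, train)
      if (self$do_minpool) h <- self$minp$forward(h, train)
      h <- self$flat$forward(h, train)
      h <- self$drop1$forward(self$act1$forward(self$dense1$forward(h, train), train), train)
      h <- self$drop2$forward(self$act2$forward(self$dense2$forward(h, train), train), train)
      self$dense3$forward(h, train)
    }
    self$backward_head <- function(dlogits) {
      d <- self$dense3$backward(dlogits)
      d <- self$drop2$backward(d); d <- self$act2$backward(d); d <- self$dense2$backward(d)
      d <- self$drop1$backward(d); d <- self$act1$backward(d); d <- self$dense1$backward(d)
      d <- self$flat$backward(d)
      if (self$do_minpool) d <- self$minp$backward(d)
      if (self$do_maxpool) d <- self$maxp$backward(d)
      d <- self$act_dw$backward(d)
      self$dw$backward(self$pw$backward(d))
    }
    self$predict <- function(images) {
      X <- stack_images(images, self$config$input_size)
      fmap <- trunk_forward(self$trunk, X)
      nn_softmax(self$forward_head(fmap, train = FALSE))
    }
    class(self) <- "iln_tl"
    self
  })
}

#' Build the maxout feature classifier
#'
#' Operates on the 201-value hybrid feature vector viewed as a 1-D
#' sequence: convolution (kernel 3, 16 channels), per-channel batch
#' normalization, max pooling (window 2), a dense maxout block (3 affine
#' pieces) and a 2-way softmax.
#'
#' @param config A [classifier_config()].
#' @param n_features Input feature dimension (201 for the full vector).
#' @return A `deep_maxout` model environment.
#' @export
build_deep_maxout <- function(config = classifier_config(), n_features = 201L) {
  stopifnot(inherits(config, "classifier_config"))
  withr::with_seed(config$seed + 7L, {
    self <- new.env(parent = emptyenv())
    self$config <- config
    self$n_features <- as.integer(n_features)
    cc <- config$dm$conv_channels
    self$conv <- nn_conv1d(1L, cc, config$dm$conv_kernel)
    self$bn <- nn_batchnorm(cc)
    self$pool <- nn_pool1d(config$dm$pool_k)
    Lp <- n_features %/% config$dm$pool_k
    self$mo <- nn_maxout_dense(Lp * cc, config$dm$maxout_units, config$dm$maxout_pieces)
    self$out <- nn_dense(config$dm$maxout_units, 2L)
    self$layers <- function() list(self$conv, self$bn, self$pool, self$mo, self$out)

    # X: N x n_features matrix -> logits N x 2
    self$forward <- function(X, train = TRUE) {
      N <- nrow(X); L <- ncol(X)
      x <- array(t(X), c(L, 1L, N))
      h <- self$conv$forward(x, train)                    # L x cc x N
      d <- dim(h)
      hm <- matrix(aperm(h, c(1, 3, 2)), ncol = d[2])     # (L*N) x cc
      hm <- self$bn$forward(hm, train)
      h <- aperm(array(hm, c(d[1], d[3], d[2])), c(1, 3, 2))
      self$bn_dim <- d
      h <- self$pool$forward(h, train)                    # Lp x cc x N
      dp <- dim(h)
      hf <- t(matrix(h, prod(dp[1:2]), dp[3]))            # N x (Lp*cc)
      self$pool_dim <- dp
      self$out$forward(self$mo$forward(hf, train), train)
    }
    self$backward <- function(dlogits) {
      d <- self$mo$backward(self$out$backward(dlogits))
      dp <- self$pool_dim
      d <- array(t(d), dp)
      d <- self$pool$backward(d)
      dd <- self$bn_dim
      dm <- matrix(aperm(d, c(1, 3, 2)), ncol = dd[2])
      dm <- self$bn$backward(dm)
      d <- aperm(array(dm, c(dd[1], dd[3], dd[2])), c(1, 3, 2))
      self$conv$backward(d)
    }
    self$predict <- function(X) nn_softmax(self$forward(as.matrix(X), train = FALSE))
    class(self) <- "deep_maxout"
    self
  })
}

# generic mini-batch Adam training of a classifier on (forward, backward)
train_classifier <- function(model, X_fw, y, epochs, batch_size, lr, seed,
                             forward, backward, layers) {
  n <- length(y)
  y1 <- cbind(1 - y, y) # column 1 = class 0
  history <- numeric(epochs)
  withr::with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      losses <- c()
      for (start in seq(1L, n, batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        logits <- forward(idx)
        sm <- nn_softmax_ce(logits, y1[idx, , drop = FALSE])
        backward(sm$dlogits)
        nn_adam_step(layers, lr)
        losses <- c(losses, sm$loss)
      }
      history[ep] <- mean(losses)
    }
  })
  history
}

#' Train the soft-voting classifier ensemble
#'
#' The image classifier trains on the segmented slices through its frozen
#' trunk (trunk features are precomputed once; the Gaussian-normalization
#' statistics are fitted on the training trunk features and then frozen);
#' the maxout classifier trains on the 201-value feature vectors. A
#' validation fraction (`iln$validation_split`) of the images is held out
#' from the image-classifier batches. Deterministic given the config seed.
#'
#' @param images List of segmented slices (numeric matrices).
#' @param feature_vectors Matrix (samples x features) of hybrid features.
#' @param labels Binary labels (0 non-cancer / 1 cancer); both classes must
#'   be present.
#' @param config A [classifier_config()].
#' @return An `ensemble` list with both trained models and loss histories.
#' @export
train_ensemble <- function(images, feature_vectors, labels,
                           config = classifier_config()) {
  labels <- as.integer(labels)
  feature_vectors <- as.matrix(feature_vectors)
  if (length(images) != length(labels) || nrow(feature_vectors) != length(labels))
    stop("images, feature_vectors and labels must be aligned", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("both classes must be present", call. = FALSE)

  iln <- build_iln_tl(config)
  X <- stack_images(images, config$input_size)
  fmap <- trunk_forward(iln$trunk, X)
  dfm <- dim(fmap)
  n <- length(labels)

  # validation hold-out for the image classifier
  n_val <- round(config$iln$validation_split * n)
  val_idx <- withr::with_seed(config$seed + 11L, sample.int(n, n_val))
  tr_idx <- setdiff(seq_len(n), val_idx)

  flat_tr <- t(matrix(fmap[, , , tr_idx, drop = FALSE], prod(dfm[1:3])))
  iln$norm <- fit_gaussian_normalization(flat_tr, Q = 2, clip = TRUE)

  sub4 <- function(a, idx) a[, , , idx, drop = FALSE]
  iln_hist <- train_classifier(
    iln, NULL, labels[tr_idx],
    epochs = config$iln$epochs, batch_size = config$iln$batch_size,
    lr = config$iln$learning_rate, seed = config$seed + 13L,
    forward = function(idx) iln$forward_head(sub4(fmap, tr_idx[idx]), train = TRUE),
    backward = iln$backward_head,
    layers = iln$head_layers())

  dm <- build_deep_maxout(config, ncol(feature_vectors))
  dm_hist <- train_classifier(
    dm, NULL, labels,
    epochs = config$dm$epochs, batch_size = config$dm$batch_size,
    lr = config$dm$learning_rate, seed = config$seed + 17L,
    forward = function(idx) dm$forward(feature_vectors[idx, , drop = FALSE], train = TRUE),
    backward = dm$backward,
    layers = dm$layers())

  structure(list(iln = iln, dm = dm, config = config,
                 history = list(iln = iln_hist, dm = dm_hist),
                 validation_index = sort(val_idx)),
            class = "ensemble")
}

#' Soft-voting fusion of classifier probability rows
#'
#' Fused class probabilities are the weighted average of the per-classifier
#' rows (`Y = argmax_i sum_j w_j p_ij`); the default weights are equal
#' (0.5 each for two classifiers). Exact probability ties resolve to class
#' 0 (non-cancer), the conservative default.
#'
#' @param P Matrix with one row per classifier and one column per class;
#'   every row must sum to 1 (tolerance 1e-6).
#' @param weights Classifier weights summing to 1; length must match
#'   `nrow(P)`.
#' @return List with `label` (0-based class index) and `probabilities`.
#' @export
soft_vote <- function(P, weights = rep(1 / nrow(P), nrow(P))) {
  P <- as.matrix(P)
  if (length(weights) != nrow(P))
    stop("weights must match the number of classifier rows", call. = FALSE)
  if (any(abs(rowSums(P) - 1) > 1e-6))
    stop("each probability row must sum to 1", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-6)
    stop("weights must sum to 1", call. = FALSE)
  fused <- as.vector(weights %*% P)
  list(label = which.max(fused) - 1L, probabilities = fused)
}

#' Predict with the trained ensemble
#'
#' @param ensemble Result of [train_ensemble()].
#' @param images List of segmented slices.
#' @param feature_vectors Matrix of hybrid features aligned with `images`.
#' @param weights Soft-voting weights.
#' @return Data frame with per-classifier and fused class probabilities and
#'   the voted `label`.
#' @export
predict_ensemble <- function(ensemble, images, feature_vectors,
                             weights = c(0.5, 0.5)) {
  p_iln <- ensemble$iln$predict(images)
  p_dm <- ensemble$dm$predict(as.matrix(feature_vectors))
  n <- nrow(p_iln)
  fused <- matrix(0, n, 2); label <- integer(n)
  for (i in seq_len(n)) {
    v <- soft_vote(rbind(p_iln[i, ], p_dm[i, ]), weights)
    fused[i, ] <- v$probabilities
    label[i] <- v$label
  }
  data.frame(p_iln_0 = p_iln[, 1], p_iln_1 = p_iln[, 2],
             p_dm_0 = p_dm[, 1], p_dm_1 = p_dm[, 2],
             p_fused_0 = fused[, 1], p_fused_1 = fused[, 2],
             label = label)
}
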