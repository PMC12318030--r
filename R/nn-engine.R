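# Minimal CPU layer engine.
#
# Batched activation tensors are 4-D arrays dim (H, W, C, N); dense
# activations are N x D matrices. Every layer is a mutable environment with
# `par` (named list of parameter arrays), `grad` (matching gradients filled
# by backward), `forward(x, train)` and `backward(dy)`; composite networks
# wire layers together with explicit forward/backward passes. Optimization
# is Adam over all unfrozen layers. Everything runs on base-R matrix algebra
# (im2col convolutions), which is plenty at the 64-px desk scale the
# package targets.

#' Parametric rectified linear unit
#'
#' `x` for positive inputs, `alpha * x` otherwise, elementwise.
#'
#' @param x Numeric scalar, vector, matrix or array.
#' @param alpha Negative-slope parameter (scalar, or broadcastable to `x`).
#' @return Same shape as `x`.
#' @export
prelu <- function(x, alpha) {
  ifelse(x > 0, x, alpha * x)
}

#' Sigmoid-derivative weighted linear activation
#'
#' The conventional variant is `s(x) * (1 + x * (1 - s(x)))` with the plain
#' logistic `s`. The improved variant gates the logistic through a
#' hyperbolic tangent first: `SF(x) = 1 / (1 + exp(-tanh(x)))`, then
#' `F(x) = SF(x) * (1 + x * (1 - SF(x)))`. The tanh gate bounds the
#' logistic argument to `[-1, 1]`, so for large `|x|` the function grows
#' linearly with slope `s(1) * (1 - s(1))` instead of saturating.
#'
#' @param x Numeric scalar, vector, matrix or array.
#' @param variant `"improved"` (tanh-gated) or `"conventional"`.
#' @return Same shape as `x`.
#' @export
d_silu <- function(x, variant = c("improved", "conventional")) {
  variant <- match.arg(variant)
  s <- if (variant == "improved") stats::plogis(tanh(x)) else stats::plogis(x)
  s * (1 + x * (1 - s))
}

# derivative of d_silu for backprop
d_silu_grad <- function(x, variant = "improved") {
  if (variant == "improved") {
    tt <- tanh(x)
    s <- stats::plogis(tt)
    ds <- s * (1 - s) * (1 - tt^2)
  } else {
    s <- stats::plogis(x)
    ds <- s * (1 - s)
  }
  ds * (1 + x - 2 * x * s) + s - s^2
}

nn_he_init <- function(fan_in, dims) {
  array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
}

new_nn_layer <- function(cls) {
  e <- new.env(parent = emptyenv())
  e$par <- list(); e$grad <- NULL; e$opt <- NULL; e$frozen <- FALSE
  class(e) <- c(cls, "nn_layer")
  e
}

# batched im2col: (H*W*N) x (k*k*C), one slice per kernel offset over the
# whole batch
im2col_batch <- function(x, k) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  p <- (k - 1L) %/% 2L
  xp <- array(0, c(H + 2L * p, W + 2L * p, C, N))
  xp[p + seq_len(H), p + seq_len(W), , ] <- x
  cols <- matrix(0, H * W * N, k * k * C)
  j <- 0L
  for (c in seq_len(C)) for (dx in seq_len(k)) for (dy in seq_len(k)) {
    j <- j + 1L
    cols[, j] <- xp[dy - 1L + seq_len(H), dx - 1L + seq_len(W), c, ]
  }
  cols
}

# the input gradient of a same-padded stride-1 convolution is itself a
# convolution of the output gradient with the spatially flipped,
# channel-transposed weights
flip_weights <- function(W, k, c_in, c_out) {
  a <- array(W, c(k, k, c_in, c_out))
  a <- a[k:1, k:1, , , drop = FALSE]
  matrix(aperm(a, c(1, 2, 4, 3)), k * k * c_out, c_in)
}

# rows of the (H*W*N) x c_out product are ordered (H, W, N); rearrange to
# the (H, W, c_out, N) tensor layout
cols_to_tensor <- function(m, H, W, N) {
  aperm(array(m, c(H, W, N, ncol(m))), c(1, 2, 4, 3))
}
tensor_to_cols <- function(a) {
  d <- dim(a)
  matrix(aperm(a, c(1, 2, 4, 3)), d[1] * d[2] * d[4], d[3])
}

# same-padded k x k convolution, stride 1
nn_conv2d <- function(c_in, c_out, k = 3L) {
  self <- new_nn_layer("nn_conv2d")
  k <- as.integer(k)
  self$k <- k; self$c_in <- c_in; self$c_out <- c_out
  self$par <- list(W = nn_he_init(k * k * c_in, c(k * k * c_in, c_out)),
                   b = numeric(c_out))
  self$forward <- function(x, train = TRUE) {
    d <- dim(x); H <- d[1]; W <- d[2]; N <- d[4]
    cols <- im2col_batch(x, self$k)
    out <- cols %*% self$par$W
    out <- sweep(out, 2, self$par$b, `+`)
    if (train) self$cache <- list(cols = cols, dim = d)
    cols_to_tensor(out, H, W, N)
  }
  self$backward <- function(dy) {
    d <- self$cache$dim; H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
    dym <- tensor_to_cols(dy)
    self$grad <- list(W = crossprod(self$cache$cols, dym), b = colSums(dym))
    self$cache <- NULL
    Wb <- flip_weights(self$par$W, self$k, C, self$c_out)
    cols_to_tensor(im2col_batch(dy, self$k) %*% Wb, H, W, N)
  }
  self
}

# depthwise k x k convolution: one spatial filter per input channel
nn_dwconv2d <- function(channels, k = 5L) {
  self <- new_nn_layer("nn_dwconv2d")
  k <- as.integer(k)
  self$k <- k; self$channels <- channels
  self$par <- list(W = nn_he_init(k * k, c(k * k, channels)),
                   b = numeric(channels))
  self$forward <- function(x, train = TRUE) {
    d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
    cols <- vector("list", C)
    out <- array(0, d)
    for (c in seq_len(C)) {
      cn <- im2col_batch(x[, , c, , drop = FALSE], self$k)
      cols[[c]] <- cn
      out[, , c, ] <- cn %*% self$par$W[, c] + self$par$b[c]
    }
    if (train) self$cache <- list(cols = cols, dim = d)
    out
  }
  self$backward <- function(dy) {
    d <- self$cache$dim; H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
    dW <- matrix(0, self$k^2, C); db <- numeric(C)
    dx <- array(0, d)
    for (c in seq_len(C)) {
      dyc <- as.vector(dy[, , c, ])
      dW[, c] <- crossprod(self$cache$cols[[c]], dyc)
      db[c] <- sum(dyc)
      Wb <- flip_weights(self$par$W[, c, drop = FALSE], self$k, 1L, 1L)
      dx[, , c, ] <- im2col_batch(dy[, , c, , drop = FALSE], self$k) %*% Wb
    }
    self$grad <- list(W = dW, b = db)
    self$cache <- NULL
    dx
  }
  self
}

nn_dense <- function(d_in, d_out) {
  self <- new_nn_layer("nn_dense")
  self$par <- list(W = nn_he_init(d_in, c(d_in, d_out)), b = numeric(d_out))
  self$forward <- function(x, train = TRUE) {
    if (train) self$cache <- x
    sweep(x %*% self$par$W, 2, self$par$b, `+`)
  }
  self$backward <- function(dy) {
    self$grad <- list(W = crossprod(self$cache, dy), b = colSums(dy))
    dx <- dy %*% t(self$par$W)
    self$cache <- NULL
    dx
  }
  self
}

# trainable negative slope, one alpha per channel (4-D input, channel dim 3)
# or per feature column (matrix input)
nn_prelu <- function(n_ch, alpha0 = 0.25) {
  self <- new_nn_layer("nn_prelu")
  self$par <- list(alpha = rep(alpha0, n_ch))
  self$forward <- function(x, train = TRUE) {
    if (train) self$cache <- x
    if (is.matrix(x)) {
      sweep_a <- matrix(self$par$alpha, nrow(x), ncol(x), byrow = TRUE)
    } else {
      d <- dim(x)
      sweep_a <- array(rep(rep(self$par$alpha, each = d[1] * d[2]), d[4]), d)
    }
    ifelse(x > 0, x, sweep_a * x)
  }
  self$backward <- function(dy) {
    x <- self$cache
    neg <- x <= 0
    if (is.matrix(x)) {
      da <- colSums(dy * x * neg)
      sweep_a <- matrix(self$par$alpha, nrow(x), ncol(x), byrow = TRUE)
    } else {
      d <- dim(x)
      contrib <- dy * x * neg
      # channel last so each column of the (H*W*N) x C matrix is one channel
      da <- colSums(matrix(aperm(contrib, c(1, 2, 4, 3)), ncol = d[3]))
      sweep_a <- array(rep(rep(self$par$alpha, each = d[1] * d[2]), d[4]), d)
    }
    self$grad <- list(alpha = da)
    dx <- dy * ifelse(neg, sweep_a, 1)
    self$cache <- NULL
    dx
  }
  self
}

# fixed elementwise activation
nn_act <- function(name = c("relu", "sigmoid", "dsilu", "dsilu_conventional")) {
  name <- match.arg(name)
  self <- new_nn_layer("nn_act")
  self$name <- name
  self$forward <- function(x, train = TRUE) {
    if (train) self$cache <- x
    switch(name,
           relu = pmax(x, 0),
           sigmoid = stats::plogis(x),
           dsilu = d_silu(x, "improved"),
           dsilu_conventional = d_silu(x, "conventional"))
  }
  self$backward <- function(dy) {
    x <- self$cache; self$cache <- NULL
    g <- switch(name,
                relu = (x > 0) * 1,
                sigmoid = { s <- stats::plogis(x); s * (1 - s) },
                dsilu = d_silu_grad(x, "improved"),
                dsilu_conventional = d_silu_grad(x, "conventional"))
    dy * g
  }
  self
}

sublattices2 <- function(x) {
  d <- dim(x)
  i1 <- seq(1L, d[1], 2L); i2 <- i1 + 1L
  j1 <- seq(1L, d[2], 2L); j2 <- j1 + 1L
  list(x[i1, j1, , , drop = FALSE], x[i2, j1, , , drop = FALSE],
       x[i1, j2, , , drop = FALSE], x[i2, j2, , , drop = FALSE])
}

nn_pool2 <- function(kind = c("max", "min")) {
  kind <- match.arg(kind)
  self <- new_nn_layer("nn_pool2")
  cmp <- if (kind == "max") pmax else pmin
  self$forward <- function(x, train = TRUE) {
    a <- sublattices2(x)
    out <- cmp(a[[1]], a[[2]], a[[3]], a[[4]])
    if (train) self$cache <- list(a = a, out = out, dim = dim(x))
    out
  }
  self$backward <- function(dy) {
    d <- self$cache$dim
    dx <- array(0, d)
    i1 <- seq(1L, d[1], 2L); i2 <- i1 + 1L
    j1 <- seq(1L, d[2], 2L); j2 <- j1 + 1L
    rows <- list(i1, i2, i1, i2); cols <- list(j1, j1, j2, j2)
    assigned <- array(FALSE, dim(self$cache$out))
  for (s in 1:4) {
      hit <- (self$cache$a[[s]] == self$cache$out) & !assigned
      assigned <- assigned | hit
      g <- array(0, dim(dy)); g[hit] <- dy[hit]
      dx[rows[[s]], cols[[s]], , ] <- dx[rows[[s]], cols[[s]], , , drop = FALSE] + g
    }
    self$cache <- NULL
    dx
  }
  self
}

nn_upsample2 <- function() {
  self <- new_nn_layer("nn_upsample2")
  self$forward <- function(x, train = TRUE) {
    d <- dim(x)
    if (train) self$cache <- d
    x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , , drop = FALSE]
  }
  self$backward <- function(dy) {
    a <- sublattices2(dy)
    self$cache <- NULL
    a[[1]] + a[[2]] + a[[3]] + a[[4]]
  }
  self
}

# global max / average pool: (H, W, C, N) -> N x C matrix
nn_gpool <- function(kind = c("max", "avg")) {
  kind <- match.arg(kind)
  self <- new_nn_layer("nn_gpool")
  self$forward <- function(x, train = TRUE) {
    d <- dim(x)
    out <- t(apply(x, c(3, 4), if (kind == "max") max else mean))
    if (d[4] == 1L) out <- matrix(out, 1L, d[3])
    if (train) {
      self$cache <- list(dim = d,
                         arg = if (kind == "max") apply(x, c(3, 4), which.max))
    }
    out
  }
  self$backward <- function(dy) {
    d <- self$cache$dim
    dx <- array(0, d)
    if (kind == "avg") {
      dx <- array(rep(t(dy), each = d[1] * d[2]), d) / (d[1] * d[2])
    } else {
      arg <- self$cache$arg
      for (n in seq_len(d[4])) for (c in seq_len(d[3])) {
        p <- arg[c, n]
        iy <- (p - 1L) %% d[1] + 1L
        ix <- (p - 1L) %/% d[1] + 1L
        dx[iy, ix, c, n] <- dy[n, c]
      }
    }
    self$cache <- NULL
    dx
  }
  self
}

nn_flatten <- function() {
  self <- new_nn_layer("nn_flatten")
  self$forward <- function(x, train = TRUE) {
    d <- dim(x)
    if (train) self$cache <- d
    t(matrix(x, prod(d[1:3]), d[4]))
  }
  self$backward <- function(dy) {
    d <- self$cache; self$cache <- NULL
    array(t(dy), d)
  }
  self
}

nn_dropout <- function(rate = 0.3) {
  self <- new_nn_layer("nn_dropout")
  self$rate <- rate
  self$forward <- function(x, train = TRUE) {
    if (!train || self$rate <= 0) { self$cache <- NULL; return(x) }
    mask <- (matrix(stats::runif(length(x)), nrow(x)) >= self$rate) / (1 - self$rate)
    self$cache <- mask
    x * mask
  }
  self$backward <- function(dy) {
    if (is.null(self$cache)) return(dy)
    m <- self$cache; self$cache <- NULL
    dy * m
  }
  self
}

# per-column batch normalization on N x D matrices
nn_batchnorm <- function(d, momentum = 0.9, eps = 1e-5) {
  self <- new_nn_layer("nn_batchnorm")
  self$par <- list(gamma = rep(1, d), beta = rep(0, d))
  self$run_mean <- rep(0, d); self$run_var <- rep(1, d)
  self$eps <- eps; self$momentum <- momentum
  self$forward <- function(x, train = TRUE) {
    if (train) {
      mu <- colMeans(x)
      v <- colMeans(sweep(x, 2, mu)^2)
      self$run_mean <- self$momentum * self$run_mean + (1 - self$momentum) * mu
      self$run_var <- self$momentum * self$run_var + (1 - self$momentum) * v
    } else {
      mu <- self$run_mean; v <- self$run_var
    }
    inv <- 1 / sqrt(v + self$eps)
    xhat <- sweep(sweep(x, 2, mu), 2, inv, `*`)
    if (train) self$cache <- list(xhat = xhat, inv = inv)
    sweep(sweep(xhat, 2, self$par$gamma, `*`), 2, self$par$beta, `+`)
  }
  self$backward <- function(dy) {
    xhat <- self$cache$xhat; inv <- self$cache$inv
    N <- nrow(dy)
    dgamma <- colSums(dy * xhat); dbeta <- colSums(dy)
    dxhat <- sweep(dy, 2, self$par$gamma, `*`)
    dx <- sweep(dxhat -
                  matrix(colMeans(dxhat), N, ncol(dy), byrow = TRUE) -
                  xhat * matrix(colMeans(dxhat * xhat), N, ncol(dy), byrow = TRUE),
                2, inv, `*`)
    self$grad <- list(gamma = dgamma, beta = dbeta)
    self$cache <- NULL
    dx
  }
  self
}

# dense maxout block: elementwise max over `pieces` affine projections
nn_maxout_dense <- function(d_in, units, pieces = 3L) {
  self <- new_nn_layer("nn_maxout_dense")
  self$pieces <- pieces
  W <- array(stats::rnorm(d_in * units * pieces, 0, sqrt(2 / d_in)),
             c(d_in, units, pieces))
  self$par <- list(W = W, b = matrix(0, units, pieces))
  self$forward <- function(x, train = TRUE) {
    zs <- lapply(seq_len(self$pieces), function(p)
      sweep(x %*% self$par$W[, , p], 2, self$par$b[, p], `+`))
    out <- Reduce(pmax, zs)
    if (train) self$cache <- list(x = x, zs = zs, out = out)
    out
  }
  self$backward <- function(dy) {
    x <- self$cache$x
    dW <- array(0, dim(self$par$W)); db <- matrix(0, nrow(self$par$b), self$pieces)
    dx <- matrix(0, nrow(x), ncol(x))
    assigned <- matrix(FALSE, nrow(dy), ncol(dy))
    for (p in seq_len(self$pieces)) {
      hit <- (self$cache$zs[[p]] == self$cache$out) & !assigned
      assigned <- assigned | hit
      dyp <- dy * hit
      dW[, , p] <- crossprod(x, dyp)
      db[, p] <- colSums(dyp)
      dx <- dx + dyp %*% t(self$par$W[, , p])
    }
    self$grad <- list(W = dW, b = db)
    self$cache <- NULL
    dx
  }
  self
}

# 1-D convolution over (L, C, N) tensors, zero-padded, stride 1
nn_conv1d <- function(c_in, c_out, k = 3L) {
  self <- new_nn_layer("nn_conv1d")
  k <- as.integer(k)
  self$k <- k
  self$par <- list(W = nn_he_init(k * c_in, c(k * c_in, c_out)), b = numeric(c_out))
  embed <- function(x2, k) { # x2: L x C -> L x (k*C)
    L <- nrow(x2); C <- ncol(x2); p <- (k - 1L) %/% 2L
    xp <- rbind(matrix(0, p, C), x2, matrix(0, p, C))
    out <- matrix(0, L, k * C)
    j <- 0L
    for (c in seq_len(C)) for (dk in seq_len(k)) {
      j <- j + 1L
      out[, j] <- xp[dk - 1L + seq_len(L), c]
    }
    out
  }
  self$embed <- embed
  self$forward <- function(x, train = TRUE) {
    d <- dim(x); L <- d[1]; N <- d[3]
    cols <- vector("list", N)
    out <- array(0, c(L, ncol(self$par$W), N))
    for (n in seq_len(N)) {
      cn <- embed(matrix(x[, , n], L, d[2]), self$k)
      cols[[n]] <- cn
      out[, , n] <- cn %*% self$par$W + rep(self$par$b, each = L)
    }
    if (train) self$cache <- list(cols = cols, dim = d)
    out
  }
  self$backward <- function(dy) {
    d <- self$cache$dim; L <- d[1]; C <- d[2]; N <- d[3]
    p <- (self$k - 1L) %/% 2L
    dW <- matrix(0, nrow(self$par$W), ncol(self$par$W)); db <- numeric(ncol(self$par$W))
    dx <- array(0, d)
    for (n in seq_len(N)) {
      dyn <- matrix(dy[, , n], L, ncol(self$par$W))
      dW <- dW + crossprod(self$cache$cols[[n]], dyn)
      db <- db + colSums(dyn)
      dcols <- dyn %*% t(self$par$W)
      xp <- matrix(0, L + 2L * p, C)
      j <- 0L
      for (c in seq_len(C)) for (dk in seq_len(self$k)) {
        j <- j + 1L
        idx <- dk - 1L + seq_len(L)
        xp[idx, c] <- xp[idx, c] + dcols[, j]
      }
      dx[, , n] <- xp[p + seq_len(L), ]
    }
    self$grad <- list(W = dW, b = db)
    self$cache <- NULL
    dx
  }
  self
}

# 1-D max pool, window/stride k, trailing remainder dropped
nn_pool1d <- function(k = 2L) {
  self <- new_nn_layer("nn_pool1d")
  self$k <- as.integer(k)
  self$forward <- function(x, train = TRUE) {
    d <- dim(x); L <- d[1]
    Lo <- L %/% self$k
    xs <- x[seq_len(Lo * self$k), , , drop = FALSE]
    slabs <- lapply(seq_len(self$k), function(s)
      xs[seq(s, Lo * self$k, self$k), , , drop = FALSE])
    out <- Reduce(pmax, slabs)
    if (train) self$cache <- list(slabs = slabs, out = out, dim = d)
    out
  }
  self$backward <- function(dy) {
    d <- self$cache$dim
    dx <- array(0, d)
    Lo <- dim(dy)[1]
    assigned <- array(FALSE, dim(dy))
    for (s in seq_len(self$k)) {
      hit <- (self$cache$slabs[[s]] == self$cache$out) & !assigned
      assigned <- assigned | hit
      g <- array(0, dim(dy)); g[hit] <- dy[hit]
      dx[seq(s, Lo * self$k, self$k), , ] <- g
    }
    self$cache <- NULL
    dx
  }
  self
}

nn_softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# cross-entropy on softmax probabilities; returns loss and gradient at logits
nn_softmax_ce <- function(logits, y_onehot) {
  p <- nn_softmax(logits)
  n <- nrow(logits)
  loss <- -mean(log(pmax(rowSums(p * y_onehot), 1e-12)))
  list(loss = loss, probs = p, dlogits = (p - y_onehot) / n)
}

nn_param_count <- function(layers) {
  sum(vapply(layers, function(l) sum(vapply(l$par, length, 1L)), 1L))
}

nn_adam_step <- function(layers, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (l in layers) {
    if (l$frozen || length(l$par) == 0L || is.null(l$grad)) next
    if (is.null(l$opt))
      l$opt <- list(t = 0,
                    m = lapply(l$par, function(p) p * 0),
                    v = lapply(l$par, function(p) p * 0))
    l$opt$t <- l$opt$t + 1
    bc1 <- 1 - beta1^l$opt$t; bc2 <- 1 - beta2^l$opt$t
    for (nm in names(l$par)) {
      g <- l$grad[[nm]]
      l$opt$m[[nm]] <- beta1 * l$opt$m[[nm]] + (1 - beta1) * g
      l$opt$v[[nm]] <- beta2 * l$opt$v[[nm]] + (1 - beta2) * g^2
      l$par[[nm]] <- l$par[[nm]] -
        lr * (l$opt$m[[nm]] / bc1) / (sqrt(l$opt$v[[nm]] / bc2) + eps)
    }
    l$grad <- NULL
  }
  invisible(NULL)
}

# digest of all parameters (determinism checks)
nn_params_digest <- function(layers) {
  v <- unlist(lapply(layers, function(l) unlist(l$par, use.names = FALSE)))
  sum(v) + sum(v^2) * 1e-3
}
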