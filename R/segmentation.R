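#' Segmentation model configuration
#'
#' Describes the attention residual U-Net: an encoder of residual blocks,
#' each followed by a dual-channel attention block, max-pool downsampling
#' between stages, and a mirrored decoder with attention, nearest-neighbour
#' upsampling, skip concatenation from the matching encoder attention
#' output and a residual block per stage; a final 1x1 convolution with
#' sigmoid produces the probability map.
#'
#' @param depth Number of encoder stages (>= 2).
#' @param base_channels Channels at the first stage (>= 4); doubled per
#'   stage.
#' @param input_size Input side length in pixels; must be divisible by
#'   `2^(depth - 1)`.
#' @param attention_enabled Include the attention blocks (`FALSE` gives the
#'   plain residual U-Net ablation).
#' @param threshold Mask cutoff on the sigmoid map, in `(0, 1)`.
#' @param loss Training loss; `"dice_bce"` (soft Dice plus binary
#'   cross-entropy) is the only option.
#' @param epochs,batch_size,learning_rate Adam training regimen.
#' @param seed Integer seed governing initialization and batch order.
#' @return An object of class `seg_config`.
#' @export
seg_config <- function(depth = 3L, base_channels = 8L, input_size = 64L,
                       attention_enabled = TRUE, threshold = 0.5,
                       loss = "dice_bce", epochs = 30L, batch_size = 4L,
                       learning_rate = 1e-3, seed = 1L) {
  depth <- as.integer(depth); base_channels <- as.integer(base_channels)
  input_size <- as.integer(input_size)
  if (depth < 2L) stop("`depth` must be >= 2", call. = FALSE)
  if (base_channels < 4L) stop("`base_channels` must be >= 4", call. = FALSE)
  if (threshold <= 0 || threshold >= 1)
    stop("`threshold` must lie in (0, 1)", call. = FALSE)
  if (input_size %% 2L^(depth - 1L) != 0L)
    stop("`input_size` must be divisible by 2^(depth - 1)", call. = FALSE)
  if (!identical(loss, "dice_bce")) stop("unsupported loss", call. = FALSE)
  structure(list(depth = depth, base_channels = base_channels,
                 input_size = input_size,
                 attention_enabled = isTRUE(attention_enabled),
                 threshold = threshold, loss = loss,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "seg_config")
}

#' Build the attention residual U-Net
#'
#' Construction is deterministic given the config (weights are drawn under
#' the config seed).
#'
#' @param config A [seg_config()].
#' @return A `p_resunet` model environment with `forward`, `backward`,
#'   `layers` and `param_count` entries.
#' @export
build_p_resunet <- function(config = seg_config()) {
  stopifnot(inherits(config, "seg_config"))
  withr::with_seed(config$seed, {
    depth <- config$depth
    ch <- config$base_channels * 2L^(0:(depth - 1L))
    self <- new.env(parent = emptyenv())
    self$config <- config
    att <- function(c) if (config$attention_enabled) module_rdcab(c) else NULL

    self$enc <- vector("list", depth)
    self$pools <- vector("list", depth - 1L)
    c_in <- 1L
    for (i in seq_len(depth)) {
      self$enc[[i]] <- list(res = module_resblock(c_in, ch[i]), att = att(ch[i]))
      if (i < depth) self$pools[[i]] <- nn_pool2("max")
      c_in <- ch[i]
    }
    self$dec <- vector("list", depth - 1L)
    self$ups <- vector("list", depth - 1L)
    cur <- ch[depth]
    for (j in seq_len(depth - 1L)) {
      lev <- depth - j
      self$dec[[j]] <- list(att = att(cur),
                            res = module_resblock(cur + ch[lev], ch[lev]))
      self$ups[[j]] <- nn_upsample2()
      cur <- ch[lev]
    }
    self$head <- nn_conv2d(ch[1], 1L, 1L)

    self$layers <- function() {
      out <- list()
      grab <- function(st) {
        out <<- c(out, st$res$layers())
        if (!is.null(st$att)) out <<- c(out, st$att$layers())
      }
      for (st in self$enc) grab(st)
      for (st in self$dec) grab(st)
      c(out, list(self$head))
    }
    self$param_count <- function() nn_param_count(self$layers())

    self$forward <- function(x, train = TRUE) {
      depth <- self$config$depth
      skips <- vector("list", depth - 1L)
      h <- x
      for (i in seq_len(depth)) {
        h <- self$enc[[i]]$res$forward(h, train)
        if (!is.null(self$enc[[i]]$att)) h <- self$enc[[i]]$att$forward(h, train)
        if (i < depth) { skips[[i]] <- h; h <- self$pools[[i]]$forward(h, train) }
      }
      self$skip_ch <- integer(depth - 1L)
      for (j in seq_len(depth - 1L)) {
        lev <- depth - j
        if (!is.null(self$dec[[j]]$att)) h <- self$dec[[j]]$att$forward(h, train)
        h <- self$ups[[j]]$forward(h, train)
        s <- skips[[lev]]
        self$skip_ch[j] <- dim(s)[3]
        d <- dim(s)
        hc <- array(0, c(d[1], d[2], d[3] + dim(h)[3], d[4]))
        hc[, , seq_len(d[3]), ] <- s
        hc[, , d[3] + seq_len(dim(h)[3]), ] <- h
        h <- self$dec[[j]]$res$forward(hc, train)
      }
      logits <- self$head$forward(h, train)
      stats::plogis(logits)
    }

    # dy is the gradient at the logits (pre-sigmoid)
    self$backward <- function(dlogits) {
      depth <- self$config$depth
      d <- self$head$backward(dlogits)
      dskips <- vector("list", depth - 1L)
      for (j in seq((depth - 1L), 1L)) {
        lev <- depth - j
        dcc <- self$dec[[j]]$res$backward(d)
        cs <- self$skip_ch[j]
        dskips[[lev]] <- dcc[, , seq_len(cs), , drop = FALSE]
        du <- dcc[, , cs + seq_len(dim(dcc)[3] - cs), , drop = FALSE]
        d <- self$ups[[j]]$backward(du)
        if (!is.null(self$dec[[j]]$att)) d <- self$dec[[j]]$att$backward(d)
      }
      for (i in seq(depth, 1L)) {
        if (i < depth) d <- self$pools[[i]]$backward(d) + dskips[[i]]
        if (!is.null(self$enc[[i]]$att)) d <- self$enc[[i]]$att$backward(d)
        d <- self$enc[[i]]$res$backward(d)
      }
      d
    }
    class(self) <- "p_resunet"
    self
  })
}

# combined soft-Dice + BCE loss on sigmoid probabilities; returns the loss
# and its gradient at the logits
dice_bce_loss <- function(probs, target, smooth = 1) {
  d <- dim(probs); N <- d[4]; npix <- prod(d[1:3])
  p <- pmin(pmax(probs, 1e-7), 1 - 1e-7)
  bce <- -mean(target * log(p) + (1 - target) * log(1 - p))
  dz_bce <- (probs - target) / (npix * N)
  dice_terms <- numeric(N)
  dz_dice <- array(0, d)
  for (n in seq_len(N)) {
    pn <- probs[, , , n]; tn <- target[, , , n]
    spt <- sum(pn * tn); S <- sum(pn) + sum(tn) + smooth
    dice_terms[n] <- (2 * spt + smooth) / S
    dp <- -(2 * tn * S - (2 * spt + smooth)) / S^2 / N
    dz_dice[, , , n] <- dp * pn * (1 - pn)
  }
  list(loss = bce + 1 - mean(dice_terms), dlogits = dz_bce + dz_dice)
}

#' Train the segmenter on a phantom dataset
#'
#' Adam on the combined soft-Dice + binary cross-entropy loss; mean loss is
#' recorded per epoch. Deterministic given the config seed.
#'
#' @param dataset A `phantom_dataset` (needs at least one non-empty mask).
#' @param config A [seg_config()].
#' @return List with `model` (the trained `p_resunet`) and `history`
#'   (numeric vector of per-epoch mean losses).
#' @export
train_segmenter <- function(dataset, config = seg_config()) {
  stopifnot(inherits(dataset, "phantom_dataset"))
  if (length(dataset$items) == 0L) stop("empty dataset", call. = FALSE)
  if (!any(vapply(dataset$items, function(it) sum(it$mask) > 0, TRUE)))
    stop("dataset needs at least one non-empty mask", call. = FALSE)
  model <- build_p_resunet(config)
  n <- length(dataset$items)
  sz <- config$input_size
  imgs <- lapply(dataset$items, function(it) {
    if (!all(dim(it$image) == sz)) stop("image size does not match config", call. = FALSE)
    it$image
  })
  masks <- lapply(dataset$items, `[[`, "mask")
  history <- numeric(config$epochs)
  withr::with_seed(config$seed + 1L, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      losses <- c()
      for (start in seq(1L, n, config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        B <- length(idx)
        X <- array(0, c(sz, sz, 1L, B)); Tm <- array(0, c(sz, sz, 1L, B))
        for (b in seq_len(B)) {
          X[, , 1L, b] <- imgs[[idx[b]]]
          Tm[, , 1L, b] <- masks[[idx[b]]]
        }
        probs <- model$forward(X, train = TRUE)
        lo <- dice_bce_loss(probs, Tm)
        model$backward(lo$dlogits)
        nn_adam_step(model$layers(), config$learning_rate)
        losses <- c(losses, lo$loss)
      }
      history[ep] <- mean(losses)
    }
  })
  list(model = model, history = history)
}

#' Segment a slice with a trained model
#'
#' @param image Numeric matrix matching the model input size.
#' @param model A trained `p_resunet`.
#' @param threshold Mask cutoff; defaults to the config value. The
#'   foreground shrinks monotonically as the threshold rises.
#' @return Binary integer matrix.
#' @export
segment <- function(image, model, threshold = NULL) {
  assert_gray_image(image)
  sz <- model$config$input_size
  if (!all(dim(image) == sz)) stop("image size does not match model", call. = FALSE)
  threshold <- threshold %||% model$config$threshold
  p <- segment_probs(image, model)
  (p > threshold) * 1L
}

#' @rdname segment
#' @export
segment_probs <- function(image, model) {
  sz <- model$config$input_size
  x <- array(image, c(sz, sz, 1L, 1L))
  matrix(model$forward(x, train = FALSE), sz, sz)
}

#' Overlap metrics between predicted and true masks
#'
#' Dice `2|A∩B| / (|A| + |B|)`, Jaccard `|A∩B| / |A∪B|` and pixel accuracy.
#' When both masks are empty all three are 1 by convention.
#'
#' @param pred,truth Same-shaped binary matrices.
#' @return Named list with `dice`, `jaccard`, `segmentation_accuracy`.
#' @export
seg_metrics <- function(pred, truth) {
  assert_same_dim(pred, truth, "masks")
  a <- pred > 0; b <- truth > 0
  inter <- sum(a & b); uni <- sum(a | b); sa <- sum(a); sb <- sum(b)
  list(
    dice = if (sa + sb == 0) 1 else 2 * inter / (sa + sb),
    jaccard = if (uni == 0) 1 else inter / uni,
    segmentation_accuracy = mean(a == b)
  )
}
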