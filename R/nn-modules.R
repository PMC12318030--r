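# Composite network modules built from engine layers. Each module is an
# environment exposing forward(x, train), backward(dy) and layers().

# Residual block: conv3x3 -> PReLU -> conv3x3, plus identity (or 1x1
# projection when channel counts differ). Batch statistics layers are
# deliberately absent: desk-scale batches of 1-8 images would make them
# noisy and break train/eval parity.
module_resblock <- function(c_in, c_out) {
  self <- new.env(parent = emptyenv())
  self$conv1 <- nn_conv2d(c_in, c_out, 3L)
  self$act1 <- nn_prelu(c_out)
  self$conv2 <- nn_conv2d(c_out, c_out, 3L)
  self$proj <- if (c_in != c_out) nn_conv2d(c_in, c_out, 1L) else NULL
  self$forward <- function(x, train = TRUE) {
    h <- self$conv2$forward(self$act1$forward(self$conv1$forward(x, train), train), train)
    s <- if (is.null(self$proj)) x else self$proj$forward(x, train)
    h + s
  }
  self$backward <- function(dy) {
    dh <- self$conv1$backward(self$act1$backward(self$conv2$backward(dy)))
    ds <- if (is.null(self$proj)) dy else self$proj$backward(dy)
    dh + ds
  }
  self$layers <- function() {
    c(list(self$conv1, self$act1, self$conv2),
      if (!is.null(self$proj)) list(self$proj))
  }
  class(self) <- "module_resblock"
  self
}

# broadcast an N x C weight matrix over the spatial dims of (H, W, C, N)
bc_channel <- function(wgt, d) {
  array(rep(t(wgt), each = d[1] * d[2]), d)
}

# sum a (H, W, C, N) tensor over H, W -> N x C
sum_hw <- function(a) {
  d <- dim(a)
  t(matrix(colSums(matrix(a, d[1] * d[2])), d[3], d[4]))
}

# Residual dual-channel attention block. Three parallel branches: global max
# pool and global average pool each feed a channel-mixing layer plus PReLU;
# their sum, passed through the tanh-gated activation, forms per-channel
# attention weights. The third branch is a spatial 3x3 conv -> PReLU ->
# conv path on the full map. Fusion: attention-weighted input plus the
# spatial branch, one more tanh-gated activation, and a residual connection
# around the whole block so attention can never erase features.
module_rdcab <- function(channels) {
  self <- new.env(parent = emptyenv())
  self$channels <- channels
  self$gmp <- nn_gpool("max"); self$gap <- nn_gpool("avg")
  self$denseA <- nn_dense(channels, channels); self$preluA <- nn_prelu(channels)
  self$denseB <- nn_dense(channels, channels); self$preluB <- nn_prelu(channels)
  self$convC1 <- nn_conv2d(channels, channels, 3L)
  self$preluC <- nn_prelu(channels)
  self$convC2 <- nn_conv2d(channels, channels, 3L)
  self$forward <- function(x, train = TRUE) {
    d <- dim(x)
    a <- self$preluA$forward(self$denseA$forward(self$gmp$forward(x, train), train), train)
    b <- self$preluB$forward(self$denseB$forward(self$gap$forward(x, train), train), train)
    g <- a + b
    wgt <- d_silu(g, "improved")
    cmap <- self$convC2$forward(self$preluC$forward(self$convC1$forward(x, train), train), train)
    fused <- x * bc_channel(wgt, d) + cmap
    out <- d_silu(fused, "improved") + x
    if (train) self$cache <- list(x = x, g = g, wgt = wgt, fused = fused, d = d)
    out
  }
  self$backward <- function(dy) {
    cc <- self$cache; d <- cc$d
    dfused <- dy * d_silu_grad(cc$fused, "improved")
    dx <- dy # residual path
    dx <- dx + self$convC1$backward(self$preluC$backward(self$convC2$backward(dfused)))
    dx <- dx + dfused * bc_channel(cc$wgt, d)
    dwgt <- sum_hw(dfused * cc$x)
    dg <- dwgt * d_silu_grad(cc$g, "improved")
    dx <- dx + self$gmp$backward(self$denseA$backward(self$preluA$backward(dg)))
    dx <- dx + self$gap$backward(self$denseB$backward(self$preluB$backward(dg)))
    self$cache <- NULL
    dx
  }
  self$layers <- function() {
    list(self$denseA, self$preluA, self$denseB, self$preluB,
         self$convC1, self$preluC, self$convC2)
  }
  class(self) <- "module_rdcab"
  self
}
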