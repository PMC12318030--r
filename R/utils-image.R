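# Shared image primitives. All images are numeric matrices (rows = y, cols = x)
# holding intensities on the [0,1] float contract; 8-bit conversion happens only
# at file I/O boundaries.

`%||%` <- function(a, b) if (is.null(a)) b else a

clip01 <- function(x) pmin(pmax(x, 0), 1)

assert_gray_image <- function(image, arg = "image") {
  if (!is.matrix(image) || !is.numeric(image))
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  if (nrow(image) < 1L || ncol(image) < 1L)
    stop(sprintf("`%s` must have positive dimensions", arg), call. = FALSE)
  if (any(!is.finite(image)))
    stop(sprintf("`%s` must contain only finite values", arg), call. = FALSE)
  invisible(image)
}

assert_same_dim <- function(a, b, what = "images") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("%s must have identical dimensions", what), call. = FALSE)
  invisible(NULL)
}

# Symmetric (edge-mirroring) padding; avoids the dark halo a zero pad would put
# at lung borders.
pad_reflect <- function(image, ph, pw = ph) {
  H <- nrow(image); W <- ncol(image)
  ri <- c(rev(seq_len(min(ph, H))), seq_len(H), H + 1L - seq_len(min(ph, H)))
  if (ph > H) ri <- rep(ri, length.out = H + 2L * ph) # degenerate tiny images
  ci <- c(rev(seq_len(min(pw, W))), seq_len(W), W + 1L - seq_len(min(pw, W)))
  if (pw > W) ci <- rep(ci, length.out = W + 2L * pw)
  image[ri, ci, drop = FALSE]
}

# Direct 2-D correlation with reflect padding; kernels are small (<= 31 px) so
# the per-offset shift-and-add loop is cheap and exact.
conv2_reflect <- function(image, kernel) {
  kh <- nrow(kernel); kw <- ncol(kernel)
  ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  xp <- pad_reflect(image, ph, pw)
  H <- nrow(image); W <- ncol(image)
  out <- matrix(0, H, W)
  for (i in seq_len(kh)) for (j in seq_len(kw)) {
    w <- kernel[i, j]
    if (w != 0) out <- out + w * xp[(i - 1L) + seq_len(H), (j - 1L) + seq_len(W)]
  }
  out
}

box_mean <- function(image, window) {
  k <- matrix(1 / (window * window), window, window)
  conv2_reflect(image, k)
}

# Local intensity variance in a square window (used by the adaptive filter).
local_variance <- function(image, window) {
  m <- box_mean(image, window)
  pmax(box_mean(image * image, window) - m * m, 0)
}

# Bilinear resize; only used to bring slices to a network's input size.
resize_bilinear <- function(image, out_h, out_w = out_h) {
  H <- nrow(image); W <- ncol(image)
  if (H == out_h && W == out_w) return(image)
  ys <- (seq_len(out_h) - 0.5) * H / out_h + 0.5
  xs <- (seq_len(out_w) - 0.5) * W / out_w + 0.5
  y0 <- pmin(pmax(floor(ys), 1L), H); y1 <- pmin(y0 + 1L, H)
  x0 <- pmin(pmax(floor(xs), 1L), W); x1 <- pmin(x0 + 1L, W)
  fy <- pmin(pmax(ys - y0, 0), 1); fx <- pmin(pmax(xs - x0, 0), 1)
  a <- image[y0, x0, drop = FALSE] * outer(1 - fy, 1 - fx) +
    image[y1, x0, drop = FALSE] * outer(fy, 1 - fx) +
    image[y0, x1, drop = FALSE] * outer(1 - fy, fx) +
    image[y1, x1, drop = FALSE] * outer(fy, fx)
  a
}
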