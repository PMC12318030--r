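#' Discrete 2-D Gaussian kernel
#'
#' Entries are proportional to `exp(-(x^2 + y^2) / (2 * sigma^2))` on the
#' integer grid `[-radius, radius]^2` and renormalized to unit sum, so
#' filtering preserves mean intensity regardless of the analytic prefactor.
#'
#' @param sigma Standard deviation in pixels (> 0).
#' @param radius Kernel half-width in pixels (>= 1); the kernel is
#'   `(2 * radius + 1)` pixels per side.
#' @return A square numeric matrix summing to 1.
#' @export
gaussian_kernel <- function(sigma, radius) {
  if (!is.numeric(sigma) || sigma <= 0)
    stop("`sigma` must be positive", call. = FALSE)
  if (radius < 1) stop("`radius` must be >= 1", call. = FALSE)
  g <- seq(-radius, radius)
  k <- exp(-outer(g^2, g^2, `+`) / (2 * sigma^2))
  k / sum(k)
}

#' Parameters of the (adaptive) Gaussian denoising filter
#'
#' With `adaptive = FALSE` the filter is a plain convolution with
#' `gaussian_kernel(sigma_max, radius)`. With `adaptive = TRUE` the
#' per-pixel smoothing strength is interpolated in `[sigma_min, sigma_max]`,
#' decreasing with local intensity variance (measured in a `window`-pixel
#' box and min-max scaled over the image), so flat noisy regions are
#' smoothed hard while edges and nodule boundaries keep a light touch.
#'
#' @param sigma_min,sigma_max Std-dev bounds in pixels,
#'   `0 < sigma_min <= sigma_max`.
#' @param radius Kernel half-width in pixels; defaults to
#'   `ceiling(2.5 * sigma_max)`.
#' @param adaptive Use the variance-driven per-pixel sigma rule.
#' @param window Local-statistics window size in pixels (odd).
#' @return An object of class `gaussian_filter_params`.
#' @export
gaussian_filter_params <- function(sigma_min = 0.5, sigma_max = 1.5,
                                   radius = NULL, adaptive = TRUE,
                                   window = 7L) {
  if (sigma_min <= 0 || sigma_min > sigma_max)
    stop("need 0 < sigma_min <= sigma_max", call. = FALSE)
  radius <- as.integer(radius %||% ceiling(2.5 * sigma_max))
  if (radius < 1L) stop("`radius` must be >= 1", call. = FALSE)
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("`window` must be an odd integer >= 3", call. = FALSE)
  structure(list(sigma_min = sigma_min, sigma_max = sigma_max,
                 radius = radius, adaptive = isTRUE(adaptive),
                 window = window),
            class = "gaussian_filter_params")
}

#' Denoise a slice with the (adaptive) Gaussian filter
#'
#' The adaptive rule blends a small bank of five Gaussian filters with
#' sigmas spanning `[sigma_min, sigma_max]`; each pixel's output is the
#' linear interpolation between the two bank members bracketing its local
#' sigma. Borders use reflect padding. Output is clipped to `[0, 1]`.
#'
#' @param image Numeric matrix on the `[0,1]` contract.
#' @param params A [gaussian_filter_params()].
#' @return Filtered image, same shape as the input.
#' @export
adaptive_gaussian_filter <- function(image, params = gaussian_filter_params()) {
  assert_gray_image(image)
  stopifnot(inherits(params, "gaussian_filter_params"))
  if (!params$adaptive || params$sigma_min == params$sigma_max) {
    out <- conv2_reflect(image, gaussian_kernel(params$sigma_max, params$radius))
    return(clip01(out))
  }
  v <- local_variance(image, params$window)
  rng <- range(v)
  vhat <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) else v * 0
  sig <- params$sigma_max - (params$sigma_max - params$sigma_min) * vhat

  bank_sigmas <- seq(params$sigma_min, params$sigma_max, length.out = 5L)
  bank <- lapply(bank_sigmas, function(s)
    conv2_reflect(image, gaussian_kernel(s, params$radius)))
  # per-pixel linear interpolation between bracketing bank members
  pos <- (sig - params$sigma_min) / (params$sigma_max - params$sigma_min) * 4 + 1
  lo <- pmin(pmax(floor(pos), 1), 4)
  frac <- pos - lo
  out <- matrix(0, nrow(image), ncol(image))
  for (b in 1:4) {
    sel <- lo == b
    if (!any(sel)) next
    out[sel] <- (1 - frac[sel]) * bank[[b]][sel] + frac[sel] * bank[[b + 1L]][sel]
  }
  clip01(out)
}

#' Peak signal-to-noise ratio between two images
#'
#' `10 * log10(max_val^2 / MSE)` in decibels; identical images give `Inf`.
#' `max_val` is 1 on the float contract (use 255 for 8-bit integer data).
#'
#' @param reference,test Same-shaped numeric matrices.
#' @param max_val Dynamic range of the data.
#' @return PSNR in dB.
#' @export
psnr <- function(reference, test, max_val = 1.0) {
  assert_gray_image(reference, "reference"); assert_gray_image(test, "test")
  assert_same_dim(reference, test)
  mse <- mean((reference - test)^2)
  if (mse == 0) return(Inf)
  10 * log10(max_val^2 / mse)
}

#' Mean structural similarity (SSIM) between two images
#'
#' Standard SSIM with a Gaussian-weighted local window (default 7 px,
#' sigma 1.5), stability constants `K1 = 0.01`, `K2 = 0.03` and dynamic
#' range 1.0. Local statistics use reflect padding so the map covers the
#' full image; the score is the mean of the local map.
#'
#' @param reference,test Same-shaped numeric matrices, at least as large as
#'   the window.
#' @param window Window size in pixels (odd).
#' @param sigma Gaussian window std-dev in pixels.
#' @param K1,K2 Stability constants.
#' @param max_val Dynamic range of the data.
#' @return Scalar score in `[-1, 1]`; 1 only for identical images.
#' @export
ssim <- function(reference, test, window = 7L, sigma = 1.5,
                 K1 = 0.01, K2 = 0.03, max_val = 1.0) {
  assert_gray_image(reference, "reference"); assert_gray_image(test, "test")
  assert_same_dim(reference, test)
  if (nrow(reference) < window || ncol(reference) < window)
    stop("images smaller than the SSIM window", call. = FALSE)
  r <- (window - 1L) %/% 2L
  g <- seq(-r, r)
  w <- exp(-outer(g^2, g^2, `+`) / (2 * sigma^2))
  w <- w / sum(w)
  C1 <- (K1 * max_val)^2; C2 <- (K2 * max_val)^2
  mu1 <- conv2_reflect(reference, w); mu2 <- conv2_reflect(test, w)
  s11 <- conv2_reflect(reference * reference, w) - mu1 * mu1
  s22 <- conv2_reflect(test * test, w) - mu2 * mu2
  s12 <- conv2_reflect(reference * test, w) - mu1 * mu2
  num <- (2 * mu1 * mu2 + C1) * (2 * s12 + C2)
  den <- (mu1^2 + mu2^2 + C1) * (s11 + s22 + C2)
  mean(num / den)
}
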