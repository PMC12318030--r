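#' Gabor filter-bank parameters
#'
#' A 2-D Gabor filter is a complex sinusoid modulated by a Gaussian
#' envelope. The bank holds one filter per orientation; responses are
#' combined by taking the pixelwise maximum magnitude over orientations.
#' Real and imaginary kernels are DC-subtracted so a constant intensity
#' offset produces no response.
#'
#' @param wavelength Sinusoid wavelength in pixels (> 0).
#' @param orientations Angles in radians (at least one); default four
#'   orientations at 0, 45, 90, 135 degrees.
#' @param envelope_sigma Gaussian envelope std-dev in pixels.
#' @param phase Sinusoid phase offset in radians.
#' @param aspect_ratio Envelope ellipticity (1 = isotropic).
#' @return An object of class `gabor_params`.
#' @export
gabor_params <- function(wavelength = 4, orientations = pi / 4 * 0:3,
                         envelope_sigma = 2, phase = 0, aspect_ratio = 1) {
  if (wavelength <= 0) stop("`wavelength` must be positive", call. = FALSE)
  if (length(orientations) < 1L)
    stop("need at least one orientation", call. = FALSE)
  structure(list(wavelength = wavelength, orientations = as.numeric(orientations),
                 envelope_sigma = envelope_sigma, phase = phase,
                 aspect_ratio = aspect_ratio),
            class = "gabor_params")
}

# Complex Gabor kernel at one orientation, DC-free in both parts.
gabor_kernel <- function(params, theta) {
  r <- max(3L, ceiling(2.5 * params$envelope_sigma))
  g <- seq(-r, r)
  x <- matrix(g, length(g), length(g), byrow = TRUE)
  y <- matrix(g, length(g), length(g))
  xr <- x * cos(theta) + y * sin(theta)
  yr <- -x * sin(theta) + y * cos(theta)
  env <- exp(-(xr^2 + (params$aspect_ratio * yr)^2) / (2 * params$envelope_sigma^2))
  arg <- 2 * pi * xr / params$wavelength + params$phase
  re <- env * cos(arg); im <- env * sin(arg)
  list(re = re - mean(re), im = im - mean(im))
}

#' Multi-orientation Gabor response map
#'
#' Filters the image with the complex Gabor bank and returns the pixelwise
#' maximum response magnitude over orientations.
#'
#' @param image Numeric matrix.
#' @param params A [gabor_params()].
#' @return Non-negative numeric matrix, same shape as `image`.
#' @export
gabor_response <- function(image, params = gabor_params()) {
  assert_gray_image(image)
  out <- matrix(0, nrow(image), ncol(image))
  for (theta in params$orientations) {
    k <- gabor_kernel(params, theta)
    mag <- sqrt(conv2_reflect(image, k$re)^2 + conv2_reflect(image, k$im)^2)
    out <- pmax(out, mag)
  }
  out
}

#' Configuration of the two-radius local transitional pattern code
#'
#' Per pixel and direction `l`, intensities `G_l1` and `G_l2` are sampled at
#' radii `r1 < r2`; the direction bit is set when both exceed the centre
#' intensity (a consistent outward transition), and the `L` bits form a code
#' in `[0, 2^L)`.
#'
#' @param directions Number of equally spaced directions `L` (>= 2).
#' @param r1,r2 Sampling radii in pixels, `r1 < r2`.
#' @param grid Region layout for the histograms: a 2x2 grid of the code map
#'   plus the whole map (5 regions).
#' @param bins Histogram bins per region over `[0, 2^L)`.
#' @return An object of class `lgtrp_config`. The default layout
#'   (5 regions x 10 bins) yields the 50-value descriptor.
#' @export
lgtrp_config <- function(directions = 8L, r1 = 1, r2 = 2, grid = c(2L, 2L),
                         bins = 10L) {
  if (r1 >= r2) stop("need r1 < r2", call. = FALSE)
  if (directions < 2L) stop("need at least 2 directions", call. = FALSE)
  structure(list(directions = as.integer(directions), r1 = r1, r2 = r2,
                 grid = as.integer(grid), bins = as.integer(bins)),
            class = "lgtrp_config")
}

# Bilinear sample of image at fractional (y, x) positions (matrices allowed).
bilinear_at <- function(image, ys, xs) {
  H <- nrow(image); W <- ncol(image)
  y0 <- floor(ys); x0 <- floor(xs)
  fy <- ys - y0; fx <- xs - x0
  y0 <- pmin(pmax(y0, 1), H); y1 <- pmin(y0 + 1, H)
  x0 <- pmin(pmax(x0, 1), W); x1 <- pmin(x0 + 1, W)
  idx <- function(yy, xx) image[cbind(as.vector(yy), as.vector(xx))]
  v <- idx(y0, x0) * (1 - fy) * (1 - fx) + idx(y1, x0) * fy * (1 - fx) +
    idx(y0, x1) * (1 - fy) * fx + idx(y1, x1) * fy * fx
  matrix(v, nrow(ys))
}

#' Local transitional pattern code map
#'
#' Computes, for every interior pixel, the `L`-bit transition code: bit `l`
#' is `step(G_l1 - G_c) * step(G_l2 - G_c)` with `step(d) = 1` iff `d > 0`
#' (ties give 0), neighbours sampled by bilinear interpolation at radii
#' `r1` and `r2` in direction `l`. Border pixels within `r2` of the edge
#' are excluded.
#'
#' @param image Numeric matrix larger than `2 * r2 + 1` per side.
#' @param config An [lgtrp_config()].
#' @return Integer matrix of codes in `[0, 2^L)` of size
#'   `(H - 2*ceiling(r2)) x (W - 2*ceiling(r2))`.
#' @export
ltp_code_map <- function(image, config = lgtrp_config()) {
  assert_gray_image(image)
  m <- ceiling(config$r2)
  H <- nrow(image); W <- ncol(image)
  if (H <= 2 * config$r2 + 1 || W <= 2 * config$r2 + 1)
    stop("image too small for the requested r2", call. = FALSE)
  rows <- (m + 1L):(H - m); cols <- (m + 1L):(W - m)
  yc <- matrix(rows, length(rows), length(cols))
  xc <- matrix(cols, length(rows), length(cols), byrow = TRUE)
  centre <- image[rows, cols, drop = FALSE]
  code <- matrix(0L, length(rows), length(cols))
  L <- config$directions
  for (l in 0:(L - 1L)) {
    ang <- 2 * pi * l / L
    dy <- sin(ang); dx <- cos(ang)
    g1 <- bilinear_at(image, yc + config$r1 * dy, xc + config$r1 * dx)
    g2 <- bilinear_at(image, yc + config$r2 * dy, xc + config$r2 * dx)
    bit <- (g1 > centre) & (g2 > centre)
    code <- code + as.integer(bit) * 2L^l
  }
  code
}

# Split a matrix into a gy x gx grid of blocks (as a list, row-major).
split_blocks <- function(m, gy, gx) {
  ry <- floor(seq(0, nrow(m), length.out = gy + 1L))
  rx <- floor(seq(0, ncol(m), length.out = gx + 1L))
  out <- list()
  for (i in seq_len(gy)) for (j in seq_len(gx))
    out[[length(out) + 1L]] <-
      m[(ry[i] + 1L):ry[i + 1L], (rx[j] + 1L):rx[j + 1L], drop = FALSE]
  out
}

#' Local Gabor transitional pattern descriptor (50 values)
#'
#' Gabor response map, then the transitional-pattern code map, then per
#' region an L1-normalized histogram of codes with `bins` equal-width bins
#' over `[0, 2^L)`. Regions are the 2x2 grid of the code map plus the whole
#' map; with the defaults this gives 5 x 10 = 50 values, ordered region by
#' region.
#'
#' @param seg_image Segmented grayscale slice (numeric matrix).
#' @param gabor A [gabor_params()].
#' @param config An [lgtrp_config()].
#' @return Numeric vector of length `prod(grid) + 1` times `bins` (50 by
#'   default); each region block is non-negative and sums to 1.
#' @export
lgtrp_features <- function(seg_image, gabor = gabor_params(),
                           config = lgtrp_config()) {
  resp <- gabor_response(seg_image, gabor)
  codes <- ltp_code_map(resp, config)
  top <- 2^config$directions
  breaks <- seq(0, top, length.out = config$bins + 1L)
  regions <- c(split_blocks(codes, config$grid[1], config$grid[2]), list(codes))
  unlist(lapply(regions, function(b) {
    h <- hist(as.vector(b), breaks = breaks, plot = FALSE, right = FALSE)$counts
    s <- sum(h)
    if (s > 0) h / s else rep(1 / length(h), length(h))
  }), use.names = FALSE)
}
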