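#' Configuration of the pyramid histogram of oriented gradients
#'
#' Level `l` splits the image into `4^l` cells; each cell votes its
#' magnitude-weighted gradient orientations into `bins` bins. The default
#' (levels 0 and 1, 10 bins, unsigned orientations) yields
#' `10 + 40 = 50` values after a single global L1 normalization.
#'
#' @param levels Pyramid levels (integer vector).
#' @param bins Orientation bins per cell.
#' @param angle_range `"unsigned_180"` folds orientations to `[0, 180)`
#'   degrees; `"signed_360"` keeps the full circle.
#' @return An object of class `phog_config`.
#' @export
phog_config <- function(levels = c(0L, 1L), bins = 10L,
                        angle_range = c("unsigned_180", "signed_360")) {
  angle_range <- match.arg(angle_range)
  structure(list(levels = as.integer(levels), bins = as.integer(bins),
                 angle_range = angle_range),
            class = "phog_config")
}

#' Sobel gradient magnitude and orientation
#'
#' Applies the 3x3 Sobel operator to get the x-derivative `G_p` and
#' y-derivative `G_q`; magnitude is `sqrt(G_p^2 + G_q^2)` and orientation
#' the full-quadrant arctangent `atan2(G_q, G_p)`, folded to `[0, pi)` under
#' the unsigned convention.
#'
#' @param image Numeric matrix, at least 3x3.
#' @param angle_range Orientation folding convention.
#' @return List with `magnitude` and `orientation` (radians) matrices.
#' @export
gradient_field <- function(image, angle_range = c("unsigned_180", "signed_360")) {
  assert_gray_image(image)
  angle_range <- match.arg(angle_range)
  if (nrow(image) < 3L || ncol(image) < 3L)
    stop("image must be at least 3x3", call. = FALSE)
  # x increases along columns, y along rows
  sx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)       # d/dx
  sy <- t(sx)                                               # d/dy
  gp <- conv2_reflect(image, sx)
  gq <- conv2_reflect(image, sy)
  mag <- sqrt(gp^2 + gq^2)
  ori <- atan2(gq, gp)
  if (angle_range == "unsigned_180") ori <- ori %% pi else ori <- ori %% (2 * pi)
  list(magnitude = mag, orientation = ori)
}

# Magnitude-weighted orientation histogram of one cell (unnormalized).
hog_cell <- function(mag, ori, bins, span) {
  b <- pmin(floor(ori / span * bins) + 1L, bins)
  h <- numeric(bins)
  for (k in seq_len(bins)) h[k] <- sum(mag[b == k])
  h
}

#' Pyramid HOG descriptor (50 values)
#'
#' Concatenates the per-cell orientation histograms over all pyramid levels
#' and L1-normalizes the final vector once. Image dimensions must be
#' divisible by `2^max(levels)`.
#'
#' @param seg_image Segmented grayscale slice.
#' @param config A [phog_config()].
#' @return Numeric vector of length `bins * sum(4^levels)` (50 by default)
#'   summing to 1 for any image with non-zero gradient energy.
#' @export
phog_features <- function(seg_image, config = phog_config()) {
  assert_gray_image(seg_image)
  div <- 2^max(config$levels)
  if (nrow(seg_image) %% div != 0L || ncol(seg_image) %% div != 0L)
    stop("image dimensions must be divisible by 2^max(levels)", call. = FALSE)
  gf <- gradient_field(seg_image, config$angle_range)
  span <- if (config$angle_range == "unsigned_180") pi else 2 * pi
  out <- numeric(0)
  for (lev in config$levels) {
    g <- 2L^lev
    mags <- split_blocks(gf$magnitude, g, g)
    oris <- split_blocks(gf$orientation, g, g)
    for (i in seq_along(mags))
      out <- c(out, hog_cell(mags[[i]], oris[[i]], config$bins, span))
  }
  s <- sum(out)
  if (s > 0) out / s else out
}
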