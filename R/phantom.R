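#' Specification of a synthetic lung-slice phantom
#'
#' Describes a square grayscale slice containing a brighter soft-tissue
#' background, two darker elliptical lung fields, and (for the cancer class)
#' one or more bright Gaussian-profile nodule blobs drawn inside a lung field.
#' Phantoms stand in for real CT slices so every downstream stage can be
#' exercised without any data download.
#'
#' @param image_size Pixels per side of the square slice (>= 32).
#' @param lung_ellipse_axes Semi-axes of each lung ellipse as fractions of
#'   `image_size`, `c(horizontal, vertical)`.
#' @param nodule_count_range Integer interval `c(lo, hi)` for the number of
#'   nodules in a cancer-class slice.
#' @param nodule_radius_range Pixel interval `c(lo, hi)` for nodule radii;
#'   must stay below `image_size / 4`.
#' @param nodule_intensity Peak nodule brightness in `[0, 1]`.
#' @param background_intensity Soft-tissue background intensity in `[0, 1]`;
#'   the lung interior is drawn at 35% of this value so lungs read darker.
#' @param noise_model `"gaussian"` (additive) or `"speckle"`
#'   (multiplicative).
#' @param noise_sigma Noise standard deviation in intensity units (>= 0).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 64L,
                         lung_ellipse_axes = c(0.17, 0.30),
                         nodule_count_range = c(1L, 3L),
                         nodule_radius_range = c(3, 6),
                         nodule_intensity = 0.90,
                         background_intensity = 0.65,
                         noise_model = c("gaussian", "speckle"),
                         noise_sigma = 0.03) {
  noise_model <- match.arg(noise_model)
  image_size <- as.integer(image_size)
  if (is.na(image_size) || image_size < 32L)
    stop("`image_size` must be an integer >= 32", call. = FALSE)
  if (length(lung_ellipse_axes) != 2L || any(lung_ellipse_axes <= 0) ||
      any(lung_ellipse_axes >= 0.5))
    stop("`lung_ellipse_axes` must be two fractions in (0, 0.5)", call. = FALSE)
  if (length(nodule_count_range) != 2L || any(nodule_count_range < 0) ||
      nodule_count_range[1] > nodule_count_range[2])
    stop("`nodule_count_range` must be a non-decreasing non-negative interval",
         call. = FALSE)
  if (length(nodule_radius_range) != 2L || any(nodule_radius_range <= 0) ||
      nodule_radius_range[1] > nodule_radius_range[2] ||
      nodule_radius_range[2] >= image_size / 4)
    stop("`nodule_radius_range` must be positive, non-decreasing and below image_size/4",
         call. = FALSE)
  for (v in c(nodule_intensity, background_intensity))
    if (v < 0 || v > 1) stop("intensities must lie in [0, 1]", call. = FALSE)
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0", call. = FALSE)
  structure(
    list(image_size = image_size,
         lung_ellipse_axes = as.numeric(lung_ellipse_axes),
         nodule_count_range = as.integer(nodule_count_range),
         nodule_radius_range = as.numeric(nodule_radius_range),
         nodule_intensity = nodule_intensity,
         background_intensity = background_intensity,
         noise_model = noise_model,
         noise_sigma = noise_sigma),
    class = "phantom_spec")
}

# Binary lung-field mask: two ellipses left/right of the midline.
lung_field_mask <- function(spec) {
  n <- spec$image_size
  a <- spec$lung_ellipse_axes[1] * n
  b <- spec$lung_ellipse_axes[2] * n
  yc <- 0.5 * n
  xs <- matrix(seq_len(n), n, n, byrow = TRUE)
  ys <- matrix(seq_len(n), n, n)
  inside <- function(xc) ((xs - xc) / a)^2 + ((ys - yc) / b)^2 <= 1
  (inside(0.28 * n) | inside(0.72 * n)) * 1L
}

#' Generate one synthetic lung-slice phantom
#'
#' Draws the soft-tissue background, the two darker lung fields, and (unless
#' suppressed) bright Gaussian-profile nodules fully contained in a lung
#' field, then applies the spec's noise model. The ground-truth mask marks
#' every pixel within a nodule radius of its centre; the class label is 1
#' exactly when the mask has foreground.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed; generation is bit-reproducible given
#'   `(spec, seed)`.
#' @param force_label Optional 0/1 to force the class of the slice
#'   (used by [generate_dataset()] to hit an exact class balance).
#' @return A `labeled_image`: list with `image` (noisy slice), `mask`
#'   (binary matrix), `label` (0/1) and attribute `clean` holding the
#'   noise-free slice.
#' @export
generate_phantom <- function(spec, seed, force_label = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  withr::with_seed(as.integer(seed), {
    n <- spec$image_size
    lung <- lung_field_mask(spec)
    lung_int <- 0.35 * spec$background_intensity
    img <- matrix(spec$background_intensity, n, n)
    img[lung == 1L] <- lung_int
    mask <- matrix(0L, n, n)

    cr <- spec$nodule_count_range
    count <- if (cr[1] == cr[2]) cr[1] else sample(cr[1]:cr[2], 1L)
    if (!is.null(force_label)) {
      if (force_label == 0) count <- 0L else count <- max(count, 1L)
    }
    if (count > 0L) {
      xs <- matrix(seq_len(n), n, n, byrow = TRUE)
      ys <- matrix(seq_len(n), n, n)
      for (k in seq_len(count)) {
        r <- stats::runif(1, spec$nodule_radius_range[1], spec$nodule_radius_range[2])
        # nodule must fit entirely inside the lung field: erode by rejection
        placed <- FALSE
        cand <- which(lung == 1L)
        for (try in seq_len(200L)) {
          p <- cand[sample.int(length(cand), 1L)]
          cy <- (p - 1L) %% n + 1L
          cx <- (p - 1L) %/% n + 1L
          d2 <- (xs - cx)^2 + (ys - cy)^2
          disk <- d2 <= r^2
          if (all(lung[disk] == 1L)) { placed <- TRUE; break }
        }
        if (!placed) next
        profile <- exp(-d2 / (2 * (r / 2)^2))
        img <- pmax(img, lung_int + (spec$nodule_intensity - lung_int) * profile)
        mask[disk] <- 1L
      }
    }
    clean <- clip01(img)
    noisy <- add_noise(clean, spec$noise_model, spec$noise_sigma,
                       seed = sample.int(.Machine$integer.max, 1L))
    label <- as.integer(sum(mask) > 0L)
    structure(list(image = noisy, mask = mask, label = label),
              clean = clean, class = "labeled_image")
  })
}

#' Add seeded noise to a grayscale image
#'
#' @param image Numeric matrix on the `[0,1]` contract.
#' @param model `"gaussian"` (additive) or `"speckle"` (multiplicative
#'   `x * (1 + noise)`).
#' @param sigma Noise standard deviation (>= 0); `sigma = 0` returns the
#'   input unchanged.
#' @param seed Integer seed; output is deterministic given `seed`.
#' @return Noisy image clipped to `[0, 1]`.
#' @export
add_noise <- function(image, model = c("gaussian", "speckle"), sigma, seed) {
  assert_gray_image(image)
  model <- match.arg(model)
  if (sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  if (sigma == 0) return(image)
  withr::with_seed(as.integer(seed), {
    noise <- matrix(stats::rnorm(length(image), 0, sigma), nrow(image))
    out <- switch(model,
                  gaussian = image + noise,
                  speckle = image * (1 + noise))
    clip01(out)
  })
}

#' Generate a labelled phantom dataset with exact class balance
#'
#' Exactly `round(n * cancer_fraction)` slices carry label 1 (nodules
#' present); the rest are nodule-free. Each item is generated from its own
#' sub-seed drawn from `seed`, so the whole dataset is bit-reproducible.
#'
#' @param n Number of slices (> 0).
#' @param cancer_fraction Proportion of cancer-class slices in `[0, 1]`.
#' @param spec A [phantom_spec()].
#' @param seed Integer seed.
#' @return A `phantom_dataset`: list with `items` (list of `labeled_image`),
#'   `labels` (integer vector), `spec` and `seed`.
#' @export
generate_dataset <- function(n, cancer_fraction, spec = phantom_spec(), seed = 1L) {
  if (n <= 0) stop("`n` must be positive", call. = FALSE)
  if (cancer_fraction < 0 || cancer_fraction > 1)
    stop("`cancer_fraction` must lie in [0, 1]", call. = FALSE)
  n <- as.integer(n)
  n_pos <- as.integer(round(n * cancer_fraction))
  withr::with_seed(as.integer(seed), {
    pos_idx <- if (n_pos > 0) sort(sample.int(n, n_pos)) else integer(0)
    item_seeds <- sample.int(.Machine$integer.max - 1L, n)
    labels <- integer(n)
    labels[pos_idx] <- 1L
    items <- lapply(seq_len(n), function(i)
      generate_phantom(spec, item_seeds[i], force_label = labels[i]))
    structure(list(items = items,
                   labels = vapply(items, `[[`, integer(1), "label"),
                   spec = spec, seed = as.integer(seed)),
              class = "phantom_dataset")
  })
}

#' Write a phantom dataset as 8-bit PNGs plus a CSV manifest
#'
#' @param dataset A `phantom_dataset`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest data frame with columns
#'   `path, mask_path, label, seed`.
#' @export
write_phantom_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "phantom_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(dataset$items), function(i) {
    it <- dataset$items[[i]]
    ip <- file.path(dir, sprintf("slice_%04d.png", i))
    mp <- file.path(dir, sprintf("mask_%04d.png", i))
    write_gray_png(it$image, ip)
    write_gray_png(it$mask, mp)
    data.frame(path = ip, mask_path = mp, label = it$label,
               seed = dataset$seed, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read/write grayscale PNG images on the float contract
#'
#' Values are quantized to 8 bits on write; [read_gray_png()] returns a
#' numeric matrix in `[0, 1]` (multi-channel files are averaged to gray).
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param path File path.
#' @return `read_gray_png` returns a numeric matrix.
#' @export
write_gray_png <- function(image, path) {
  assert_gray_image(image)
  png::writePNG(round(clip01(image) * 255) / 255, path)
  invisible(path)
}

#' @rdname write_gray_png
#' @export
read_gray_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- apply(a[, , seq_len(min(3L, dim(a)[3])), drop = FALSE], c(1, 2), mean)
  a
}
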