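test_that("gabor response is zero on a zero image and orientation selective", {
  z <- matrix(0, 32, 32)
  expect_equal(gabor_response(z), z)
  # vertical grating at the filter wavelength: intensity varies along x
  lambda <- 4
  xs <- matrix(seq_len(32), 32, 32, byrow = TRUE)
  grating <- 0.5 + 0.5 * sin(2 * pi * xs / lambda)
  matched <- gabor_response(grating, gabor_params(wavelength = lambda,
                                                  orientations = 0))
  ortho <- gabor_response(grating, gabor_params(wavelength = lambda,
                                                orientations = pi / 2))
  core <- 9:24 # interior, away from padding effects
  expect_gt(mean(matched[core, core]), mean(ortho[core, core]))
})

test_that("gabor response ignores constant intensity offsets", {
  img <- 0.6 * fixture_image(24, seed = 3L)
  r1 <- gabor_response(img)
  r2 <- gabor_response(img + 0.3)
  expect_equal(r1, r2, tolerance = 1e-10)
})

test_that("transition codes are zero on constants and bounded by 2^L", {
  cfg <- lgtrp_config()
  expect_true(all(ltp_code_map(matrix(0.5, 12, 12), cfg) == 0L))
  codes <- ltp_code_map(fixture_image(16, seed = 4L), cfg)
  expect_true(all(codes >= 0 & codes < 2^cfg$directions))
  expect_error(ltp_code_map(matrix(0.5, 4, 4), cfg))
})

test_that("the centre code of a ramp patch matches a per-direction hand trace", {
  # 7x7 ramp increasing along x plus a transposed-index tweak so directions
  # differ; oracle walks the 8 directions with its own bilinear sampler
  patch <- outer(seq(0, 0.6, length.out = 7), seq(0, 1, length.out = 7),
                 function(a, b) 0.3 * a + 0.7 * b)
  patch[3, 5] <- 0.9 # a local bump
  cfg <- lgtrp_config(directions = 8L, r1 = 1, r2 = 2)
  codes <- ltp_code_map(patch, cfg)
  centre <- patch[4, 4]
  sample_at <- function(y, x) {
    y0 <- floor(y); x0 <- floor(x); fy <- y - y0; fx <- x - x0
    y1 <- min(y0 + 1, 7); x1 <- min(x0 + 1, 7)
    patch[y0, x0] * (1 - fy) * (1 - fx) + patch[y1, x0] * fy * (1 - fx) +
      patch[y0, x1] * (1 - fy) * fx + patch[y1, x1] * fy * fx
  }
  code <- 0L
  for (l in 0:7) {
    ang <- 2 * pi * l / 8
    g1 <- sample_at(4 + 1 * sin(ang), 4 + 1 * cos(ang))
    g2 <- sample_at(4 + 2 * sin(ang), 4 + 2 * cos(ang))
    if (g1 > centre && g2 > centre) code <- code + 2L^l
  }
  expect_gt(code, 0L) # the fixture must exercise at least one transition
  expect_identical(codes[2, 2], code) # centre of the valid region
})

test_that("the texture descriptor has 50 normalized, offset-invariant values", {
  img <- fixture_phantom()$image
  v <- lgtrp_features(img)
  expect_length(v, 50L)
  expect_true(all(v >= 0))
  for (r in 0:4) expect_equal(sum(v[r * 10 + 1:10]), 1)
  # adding a constant changes neither the gabor response nor the transitions
  expect_equal(v, lgtrp_features(img + 0.02), tolerance = 1e-10)
})

test_that("sobel gradients behave on constants, edges and in magnitude", {
  z <- matrix(0.7, 8, 8)
  gf <- gradient_field(z)
  expect_true(all(gf$magnitude < 1e-12)) # float cancellation only
  # vertical step edge: gradient along x, unsigned orientation 0
  step5 <- cbind(matrix(0, 5, 2), matrix(1, 5, 3))
  gs <- gradient_field(step5)
  edge <- which(gs$magnitude[2:4, 2:4] > 0)
  expect_true(all(abs(gs$orientation[2:4, 2:4][edge]) < 1e-12))
  img <- fixture_image(12, seed = 6L)
  gi <- gradient_field(img)
  expect_true(all(gi$magnitude >= 0))
  expect_error(gradient_field(matrix(1, 2, 2)))
})

test_that("the pyramid descriptor is 50-long, L1-normalized, and its level 0 matches a direct histogram", {
  img <- fixture_phantom()$image
  v <- phog_features(img)
  expect_length(v, 50L)
  expect_equal(sum(v), 1)
  expect_true(all(v >= 0))
  # oracle: whole-image magnitude-weighted histogram, independently binned
  gf <- gradient_field(img)
  h <- numeric(10)
  b <- pmin(floor(gf$orientation / pi * 10) + 1L, 10L)
  for (k in 1:10) h[k] <- sum(gf$magnitude[b == k])
  expect_equal(v[1:10] / sum(v[1:10]), h / sum(h), tolerance = 1e-12)
  expect_error(phog_features(matrix(0.5, 31, 31))) # not divisible by 2
})

test_that("translating an interior object permutes pyramid cells without changing level 0", {
  # object on constant background, moved by exactly one cell (32 px)
  base <- matrix(0.2, 64, 64)
  obj <- function(cy, cx) {
    m <- base
    ys <- matrix(seq_len(64), 64, 64); xs <- t(ys)
    m[(ys - cy)^2 + (xs - cx)^2 <= 36] <- 0.9
    m
  }
  a <- obj(16, 16); b <- obj(48, 16) # shift down one cell
  va <- phog_features(a); vb <- phog_features(b)
  expect_equal(va[1:10], vb[1:10], tolerance = 1e-12) # level 0 invariant
  # level-1 blocks: cell (1,1) of a equals cell (2,1) of b
  expect_equal(va[10 + 1:10], vb[30 + 1:10], tolerance = 1e-12)
})
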