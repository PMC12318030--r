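test_that("phantom generation is bit-reproducible from (spec, seed)", {
  spec <- tiny_spec()
  a <- generate_phantom(spec, 42L)
  b <- generate_phantom(spec, 42L)
  expect_identical(a, b)
  d1 <- generate_dataset(6, 0.5, spec, seed = 9L)
  d2 <- generate_dataset(6, 0.5, spec, seed = 9L)
  expect_identical(d1, d2)
  d3 <- generate_dataset(6, 0.5, spec, seed = 10L)
  expect_false(identical(d1$items, d3$items))
})

test_that("a nodule-free spec yields an empty mask and label 0", {
  spec <- tiny_spec(nodule_count_range = c(0L, 0L))
  p <- generate_phantom(spec, 5L)
  expect_equal(sum(p$mask), 0)
  expect_equal(p$label, 0L)
})

test_that("a single radius-5 nodule covers the discrete-disk pixel count", {
  # oracle: rasterized disk of radius 5 has 81 pixels (61..97 tolerated for
  # fractional centres)
  spec <- tiny_spec(nodule_count_range = c(1L, 1L), nodule_radius_range = c(5, 5))
  for (s in 1:5) {
    p <- generate_phantom(spec, s)
    expect_gte(sum(p$mask), 61)
    expect_lte(sum(p$mask), 97)
  }
})

test_that("the lung field is darker than the background and nodules sit inside it", {
  spec <- tiny_spec(noise_sigma = 0)
  p <- generate_phantom(spec, 21L, force_label = 1L)
  lung <- noduleCT:::lung_field_mask(spec)
  expect_lt(mean(p$image[lung == 1 & p$mask == 0]), mean(p$image[lung == 0]))
  expect_true(all(lung[p$mask == 1] == 1))
})

test_that("noise is seeded, sized as requested, and clipped", {
  base <- matrix(0.5, 256, 256)
  expect_identical(add_noise(base, "gaussian", 0, 1L), base)
  n1 <- add_noise(base, "gaussian", 0.05, 7L)
  expect_identical(n1, add_noise(base, "gaussian", 0.05, 7L))
  expect_gte(stats::sd(n1), 0.045)
  expect_lte(stats::sd(n1), 0.055)
  hot <- add_noise(matrix(0.95, 64, 64), "gaussian", 0.3, 2L)
  expect_gte(min(hot), 0)
  expect_lte(max(hot), 1)
  spk <- add_noise(base, "speckle", 0.1, 3L)
  expect_false(identical(spk, n1))
  expect_error(add_noise(base, "salt", 0.1, 1L))
})

test_that("dataset class balance is exact and labels match masks", {
  d <- generate_dataset(10, 0.5, tiny_spec(), seed = 4L)
  expect_equal(sum(d$labels == 1L), 5L)
  d0 <- generate_dataset(10, 0, tiny_spec(), seed = 4L)
  expect_true(all(d0$labels == 0L))
  expect_error(generate_dataset(0, 0.5, tiny_spec(), 1L))
})

test_that("label/mask consistency holds across random specs", {
  withr::with_seed(99L, {
    for (k in 1:100) {
      spec <- phantom_spec(
        image_size = sample(c(32L, 48L, 64L), 1),
        nodule_count_range = sort(sample(0:3, 2, replace = TRUE)),
        nodule_radius_range = sort(stats::runif(2, 2, 5)),
        noise_sigma = stats::runif(1, 0, 0.08))
      p <- generate_phantom(spec, sample.int(1e6, 1))
      expect_identical(p$label, as.integer(sum(p$mask) > 0))
      expect_identical(dim(p$image), dim(p$mask))
      expect_true(all(p$mask %in% c(0L, 1L)))
      expect_true(min(p$image) >= 0 && max(p$image) <= 1)
    }
  })
})

test_that("datasets round-trip through PNG files and a manifest", {
  dir <- withr::local_tempdir()
  d <- generate_dataset(4, 0.5, tiny_spec(), seed = 2L)
  manifest <- write_phantom_dataset(d, dir)
  expect_equal(nrow(manifest), 4)
  expect_setequal(names(manifest), c("path", "mask_path", "label", "seed"))
  img <- read_gray_png(manifest$path[1])
  expect_equal(dim(img), dim(d$items[[1]]$image))
  # 8-bit quantization bounds the round-trip error
  expect_lt(max(abs(img - d$items[[1]]$image)), 1 / 255)
  msk <- read_gray_png(manifest$mask_path[2])
  expect_equal(matrix(as.integer(msk > 0.5), nrow(msk)),
               unname(d$items[[2]]$mask))
})

test_that("invalid phantom specs are rejected", {
  expect_error(phantom_spec(image_size = 16L))
  expect_error(phantom_spec(nodule_radius_range = c(10, 20)))
  expect_error(phantom_spec(nodule_intensity = 1.2))
  expect_error(phantom_spec(noise_sigma = -1))
})
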