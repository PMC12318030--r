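# shared fixtures: everything is generated in code under fixed seeds

tiny_spec <- function(...) {
  args <- utils::modifyList(list(image_size = 64L, noise_sigma = 0.03),
                            list(...))
  do.call(phantom_spec, args)
}

# a single cancer-class phantom reused across files
fixture_phantom <- function(seed = 11L, ...) {
  generate_phantom(tiny_spec(...), seed, force_label = 1L)
}

# deterministic pseudo-random image
fixture_image <- function(h = 16L, w = h, seed = 1L) {
  withr::with_seed(seed, matrix(stats::runif(h * w), h, w))
}

# small dataset for training-progress tests
fixture_dataset <- function(n = 8L, size = 32L, seed = 3L) {
  generate_dataset(n, 0.5, phantom_spec(image_size = size, noise_sigma = 0.03),
                   seed = seed)
}
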