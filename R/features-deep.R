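#' Deep-feature extraction configuration
#'
#' Two convolutional backbones provide complementary representation taps:
#' an AlexNet-style plain stack tapped at its fully connected layer and a
#' ResNet-style residual stack tapped at its global average pool. The taps
#' are concatenated and compressed by one joint PCA. Backbones are
#' seed-initialized (untrained) at desk scale so that feature extraction
#' needs no downloads; the representation is a deterministic random
#' projection with convolutional structure, which is sufficient for the
#' linear-separability demands of the phantom benchmark.
#'
#' @param backbones Which taps to include (default both).
#' @param pretrained Must be `FALSE`: no trained weights ship with the
#'   package.
#' @param pca_components Output dimensionality (100 for the standard
#'   layout); must not exceed the PCA training-sample count or the raw tap
#'   length.
#' @param input_size Side length the slice is resized to before the
#'   backbone pass.
#' @param seed Integer seed for the backbone weights.
#' @return An object of class `deep_feat_config`.
#' @export
deep_feat_config <- function(backbones = c("alexnet", "resnet"),
                             pretrained = FALSE, pca_components = 100L,
                             input_size = 64L, seed = 1L) {
  backbones <- match.arg(backbones, several.ok = TRUE)
  if (isTRUE(pretrained))
    stop("pretrained backbone weights are not available; use pretrained = FALSE",
         call. = FALSE)
  structure(list(backbones = backbones, pretrained = FALSE,
                 pca_components = as.integer(pca_components),
                 input_size = as.integer(input_size), seed = as.integer(seed)),
            class = "deep_feat_config")
}

#' Build the seed-initialized deep-feature backbones
#'
#' @param config A [deep_feat_config()].
#' @return A `deep_backbones` object; pass to [deep_raw_features()].
#' @export
build_deep_backbones <- function(config = deep_feat_config()) {
  stopifnot(inherits(config, "deep_feat_config"))
  withr::with_seed(config$seed + 23L, {
    out <- list(config = config)
    if ("alexnet" %in% config$backbones) {
      # plain stack: conv5 -> pool -> conv3 -> pool -> conv3 -> pool -> fc(256)
      s <- config$input_size %/% 8L
      out$alex <- list(
        conv1 = nn_conv2d(1L, 16L, 5L), conv2 = nn_conv2d(16L, 32L, 3L),
        conv3 = nn_conv2d(32L, 32L, 3L),
        fc = nn_dense(s * s * 32L, 256L))
    }
    if ("resnet" %in% config$backbones) {
      # residual stack: conv3 -> pool -> resblock -> pool -> resblock -> GAP(128)
      out$res <- list(
        stem = nn_conv2d(1L, 16L, 3L),
        block1 = module_resblock(16L, 32L),
        block2 = module_resblock(32L, 128L))
    }
    structure(out, class = "deep_backbones")
  })
}

#' Raw (pre-PCA) deep-feature tap of one slice
#'
#' @param image Numeric matrix; resized to the configured input size.
#' @param backbones A `deep_backbones` object.
#' @return Numeric vector: AlexNet-style fc tap (256) followed by the
#'   ResNet-style pooled tap (128), for the default configuration.
#' @export
deep_raw_features <- function(image, backbones) {
  stopifnot(inherits(backbones, "deep_backbones"))
  sz <- backbones$config$input_size
  x <- array(resize_bilinear(image, sz), c(sz, sz, 1L, 1L))
  pool <- function(h) { p <- nn_pool2("max"); p$forward(h, train = FALSE) }
  relu <- function(h) pmax(h, 0)
  feats <- numeric(0)
  if (!is.null(backbones$alex)) {
    a <- backbones$alex
    h <- pool(relu(a$conv1$forward(x, FALSE)))
    h <- pool(relu(a$conv2$forward(h, FALSE)))
    h <- pool(relu(a$conv3$forward(h, FALSE)))
    fl <- t(matrix(h, prod(dim(h)[1:3]), 1L))
    feats <- c(feats, as.vector(relu(a$fc$forward(fl, FALSE))))
  }
  if (!is.null(backbones$res)) {
    r <- backbones$res
    h <- pool(relu(r$stem$forward(x, FALSE)))
    h <- pool(r$block1$forward(h, FALSE))
    h <- r$block2$forward(h, FALSE)
    feats <- c(feats, as.vector(apply(h, 3, mean)))
  }
  feats
}

#' Fit the joint PCA compressor for deep features
#'
#' Mean-centred principal components via [stats::prcomp()]; requires at
#' least as many samples as components.
#'
#' @param raw_features Matrix (samples x raw dims) of [deep_raw_features()]
#'   rows from the training split.
#' @param components Number of components to keep.
#' @return A `deep_pca` object.
#' @export
fit_pca <- function(raw_features, components = 100L) {
  raw_features <- as.matrix(raw_features)
  if (nrow(raw_features) < components)
    stop("need at least as many samples as components", call. = FALSE)
  if (ncol(raw_features) < components)
    stop("raw feature length below the requested components", call. = FALSE)
  pc <- stats::prcomp(raw_features, center = TRUE, scale. = FALSE)
  structure(list(rotation = pc$rotation[, seq_len(components), drop = FALSE],
                 center = pc$center,
                 sdev = pc$sdev[seq_len(components)],
                 components = as.integer(components)),
            class = "deep_pca")
}

#' @rdname fit_pca
#' @param pca A fitted `deep_pca`.
#' @param x Raw feature vector or matrix.
#' @export
pca_project <- function(pca, x) {
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  sweep(x, 2, pca$center) %*% pca$rotation
}

#' PCA-compressed deep features of one slice
#'
#' @param seg_image Segmented slice (numeric matrix).
#' @param backbones A `deep_backbones` object.
#' @param pca A fitted `deep_pca` (state error if missing).
#' @return Numeric vector of length `pca$components` (100 by default).
#' @export
deep_features <- function(seg_image, backbones, pca) {
  if (!inherits(pca, "deep_pca"))
    stop("`pca` must be fitted with fit_pca() first", call. = FALSE)
  as.vector(pca_project(pca, deep_raw_features(seg_image, backbones)))
}
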