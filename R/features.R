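#' Assemble the 201-value hybrid feature vector
#'
#' Ordered concatenation of the four feature families extracted from a
#' segmented slice: local Gabor transitional patterns (50), pyramid HOG
#' (50), PCA-compressed deep features (100) and the improved entropy
#' scalar (1). The segment layout is recorded in the `layout` attribute as
#' name -> index range.
#'
#' @param seg_image Segmented slice (numeric matrix).
#' @param backbones A `deep_backbones` object (see
#'   [build_deep_backbones()]).
#' @param pca A fitted `deep_pca` from [fit_pca()].
#' @param gabor,lgtrp,phog,entropy Family configurations.
#' @param entropy_variant `"improved"` or `"shannon"` (ablation).
#' @return Named numeric vector of length 201 with attribute `layout`.
#' @export
extract_feature_vector <- function(seg_image, backbones, pca,
                                   gabor = gabor_params(),
                                   lgtrp = lgtrp_config(),
                                   phog = phog_config(),
                                   entropy = entropy_config(),
                                   entropy_variant = "improved") {
  v_lgtrp <- lgtrp_features(seg_image, gabor, lgtrp)
  v_phog <- phog_features(seg_image, phog)
  v_deep <- deep_features(seg_image, backbones, pca)
  v_ien <- improved_entropy(seg_image, entropy, entropy_variant)
  segs <- list(lgtrp = v_lgtrp, phog = v_phog, deep = v_deep, ien = v_ien)
  lens <- vapply(segs, length, 1L)
  out <- unlist(segs, use.names = FALSE)
  names(out) <- sprintf("f%03d", seq_along(out) - 1L)
  ends <- cumsum(lens)
  layout <- Map(function(a, b) a:b, ends - lens + 1L, ends)
  names(layout) <- names(segs)
  attr(out, "layout") <- layout
  out
}

#' Slice a feature vector back into its named families
#'
#' @param v A vector produced by [extract_feature_vector()].
#' @return Named list of the per-family sub-vectors.
#' @export
feature_segments <- function(v) {
  layout <- attr(v, "layout")
  if (is.null(layout)) stop("vector has no layout attribute", call. = FALSE)
  lapply(layout, function(idx) unname(v[idx]))
}
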