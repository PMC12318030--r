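#' Entropy quantization settings
#'
#' Intensities on the `[0,1]` contract are scaled to `[0, 2^t - 1]` and
#' rounded before any entropy computation; `t = 8` reproduces standard
#' 8-bit grayscale histogramming exactly on PNG-derived data.
#'
#' @param t Bits per pixel (>= 1); the number of gray levels is `M = 2^t`.
#' @return An object of class `entropy_config`.
#' @export
entropy_config <- function(t = 8L) {
  t <- as.integer(t)
  if (t < 1L) stop("`t` must be >= 1", call. = FALSE)
  structure(list(t = t, log_base = 2), class = "entropy_config")
}

quantize_levels <- function(image, t) {
  round(clip01(image) * (2^t - 1))
}

#' Shannon entropy of the quantized intensity histogram
#'
#' `-sum p(m) log2 p(m)` over the `M = 2^t` gray levels with
#' `0 * log 0 := 0`; the result lies in `[0, t]` bits.
#'
#' @param image Numeric matrix on the `[0,1]` contract.
#' @param config An [entropy_config()].
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(image, config = entropy_config()) {
  assert_gray_image(image)
  q <- quantize_levels(image, config$t)
  p <- tabulate(q + 1L, nbins = 2^config$t) / length(q)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Entropy-dependent mixing weight
#'
#' `W_En = 2 * (1 - 1 / (1 + exp(En)))`: a rescaled logistic of the Shannon
#' entropy, equal to 1 at `En = 0` and approaching 2 as entropy grows. Note
#' that `W_En > 1` for any positive entropy, so the complementary weight
#' `1 - W_En` on the normalized entropy is negative; the formula is applied
#' exactly as defined.
#'
#' @param En Shannon entropy in bits (>= 0).
#' @return Weight in `[1, 2)`.
#' @export
entropy_weight <- function(En) {
  if (any(En < 0)) stop("`En` must be >= 0", call. = FALSE)
  2 * (1 - 1 / (1 + exp(En)))
}

#' Normalized first-order entropy
#'
#' First-order entropy over the `N_m` gray levels actually present in the
#' quantized image, divided by `log2(N_m)`; equals 1 when the present
#' levels are equifrequent and 0 by convention for a constant image
#' (`N_m = 1`).
#'
#' @param image Numeric matrix on the `[0,1]` contract.
#' @param config An [entropy_config()].
#' @return Value in `[0, 1]`.
#' @export
normalized_entropy <- function(image, config = entropy_config()) {
  assert_gray_image(image)
  q <- quantize_levels(image, config$t)
  counts <- table(as.vector(q))
  n_m <- length(counts)
  if (n_m <= 1L) return(0)
  p <- as.numeric(counts) / length(q)
  (-sum(p * log2(p))) / log2(n_m)
}

#' Improved (weighted) entropy feature
#'
#' The scalar texture feature
#' `IEn = W_En * En + (1 - W_En) * NEn`, mixing the Shannon entropy `En`
#' and the normalized entropy `NEn` with the data-dependent weight
#' [entropy_weight()]. The `"shannon"` variant (ablation) returns the plain
#' Shannon entropy instead.
#'
#' @param image Numeric matrix on the `[0,1]` contract.
#' @param config An [entropy_config()].
#' @param variant `"improved"` (default) or `"shannon"`.
#' @return Scalar feature value.
#' @export
improved_entropy <- function(image, config = entropy_config(),
                             variant = c("improved", "shannon")) {
  variant <- match.arg(variant)
  En <- shannon_entropy(image, config)
  if (variant == "shannon") return(En)
  W <- entropy_weight(En)
  NEn <- normalized_entropy(image, config)
  W * En + (1 - W) * NEn
}
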