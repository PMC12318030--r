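#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the
#' `phantom`, `preprocess`, `segmentation` and `classify` sections hold
#' the arguments of the respective constructors, and a `features` section
#' may hold `gabor`, `lgtrp`, `phog`, `entropy` and `deep` subsections.
#' `preprocess: {enabled: false}` or `segmentation: {enabled: false}`
#' disable the stage (ablation).
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  # YAML 1.1 reads a bare `n:` key as the boolean FALSE; restore it
  names(y)[names(y) %in% c("FALSE", "no")] <- "n"
  section <- function(name, fun) {
    s <- y[[name]]
    if (is.null(s)) return(NULL)          # fall back to the default
    if (isFALSE(s$enabled)) return("off") # stage disabled
    s$enabled <- NULL
    do.call(fun, s)
  }
  args <- list()
  for (k in c("n", "cancer_fraction", "train_fraction", "entropy_variant",
              "feature_families", "repeats", "seed"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  pre <- section("preprocess", gaussian_filter_params)
  seg <- section("segmentation", seg_config)
  if (!is.null(pre) && !identical(pre, "off")) args$preprocess <- pre
  if (!is.null(seg) && !identical(seg, "off")) args$segmentation <- seg
  ph <- section("phantom", phantom_spec)
  if (!is.null(ph)) args$phantom <- ph
  cl <- section("classify", classifier_config)
  if (!is.null(cl)) args$classify <- cl
  if (!is.null(y$features)) {
    funs <- list(gabor = gabor_params, lgtrp = lgtrp_config,
                 phog = phog_config, entropy = entropy_config,
                 deep = deep_feat_config)
    args$features <- Map(function(nm, s) do.call(funs[[nm]], s),
                         names(y$features), y$features)
  }
  cfg <- do.call(pipeline_config, args)
  if (identical(pre, "off")) cfg$preprocess <- NULL
  if (identical(seg, "off")) cfg$segmentation <- NULL
  cfg
}
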