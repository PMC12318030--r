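#' Full pipeline configuration
#'
#' One validated record holding every tunable of the end-to-end run:
#' phantom simulation, denoising, segmentation, feature extraction,
#' classification and evaluation, plus the ablation switches. Values can
#' be overridden per section; the seed governs every stochastic stage.
#'
#' @param n Number of simulated slices.
#' @param cancer_fraction Proportion of cancer-class slices.
#' @param train_fraction Train split fraction (floor rule).
#' @param phantom A [phantom_spec()].
#' @param preprocess A [gaussian_filter_params()], or `NULL` to skip
#'   denoising (ablation).
#' @param segmentation A [seg_config()], or `NULL` to skip segmentation
#'   and extract features from the whole preprocessed slice (ablation).
#' @param features Named list with `gabor`, `lgtrp`, `phog`, `entropy`,
#'   `deep` configuration objects.
#' @param classify A [classifier_config()].
#' @param entropy_variant `"improved"` or `"shannon"` (ablation).
#' @param feature_families Subset of
#'   `c("lgtrp", "phog", "deep", "entropy")` to feed the feature
#'   classifier.
#' @param repeats Number of seed-varied reruns for the accuracy
#'   statistics.
#' @param seed Master seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(n = 200L, cancer_fraction = 0.5,
                            train_fraction = 0.8,
                            phantom = phantom_spec(noise_sigma = 0.05),
                            preprocess = gaussian_filter_params(),
                            segmentation = seg_config(epochs = 8L),
                            features = list(),
                            classify = classifier_config(),
                            entropy_variant = c("improved", "shannon"),
                            feature_families = c("lgtrp", "phog", "deep", "entropy"),
                            repeats = 1L, seed = 1L) {
  entropy_variant <- match.arg(entropy_variant)
  feature_families <- match.arg(feature_families, several.ok = TRUE)
  fdef <- list(gabor = gabor_params(), lgtrp = lgtrp_config(),
               phog = phog_config(), entropy = entropy_config(),
               deep = deep_feat_config())
  features <- utils::modifyList(fdef, features)
  if (n < 4L) stop("`n` must be at least 4", call. = FALSE)
  structure(list(n = as.integer(n), cancer_fraction = cancer_fraction,
                 train_fraction = train_fraction, phantom = phantom,
                 preprocess = preprocess, segmentation = segmentation,
                 features = features, classify = classify,
                 entropy_variant = entropy_variant,
                 feature_families = feature_families,
                 repeats = as.integer(repeats), seed = as.integer(seed)),
            class = "pipeline_config")
}

# derive a stage seed from the master seed (kept below 2^31)
stage_seed <- function(seed, k) (as.integer(seed) * 101L + k * 7919L) %% 2147480017L

pipeline_log <- function(verbose, stage, t0, seed = NA) {
  if (!verbose) return(invisible(NULL))
  message(sprintf("[%s] %.1fs seed=%s", stage,
                  as.numeric(Sys.time() - t0, units = "secs"),
                  as.character(seed)))
}

run_pipeline_once <- function(config, seed, verbose = FALSE) {
  t0 <- Sys.time()

  # simulate
  ds <- generate_dataset(config$n, config$cancer_fraction, config$phantom,
                         seed = stage_seed(seed, 1L))
  labels <- ds$labels
  pipeline_log(verbose, "simulate", t0, stage_seed(seed, 1L))

  # preprocess
  pre <- if (!is.null(config$preprocess)) {
    lapply(ds$items, function(it) adaptive_gaussian_filter(it$image, config$preprocess))
  } else {
    lapply(ds$items, `[[`, "image")
  }
  quality <- if (!is.null(config$preprocess)) {
    ps <- vapply(seq_along(pre), function(i) {
      cl <- attr(ds$items[[i]], "clean")
      c(psnr(cl, ds$items[[i]]$image), psnr(cl, pre[[i]]),
        ssim(cl, ds$items[[i]]$image), ssim(cl, pre[[i]]))
    }, numeric(4))
    list(psnr_noisy = mean(ps[1, ]), psnr_filtered = mean(ps[2, ]),
         ssim_noisy = mean(ps[3, ]), ssim_filtered = mean(ps[4, ]))
  } else NULL
  pipeline_log(verbose, "preprocess", t0)

  # split
  sp <- split_dataset(seq_len(config$n), config$train_fraction,
                      stratified = TRUE, labels = labels,
                      seed = stage_seed(seed, 2L))
  tr <- sp$train; te <- sp$test

  # segmentation
  seg_quality <- NULL
  if (!is.null(config$segmentation)) {
    seg_cfg <- config$segmentation
    seg_cfg$seed <- stage_seed(seed, 3L)
    train_ds <- structure(list(items = Map(function(img, it)
      structure(list(image = img, mask = it$mask, label = it$label),
                class = "labeled_image"),
      pre[tr], ds$items[tr]),
      labels = labels[tr], spec = ds$spec, seed = seg_cfg$seed),
      class = "phantom_dataset")
    fit <- train_segmenter(train_ds, seg_cfg)
    masks <- lapply(pre, segment, model = fit$model)
    sm <- vapply(te, function(i)
      unlist(seg_metrics(masks[[i]], ds$items[[i]]$mask)), numeric(3))
    seg_quality <- list(dice = mean(sm[1, ]), jaccard = mean(sm[2, ]),
                        segmentation_accuracy = mean(sm[3, ]),
                        loss_history = fit$history)
    seg_in <- lapply(seq_along(pre), function(i) pre[[i]] * masks[[i]])
  } else {
    seg_in <- pre
  }
  pipeline_log(verbose, "segment", t0)

  # features
  fc <- config$features
  fc$deep$seed <- stage_seed(seed, 4L)
  backbones <- build_deep_backbones(fc$deep)
  raw1 <- deep_raw_features(seg_in[[1]], backbones)
  raw <- t(vapply(seg_in, deep_raw_features, backbones = backbones,
                  FUN.VALUE = numeric(length(raw1))))
  ncomp <- min(fc$deep$pca_components, length(tr))
  pca <- fit_pca(raw[tr, , drop = FALSE], ncomp)
  feats <- t(vapply(seq_along(seg_in), function(i) {
    extract_feature_vector(seg_in[[i]], backbones, pca,
                           gabor = fc$gabor, lgtrp = fc$lgtrp,
                           phog = fc$phog, entropy = fc$entropy,
                           entropy_variant = config$entropy_variant)
  }, numeric(100L + ncomp + 1L)))
  # restrict families for the feature classifier (ablation switch)
  fam_idx <- list(lgtrp = 1:50, phog = 51:100,
                  deep = 100 + seq_len(ncomp), entropy = 101 + ncomp)
  keep <- sort(unlist(fam_idx[match(config$feature_families,
                                    c("lgtrp", "phog", "deep", "entropy"))]))
  feats_used <- feats[, keep, drop = FALSE]
  pipeline_log(verbose, "features", t0)

  # classify
  cl_cfg <- config$classify
  cl_cfg$seed <- stage_seed(seed, 5L)
  ens <- train_ensemble(seg_in[tr], feats_used[tr, , drop = FALSE], labels[tr],
                        cl_cfg)
  predictions <- predict_ensemble(ens, seg_in[te], feats_used[te, , drop = FALSE])
  pipeline_log(verbose, "classify", t0)

  # evaluate
  cm <- confusion_and_metrics(predictions$label, labels[te])
  auc <- roc_auc(predictions$p_fused_1, labels[te])
  list(split = sp$plan, confusion = cm$confusion, metrics = cm$metrics,
       auc = auc, quality = quality, segmentation = seg_quality,
       predictions = predictions, test_labels = labels[te], seed = seed)
}

#' Run the end-to-end classification pipeline
#'
#' Simulate (or rerun on) phantoms, denoise, train and apply the
#' segmenter, extract the hybrid features, train the soft-voting ensemble
#' and evaluate on the held-out split. With `repeats > 1` the whole run is
#' repeated under varied seeds and accuracy summary statistics are added.
#' Two calls with the same config produce identical reports.
#'
#' @param config A [pipeline_config()].
#' @param verbose Log stage timings.
#' @return An `eval_report` list: split plan, confusion counts, the nine
#'   classification metrics, ROC-AUC, preprocessing quality (PSNR/SSIM),
#'   segmentation quality (Dice/Jaccard/accuracy) and per-repeat
#'   accuracies.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  runs <- lapply(seq_len(config$repeats), function(k)
    run_pipeline_once(config, seed = config$seed + (k - 1L), verbose = verbose))
  first <- runs[[1]]
  accs <- vapply(runs, function(r) r$metrics$accuracy, 1)
  report <- list(split = first$split, confusion = first$confusion,
                 metrics = first$metrics, auc = first$auc,
                 quality = first$quality, segmentation = first$segmentation,
                 run_stats = run_statistics(accs),
                 repeats = config$repeats, seed = config$seed,
                 predictions = first$predictions,
                 test_labels = first$test_labels)
  class(report) <- "eval_report"
  report
}

#' Write an evaluation report as JSON and CSV
#'
#' @param report An `eval_report` from [run_pipeline()].
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_eval_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jp <- file.path(dir, "report.json")
  slim <- report[c("split", "confusion", "metrics", "auc", "quality",
                   "segmentation", "run_stats", "repeats", "seed")]
  slim$segmentation$loss_history <- NULL
  jsonlite::write_json(slim, jp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cp <- file.path(dir, "metrics.csv")
  utils::write.csv(data.frame(metric = c(names(report$metrics), "auc"),
                              value = c(unlist(report$metrics), report$auc)),
                   cp, row.names = FALSE)
  pp <- file.path(dir, "predictions.csv")
  utils::write.csv(cbind(report$predictions, truth = report$test_labels),
                   pp, row.names = FALSE)
  invisible(c(jp, cp, pp))
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Evaluation report (test n =", x$split$n_test, ")\n")
  cat(sprintf("  accuracy    %.3f\n", x$metrics$accuracy))
  cat(sprintf("  sensitivity %.3f  specificity %.3f\n",
              x$metrics$sensitivity, x$metrics$specificity))
  cat(sprintf("  precision   %.3f  f-measure   %.3f\n",
              x$metrics$precision, x$metrics$f_measure))
  cat(sprintf("  mcc         %.3f  npv         %.3f\n",
              x$metrics$mcc, x$metrics$npv))
  cat(sprintf("  fpr         %.3f  fnr         %.3f\n",
              x$metrics$fpr, x$metrics$fnr))
  cat(sprintf("  auc         %.3f\n", x$auc))
  if (!is.null(x$segmentation))
    cat(sprintf("  dice        %.3f  jaccard     %.3f\n",
                x$segmentation$dice, x$segmentation$jaccard))
  if (!is.null(x$quality))
    cat(sprintf("  psnr %.2f -> %.2f dB  ssim %.3f -> %.3f\n",
                x$quality$psnr_noisy, x$quality$psnr_filtered,
                x$quality$ssim_noisy, x$quality$ssim_filtered))
  invisible(x)
}
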