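#' Train/test split with floor-based train count
#'
#' `n_train = floor(train_fraction * n)`; the partition is disjoint and
#' exhaustive, optionally stratified by label (per-class counts allocated
#' by largest remainder so the total is exact), and deterministic given the
#' seed.
#'
#' @param ids Vector of instance identifiers.
#' @param train_fraction Proportion in `(0, 1)`.
#' @param stratified Stratify by `labels`.
#' @param labels Binary labels aligned with `ids` (required when
#'   `stratified = TRUE`).
#' @param seed Integer seed.
#' @return List with `plan` (train_fraction, n_total, n_train, n_test,
#'   stratified, seed), `train` and `test` id vectors.
#' @export
split_dataset <- function(ids, train_fraction, stratified = TRUE,
                          labels = NULL, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("`train_fraction` must lie in (0, 1)", call. = FALSE)
  n <- length(ids)
  n_train <- floor(train_fraction * n)
  withr::with_seed(as.integer(seed), {
    if (stratified) {
      if (is.null(labels) || length(labels) != n)
        stop("stratified splitting needs aligned `labels`", call. = FALSE)
      classes <- sort(unique(labels))
      exact <- vapply(classes, function(cl) sum(labels == cl) * train_fraction, 1)
      base <- floor(exact)
      rem <- n_train - sum(base)
      if (rem > 0) {
        order_rem <- order(exact - base, decreasing = TRUE)
        base[order_rem[seq_len(rem)]] <- base[order_rem[seq_len(rem)]] + 1L
      }
      train_pos <- unlist(lapply(seq_along(classes), function(k) {
        pos <- which(labels == classes[k])
        sample(pos, base[k])
      }))
    } else {
      train_pos <- sample.int(n, n_train)
    }
    train_pos <- sort(train_pos)
    list(plan = list(train_fraction = train_fraction, n_total = n,
                     n_train = n_train, n_test = n - n_train,
                     stratified = stratified, seed = as.integer(seed)),
         train = ids[train_pos],
         test = ids[setdiff(seq_len(n), train_pos)])
  })
}

#' Confusion matrix and the nine binary-classification metrics
#'
#' Accuracy, sensitivity (TPR), specificity (TNR), precision, F-measure,
#' Matthews correlation coefficient, negative predictive value, and the
#' false-positive / false-negative rates, all from the 2x2 confusion
#' counts. A metric whose denominator is zero is reported as 0 with a
#' warning so degenerate ablations still produce complete reports.
#'
#' @param predictions,truths Aligned binary (0/1) vectors.
#' @return List with `confusion` (named TP/FP/TN/FN counts) and `metrics`.
#' @export
confusion_and_metrics <- function(predictions, truths) {
  if (length(predictions) != length(truths))
    stop("predictions and truths must be aligned", call. = FALSE)
  p <- as.integer(predictions); t <- as.integer(truths)
  TP <- sum(p == 1 & t == 1); TN <- sum(p == 0 & t == 0)
  FP <- sum(p == 1 & t == 0); FN <- sum(p == 0 & t == 1)
  sdiv <- function(num, den, what) {
    if (den == 0) { warning(sprintf("zero denominator for %s; reporting 0", what)); 0 }
    else num / den
  }
  prec <- sdiv(TP, TP + FP, "precision")
  sens <- sdiv(TP, TP + FN, "sensitivity")
  f <- if (prec + sens == 0) 0 else 2 * prec * sens / (prec + sens)
  mcc_den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  mcc <- if (mcc_den == 0) {
    warning("zero denominator for mcc; reporting 0"); 0
  } else (TP * TN - FP * FN) / mcc_den
  list(confusion = c(TP = TP, FP = FP, TN = TN, FN = FN),
       metrics = list(
         accuracy = (TP + TN) / length(p),
         sensitivity = sens,
         specificity = sdiv(TN, TN + FP, "specificity"),
         precision = prec,
         f_measure = f,
         mcc = mcc,
         npv = sdiv(TN, TN + FN, "npv"),
         fpr = sdiv(FP, FP + TN, "fpr"),
         fnr = sdiv(FN, FN + TP, "fnr")))
}

#' Area under the ROC curve
#'
#' Computed in the rank (Wilcoxon) form, which equals the trapezoidal area
#' over all thresholds and the probability that a random positive outscores
#' a random negative with ties counted one half.
#'
#' @param scores Numeric scores (larger = more positive).
#' @param truths Binary labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, truths) {
  truths <- as.integer(truths)
  n1 <- sum(truths == 1); n0 <- sum(truths == 0)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[truths == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Summary statistics of repeated accuracy measurements
#'
#' @param accs Numeric vector of per-repeat accuracies.
#' @return Named list with mean, median, std, min, max.
#' @export
run_statistics <- function(accs) {
  list(mean = mean(accs), median = stats::median(accs),
       std = if (length(accs) > 1) stats::sd(accs) else 0,
       min = min(accs), max = max(accs))
}
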