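test_that("the floor-rule splitter reproduces the 2336-instance arithmetic", {
  ids <- seq_len(2336L)
  labels <- rep(c(0L, 1L), c(1112L, 1224L))
  for (case in list(c(0.6, 1401, 935), c(0.7, 1635, 701), c(0.8, 1868, 468))) {
    sp <- split_dataset(ids, case[1], stratified = TRUE, labels = labels, seed = 1L)
    expect_equal(sp$plan$n_train, case[2])
    expect_equal(sp$plan$n_test, case[3])
    expect_length(sp$train, case[2])
    expect_length(sp$test, case[3])
    expect_setequal(c(sp$train, sp$test), ids)
    expect_length(intersect(sp$train, sp$test), 0L)
  }
  sp2 <- split_dataset(ids, 0.6, stratified = FALSE, seed = 2L)
  expect_equal(length(sp2$train), 1401L)
  expect_identical(split_dataset(ids, 0.6, FALSE, seed = 2L)$train, sp2$train)
  expect_error(split_dataset(ids, 1.2))
  expect_error(split_dataset(ids, 0.6, stratified = TRUE, labels = NULL))
})

test_that("stratified splits keep per-class proportions", {
  labels <- rep(c(0L, 1L), c(30L, 70L))
  sp <- split_dataset(seq_len(100L), 0.6, stratified = TRUE, labels = labels,
                      seed = 3L)
  expect_equal(sum(labels[sp$train] == 1L), 42L)
  expect_equal(sum(labels[sp$train] == 0L), 18L)
})

test_that("confusion metrics match plug-in arithmetic", {
  perfect <- confusion_and_metrics(c(1, 0, 1, 0), c(1, 0, 1, 0))
  expect_equal(perfect$metrics$accuracy, 1)
  expect_equal(perfect$metrics$fpr, 0)
  expect_equal(perfect$metrics$fnr, 0)
  expect_equal(perfect$metrics$mcc, 1)
  allpos <- suppressWarnings(
    confusion_and_metrics(rep(1, 10), rep(c(0, 1), 5)))
  expect_equal(allpos$metrics$sensitivity, 1)
  expect_equal(allpos$metrics$specificity, 0)

  # the printed example counts: TP 112, FP 2, FN 4, TN 116
  y <- c(rep(1, 116), rep(0, 118))
  p <- c(rep(1, 112), rep(0, 4), rep(1, 2), rep(0, 116))
  r <- confusion_and_metrics(p, y)
  expect_equal(unname(r$confusion), c(112, 2, 116, 4))
  mcc_o <- (112 * 116 - 2 * 4) /
    sqrt((112 + 2) * (112 + 4) * (116 + 2) * (116 + 4))
  expect_equal(r$metrics$mcc, mcc_o, tolerance = 1e-12)

  # 100 random confusion matrices against independent plug-in arithmetic
  withr::with_seed(21L, {
    for (k in 1:100) {
      n <- sample(20:60, 1)
      y <- stats::rbinom(n, 1, stats::runif(1, 0.2, 0.8))
      p <- stats::rbinom(n, 1, stats::runif(1, 0.2, 0.8))
      r <- suppressWarnings(confusion_and_metrics(p, y))
      TP <- sum(p & y); TN <- sum(!p & !y); FP <- sum(p & !y); FN <- sum(!p & y)
      z <- function(num, den) if (den == 0) 0 else num / den
      expect_equal(r$metrics$accuracy, (TP + TN) / n)
      expect_equal(r$metrics$sensitivity, z(TP, TP + FN))
      expect_equal(r$metrics$specificity, z(TN, TN + FP))
      expect_equal(r$metrics$precision, z(TP, TP + FP))
      pr <- z(TP, TP + FP); se <- z(TP, TP + FN)
      expect_equal(r$metrics$f_measure, if (pr + se == 0) 0 else 2 * pr * se / (pr + se))
      den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
      expect_equal(r$metrics$mcc, if (den == 0) 0 else (TP * TN - FP * FN) / den)
      expect_equal(r$metrics$npv, z(TN, TN + FN))
      expect_equal(r$metrics$fpr, z(FP, FP + TN))
      expect_equal(r$metrics$fnr, z(FN, FN + TP))
      expect_true(r$metrics$mcc >= -1 && r$metrics$mcc <= 1)
      expect_equal(sum(r$confusion), n)
    }
  })
  expect_error(confusion_and_metrics(c(1, 0), c(1)))
})

test_that("auc matches the pairwise-comparison oracle and its symmetries", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  withr::with_seed(22L, {
    for (k in 1:10) {
      s <- round(stats::runif(50), 2) # rounding forces ties
      y <- stats::rbinom(50, 1, 0.5)
      if (length(unique(y)) < 2) next
      pos <- s[y == 1]; neg <- s[y == 0]
      cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
      expect_equal(roc_auc(s, y), mean(cmp), tolerance = 1e-12)
      expect_equal(roc_auc(-s, y), 1 - roc_auc(s, y), tolerance = 1e-12)
    }
  })
  expect_error(roc_auc(1:4, rep(1, 4)))
})

test_that("auc agrees with an established implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(23L, {
    s <- stats::runif(80)
    y <- stats::rbinom(80, 1, 0.5)
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<", levels = c(0, 1))))
    expect_equal(roc_auc(s, y), ref, tolerance = 1e-12)
  })
})

test_that("repeat statistics summarize accuracies", {
  st <- run_statistics(c(0.8, 0.9, 0.85))
  expect_equal(st$mean, 0.85)
  expect_equal(st$median, 0.85)
  expect_equal(st$min, 0.8)
  expect_equal(st$max, 0.9)
  expect_equal(run_statistics(0.7)$std, 0)
})
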