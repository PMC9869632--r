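test_that("Clopper-Pearson matches closed forms and binom.test", {
  ci0 <- clopper_pearson(0, 10)
  expect_equal(ci0[["lower"]], 0)
  expect_equal(ci0[["upper"]], 1 - (0.025)^(1 / 10), tolerance = 1e-9)
  expect_equal(ci0[["upper"]], 0.3085, tolerance = 5e-5)

  ci10 <- clopper_pearson(10, 10)
  expect_equal(ci10[["upper"]], 1)
  expect_equal(ci10[["lower"]], (0.025)^(1 / 10), tolerance = 1e-9)

  ci5 <- clopper_pearson(5, 10)
  expect_equal(unname(ci5), c(0.1871, 0.8129), tolerance = 5e-5)

  # binom.test computes the same exact interval
  for (k in c(0, 3, 7, 10)) {
    bt <- stats::binom.test(k, 10)$conf.int
    expect_equal(unname(clopper_pearson(k, 10)), as.numeric(bt),
                 tolerance = 1e-12)
  }
  expect_error(clopper_pearson(5, 4), "k <= n")
  expect_error(clopper_pearson(-1, 4), "k <= n")
})

test_that("Clopper-Pearson intervals achieve nominal coverage", {
  set.seed(2024)
  n <- 50
  p <- 0.3
  k <- stats::rbinom(2000, n, p)
  lower <- ifelse(k == 0, 0, stats::qbeta(0.025, k, n - k + 1))
  upper <- ifelse(k == n, 1, stats::qbeta(0.975, k + 1, n - k))
  coverage <- mean(lower <= p & p <= upper)
  expect_gte(coverage, 0.93)
  expect_lte(coverage, 0.975)
})

test_that("roc_auc matches examples and brute-force concordance", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.5, 8), rep(c(0, 1), 4)), 0.5)
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_error(roc_auc(c(0.1, 0.2), c(1, 1)), "both label")

  set.seed(14)
  for (i in 1:200) {
    n <- sample(4:50, 1)
    scores <- round(runif(n), sample(1:3, 1))   # force some ties
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    expect_identical(roc_auc(scores, labels),
                     oracle_auc(scores, labels))
  }
})

test_that("roc_auc agrees with pROC on random data", {
  skip_if_not_installed("pROC")
  set.seed(6)
  scores <- runif(60)
  labels <- rbinom(60, 1, 0.4)
  expect_equal(roc_auc(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores,
                                              quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

fake_confidence <- function(P) {
  wsi_confidence(stats::setNames(P, diagnostic_classes()))
}

test_that("slide-level evaluation handles perfect and degenerate predictors", {
  truth <- rep(diagnostic_classes(), each = 10)
  perfect <- lapply(truth, function(t) {
    P <- stats::setNames(c(0.2, 0.2, 0.2), diagnostic_classes())
    P[t] <- 0.95
    fake_confidence(P)
  })
  rep1 <- evaluate_wsi(perfect, truth)
  expect_equal(rep1$overall_accuracy$estimate, 1)
  expect_true(all(rep1$auc == 1))
  expect_equal(rep1$macro_auc, 1)
  expect_equal(unname(diag(rep1$confusion)), c(10, 10, 10))
  expect_equal(rowSums(rep1$confusion),
               table(factor(truth, levels = diagnostic_classes())) * 1,
               ignore_attr = TRUE)
  expect_equal(rep1$binary$mibc$auc, 1)
  expect_equal(rep1$binary$grade$accuracy$estimate, 1)

  # degenerate: always predicts LGNMI
  always <- lapply(truth, function(t) {
    fake_confidence(c(0.1, 0.2, 0.9))
  })
  rep2 <- evaluate_wsi(always, truth)
  pc <- rep2$per_class
  sens <- function(cls) pc$estimate[pc$class == cls &
                                      pc$metric == "sensitivity"]
  expect_equal(sens("LGNMI"), 1)
  expect_equal(sens("HGMI"), 0)
  expect_equal(sens("HGNMI"), 0)
  expect_equal(rep2$overall_accuracy$estimate, 1 / 3)

  expect_error(evaluate_wsi(perfect[1:5], truth), "length")
})

test_that("sensitivity and specificity recompute from the confusion matrix", {
  set.seed(77)
  truth <- sample(diagnostic_classes(), 60, replace = TRUE)
  preds <- lapply(seq_along(truth), function(i) {
    fake_confidence(runif(3, 0.1, 0.9))
  })
  rep <- evaluate_wsi(preds, truth)
  cm <- rep$confusion
  for (cls in diagnostic_classes()) {
    tp <- cm[cls, cls]
    fn <- sum(cm[cls, ]) - tp
    fp <- sum(cm[, cls]) - tp
    tn <- sum(cm) - tp - fn - fp
    pc <- rep$per_class
    expect_equal(pc$estimate[pc$class == cls &
                               pc$metric == "sensitivity"],
                 tp / (tp + fn))
    expect_equal(pc$estimate[pc$class == cls &
                               pc$metric == "specificity"],
                 tn / (tn + fp))
  }
})

test_that("permuted labels give chance-level macro AUC", {
  set.seed(300)
  n <- 300
  truth <- sample(diagnostic_classes(), n, replace = TRUE)
  preds <- lapply(seq_len(n), function(i) fake_confidence(runif(3)))
  rep <- evaluate_wsi(preds, truth)
  expect_lt(abs(rep$macro_auc - 0.5), 0.08)
})

test_that("patch-level evaluation covers six classes", {
  classes <- label_classes()$code
  truth <- rep(classes, each = 5)
  probs <- t(vapply(truth, function(t) {
    p <- rep(0.02, 6)
    p[match(t, classes)] <- 0.9
    p / sum(p)
  }, numeric(6)))
  rep <- evaluate_patches(probs, truth)
  expect_equal(dim(rep$confusion), c(6, 6))
  expect_equal(sum(rep$confusion), 30)
  expect_equal(unname(diag(rep$confusion)), rep(5, 6))
  expect_length(rep$auc, 6)
  expect_true(all(rep$auc == 1))
  expect_equal(rep$macro_auc, mean(rep$auc))
})

test_that("bootstrap AUC intervals bracket the estimate", {
  set.seed(55)
  truth <- rep(diagnostic_classes(), each = 15)
  preds <- lapply(truth, function(t) {
    P <- stats::setNames(runif(3, 0.1, 0.5), diagnostic_classes())
    P[t] <- P[t] + runif(1, 0, 0.4)
    fake_confidence(P)
  })
  rep <- evaluate_wsi(preds, truth, boot = 200, seed = 3)
  expect_false(is.null(rep$auc_ci))
  for (i in seq_len(nrow(rep$auc_ci))) {
    cls <- rep$auc_ci$class[i]
    expect_lte(rep$auc_ci$lower[i], rep$auc[[cls]])
    expect_gte(rep$auc_ci$upper[i], rep$auc[[cls]])
  }
})
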