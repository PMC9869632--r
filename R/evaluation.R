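# Evaluation surface: exact binomial (Clopper-Pearson) intervals for
# the diagnostic proportions, rank-based ROC/AUC, confusion matrices
# and per-class one-vs-rest reports at patch and slide level.

#' Clopper-Pearson exact binomial interval
#'
#' Two-sided `1 - alpha` interval from beta quantiles:
#' lower = `qbeta(alpha/2, k, n - k + 1)` (0 when `k = 0`),
#' upper = `qbeta(1 - alpha/2, k + 1, n - k)` (1 when `k = n`).
#'
#' @param k Number of successes, `0 <= k <= n`.
#' @param n Number of trials, `n >= 1`.
#' @param alpha Two-sided error level (default 0.05 for 95% CIs).
#' @return Numeric `c(lower, upper)`.
#' @export
clopper_pearson <- function(k, n, alpha = 0.05) {
  if (length(k) != 1 || length(n) != 1 || n < 1 || k < 0 || k > n ||
      k != round(k) || n != round(n)) {
    stop("need integers 0 <= k <= n with n >= 1", call. = FALSE)
  }
  stopifnot(alpha > 0, alpha < 1)
  lower <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  c(lower = lower, upper = upper)
}

metric_ci <- function(k, n, alpha = 0.05) {
  if (n == 0) {
    return(data.frame(estimate = NA_real_, lower = NA_real_,
                      upper = NA_real_, k = 0L, n = 0L))
  }
  ci <- clopper_pearson(k, n, alpha)
  data.frame(estimate = k / n, lower = unname(ci[1]),
             upper = unname(ci[2]), k = as.integer(k), n = as.integer(n))
}

#' ROC AUC by rank statistic
#'
#' The Mann-Whitney concordance probability: the chance that a random
#' positive outscores a random negative, with half credit for ties.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels (logical, or 0/1).
#' @return The AUC.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), all(!is.na(labels)),
            all(is.finite(scores)))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("both label values must be present", call. = FALSE)
  }
  r <- rank(scores)          # average ranks give tie half-credit
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve points
#'
#' False/true positive rates over all score thresholds, for plotting or
#' CSV export.
#'
#' @inheritParams roc_auc
#' @return Data frame `threshold`, `fpr`, `tpr` (thresholds decreasing).
#' @export
roc_points <- function(scores, labels) {
  labels <- as.logical(labels)
  ord <- order(scores, decreasing = TRUE)
  thr <- unique(scores[ord])
  out <- t(vapply(thr, function(t) {
    pred <- scores >= t
    c(fpr = sum(pred & !labels) / sum(!labels),
      tpr = sum(pred & labels) / sum(labels))
  }, c(fpr = 0, tpr = 0)))
  data.frame(threshold = thr, fpr = out[, 1], tpr = out[, 2])
}

one_vs_rest_metrics <- function(truth, pred, cls, alpha = 0.05) {
  tp <- sum(truth == cls & pred == cls)
  fn <- sum(truth == cls & pred != cls)
  fp <- sum(truth != cls & pred == cls)
  tn <- sum(truth != cls & pred != cls)
  rbind(
    cbind(metric = "sensitivity", metric_ci(tp, tp + fn, alpha)),
    cbind(metric = "specificity", metric_ci(tn, tn + fp, alpha)),
    cbind(metric = "ppv", metric_ci(tp, tp + fp, alpha)),
    cbind(metric = "npv", metric_ci(tn, tn + fn, alpha)),
    cbind(metric = "accuracy", metric_ci(tp + tn, tp + tn + fp + fn,
                                         alpha))
  )
}

# stratified bootstrap CI for an AUC (resampling within label strata)
auc_boot_ci <- function(scores, labels, boot, seed, alpha = 0.05) {
  labels <- as.logical(labels)
  local_seed(seed, {
    pos <- which(labels)
    neg <- which(!labels)
    stat <- vapply(seq_len(boot), function(b) {
      idx <- c(pos[sample.int(length(pos), replace = TRUE)],
               neg[sample.int(length(neg), replace = TRUE)])
      roc_auc(scores[idx], labels[idx])
    }, numeric(1))
    stats::quantile(stat, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  })
}

build_report <- function(truth, pred, prob, classes, alpha = 0.05,
                         boot = 0, seed = 1) {
  confusion <- table(factor(truth, levels = classes),
                     factor(pred, levels = classes),
                     dnn = c("truth", "predicted"))
  per_class <- do.call(rbind, lapply(classes, function(cls) {
    cbind(class = cls, one_vs_rest_metrics(truth, pred, cls, alpha))
  }))
  present <- classes[classes %in% unique(truth)]
  auc <- stats::setNames(rep(NA_real_, length(classes)), classes)
  auc_ci <- NULL
  for (cls in present) {
    if (all(truth == cls)) next
    auc[cls] <- roc_auc(prob[, cls], truth == cls)
    if (boot > 0) {
      ci <- auc_boot_ci(prob[, cls], truth == cls, boot, seed)
      auc_ci <- rbind(auc_ci, data.frame(class = cls, lower = ci[1],
                                         upper = ci[2]))
    }
  }
  pooled_scores <- as.vector(prob[, present])
  pooled_truth <- as.vector(vapply(present, function(cls) truth == cls,
                                   logical(length(truth))))
  list(
    classes = classes,
    confusion = confusion,
    per_class = per_class,
    overall_accuracy = metric_ci(sum(truth == pred), length(truth),
                                 alpha),
    auc = auc,
    macro_auc = mean(auc[present], na.rm = TRUE),
    micro_auc = roc_auc(pooled_scores, pooled_truth),
    auc_ci = auc_ci
  )
}

#' Evaluate slide-level predictions
#'
#' Per-class one-vs-rest AUC from the softmax confidences `Prob_k`,
#' the overall (macro-average) AUC, hard-label metrics with
#' Clopper-Pearson intervals from the predicted labels, and the two
#' derived binary tasks: muscle invasion (truth HGMI, score
#' `mibc_score`) and grading (truth HGMI or HGNMI -- all
#' muscle-invasive disease is high-grade -- score `high_grade_score`).
#'
#' @param preds List of [wsi_confidence()] objects.
#' @param truth Character vector of true slide categories, aligned with
#'   `preds`.
#' @param alpha CI level (default 0.05).
#' @param boot Bootstrap resamples for AUC CIs (0 = skip; 2000 is a
#'   reasonable production value).
#' @param seed Seed for the bootstrap.
#' @return Object of class `eval_report`.
#' @export
evaluate_wsi <- function(preds, truth, alpha = 0.05, boot = 0,
                         seed = 1) {
  if (length(preds) != length(truth)) {
    stop("preds and truth have different lengths", call. = FALSE)
  }
  check_label(truth, diagnostic_only = TRUE)
  stopifnot(length(unique(truth)) >= 2)
  classes <- diagnostic_classes()
  prob <- t(vapply(preds, function(p) p$prob, numeric(3)))
  colnames(prob) <- classes
  pred <- vapply(preds, function(p) p$predicted_label, character(1))
  report <- build_report(truth, pred, prob, classes, alpha, boot, seed)
  mibc_score <- vapply(preds, function(p) p$mibc_score, numeric(1))
  hg_score <- vapply(preds, function(p) p$high_grade_score, numeric(1))
  binary_task <- function(truth_bin, pred_bin, score) {
    list(
      auc = if (length(unique(truth_bin)) == 2) {
        roc_auc(score, truth_bin)
      } else NA_real_,
      sensitivity = metric_ci(sum(truth_bin & pred_bin), sum(truth_bin),
                              alpha),
      specificity = metric_ci(sum(!truth_bin & !pred_bin),
                              sum(!truth_bin), alpha),
      ppv = metric_ci(sum(truth_bin & pred_bin), sum(pred_bin), alpha),
      npv = metric_ci(sum(!truth_bin & !pred_bin), sum(!pred_bin),
                      alpha),
      accuracy = metric_ci(sum(truth_bin == pred_bin), length(truth_bin),
                           alpha)
    )
  }
  report$binary <- list(
    mibc = binary_task(truth == "HGMI", pred == "HGMI", mibc_score),
    grade = binary_task(truth %in% c("HGMI", "HGNMI"),
                        pred %in% c("HGMI", "HGNMI"), hg_score)
  )
  report$level <- "wsi"
  structure(report, class = "eval_report")
}

#' Evaluate patch-level predictions over six classes
#'
#' As [evaluate_wsi()] but over the six patch classes, with hard labels
#' taken as the argmax of each probability vector; no binary tasks.
#'
#' @param preds `n x 6` matrix of class probabilities (columns in
#'   channel order), or a list of 6-vectors.
#' @param truth Character vector of true patch labels.
#' @inheritParams evaluate_wsi
#' @return Object of class `eval_report`.
#' @export
evaluate_patches <- function(preds, truth, alpha = 0.05, boot = 0,
                             seed = 1) {
  if (is.list(preds)) preds <- do.call(rbind, preds)
  if (nrow(preds) != length(truth)) {
    stop("preds and truth have different lengths", call. = FALSE)
  }
  check_label(truth)
  stopifnot(length(unique(truth)) >= 2, ncol(preds) == 6)
  classes <- label_classes()$code
  colnames(preds) <- classes
  pred <- classes[max.col(preds, ties.method = "first")]
  report <- build_report(truth, pred, preds, classes, alpha, boot, seed)
  report$level <- "patch"
  structure(report, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s-level, n = %d\n", x$level,
              sum(x$confusion)))
  cat(sprintf("  overall accuracy %.3f (%.3f-%.3f)\n",
              x$overall_accuracy$estimate, x$overall_accuracy$lower,
              x$overall_accuracy$upper))
  aucs <- x$auc[!is.na(x$auc)]
  cat(sprintf("  AUC: %s; macro %.3f, micro %.3f\n",
              paste(sprintf("%s %.3f", names(aucs), aucs),
                    collapse = ", "),
              x$macro_auc, x$micro_auc))
  if (!is.null(x$binary)) {
    cat(sprintf("  MIBC: AUC %.3f, accuracy %.3f, specificity %.3f\n",
                x$binary$mibc$auc, x$binary$mibc$accuracy$estimate,
                x$binary$mibc$specificity$estimate))
    cat(sprintf("  grading: AUC %.3f, accuracy %.3f\n",
                x$binary$grade$auc, x$binary$grade$accuracy$estimate))
  }
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' @param report An `eval_report`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  out <- unclass(report)
  out$confusion <- as.data.frame.matrix(out$confusion)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
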