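# Multiclass evaluation surface: confusion matrix, one-vs-rest class
# metrics, exact accuracy confidence interval with a no-information-rate
# test, Cohen's kappa, and binary ROC/AUC for low-vs-high within a task.

#' Confusion matrix
#'
#' @param truth,predicted Equal-length label vectors over the model's class
#'   set. Labels outside `classes` raise an error.
#' @param classes Optional class order; defaults to the union of observed
#'   labels (sorted).
#' @return Integer matrix, rows = true class, columns = predicted class.
#' @export
confusion_matrix <- function(truth, predicted, classes = NULL) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  if (is.null(classes)) classes <- sort(unique(c(truth, predicted)))
  unseen <- setdiff(unique(c(truth, predicted)), classes)
  if (length(unseen) > 0)
    stop("label(s) outside the class set: ",
         paste(unseen, collapse = ", "))
  cm <- table(factor(truth, levels = classes),
              factor(predicted, levels = classes))
  m <- matrix(as.integer(cm), nrow = length(classes),
              dimnames = list(true = classes, predicted = classes))
  m
}

#' One-vs-rest metrics per class
#'
#' For each class: sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`,
#' balanced accuracy (their mean), precision `TP/(TP+FP)`, recall
#' (= sensitivity) and F1 `2PR/(P+R)`. A zero denominator yields `NA`
#' (reported missing, not 0).
#'
#' @param cm Confusion matrix from [confusion_matrix()].
#' @param classes Classes to report (default: all).
#' @return `data.frame` with one row per class.
#' @export
class_metrics <- function(cm, classes = rownames(cm)) {
  stopifnot(all(classes %in% rownames(cm)))
  total <- sum(cm)
  out <- lapply(classes, function(cl) {
    tp <- cm[cl, cl]
    fn <- sum(cm[cl, ]) - tp
    fp <- sum(cm[, cl]) - tp
    tn <- total - tp - fn - fp
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    data.frame(class = cl, sensitivity = sens, specificity = spec,
               balanced_accuracy = balanced_accuracy(sens, spec),
               precision = prec, recall = sens,
               f1 = f1_score(prec, sens), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Balanced accuracy from sensitivity and specificity
#'
#' @param sensitivity,specificity Rates in [0, 1].
#' @return `(sensitivity + specificity) / 2`.
#' @export
balanced_accuracy <- function(sensitivity, specificity) {
  (sensitivity + specificity) / 2
}

#' F1 score from precision and recall
#'
#' @param precision,recall Rates in [0, 1].
#' @return Harmonic mean `2PR/(P+R)`; `NA` when both are 0 or missing.
#' @export
f1_score <- function(precision, recall) {
  ifelse(is.na(precision) | is.na(recall) | (precision + recall) == 0,
         NA_real_, 2 * precision * recall / (precision + recall))
}

#' Overall accuracy with exact confidence interval and NIR test
#'
#' Accuracy is `trace/total`; the confidence interval is the exact
#' Clopper-Pearson interval; the p-value is a one-sided exact binomial test
#' of accuracy against the no-information rate (the largest class frequency
#' in the evaluated rows).
#'
#' @param cm Confusion matrix.
#' @param level Confidence level.
#' @return List: `accuracy`, `ci_lower`, `ci_upper`, `nir`, `p_value`,
#'   `n_correct`, `n_total`.
#' @export
overall_accuracy_ci <- function(cm, level = 0.95) {
  n <- sum(cm)
  if (n == 0) stop("empty confusion matrix")
  x <- sum(diag(cm))
  ci <- stats::binom.test(x, n, conf.level = level)$conf.int
  nir <- max(rowSums(cm)) / n
  p <- stats::binom.test(x, n, p = nir, alternative = "greater")$p.value
  list(accuracy = x / n, ci_lower = ci[1], ci_upper = ci[2],
       nir = nir, p_value = p, n_correct = x, n_total = n)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with the expected
#' agreement `p_e` from the marginal products.
#'
#' @param cm Confusion matrix.
#' @return Kappa; `NA` with a warning when `p_e = 1`.
#' @export
cohens_kappa <- function(cm) {
  n <- sum(cm)
  if (n == 0) stop("empty confusion matrix")
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (pe >= 1) {
    warning("expected agreement is 1; kappa undefined")
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' ROC curve and AUC for a binary contrast
#'
#' Sweeps thresholds over the unique scores (plus sentinels), computing the
#' true- and false-positive rates of classifying `score >= threshold` as
#' positive, and integrates the curve by the trapezoid rule -- equal to the
#' tie-corrected Mann-Whitney statistic.
#'
#' @param scores Numeric scores (e.g. posterior probability of the
#'   high-load class).
#' @param labels Binary labels; coerced to factor.
#' @param positive Label treated as positive. Defaults to the second factor
#'   level.
#' @return Object of class `cogload_roc`: list with `thresholds`, `tpr`,
#'   `fpr`, `auc`, `positive`.
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  stopifnot(length(scores) == length(labels))
  f <- factor(labels)
  if (nlevels(f) != 2)
    stop("labels must contain exactly 2 classes, got ", nlevels(f))
  if (is.null(positive)) positive <- levels(f)[2]
  stopifnot(positive %in% levels(f))
  y <- f == positive
  if (all(y) || !any(y)) stop("both classes must be present")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[y] >= t), 0)
  fpr <- vapply(thr, function(t) mean(scores[!y] >= t), 0)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc,
                 positive = positive),
            class = "cogload_roc")
}

#' @export
print.cogload_roc <- function(x, ...) {
  cat(sprintf("<cogload_roc> AUC = %.4f (positive class: %s)\n",
              x$auc, x$positive))
  invisible(x)
}

#' Full evaluation report for a set of predictions
#'
#' Assembles the confusion matrix, per-class metrics, overall accuracy with
#' exact CI and NIR test, Cohen's kappa, and -- when task and load labels
#' are supplied -- the low-vs-high ROC/AUC within each task, scored by the
#' posterior probability of that task's high-load class.
#'
#' @param truth True group labels of the evaluated rows.
#' @param predicted Predicted group labels.
#' @param posterior Optional posterior matrix (columns named by class).
#' @param task,load Optional per-row task and load labels for the per-task
#'   ROC analysis.
#' @param level Confidence level for the accuracy interval.
#' @return Object of class `cogload_evaluation`.
#' @export
evaluate_predictions <- function(truth, predicted, posterior = NULL,
                                 task = NULL, load = NULL, level = 0.95) {
  cm <- confusion_matrix(truth, predicted)
  rep <- list(confusion = cm,
              class_metrics = class_metrics(cm),
              accuracy = overall_accuracy_ci(cm, level),
              kappa = cohens_kappa(cm))
  if (!is.null(posterior) && !is.null(task) && !is.null(load)) {
    roc <- list()
    for (tk in unique(task)) {
      i <- task == tk
      if (length(unique(load[i])) != 2) next
      high_cls <- grep("high$", colnames(posterior), value = TRUE)
      high_cls <- high_cls[substr(high_cls, 1, 2) ==
                             if (tk == "mental_calculation") "mc" else "vs"]
      if (length(high_cls) != 1) next
      roc[[tk]] <- roc_auc(posterior[i, high_cls],
                           factor(load[i], levels = c("low", "high")),
                           positive = "high")
    }
    rep$roc <- roc
  }
  structure(rep, class = "cogload_evaluation")
}

#' @export
print.cogload_evaluation <- function(x, ...) {
  cat("<cogload_evaluation>\n")
  cat(sprintf("Accuracy %.4f (%d%% CI %.4f-%.4f), NIR %.4f, p = %.3g\n",
              x$accuracy$accuracy, 95,
              x$accuracy$ci_lower, x$accuracy$ci_upper,
              x$accuracy$nir, x$accuracy$p_value))
  cat(sprintf("Cohen's kappa %.3f\n", x$kappa))
  cat("Confusion matrix (rows = true):\n")
  print(x$confusion)
  cat("Per-class metrics (3 dp):\n")
  cm3 <- x$class_metrics
  cm3[-1] <- round(cm3[-1], 3)
  print(cm3, row.names = FALSE)
  for (tk in names(x$roc))
    cat(sprintf("AUC low-vs-high, %s: %.4f\n", tk, x$roc[[tk]]$auc))
  invisible(x)
}
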