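#' One-vs-rest ROC curve
#'
#' Receiver operating characteristic of a score vector against a
#' binary truth, swept over all score thresholds.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param positive Logical vector, `TRUE` for the positive class.
#' @return Data frame with columns `fpr`, `tpr`, from (0, 0) to (1, 1).
#' @export
roc_curve <- function(scores, positive) {
  stopifnot(length(scores) == length(positive))
  ord <- order(scores, decreasing = TRUE)
  pos <- as.logical(positive)[ord]
  P <- sum(pos); N <- sum(!pos)
  if (P == 0 || N == 0)
    stopf("ROC undefined: need both positive and negative examples")
  tp <- cumsum(pos); fp <- cumsum(!pos)
  # collapse threshold ties: keep the last point of each tied block
  keep <- c(diff(scores[ord]) != 0, TRUE)
  data.frame(fpr = c(0, fp[keep] / N), tpr = c(0, tp[keep] / P))
}

#' Area under a ROC curve
#'
#' Trapezoidal integration of [roc_curve()].
#'
#' @inheritParams roc_curve
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, positive) {
  rc <- roc_curve(scores, positive)
  sum(diff(rc$fpr) * (utils::head(rc$tpr, -1) + utils::tail(rc$tpr, -1)) / 2)
}

#' Classification metrics report
#'
#' Builds the full evaluation report from true labels and predicted
#' class probabilities: confusion matrix (rows = true class), per-class
#' one-vs-rest accuracy, precision, recall, F1 and AUC, their macro
#' (unweighted) means, overall accuracy (`trace / total`), and
#' per-class ROC point lists.  Zero-denominator precision/recall/F1
#' are reported as 0 with a warning; classes absent from the test set
#' get `NA` AUC and are excluded from the macro AUC with a warning.
#'
#' @param y_true Character vector of true labels.
#' @param probs `n x E` matrix of class probabilities with class
#'   column names (or columns in `classes` order).
#' @param classes Class vocabulary (default [gait_classes()]).
#' @return A `metrics_report` object.
#' @export
metrics_report <- function(y_true, probs, classes = gait_classes()) {
  E <- length(classes)
  if (is.null(colnames(probs))) colnames(probs) <- classes
  probs <- probs[, classes, drop = FALSE]
  n <- length(y_true)
  if (nrow(probs) != n) stopf("y_true and probs disagree on n")
  pred <- classes[max.col(probs, ties.method = "first")]
  confusion <- matrix(0L, E, E, dimnames = list(true = classes,
                                                predicted = classes))
  for (i in seq_len(n))
    confusion[y_true[i], pred[i]] <- confusion[y_true[i], pred[i]] + 1L
  per <- data.frame(class = classes, accuracy = NA_real_,
                    precision = NA_real_, recall = NA_real_,
                    f1 = NA_real_, auc = NA_real_)
  roc_curves <- stats::setNames(vector("list", E), classes)
  safe_div <- function(num, den, what, cl) {
    if (den == 0) {
      warnf("%s undefined for class '%s' (zero denominator); reporting 0",
            what, cl)
      0
    } else num / den
  }
  for (e in seq_len(E)) {
    cl <- classes[e]
    tp <- confusion[e, e]
    fp <- sum(confusion[-e, e])
    fn <- sum(confusion[e, -e])
    tn <- n - tp - fp - fn
    per$accuracy[e] <- (tp + tn) / n
    per$precision[e] <- safe_div(tp, tp + fp, "precision", cl)
    per$recall[e] <- safe_div(tp, tp + fn, "recall", cl)
    per$f1[e] <- if (per$precision[e] + per$recall[e] == 0) {
      warnf("F1 undefined for class '%s'; reporting 0", cl)
      0
    } else {
      2 * per$precision[e] * per$recall[e] /
        (per$precision[e] + per$recall[e])
    }
    truth <- y_true == cl
    if (sum(truth) == 0 || sum(!truth) == 0) {
      warnf("AUC undefined for class '%s' (one-sided test set); excluded from macro AUC",
            cl)
    } else {
      per$auc[e] <- auc(probs[, e], truth)
      roc_curves[[cl]] <- roc_curve(probs[, e], truth)
    }
  }
  macro <- list(accuracy = mean(per$accuracy),
                precision = mean(per$precision),
                recall = mean(per$recall),
                f1 = mean(per$f1),
                auc = mean(per$auc, na.rm = TRUE))
  structure(list(confusion = confusion, per_class = per, macro = macro,
                 overall_accuracy = sum(diag(confusion)) / n,
                 roc_curves = roc_curves, n = n),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n=%d overall accuracy %.2f%%\n", x$n,
              100 * x$overall_accuracy))
  print(x$confusion)
  print(x$per_class, digits = 3)
  cat(sprintf("macro: acc %.3f prec %.3f rec %.3f f1 %.3f auc %.3f\n",
              x$macro$accuracy, x$macro$precision, x$macro$recall,
              x$macro$f1, x$macro$auc))
  invisible(x)
}
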