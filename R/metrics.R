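# Evaluation panel for the binary taste classifier. All rate metrics are
# stored as fractions; rendering to percent is left to the caller. Undefined
# ratios (zero denominators) are reported as NA, never coerced to 0.

#' Confusion counts for one positive-class perspective
#'
#' @param labels true classes (`"sweet"`/`"bitter"`).
#' @param predictions predicted classes.
#' @param positiveClass the class treated as positive.
#' @return list with `tp`, `tn`, `fp`, `fn`, `positive_class`
#'   (class `"ConfusionCounts"`).
#' @examples
#' confusionCounts(c("sweet", "bitter"), c("sweet", "sweet"), "sweet")
#' @export
confusionCounts <- function(labels, predictions, positiveClass = "sweet") {
  if (length(labels) != length(predictions))
    stop("labels and predictions lengths differ")
  known <- c(.TASTE_CLASSES)
  if (!all(c(labels, predictions) %in% known))
    stop("unknown class token; expected ",
         paste(known, collapse = "/"))
  if (!positiveClass %in% known) stop("unknown positive class")
  pos <- labels == positiveClass
  ppos <- predictions == positiveClass
  out <- list(tp = sum(pos & ppos), tn = sum(!pos & !ppos),
              fp = sum(!pos & ppos), fn = sum(pos & !ppos),
              positive_class = positiveClass)
  class(out) <- "ConfusionCounts"
  out
}

.safeRatio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Threshold-metric panel from confusion counts
#'
#' Computes accuracy, sensitivity (recall, TP/(TP+FN)), specificity,
#' precision, F-measure, the non-error rate (NER, mean of sensitivity and
#' specificity) and Cohen's kappa.
#'
#' @param counts a `ConfusionCounts` object or list with `tp`, `tn`, `fp`, `fn`.
#' @return list of metrics (class `"MetricsReport"`), fractions in `[0, 1]`
#'   (kappa in `[-1, 1]`); ratios with zero denominators are `NA`.
#' @examples
#' metricsPanel(list(tp = 9, tn = 9, fp = 1, fn = 1))$cohens_kappa  # 0.8
#' @export
metricsPanel <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  n <- tp + tn + fp + fn
  if (n == 0) stop("empty confusion counts")
  sens <- .safeRatio(tp, tp + fn)
  spec <- .safeRatio(tn, tn + fp)
  prec <- .safeRatio(tp, tp + fp)
  f <- if (is.na(prec) || is.na(sens) || prec + sens == 0) NA_real_
       else 2 * prec * sens / (prec + sens)
  acc <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (pe == 1) NA_real_ else (acc - pe) / (1 - pe)
  out <- list(positive_class = counts$positive_class,
              accuracy = acc, sensitivity = sens, specificity = spec,
              precision = prec, f_measure = f,
              ner = mean(c(sens, spec)), cohens_kappa = kappa,
              counts = counts)
  class(out) <- "MetricsReport"
  out
}

#' ROC-AUC by the rank (Mann-Whitney) formula
#'
#' Normalized U statistic: ties contribute 1/2; equals the trapezoidal area
#' under the empirical ROC curve.
#'
#' @param labels true classes.
#' @param scores score of the positive class for each sample (finite).
#' @param positiveClass class treated as positive.
#' @return AUC in `[0, 1]`.
#' @examples
#' rocAUC(c("sweet", "sweet", "bitter", "bitter"), c(0.9, 0.4, 0.6, 0.1))  # 0.75
#' @export
rocAUC <- function(labels, scores, positiveClass = "sweet") {
  if (length(labels) != length(scores))
    stop("labels and scores lengths differ")
  if (!all(is.finite(scores))) stop("scores must be finite")
  pos <- labels == positiveClass
  nPos <- sum(pos); nNeg <- sum(!pos)
  if (nPos == 0L || nNeg == 0L)
    stop("need at least one positive and one negative label")
  r <- rank(scores)
  (sum(r[pos]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Full evaluation report: confusion, panel and ROC-AUC
#'
#' @param labels true classes.
#' @param predictions predicted classes.
#' @param scores positive-class scores (for AUC); `NULL` to skip AUC.
#' @param positiveClass class treated as positive.
#' @return A `MetricsReport` list with `roc_auc` added.
#' @export
evaluateClassifier <- function(labels, predictions, scores = NULL,
                               positiveClass = "sweet") {
  rep <- metricsPanel(confusionCounts(labels, predictions, positiveClass))
  rep$roc_auc <- if (is.null(scores)) NA_real_
                 else rocAUC(labels, scores, positiveClass)
  rep
}

#' Two-perspective metrics table
#'
#' One row per class treated as positive (the sweet-positive row's
#' sensitivity equals the bitter-positive row's specificity, and vice versa).
#'
#' @param labels,predictions true and predicted classes.
#' @param scoreSweet score of the sweet class per sample.
#' @return data.frame with columns `positive_class`, `positives`, `negatives`,
#'   `accuracy`, `roc_auc`, `sensitivity`, `specificity`, `precision`,
#'   `f_measure`, `ner`, `cohens_kappa`.
#' @export
metricsTable <- function(labels, predictions, scoreSweet = NULL) {
  rows <- lapply(.TASTE_CLASSES, function(cls) {
    sc <- if (is.null(scoreSweet)) NULL
          else if (cls == "sweet") scoreSweet else 1 - scoreSweet
    r <- evaluateClassifier(labels, predictions, sc, positiveClass = cls)
    data.frame(positive_class = cls,
               positives = r$counts$tp + r$counts$fn,
               negatives = r$counts$tn + r$counts$fp,
               accuracy = r$accuracy, roc_auc = r$roc_auc,
               sensitivity = r$sensitivity, specificity = r$specificity,
               precision = r$precision, f_measure = r$f_measure,
               ner = r$ner, cohens_kappa = r$cohens_kappa)
  })
  do.call(rbind, rows)
}

#' @export
print.MetricsReport <- function(x, ...) {
  cat(sprintf("MetricsReport (positive = %s)\n", x$positive_class))
  for (m in c("accuracy", "sensitivity", "specificity", "precision",
              "f_measure", "ner", "cohens_kappa", "roc_auc")) {
    if (!is.null(x[[m]]))
      cat(sprintf("  %-12s %s\n", m,
                  ifelse(is.na(x[[m]]), "NA", sprintf("%.4f", x[[m]]))))
  }
  invisible(x)
}

#' @export
print.ConfusionCounts <- function(x, ...) {
  cat(sprintf("ConfusionCounts (positive = %s): TP=%d TN=%d FP=%d FN=%d\n",
              x$positive_class, x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}
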