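#' Confusion matrix over the severity classes
#'
#' `counts[i, j]` is the number of patients with true class `i` predicted as
#' class `j`, with classes in the fixed order (low, mild, moderate, severe)
#' or any supplied order.
#'
#' @param trueLabels,predictedLabels Aligned, nonempty label vectors whose
#'   values all belong to `classes`.
#' @param classes Class order (default `severityLevels()`).
#' @return Integer `length(classes)` square matrix with dimnames
#'   `true`/`predicted`.
#' @examples
#' confusionCounts(c("low", "low", "mild"), c("low", "mild", "mild"))
#' @export
confusionCounts <- function(trueLabels, predictedLabels,
                            classes = severityLevels()) {
  trueLabels <- as.character(trueLabels)
  predictedLabels <- as.character(predictedLabels)
  stopIfNot(length(trueLabels) == length(predictedLabels) &&
              length(trueLabels) > 0, "aligned, nonempty labels required")
  unknown <- setdiff(unique(c(trueLabels, predictedLabels)), classes)
  if (length(unknown))
    stop("unknown label(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  tf <- factor(trueLabels, levels = classes)
  pf <- factor(predictedLabels, levels = classes)
  m <- as.matrix(table(true = tf, predicted = pf))
  storage.mode(m) <- "integer"
  m
}

#' Per-class sensitivity (recall)
#'
#' `counts[c, c] / rowSum(c)` for each class. A class with no true members
#' has undefined sensitivity and is reported as `NA`, never silently 0.
#'
#' @param counts A square confusion matrix (rows = true class).
#' @return Named fractions in \[0, 1\] (with `NA` for empty classes).
#' @examples
#' m <- rbind(c(656, 30, 4, 0), c(0, 10, 0, 0), c(0, 0, 5, 0), c(0, 0, 0, 2))
#' classSensitivity(m)[1]   # 656/690
#' @export
classSensitivity <- function(counts) {
  counts <- as.matrix(counts)
  stopIfNot(nrow(counts) == ncol(counts), "confusion matrix must be square")
  rs <- rowSums(counts)
  out <- ifelse(rs > 0, diag(counts) / rs, NA_real_)
  names(out) <- rownames(counts)
  out
}

#' Per-class precision (positive predictive value)
#'
#' `counts[c, c] / colSum(c)` for each class; `NA` when the class was never
#' predicted.
#'
#' @inheritParams classSensitivity
#' @return Named fractions in \[0, 1\] (with `NA` for never-predicted
#'   classes).
#' @export
classPrecision <- function(counts) {
  counts <- as.matrix(counts)
  stopIfNot(nrow(counts) == ncol(counts), "confusion matrix must be square")
  cs <- colSums(counts)
  out <- ifelse(cs > 0, diag(counts) / cs, NA_real_)
  names(out) <- colnames(counts)
  out
}

#' Overall accuracy
#'
#' Trace of the confusion matrix over its total — the lower-right summary
#' cell of the published confusion-matrix layout.
#'
#' @inheritParams classSensitivity
#' @return Fraction in \[0, 1\].
#' @export
overallAccuracy <- function(counts) {
  counts <- as.matrix(counts)
  stopIfNot(nrow(counts) == ncol(counts), "confusion matrix must be square")
  tot <- sum(counts)
  stopIfNot(tot > 0, "confusion matrix must be nonempty")
  sum(diag(counts)) / tot
}

#' Format a fraction as a percentage to one decimal
#'
#' The reporting convention used for sensitivity/precision/accuracy tables;
#' `NA` (undefined) values format as `"n/a"`.
#'
#' @param x Fractions in \[0, 1\].
#' @return For `asPercent`, numeric percentages rounded to one decimal
#'   (`NA` kept); for `formatPercent`, character with `"n/a"`.
#' @examples
#' asPercent(656 / 690)   # 95.1
#' @export
asPercent <- function(x) round(100 * x, 1)

#' @rdname asPercent
#' @export
formatPercent <- function(x) {
  ifelse(is.na(x), "n/a", sprintf("%.1f%%", 100 * x))
}

#' One-vs-rest ROC curve and AUC
#'
#' Treats `positiveClass` as positive and every other label as negative,
#' sweeps thresholds over the unique scores (ties grouped into a single
#' step), and accumulates false/true positive rates from (0, 0) to (1, 1).
#' AUC is computed by the trapezoid rule.
#'
#' @param scores Numeric score per sample (higher = more confidently
#'   positive).
#' @param trueLabels Aligned label vector.
#' @param positiveClass Label treated as positive; must be present.
#' @return `list(thresholds, fpr, tpr, auc)`; `fpr` and `tpr` are
#'   non-decreasing and `auc` lies in \[0, 1\].
#' @examples
#' rocOneVsRest(c(0.9, 0.8, 0.3, 0.1), c("a", "a", "b", "b"), "a")$auc  # 1
#' @export
rocOneVsRest <- function(scores, trueLabels, positiveClass) {
  stopIfNot(length(scores) == length(trueLabels) && length(scores) > 0,
            "aligned, nonempty scores and labels required")
  pos <- as.character(trueLabels) == as.character(positiveClass)
  if (!any(pos)) stop("positive class absent", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  # group tied scores into one threshold step
  last <- cumsum(rle(s)$lengths)
  tp <- cumsum(p)[last]; fp <- cumsum(!p)[last]
  nP <- sum(pos); nN <- sum(!pos)
  tpr <- c(0, tp / nP)
  fpr <- c(0, if (nN > 0) fp / nN else rep(0, length(fp)))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(thresholds = c(Inf, s[last]), fpr = fpr, tpr = tpr, auc = auc)
}

#' Full evaluation report for one classifier
#'
#' Confusion counts, per-class sensitivity and precision, overall accuracy,
#' and one-vs-rest ROC/AUC per class (where scores are supplied) plus their
#' macro average.
#'
#' @param trueLabels,predictedLabels Aligned label vectors.
#' @param scores Optional patients x classes score matrix (column names =
#'   classes) for ROC/AUC.
#' @param classes Class order (default `severityLevels()`).
#' @return A list with elements `confusion`, `sensitivity`, `precision`,
#'   `accuracy`, `roc` (per-class curves or `NULL`), `auc` (named vector),
#'   `macroAuc`.
#' @export
evaluationReport <- function(trueLabels, predictedLabels, scores = NULL,
                             classes = severityLevels()) {
  cm <- confusionCounts(trueLabels, predictedLabels, classes)
  roc <- NULL; auc <- setNames(rep(NA_real_, length(classes)), classes)
  if (!is.null(scores)) {
    scores <- as.matrix(scores)
    roc <- lapply(classes, function(cl) {
      if (!any(as.character(trueLabels) == cl) || !(cl %in% colnames(scores)))
        return(NULL)
      rocOneVsRest(scores[, cl], trueLabels, cl)
    })
    names(roc) <- classes
    auc <- vapply(roc, function(r) if (is.null(r)) NA_real_ else r$auc, 0)
  }
  list(confusion = cm,
       sensitivity = classSensitivity(cm),
       precision = classPrecision(cm),
       accuracy = overallAccuracy(cm),
       roc = roc, auc = auc,
       macroAuc = mean(auc, na.rm = TRUE))
}
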