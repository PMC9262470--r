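#' Two-class confusion matrix
#'
#' Counts (true, predicted) pairs into a 2 x 2 integer matrix with rows =
#' true class and columns = predicted class, in the given class order
#' (default alphabetical, which puts "cancer" before "noncancer").
#'
#' @param trueLabels,predictedLabels equal-length label vectors over the
#'   two known classes.
#' @param classes length-2 character giving the row/column order.
#' @return 2 x 2 integer matrix with dimnames `true` x `predicted`.
#' @export
confusionCounts <- function(trueLabels, predictedLabels,
                            classes = sort(unique(as.character(trueLabels)))) {
  trueLabels <- as.character(trueLabels)
  predictedLabels <- as.character(predictedLabels)
  if (length(trueLabels) == 0) stop("empty label input")
  if (length(trueLabels) != length(predictedLabels))
    stop("label vectors must have equal length")
  if (length(classes) != 2) stop("exactly two classes expected")
  if (!all(trueLabels %in% classes) || !all(predictedLabels %in% classes))
    stop("unknown label encountered")
  cm <- matrix(0L, 2, 2, dimnames = list(true = classes, predicted = classes))
  for (i in seq_along(trueLabels))
    cm[trueLabels[i], predictedLabels[i]] <- cm[trueLabels[i], predictedLabels[i]] + 1L
  cm
}

#' Per-class and macro-averaged metrics from a confusion matrix
#'
#' For each class: precision = 100 TP / (TP + FP), recall =
#' 100 TP / (TP + FN), F-score = harmonic mean of the two; accuracy =
#' 100 trace / total, reported on every row (it is an overall, not a
#' per-class, quantity). The "Average" row is the unweighted (macro) mean
#' of the per-class columns computed from UNROUNDED values; rounding
#' (half away from zero, 2 decimals) happens only in
#' [formatMetricsTable()]. A zero denominator yields 0 with the
#' `"zero_denominator"` attribute set.
#'
#' @param cm 2 x 2 confusion matrix from [confusionCounts()].
#' @return data.frame with rows (class1, class2, Average) and columns
#'   `class`, `accuracy`, `precision`, `recall`, `fscore` in percent,
#'   unrounded.
#' @export
metricsFromConfusion <- function(cm) {
  if (sum(cm) == 0) stop("empty confusion matrix")
  classes <- rownames(cm)
  accuracy <- 100 * sum(diag(cm)) / sum(cm)
  flag <- FALSE
  safe <- function(num, den) {
    if (den == 0) { flag <<- TRUE; 0 } else 100 * num / den
  }
  prec <- rec <- f <- numeric(2)
  for (k in 1:2) {
    tp <- cm[k, k]
    prec[k] <- safe(tp, sum(cm[, k]))
    rec[k] <- safe(tp, sum(cm[k, ]))
    f[k] <- if (prec[k] + rec[k] == 0) { flag <- TRUE; 0 }
            else 2 * prec[k] * rec[k] / (prec[k] + rec[k])
  }
  out <- data.frame(
    class = c(classes, "Average"),
    accuracy = rep(accuracy, 3),
    precision = c(prec, mean(prec)),
    recall = c(rec, mean(rec)),
    fscore = c(f, mean(f)))
  attr(out, "zero_denominator") <- flag
  out
}

#' F-score from precision and recall percentages
#'
#' 2 P R / (P + R); returns 0 with a `"zero_denominator"` attribute when
#' both are zero.
#'
#' @param precision,recall percentages in \[0, 100\].
#' @return F-score percentage.
#' @export
fFromPR <- function(precision, recall) {
  if (precision + recall == 0)
    return(structure(0, zero_denominator = TRUE))
  2 * precision * recall / (precision + recall)
}

#' Display-round a metric table
#'
#' Applies half-away-from-zero rounding to 2 decimals, the only place
#' rounding happens.
#'
#' @param metrics a [metricsFromConfusion()] table.
#' @param digits decimal places.
#' @return the table with rounded numeric columns.
#' @export
formatMetricsTable <- function(metrics, digits = 2) {
  for (cl in c("accuracy", "precision", "recall", "fscore"))
    metrics[[cl]] <- roundHalfUp(metrics[[cl]], digits)
  metrics
}

#' ROC curve points
#'
#' Sweeps a decision threshold over the unique scores in descending order
#' (ties grouped); returns (FPR, TPR) points starting at (0, 0) and ending
#' at (1, 1). Scores are probabilities of the positive class.
#'
#' @param scores numeric scores for the positive class.
#' @param trueLabels labels; `positive` marks the positive class.
#' @param positive the positive class label (default `"cancer"`).
#' @return data.frame with columns `threshold`, `fpr`, `tpr`.
#' @export
rocPoints <- function(scores, trueLabels, positive = "cancer") {
  trueLabels <- as.character(trueLabels)
  pos <- trueLabels == positive
  if (all(pos) || !any(pos)) stop("both classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))
  data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Precision-recall curve points
#'
#' Same descending threshold sweep as [rocPoints()]; returns (recall,
#' precision) pairs.
#'
#' @inheritParams rocPoints
#' @return data.frame with columns `threshold`, `recall`, `precision`.
#' @export
prPoints <- function(scores, trueLabels, positive = "cancer") {
  trueLabels <- as.character(trueLabels)
  pos <- trueLabels == positive
  if (all(pos) || !any(pos)) stop("both classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  rec <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  prec <- vapply(thr, function(t) {
    sel <- scores >= t
    if (!any(sel)) 1 else mean(pos[sel])
  }, numeric(1))
  data.frame(threshold = thr, recall = rec, precision = prec)
}

#' Area under the ROC curve
#'
#' Trapezoidal integration of [rocPoints()] output.
#'
#' @param roc a [rocPoints()] data.frame.
#' @return AUROC in \[0, 1\].
#' @export
aucFromROC <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

#' Write a split evaluation report
#'
#' Emits the metric table (Table-style CSV, one row per class plus the
#' macro average), a JSON report with the confusion counts, and the ROC
#' and PR curve points as CSV.
#'
#' @param report a split report from [runPipeline()].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
writeSplitReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tag <- gsub(":", "_", report$ratioLabel)
  utils::write.csv(formatMetricsTable(report$metrics),
                   file.path(dir, paste0("metrics_", tag, ".csv")),
                   row.names = FALSE)
  jsonlite::write_json(
    list(ratio = report$ratioLabel,
         confusion = as.integer(t(report$confusion)),
         class_order = rownames(report$confusion),
         auroc = report$auroc,
         accuracy = report$metrics$accuracy[1],
         tuned = report$tuned),
    file.path(dir, paste0("report_", tag, ".json")),
    digits = NA, auto_unbox = TRUE)
  utils::write.csv(report$roc, file.path(dir, paste0("roc_", tag, ".csv")),
                   row.names = FALSE)
  utils::write.csv(report$pr, file.path(dir, paste0("pr_", tag, ".csv")),
                   row.names = FALSE)
  invisible(dir)
}
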