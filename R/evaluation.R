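# One-vs-rest confusion counts and the derived performance metrics
# (MCC, F1, precision, sensitivity, specificity), plus a two-classifier
# comparison on a shared labeled set.

#' One-vs-rest confusion counts
#'
#' Counts TP/TN/FP/FN for `positive_class` against everything else.
#' `labels` and `predictions` must be named by sequence id and cover
#' identical id sets; matching is by id, not position.
#'
#' @param labels Named character vector of true classes.
#' @param predictions Named character vector of predicted classes.
#' @param positive_class The class treated as positive.
#' @return An object of class `confusion_counts`: list with integer
#'   `tp`, `tn`, `fp`, `fn`.
#' @export
confusion <- function(labels, predictions, positive_class) {
  if (is.null(names(labels)) || is.null(names(predictions))) {
    stop("labels and predictions must be named by sequence id", call. = FALSE)
  }
  only_l <- setdiff(names(labels), names(predictions))
  only_p <- setdiff(names(predictions), names(labels))
  if (length(only_l) > 0L || length(only_p) > 0L) {
    stop("label/prediction id mismatch; only in labels: ",
         paste(head(only_l, 5L), collapse = ", "),
         "; only in predictions: ",
         paste(head(only_p, 5L), collapse = ", "), call. = FALSE)
  }
  pred <- predictions[names(labels)]
  pos_true <- labels == positive_class
  pos_pred <- pred == positive_class
  structure(list(
    tp = as.numeric(sum(pos_true & pos_pred)),
    tn = as.numeric(sum(!pos_true & !pos_pred)),
    fp = as.numeric(sum(!pos_true & pos_pred)),
    fn = as.numeric(sum(pos_true & !pos_pred))
  ), class = "confusion_counts")
}

#' Construct confusion counts directly
#'
#' @param tp,tn,fp,fn Non-negative integer counts.
#' @return A `confusion_counts` object.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  structure(list(tp = as.numeric(tp), tn = as.numeric(tn),
                 fp = as.numeric(fp), fn = as.numeric(fn)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP %g  TN %g  FP %g  FN %g\n", x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

#' Binary classification metrics from confusion counts
#'
#' Computes the Matthews correlation coefficient
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))` (defined as 0
#' when any marginal factor is 0), F1 `2tp/(2tp+fp+fn)`, precision
#' `tp/(tp+fp)` (0 when no positive prediction), sensitivity `tp/(tp+fn)`,
#' and specificity `tn/(tn+fp)`. All values at full precision; rounding is
#' left to the presentation layer.
#'
#' @param counts A `confusion_counts` object.
#' @return An object of class `metric_report`: list with `mcc`, `f1`,
#'   `precision`, `sensitivity`, `specificity` and the input `counts`.
#' @examples
#' metrics(confusion_counts(tp = 10, tn = 14487, fp = 17, fn = 0))
#' @export
metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  if (tp + tn + fp + fn < 1) {
    stop("confusion counts are all zero: no sequences evaluated", call. = FALSE)
  }
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / sqrt(denom)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  sensitivity <- if (tp + fn == 0) 0 else tp / (tp + fn)
  specificity <- if (tn + fp == 0) 0 else tn / (tn + fp)
  structure(list(mcc = mcc, f1 = f1, precision = precision,
                 sensitivity = sensitivity, specificity = specificity,
                 counts = counts),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, digits = 2, ...) {
  c_ <- x$counts
  cat(sprintf("TP\tTN\tFP\tFN\tMCC\tF1\tPre\tSen\tSpe\n"))
  cat(sprintf("%g\t%g\t%g\t%g\t%.*f\t%.*f\t%.*f\t%.*f\t%.*f\n",
              c_$tp, c_$tn, c_$fp, c_$fn,
              digits, x$mcc, digits, x$f1, digits, x$precision,
              digits, x$sensitivity, digits, x$specificity))
  invisible(x)
}

#' Compare two metric reports
#'
#' Per-metric signed differences `a - b` for two classifiers evaluated on
#' the same labeled set.
#'
#' @param report_a,report_b `metric_report` objects.
#' @return Named numeric vector of deltas (mcc, f1, precision,
#'   sensitivity, specificity).
#' @export
compare_reports <- function(report_a, report_b) {
  stopifnot(inherits(report_a, "metric_report"),
            inherits(report_b, "metric_report"))
  keys <- c("mcc", "f1", "precision", "sensitivity", "specificity")
  vapply(keys, function(k) report_a[[k]] - report_b[[k]], numeric(1))
}

#' Multiclass (pooled) Matthews correlation coefficient
#'
#' The K-class generalisation of the MCC computed from a square confusion
#' matrix (rows = truth, columns = prediction); equals the binary MCC for
#' K = 2 and is 0 when either marginal term degenerates.
#'
#' @param conf_mat Square numeric confusion matrix.
#' @return MCC in \[-1, 1\].
#' @export
mcc_multiclass <- function(conf_mat) {
  stopifnot(is.matrix(conf_mat), nrow(conf_mat) == ncol(conf_mat))
  s <- sum(conf_mat)
  c_ <- sum(diag(conf_mat))
  t_k <- rowSums(conf_mat)   # true per class
  p_k <- colSums(conf_mat)   # predicted per class
  num <- c_ * s - sum(p_k * t_k)
  den <- sqrt(s^2 - sum(p_k^2)) * sqrt(s^2 - sum(t_k^2))
  if (den == 0) 0 else num / den
}

#' Table-style evaluation report per organellar class
#'
#' One-vs-rest metrics for each organellar class present, as a data.frame
#' mirroring the standard column order TP TN FP FN MCC F1 Pre Sen Spe.
#'
#' @param labels Named character vector of true classes.
#' @param predictions Named character vector of predicted classes.
#' @param classes Positive classes to report (default: the organellar
#'   classes present in the labels).
#' @return Data.frame with one row per class.
#' @export
evaluation_table <- function(labels, predictions,
                             classes = intersect(c("mitochondrion", "plastid"),
                                                 unique(labels))) {
  rows <- lapply(classes, function(cl) {
    m <- metrics(confusion(labels, predictions, cl))
    data.frame(class = cl, TP = m$counts$tp, TN = m$counts$tn,
               FP = m$counts$fp, FN = m$counts$fn,
               MCC = m$mcc, F1 = m$f1, Pre = m$precision,
               Sen = m$sensitivity, Spe = m$specificity)
  })
  do.call(rbind, rows)
}
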