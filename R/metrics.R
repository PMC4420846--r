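# Classification metrics: confusion counts, Matthews correlation
# coefficient, AUROC.

#' Confusion counts
#'
#' @param tp,tn,fp,fn Nonnegative integer counts.
#' @return Object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  v <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(v < 0) || any(v != round(v))) stop("counts must be nonnegative integers")
  structure(as.list(v), class = "confusion_counts")
}

#' Tally confusion counts from labels and predictions
#'
#' @param truth,predicted Vectors in \{-1, +1\}.
#' @return A [confusion_counts()] object.
#' @export
count_confusion <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  confusion_counts(tp = sum(truth == 1 & predicted == 1),
                   tn = sum(truth == -1 & predicted == -1),
                   fp = sum(truth == -1 & predicted == 1),
                   fn = sum(truth == 1 & predicted == -1))
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP=%d TN=%d FP=%d FN=%d (MCC=%.4f)\n",
              x$tp, x$tn, x$fp, x$fn, compute_mcc(x)))
  invisible(x)
}

#' Matthews correlation coefficient
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, the
#' balanced binary-classification measure; returns 0 when any factor of
#' the denominator is zero (the usual convention for degenerate
#' confusion tables).
#'
#' @param counts A [confusion_counts()] object, or TP when the four counts
#'   are given separately.
#' @param tn,fp,fn Remaining counts when `counts` is TP.
#' @return MCC in `[-1, 1]`.
#' @export
compute_mcc <- function(counts, tn = NULL, fp = NULL, fn = NULL) {
  if (inherits(counts, "confusion_counts")) {
    tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  } else tp <- counts
  tp <- as.numeric(tp); tn <- as.numeric(tn)
  fp <- as.numeric(fp); fn <- as.numeric(fn)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the fraction of (positive, negative) score
#' pairs in which the positive scores higher, ties counted one half.
#'
#' @param scores_pos,scores_neg Numeric score vectors for the positive and
#'   negative class (both nonempty).
#' @return AUROC in `[0, 1]`.
#' @export
compute_auroc <- function(scores_pos, scores_neg) {
  if (length(scores_pos) == 0 || length(scores_neg) == 0)
    stop("both classes need at least one score")
  r <- rank(c(scores_pos, scores_neg), ties.method = "average")
  np <- length(scores_pos); nn <- length(scores_neg)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}
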