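#' Confusion matrix from truth and prediction
#'
#' @param truth,pred Vectors of 0/1 labels of equal length, or counts via
#'   `confusion_matrix(tp =, fp =, tn =, fn =)`.
#' @param tp,fp,tn,fn Direct counts (used when `truth` is missing).
#' @return An object of class `confusion_matrix`: named integer vector
#'   `c(tp, fp, tn, fn)`.
#' @export
confusion_matrix <- function(truth, pred, tp = 0, fp = 0, tn = 0, fn = 0) {
  if (!missing(truth)) {
    stopifnot(length(truth) == length(pred))
    truth <- as.integer(truth); pred <- as.integer(pred)
    tp <- sum(truth == 1L & pred == 1L)
    fp <- sum(truth == 0L & pred == 1L)
    tn <- sum(truth == 0L & pred == 0L)
    fn <- sum(truth == 1L & pred == 0L)
  }
  cm <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(cm < 0) || sum(cm) < 1) {
    stop("confusion matrix needs non-negative counts summing to >= 1",
         call. = FALSE)
  }
  structure(as.integer(cm), names = names(cm), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> TP=%d FP=%d TN=%d FN=%d\n",
              x["tp"], x["fp"], x["tn"], x["fn"]))
  invisible(x)
}

#' Sensitivity and specificity
#'
#' `sensitivity = TP/(TP+FN)`, `specificity = TN/(TN+FP)`. A zero
#' denominator yields `NA` (undefined metric), never silently 0.
#'
#' @param cm A [confusion_matrix()].
#' @return A fraction in `[0, 1]`, or `NA` when undefined.
#' @export
sensitivity <- function(cm) {
  d <- cm["tp"] + cm["fn"]
  if (d == 0) return(NA_real_)
  unname(cm["tp"] / d)
}

#' @rdname sensitivity
#' @export
specificity <- function(cm) {
  d <- cm["tn"] + cm["fp"]
  if (d == 0) return(NA_real_)
  unname(cm["tn"] / d)
}

#' Matthews correlation coefficient
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, with the
#' standard convention that a zero factor in the denominator gives 0.
#'
#' @param cm A [confusion_matrix()].
#' @return A value in `[-1, 1]`.
#' @export
mcc <- function(cm) {
  tp <- as.numeric(cm["tp"]); fp <- as.numeric(cm["fp"])
  tn <- as.numeric(cm["tn"]); fn <- as.numeric(cm["fn"])
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  unname((tp * tn - fp * fn) / sqrt(den))
}

#' F1 score
#'
#' `F1 = 2TP / (2TP + FP + FN)`; `NA` when the denominator is zero (no
#' positive instance anywhere).
#'
#' @param cm A [confusion_matrix()].
#' @return A value in `[0, 1]` or `NA`.
#' @export
f1_score <- function(cm) {
  d <- 2 * as.numeric(cm["tp"]) + cm["fp"] + cm["fn"]
  if (d == 0) return(NA_real_)
  unname(2 * as.numeric(cm["tp"]) / d)
}

#' Geometric mean of sensitivity and specificity
#'
#' `Gmean = sqrt(SE * SP)`; `NA` when either factor is undefined.
#'
#' @param cm A [confusion_matrix()].
#' @return A value in `[0, 1]` or `NA`.
#' @export
gmean <- function(cm) {
  se <- sensitivity(cm); sp <- specificity(cm)
  if (is.na(se) || is.na(sp)) return(NA_real_)
  sqrt(se * sp)
}

#' Area under the ROC curve
#'
#' Computed by the rank (Mann-Whitney) formula with midranks, so ties count
#' one half: `AUC = (R1 - n1(n1+1)/2) / (n1 n0)` where `R1` is the rank sum
#' of the positive-class scores.
#'
#' @param scores Numeric classifier scores (larger = more positive).
#' @param labels 0/1 labels, same length.
#' @return AUC in `[0, 1]`, or `NA` when only one class is present.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Full metric set for one evaluation
#'
#' @param cm A [confusion_matrix()].
#' @param scores,labels Optional score/label vectors for AUC.
#' @return Named numeric vector with `se`, `sp`, `mcc`, `f1`, `gmean` and
#'   `auc` (`NA` when not computable).
#' @export
metric_set <- function(cm, scores = NULL, labels = NULL) {
  auc <- if (is.null(scores)) NA_real_ else roc_auc(scores, labels)
  c(se = sensitivity(cm), sp = specificity(cm), mcc = mcc(cm),
    f1 = f1_score(cm), gmean = gmean(cm), auc = auc)
}
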