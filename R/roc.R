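#' ROC curve and AUC from cross-validated predictions
#'
#' Sweeps a threshold over the unique predicted values (sample classified
#' positive when its score is >= the threshold), yielding the ROC points and
#' the trapezoidal AUC. The rank-based Mann-Whitney AUC (ties credited 1/2)
#' is computed alongside; the two agree to numerical precision. Sensitivity
#' and specificity are additionally reported at the 0.5 class-assignment
#' cutoff of the 0/1 prediction scale.
#'
#' @param ypredcv numeric predicted scores (e.g. `cv_result$ypredcv`).
#' @param labels class labels.
#' @param positive_class label treated as positive (coded 1).
#' @param cutoff class-assignment cutoff.
#' @return list of class `roc_result`: `thresholds`, `tpr`, `fpr`, `auc`
#'   (trapezoidal), `auc_mw`, `sensitivity`, `specificity`.
#' @export
roc_from_cv <- function(ypredcv, labels, positive_class, cutoff = 0.5) {
  labels <- as.character(labels)
  pos <- labels == positive_class
  if (!any(pos) || all(pos)) stop("both classes must be present")
  th <- c(Inf, sort(unique(ypredcv), decreasing = TRUE))
  tpr <- vapply(th, function(t) mean(ypredcv[pos] >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(ypredcv[!pos] >= t), numeric(1))
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  r <- rank(ypredcv)  # midranks: ties get half credit
  n1 <- sum(pos); n0 <- sum(!pos)
  auc_mw <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  structure(list(thresholds = th, tpr = tpr, fpr = fpr, auc = auc,
                 auc_mw = auc_mw,
                 sensitivity = mean(ypredcv[pos] >= cutoff),
                 specificity = mean(ypredcv[!pos] < cutoff),
                 positive_class = positive_class, cutoff = cutoff),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (positive class %s), sens %.2f / spec %.2f at cutoff %.2f\n",
              x$auc, x$positive_class, x$sensitivity, x$specificity, x$cutoff))
  invisible(x)
}

#' Export ROC points as a data frame
#'
#' @param x a `roc_result`.
#' @return data frame with `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(x) {
  data.frame(threshold = x$thresholds, fpr = x$fpr, tpr = x$tpr)
}
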