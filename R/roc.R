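#' ROC curve from scores and labels
#'
#' Builds the receiver operating characteristic of a score against binary
#' ground truth by sweeping the decision threshold over the distinct score
#' values (descending; larger score = called positive).
#'
#' @param scores numeric vector.
#' @param labels logical (or 0/1) vector, `TRUE` for true positives.
#' @return Object of class `wcps_roc`: list with `thresholds`, `fpr`, `tpr`
#'   (each non-decreasing from 0 to 1) and `auc` (trapezoidal area).
#' @examples
#' r <- roc_curve(c(3, 2, 1, 0.5), c(TRUE, TRUE, FALSE, FALSE))
#' auc(r)  # 1
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0 || nn == 0)
    stop("need at least one positive and one negative label", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  keep <- c(s[-1] != s[-length(s)], TRUE)  # collapse tied thresholds
  tpr <- c(0, cumsum(l)[keep] / np)
  fpr <- c(0, cumsum(!l)[keep] / nn)
  a <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(thresholds = c(Inf, s[keep]), fpr = fpr, tpr = tpr, auc = a),
            class = "wcps_roc")
}

#' Area under a ROC curve
#' @param roc a [roc_curve()] object.
#' @return The trapezoidal AUC in `[0, 1]`.
#' @export
auc <- function(roc) {
  stopifnot(inherits(roc, "wcps_roc"))
  roc$auc
}

#' @export
print.wcps_roc <- function(x, ...) {
  cat(sprintf("<wcps_roc> %d thresholds, AUC = %.4f\n",
              length(x$thresholds), x$auc))
  invisible(x)
}
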