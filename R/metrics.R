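#' Confusion matrix with DM as the positive class
#'
#' @param truth,pred character vectors of equal length with values in
#'   `{"ND", "DM"}`; `"DM"` (demineralized) is the positive class
#'   throughout the package, so recall measures sensitivity to
#'   demineralization.
#' @return An object of class `confusion_matrix`: list with counts
#'   `tp`, `fn`, `tn`, `fp`.
#' @export
confusion_matrix <- function(truth, pred) {
  if (length(truth) == 0L) stop("empty input", call. = FALSE)
  if (length(truth) != length(pred))
    stop("`truth` and `pred` lengths differ", call. = FALSE)
  if (!all(c(truth, pred) %in% c("ND", "DM")))
    stop('labels must be "ND" or "DM"', call. = FALSE)
  structure(list(
    tp = sum(truth == "DM" & pred == "DM"),
    fn = sum(truth == "DM" & pred == "ND"),
    tn = sum(truth == "ND" & pred == "ND"),
    fp = sum(truth == "ND" & pred == "DM")),
    class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(truth = c("DM", "ND"), pred = c("DM", "ND")))
  print(m)
  invisible(x)
}

#' Classification scores from a confusion matrix
#'
#' Accuracy, F1, recall (sensitivity), specificity, precision and
#' negative predictive value. A score whose denominator is zero is
#' returned as `NA` and named in the `undefined` attribute rather than
#' silently coerced to 0.
#'
#' @param cm a [confusion_matrix].
#' @return An object of class `score_report`: named list of the six
#'   scores, each in \[0, 1\] or `NA` when undefined.
#' @examples
#' cm <- structure(list(tp = 11, fn = 1, tn = 10, fp = 2),
#'                 class = "confusion_matrix")
#' classification_scores(cm)
#' @export
classification_scores <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$tp + cm$fn + cm$tn + cm$fp
  if (total == 0L) stop("empty confusion matrix", call. = FALSE)
  sdiv <- function(num, den) if (den > 0) num / den else NA_real_
  recall <- sdiv(cm$tp, cm$tp + cm$fn)
  precision <- sdiv(cm$tp, cm$tp + cm$fp)
  f1 <- if (!is.na(recall) && !is.na(precision) && recall + precision > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  out <- list(accuracy = (cm$tp + cm$tn) / total,
              f1 = f1,
              recall = recall,
              specificity = sdiv(cm$tn, cm$tn + cm$fp),
              precision = precision,
              npv = sdiv(cm$tn, cm$tn + cm$fn))
  undef <- names(out)[vapply(out, is.na, logical(1))]
  structure(out, undefined = undef, class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  for (nm in names(x))
    cat(sprintf("  %-12s %s\n", nm,
                if (is.na(x[[nm]])) "undefined" else sprintf("%.3f", x[[nm]])))
  invisible(x)
}

#' ROC curve and trapezoidal AUC
#'
#' Sweeps the decision threshold over the unique predicted scores
#' (ties grouped into single steps), accumulating true- and
#' false-positive rates from (0, 0) to (1, 1), and integrates the AUC
#' by the trapezoidal rule. With ties handled this way the trapezoid
#' AUC coincides exactly with the Mann-Whitney pair-counting statistic
#' ([auc_rank]).
#'
#' @param scores numeric scores, larger meaning more DM-like.
#' @param labels `"ND"`/`"DM"` truth labels; both classes required.
#' @return An object of class `roc_curve`: list with `thresholds`,
#'   `fpr`, `tpr` (aligned, threshold `Inf` first) and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("`scores` and `labels` lengths differ", call. = FALSE)
  y <- labels_to_binary(labels)
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- y[ord]
  thr <- unique(s)
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- cumsum(rle(s)$lengths)  # last index of each tie group
  tpr <- c(0, tp[last] / n_pos)
  fpr <- c(0, fp[last] / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = c(Inf, thr), fpr = fpr, tpr = tpr, auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d threshold steps, AUC = %.4f\n",
              length(x$thresholds), x$auc))
  invisible(x)
}

#' Mann-Whitney (rank) AUC
#'
#' The probability that a randomly chosen DM sample scores above a
#' randomly chosen ND sample, with ties counted one half. Serves as the
#' pair-counting route to the AUC, identical to the trapezoidal
#' integral of [roc_curve].
#'
#' @inheritParams roc_curve
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(scores, labels) {
  y <- labels_to_binary(labels)
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present", call. = FALSE)
  r <- rank(scores)  # midranks handle ties as 1/2
  (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
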