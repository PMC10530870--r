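#' Classification accuracy as a percentage
#'
#' `100 * (#correct) / (#total)`, kept at full precision internally and
#' conventionally printed to two decimals.
#'
#' @param y_true,y_pred equal-length label vectors.
#' @return Accuracy percentage in `[0, 100]`.
#' @export
accuracy_pct <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred lengths differ", call. = FALSE)
  }
  if (length(y_true) < 1) stop("need at least one sample", call. = FALSE)
  100 * mean(y_true == y_pred)
}

#' Confusion matrix (rows = actual, columns = predicted)
#'
#' @param y_true,y_pred integer class labels in `[0, n_classes)`.
#' @param n_classes number of classes `k`.
#' @return `k x k` integer matrix; entry `(r, c)` counts samples of true
#'   class `r - 1` predicted as class `c - 1`. Dimnames carry the class
#'   indices.
#' @export
confusion_matrix <- function(y_true, y_pred, n_classes) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred lengths differ", call. = FALSE)
  }
  labs <- c(y_true, y_pred)
  if (any(labs < 0) || any(labs >= n_classes)) {
    stop("labels out of range [0, ", n_classes, ")", call. = FALSE)
  }
  lev <- seq_len(n_classes) - 1L
  cm <- table(factor(y_true, levels = lev), factor(y_pred, levels = lev))
  m <- matrix(as.integer(cm), n_classes, n_classes,
              dimnames = list(actual = lev, predicted = lev))
  m
}

#' Per-class and macro precision, recall and F1
#'
#' Per class: precision `TP / (TP + FP)`, recall `TP / (TP + FN)`, F1 their
#' harmonic mean; any zero denominator defines the metric as 0 (flagged in
#' the result). Macro values are unweighted means over classes.
#'
#' @param confusion a square confusion matrix (rows = actual).
#' @return List with `per_class` (data frame: class, precision, recall, f1),
#'   `macro` (named numeric vector), and `zero_division` (logical flag).
#' @export
precision_recall_f1 <- function(confusion) {
  confusion <- as.matrix(confusion)
  stopifnot(nrow(confusion) == ncol(confusion))
  k <- nrow(confusion)
  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- rowSums(confusion) - tp
  safe_div <- function(num, den) ifelse(den == 0, 0, num / den)
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  list(
    per_class = data.frame(class = seq_len(k) - 1L, precision = precision,
                           recall = recall, f1 = f1, row.names = NULL),
    macro = c(precision = mean(precision), recall = mean(recall),
              f1 = mean(f1)),
    zero_division = any((tp + fp) == 0 | (tp + fn) == 0 |
                          (precision + recall) == 0)
  )
}

## Binary AUROC by the rank (Mann-Whitney) statistic, ties counted 1/2.
auroc_binary <- function(positive, scores) {
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Macro one-vs-rest AUROC
#'
#' Binary problems reduce to the rank statistic on the positive-class score
#' (ties counted one half). Multiclass problems compute a one-vs-rest AUROC
#' per class present in `y_true` — scoring each class against all others with
#' its own score column — and macro-average them. Classes absent from
#' `y_true` (or present in every sample, leaving no negatives) are excluded
#' with a warning.
#'
#' @param y_true integer class labels in `[0, k)`.
#' @param scores samples x classes score matrix (columns in class-index
#'   order, e.g. from [vote_scores()]); for a binary problem a plain numeric
#'   vector of positive-class (class 1) scores is also accepted.
#' @return AUROC in `[0, 1]`, or `NA` if no class is scorable.
#' @export
macro_auroc <- function(y_true, scores) {
  if (is.null(dim(scores))) {
    return(auroc_binary(y_true == 1L, as.numeric(scores)))
  }
  scores <- as.matrix(scores)
  k <- ncol(scores)
  per_class <- vapply(seq_len(k) - 1L, function(cl) {
    auroc_binary(y_true == cl, scores[, cl + 1L])
  }, numeric(1))
  usable <- !is.na(per_class)
  if (!all(usable)) {
    warning("class(es) without both positives and negatives excluded ",
            "from the macro AUROC: ",
            paste(which(!usable) - 1L, collapse = ", "))
  }
  if (!any(usable)) return(NA_real_)
  mean(per_class[usable])
}

#' Full evaluation report for one classifier on one feature set
#'
#' @param y_true,y_pred integer class labels.
#' @param n_classes number of classes.
#' @param scores optional samples x classes score matrix for the AUROC.
#' @return An object of class `evaluation_report`: accuracy percentage,
#'   confusion matrix, per-class and macro precision/recall/F1, AUROC and
#'   `n_test`.
#' @export
evaluate_predictions <- function(y_true, y_pred, n_classes, scores = NULL) {
  cm <- confusion_matrix(y_true, y_pred, n_classes)
  prf <- precision_recall_f1(cm)
  auroc <- if (is.null(scores)) NA_real_ else macro_auroc(y_true, scores)
  structure(
    list(accuracy_pct = accuracy_pct(y_true, y_pred), confusion = cm,
         per_class = prf$per_class, macro = prf$macro,
         zero_division = prf$zero_division, auroc = auroc,
         n_test = length(y_true)),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> accuracy %.2f%% on %d samples",
              x$accuracy_pct, x$n_test))
  if (!is.na(x$auroc)) cat(sprintf(", AUROC %.3f", x$auroc))
  cat("\n  macro precision/recall/F1: ",
      paste(sprintf("%.3f", x$macro), collapse = " / "), "\n", sep = "")
  print(x$confusion)
  invisible(x)
}
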