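# ---- confusion counts, ROC / PR curves, areas -------------------------------

#' Confusion matrix
#'
#' @param y_true integer true labels in `[0, num_classes)`.
#' @param y_pred integer predicted labels in the same range.
#' @param num_classes number of classes K.
#' @return K x K integer matrix; entry (i, j) counts items of true class
#'   i - 1 predicted as class j - 1. Row sums are the class supports.
#' @export
confusion_matrix <- function(y_true, y_pred, num_classes) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  K <- as.integer(num_classes)
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (any(y_true < 0L | y_true >= K) || any(y_pred < 0L | y_pred >= K)) {
    stop("label outside [0, ", K, ")")
  }
  m <- matrix(0L, K, K)
  for (i in seq_along(y_true)) {
    m[y_true[i] + 1L, y_pred[i] + 1L] <- m[y_true[i] + 1L, y_pred[i] + 1L] + 1L
  }
  dimnames(m) <- list(true = 0:(K - 1), pred = 0:(K - 1))
  m
}

#' Accuracy from a confusion matrix
#'
#' Trace over total; for the binary case this reduces to
#' (TP + TN) / (TP + TN + FP + FN).
#'
#' @param confusion square count matrix from [confusion_matrix()].
#' @return proportion of correct predictions.
#' @export
accuracy <- function(confusion) {
  total <- sum(confusion)
  if (total == 0) stop("empty confusion matrix")
  sum(diag(confusion)) / total
}

# shared threshold sweep: one operating point per distinct score, descending;
# equal scores are processed together
sweep_counts <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  keep <- c(diff(s) != 0, TRUE)   # last index of each tied block
  tp <- cumsum(l)[keep]
  fp <- cumsum(1 - l)[keep]
  list(tp = tp, fp = fp, P = sum(l), Neg = sum(1 - l))
}

check_binary <- function(labels) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  labels
}

#' ROC curve
#'
#' Sweeps thresholds over the distinct score values (ties collapsed into one
#' step) and records (FPR, TPR) = (FP/(FP+TN), TP/(TP+FN)) at each, with the
#' (0, 0) and (1, 1) sentinels included.
#'
#' @param scores numeric scores, larger = more positive.
#' @param labels binary 0/1 labels; both classes must be present.
#' @return object of class `msn_curve` with `points` (data frame x = FPR,
#'   y = TPR), `area` (trapezoidal AUC), `kind = "roc"`.
#' @export
roc_points <- function(scores, labels) {
  labels <- check_binary(labels)
  if (length(unique(labels)) < 2L) {
    stop("AUC undefined: labels contain a single class")
  }
  sw <- sweep_counts(scores, labels)
  x <- c(0, sw$fp / sw$Neg)
  y <- c(0, sw$tp / sw$P)
  curve <- structure(list(points = data.frame(x = x, y = y), kind = "roc"),
                     class = "msn_curve")
  curve$area <- curve_area(curve)
  curve
}

#' Precision-recall curve
#'
#' Precision TP/(TP+FP) and recall TP/(TP+FN) at each distinct-score
#' threshold in descending score order.
#'
#' @inheritParams roc_points
#' @return object of class `msn_curve` with `points` (x = recall,
#'   y = precision), `area` (step-wise average precision), `kind = "pr"`.
#' @export
pr_points <- function(scores, labels) {
  labels <- check_binary(labels)
  if (sum(labels) == 0L) stop("PR curve undefined: no positives")
  sw <- sweep_counts(scores, labels)
  rec <- sw$tp / sw$P
  prec <- sw$tp / (sw$tp + sw$fp)
  curve <- structure(list(points = data.frame(x = rec, y = prec), kind = "pr"),
                     class = "msn_curve")
  curve$area <- curve_area(curve)
  curve
}

#' Area under a curve
#'
#' ROC curves are integrated trapezoidally over FPR; PR curves use the
#' step-wise (average-precision) sum, which avoids the optimistic bias of
#' linear PR interpolation.
#'
#' @param curve an `msn_curve` from [roc_points()] or [pr_points()].
#' @return scalar area.
#' @export
curve_area <- function(curve) {
  stopifnot(inherits(curve, "msn_curve"))
  p <- curve$points
  if (nrow(p) < 2L && curve$kind == "roc") stop("need at least 2 points")
  if (curve$kind == "roc") {
    if (is.unsorted(p$x)) stop("ROC points must be ordered by FPR")
    sum(diff(p$x) * (head(p$y, -1) + tail(p$y, -1)) / 2)
  } else {
    r <- c(0, p$x)
    sum(diff(r) * p$y)
  }
}

#' One-vs-rest multiclass curves
#'
#' Scores class c by probability column c against binarized labels; classes
#' absent from the labels are flagged undefined and excluded from the macro
#' averages.
#'
#' @param prob_matrix N x K matrix of class probabilities (rows sum to 1).
#' @param labels integer labels in `[0, K)`.
#' @return list with per-class `roc` and `pr` curves (NULL where undefined),
#'   vectors `auc` and `ap`, and `macro_auc` / `macro_ap`.
#' @export
one_vs_rest <- function(prob_matrix, labels) {
  prob_matrix <- as.matrix(prob_matrix)
  K <- ncol(prob_matrix)
  labels <- as.integer(labels)
  roc <- vector("list", K); pr <- vector("list", K)
  auc <- rep(NA_real_, K); ap <- rep(NA_real_, K)
  for (c in seq_len(K)) {
    bin <- as.integer(labels == (c - 1L))
    if (length(unique(bin)) < 2L) next
    roc[[c]] <- roc_points(prob_matrix[, c], bin)
    pr[[c]] <- pr_points(prob_matrix[, c], bin)
    auc[c] <- roc[[c]]$area
    ap[c] <- pr[[c]]$area
  }
  list(roc = roc, pr = pr, auc = auc, ap = ap,
       macro_auc = mean(auc, na.rm = TRUE), macro_ap = mean(ap, na.rm = TRUE),
       undefined = which(is.na(auc)) - 1L)
}

#' @export
print.msn_curve <- function(x, ...) {
  cat(toupper(x$kind), "curve:", nrow(x$points), "points, area =",
      format(x$area, digits = 4), "\n")
  invisible(x)
}
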