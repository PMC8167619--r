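#' Confusion matrix over the three report classes
#'
#' Rows are true classes, columns predicted, both in the canonical
#' (negative, positive, obscure) order.
#'
#' @param true_labels,predicted_labels Character vectors of labels.
#' @return An integer 3x3 matrix of class `confusion_matrix`.
#' @export
confusion <- function(true_labels, predicted_labels) {
  if (length(true_labels) != length(predicted_labels)) {
    stop("label vectors have different lengths")
  }
  tl <- factor(.validate_label(true_labels, allow_na = FALSE), levels = .LABELS)
  pl <- factor(.validate_label(predicted_labels, allow_na = FALSE), levels = .LABELS)
  m <- table(true = tl, predicted = pl)
  structure(unclass(m), class = c("confusion_matrix", "matrix"))
}

#' One-vs-rest precision, recall and F1 for one class
#'
#' The class of interest is treated as positive and the other two classes as
#' negative: precision = TP / column total, recall = TP / row total,
#' F1 = 2 TP / (column + row totals). A 0/0 is reported as 0 and flagged via
#' `attr(x, "zero_division")`.
#'
#' @param cm A [confusion()] matrix.
#' @param cls One of `"negative"`, `"positive"`, `"obscure"`.
#' @return Named numeric vector `(precision, recall, f1)`.
#' @export
one_vs_rest_prf <- function(cm, cls) {
  stopifnot(inherits(cm, "confusion_matrix"), cls %in% .LABELS)
  tp <- cm[cls, cls]
  pred <- sum(cm[, cls])
  act <- sum(cm[cls, ])
  zd <- FALSE
  div <- function(a, b) if (b == 0) { zd <<- TRUE; 0 } else a / b
  p <- div(tp, pred)
  r <- div(tp, act)
  f1 <- div(2 * tp, pred + act)
  out <- c(precision = p, recall = r, f1 = f1)
  attr(out, "zero_division") <- zd
  out
}

#' Worked-example F1 from printed count cells
#'
#' Computes precision, recall and F1 from the `TP / N` count pairs the
#' study tables print for each class, with the tables' display rounding:
#' percentages to 0.1 and F1 to an integer percent.
#'
#' @param tp True positives of the class.
#' @param n_pred Number of reports predicted as the class.
#' @param n_true Number of reports truly of the class.
#' @return List with `precision_pct`, `recall_pct` (one decimal) and
#'   `f1_pct` (integer percent), plus the unrounded `f1`.
#' @export
f1_from_counts <- function(tp, n_pred, n_true) {
  stopifnot(tp >= 0, n_pred >= tp, n_true >= tp)
  p <- tp / n_pred
  r <- tp / n_true
  f1 <- 2 * tp / (n_pred + n_true)
  list(precision_pct = round(100 * p, 1), recall_pct = round(100 * r, 1),
       f1_pct = round(100 * f1), f1 = f1)
}

#' Overall accuracy from a confusion matrix
#'
#' @param cm A [confusion()] matrix.
#' @return `trace / total`.
#' @export
accuracy <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tot <- sum(cm)
  if (tot == 0) stop("empty confusion matrix")
  sum(diag(cm)) / tot
}

#' Area under the ROC curve (midrank / Mann-Whitney)
#'
#' Equals the probability that a random positive is scored above a random
#' negative, ties counting one half — computed with midranks in O(n log n).
#'
#' @param scores Numeric scores (larger = more positive).
#' @param positives Logical (or 0/1) vector marking the positive class.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, positives) {
  positives <- as.logical(positives)
  stopifnot(length(scores) == length(positives), !anyNA(scores))
  n1 <- sum(positives)
  n0 <- sum(!positives)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[positives]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Non-interpolated average precision: thresholds sweep the distinct scores
#' from high to low, and each threshold contributes
#' `precision * (recall step)`. Tied scores enter together.
#'
#' @inheritParams auroc
#' @return Average precision in `(0, 1]`.
#' @export
auprc <- function(scores, positives) {
  positives <- as.logical(positives)
  stopifnot(length(scores) == length(positives), !anyNA(scores))
  P <- sum(positives)
  if (P == 0) stop("no positive examples")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- positives[ord]
  grp_end <- which(s != c(s[-1], NA) | seq_along(s) == length(s))
  tp <- cumsum(y)[grp_end]
  n_seen <- grp_end
  prec <- tp / n_seen
  rec <- tp / P
  sum(prec * diff(c(0, rec)))
}

#' Cohen's kappa between two labelings
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with `p_e` from the
#' marginal products. When both raters are constant and identical
#' (`p_e = 1`), kappa is defined as 1 and flagged.
#'
#' @param labels_a,labels_b Equal-length label vectors over the same set.
#' @return Kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stop("length mismatch")
  lev <- sort(unique(c(labels_a, labels_b)))
  a <- factor(labels_a, levels = lev)
  b <- factor(labels_b, levels = lev)
  n <- length(a)
  tab <- table(a, b)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - pe) < 1e-15) {
    out <- 1
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  (po - pe) / (1 - pe)
}

#' Assemble the full metric suite
#'
#' Per class: one-vs-rest precision/recall/F1 with supports, AUROC and AUPRC
#' on that class's predicted probability; overall accuracy and Cohen's kappa
#' of predictions against the reference labels.
#'
#' @param predictions Either a list of `attention_prediction` objects or a
#'   numeric matrix of class probabilities with columns in the canonical
#'   label order.
#' @param true_labels Character vector of reference labels.
#' @return An object of class `metrics_report`.
#' @export
evaluate <- function(predictions, true_labels) {
  probs <- .prob_matrix(predictions)
  true_labels <- .validate_label(true_labels, allow_na = FALSE)
  if (nrow(probs) != length(true_labels)) stop("prediction/label length mismatch")
  pred_labels <- .LABELS[max.col(probs, ties.method = "first")]
  cm <- confusion(true_labels, pred_labels)
  per_class <- lapply(.LABELS, function(cls) {
    prf <- one_vs_rest_prf(cm, cls)
    pos <- true_labels == cls
    list(
      precision = unname(prf["precision"]), recall = unname(prf["recall"]),
      f1 = unname(prf["f1"]),
      tp = unname(cm[cls, cls]), n_pred = unname(sum(cm[, cls])),
      support = unname(sum(cm[cls, ])),
      auroc = if (any(pos) && !all(pos)) auroc(probs[, cls], pos) else NA_real_,
      auprc = if (any(pos)) auprc(probs[, cls], pos) else NA_real_
    )
  })
  names(per_class) <- .LABELS
  structure(list(confusion = cm, per_class = per_class,
                 accuracy = accuracy(cm),
                 kappa = as.numeric(cohens_kappa(true_labels, pred_labels)),
                 n = length(true_labels)),
            class = "metrics_report")
}

.prob_matrix <- function(predictions) {
  if (is.matrix(predictions)) {
    stopifnot(ncol(predictions) == 3)
    colnames(predictions) <- .LABELS
    return(predictions)
  }
  if (is.list(predictions) &&
      all(vapply(predictions, inherits, logical(1), "attention_prediction"))) {
    return(do.call(rbind, lapply(predictions, function(p) p$probabilities)))
  }
  stop("predictions must be a probability matrix or a list of attention_prediction")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' @export
format.metrics_report <- function(x, ...) {
  pct <- function(a, b) sprintf("%d/%d (%.1f)", a, b, 100 * a / max(b, 1))
  rows <- vapply(.LABELS, function(cls) {
    m <- x$per_class[[cls]]
    sprintf("| %s | %s | %s | %d | %.2f | %.2f |",
            tools::toTitleCase(cls),
            pct(m$tp, m$n_pred), pct(m$tp, m$support),
            round(100 * m$f1), m$auroc, m$auprc)
  }, character(1))
  c("| Class | Precision, n/N (%) | Recall, n/N (%) | F1 (%) | AUROC | AUPRC |",
    "|---|---|---|---|---|---|",
    rows,
    sprintf("Accuracy: %.2f%% (%d/%d); kappa vs reference: %.3f",
            100 * x$accuracy, sum(diag(x$confusion)), x$n, x$kappa))
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  do.call(rbind, lapply(.LABELS, function(cls) {
    m <- x$per_class[[cls]]
    data.frame(class = cls, precision = m$precision, recall = m$recall,
               f1 = m$f1, support = m$support, auroc = m$auroc,
               auprc = m$auprc, stringsAsFactors = FALSE)
  }))
}

#' Serialize a metrics report to JSON
#'
#' @param x A `metrics_report`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
metrics_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "metrics_report"))
  obj <- list(per_class = x$per_class, accuracy = x$accuracy,
              kappa = x$kappa, n = x$n,
              confusion = unclass(x$confusion))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
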