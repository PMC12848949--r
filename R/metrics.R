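# Five-metric evaluation bundle for multi-class edge classification:
# accuracy, macro-F1, macro one-vs-rest AUROC and AUPR, and the Matthews
# correlation coefficient (multi-category generalization).

#' Confusion counts for multi-class predictions
#'
#' @param truth Integer true classes in `1..n_classes`.
#' @param predicted Integer predicted classes in `1..n_classes`.
#' @param n_classes Number of classes C.
#' @return A `C x C` integer matrix; rows are true classes, columns predicted.
#' @export
confusion_counts <- function(truth, predicted, n_classes) {
  stopifnot(length(truth) == length(predicted), length(truth) > 0,
            all(truth >= 1 & truth <= n_classes),
            all(predicted >= 1 & predicted <= n_classes))
  cm <- matrix(0L, n_classes, n_classes)
  tab <- table(factor(truth, levels = seq_len(n_classes)),
               factor(predicted, levels = seq_len(n_classes)))
  cm[] <- as.integer(tab)
  cm
}

#' Accuracy from a confusion matrix
#'
#' @param cm Confusion matrix from [confusion_counts()].
#' @return Proportion of correctly predicted instances.
#' @export
metric_accuracy <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  sum(diag(cm)) / total
}

#' Macro-averaged F1 from a confusion matrix
#'
#' Per-class F1 is `2 P R / (P + R)`, taken as 0 when `P + R = 0` (class
#' never predicted and never true); the macro score is the unweighted mean
#' over all classes.
#'
#' @param cm Confusion matrix.
#' @return Macro-F1 in `[0, 1]`.
#' @export
metric_macro_f1 <- function(cm) {
  if (sum(cm) == 0) stop("empty confusion matrix")
  per <- per_class_prf(cm)
  mean(per$f1)
}

per_class_prf <- function(cm) {
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  tibble::tibble(class = seq_len(nrow(cm)), precision = precision,
                 recall = recall, f1 = f1,
                 support = rowSums(cm))
}

#' Matthews correlation coefficient
#'
#' Binary inputs use the textbook formula
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. For more than two
#' classes the multi-category correlation generalization is used; it reduces
#' exactly to the binary formula at C = 2. A zero denominator yields 0.
#'
#' @param truth Integer true classes in `1..n_classes`.
#' @param predicted Integer predicted classes.
#' @param n_classes Number of classes (default: max observed).
#' @return MCC in `[-1, 1]`.
#' @export
metric_mcc <- function(truth, predicted, n_classes = max(truth, predicted)) {
  if (length(unique(truth)) < 2L) {
    stop("MCC is undefined when the true labels contain a single class")
  }
  cm <- confusion_counts(truth, predicted, n_classes)
  s <- sum(cm)
  c_ <- sum(diag(cm))
  pk <- colSums(cm) # predicted counts
  tk <- rowSums(cm) # true counts
  num <- c_ * s - sum(pk * tk)
  den <- sqrt(s^2 - sum(pk^2)) * sqrt(s^2 - sum(tk^2))
  if (den == 0) return(0)
  num / den
}

# one-vs-rest AUROC by the rank (Mann-Whitney) statistic; ties share ranks
auroc_binary <- function(scores, positive) {
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# one-vs-rest AUPR by precision-at-recall-step summation (average precision)
aupr_binary <- function(scores, positive) {
  n_pos <- sum(positive)
  if (n_pos == 0 || all(positive)) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  pos <- positive[ord]
  tp <- cumsum(pos)
  precision <- tp / seq_along(pos)
  sum(precision[pos]) / n_pos
}

#' Macro one-vs-rest AUROC
#'
#' For each class present in the labels, treats it as positive against all
#' others and computes the area under the ROC curve from class-score
#' rankings (rank statistic; equivalent to trapezoid integration of the
#' curve); the macro score is the unweighted mean over contributing classes.
#' Classes absent from the labels are skipped with a warning.
#'
#' @param scores `n x C` matrix of class scores or probabilities.
#' @param labels Integer true classes in `1..C`.
#' @return Macro AUROC in `[0, 1]`.
#' @export
metric_auroc <- function(scores, labels) {
  macro_ovr(scores, labels, auroc_binary, "AUROC")
}

#' Macro one-vs-rest AUPR
#'
#' Average precision (step-wise precision-at-recall summation, no trapezoid
#' interpolation) per class, macro-averaged over classes present in the
#' labels.
#'
#' @inheritParams metric_auroc
#' @return Macro AUPR in `[0, 1]`.
#' @export
metric_aupr <- function(scores, labels) {
  macro_ovr(scores, labels, aupr_binary, "AUPR")
}

macro_ovr <- function(scores, labels, fun, what) {
  stopifnot(is.matrix(scores), nrow(scores) == length(labels))
  n_classes <- ncol(scores)
  present <- sort(unique(labels))
  if (length(present) < 2L) stop(what, " is undefined when labels contain a single class")
  absent <- setdiff(seq_len(n_classes), present)
  if (length(absent)) {
    warning(sprintf("%s: skipping class(es) absent from labels: %s", what,
                    paste(absent, collapse = ", ")))
  }
  vals <- vapply(present, function(cl) fun(scores[, cl], labels == cl), numeric(1))
  mean(vals)
}

#' Evaluate predictions with the five-metric bundle
#'
#' @param truth Integer true classes in `1..C`.
#' @param scores `n x C` matrix of predicted class probabilities; predicted
#'   classes are the row-wise argmax.
#' @param n_classes Number of classes (default `ncol(scores)`).
#' @return An object of class `dgi_metrics`: a list with `acc`, `macro_f1`,
#'   `auroc`, `aupr`, `mcc`, `per_class` (tibble of per-class
#'   precision/recall/F1/support) and `n_evaluated`.
#' @export
evaluate_predictions <- function(truth, scores, n_classes = ncol(scores)) {
  predicted <- max.col(scores, ties.method = "first")
  cm <- confusion_counts(truth, predicted, n_classes)
  structure(list(
    acc = metric_accuracy(cm),
    macro_f1 = metric_macro_f1(cm),
    auroc = metric_auroc(scores, truth),
    aupr = metric_aupr(scores, truth),
    mcc = metric_mcc(truth, predicted, n_classes),
    per_class = per_class_prf(cm),
    confusion = cm,
    n_evaluated = length(truth)
  ), class = "dgi_metrics")
}

#' @export
print.dgi_metrics <- function(x, ...) {
  cat(sprintf(
    "<dgi_metrics> n=%d  acc %.4f | macro-F1 %.4f | AUROC %.4f | AUPR %.4f | MCC %.4f\n",
    x$n_evaluated, x$acc, x$macro_f1, x$auroc, x$aupr, x$mcc
  ))
  invisible(x)
}

#' Serialize a metrics report to JSON
#'
#' Stable keys: `acc`, `macro_f1`, `auroc`, `aupr`, `mcc`, `n_evaluated`,
#' plus `per_class`.
#'
#' @param x A `dgi_metrics`.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to a file).
#' @export
metrics_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "dgi_metrics"))
  obj <- list(
    acc = x$acc, macro_f1 = x$macro_f1, auroc = x$auroc, aupr = x$aupr,
    mcc = x$mcc, n_evaluated = x$n_evaluated,
    per_class = x$per_class
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Evaluate a fitted model on a set of edges
#'
#' Scores the requested edges with the fitted model (message passing over
#' training edges only) and computes the metric bundle against their true
#' classes.
#'
#' @param fit A `dgi_fit`.
#' @param g The `dgi_graph` the fit was trained on.
#' @param rows Integer edge rows of `g` to evaluate (e.g. `split$test`).
#' @return A `dgi_metrics`.
#' @export
evaluate_fit <- function(fit, g, rows) {
  e <- g$edges[rows, , drop = FALSE]
  preds <- predict(fit, tibble::tibble(
    drug_id = g$drug_ids[e$drug_index],
    gene_id = g$gene_ids[e$gene_index]
  ))
  scores <- as.matrix(preds[, grepl("^prob_", names(preds)), drop = FALSE])
  evaluate_predictions(e$class, scores, n_classes = g$n_classes)
}
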