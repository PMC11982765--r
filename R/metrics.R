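# Confusion matrices and the evaluation-metric suite: precision, recall,
# F1, specificity, per-class and overall balanced accuracy, weighted F1 and
# one-vs-rest AUC.

#' Presentation rounding: two decimals, half up
#'
#' Internal values are kept at full precision; rounding is applied only when
#' reporting (matching the two-decimal presentation of the metric tables).
#'
#' @param x Numeric.
#' @param digits Decimal places (default 2).
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Confusion matrix
#'
#' Rows are ground-truth classes, columns model-proposed classes, both in
#' the fixed class order.
#'
#' @param labels Factor/character of true classes.
#' @param predictions Factor/character of predicted classes (same length).
#' @param classes Class order (default [hs_classes()]).
#' @return 4x4 integer matrix of class `hs_confusion`.
#' @export
confusion <- function(labels, predictions, classes = hs_classes()) {
  if (length(labels) != length(predictions))
    hs_error("hierscore_length_mismatch",
             "labels and predictions differ in length")
  l <- as.character(labels); p <- as.character(predictions)
  bad <- unique(c(l[!l %in% classes], p[!p %in% classes]))
  if (length(bad))
    hs_error("hierscore_unknown_class",
             paste0("unknown classes: ", paste(bad, collapse = ", ")))
  cm <- table(factor(l, levels = classes), factor(p, levels = classes))
  m <- matrix(as.integer(cm), length(classes), length(classes),
              dimnames = list(truth = classes, predicted = classes))
  structure(m, class = c("hs_confusion", class(m)))
}

#' Coerce a bare count matrix to an `hs_confusion`
#'
#' @param m 4x4 numeric matrix of counts, rows = truth, columns = predicted.
#' @param classes Class order.
#' @return An `hs_confusion`.
#' @export
as_confusion <- function(m, classes = hs_classes()) {
  m <- as.matrix(m)
  stopifnot(nrow(m) == length(classes), ncol(m) == length(classes),
            all(m >= 0), all(m == round(m)))
  m <- matrix(as.integer(m), nrow(m), ncol(m),
              dimnames = list(truth = classes, predicted = classes))
  structure(m, class = c("hs_confusion", class(m)))
}

#' Metric table from a confusion matrix
#'
#' Per class: precision `TP/column`, recall `TP/row`, F1 (harmonic mean),
#' specificity `TN/(TN+FP)` and per-class balanced accuracy
#' `(recall + specificity)/2`. Aggregates: overall balanced accuracy (the
#' unweighted mean of the four recalls) and support-weighted F1. Metrics
#' with an empty denominator (no true or no predicted instances of a class)
#' are returned as `NA` and flagged in `undefined`, never silently zeroed.
#'
#' @param cm An `hs_confusion` (or bare 4x4 count matrix).
#' @param auc Optional named per-class AUC vector to attach.
#' @return List of class `hs_metrics`: `per_class` data.frame,
#'   `balanced_accuracy`, `weighted_f1`, `n`, `undefined`.
#' @export
metrics_from_confusion <- function(cm, auc = NULL) {
  if (!inherits(cm, "hs_confusion")) cm <- as_confusion(cm)
  n <- sum(cm)
  if (n == 0) hs_error("hierscore_empty_cohort", "empty confusion matrix")
  classes <- rownames(cm)
  tp <- diag(cm); row <- rowSums(cm); col <- colSums(cm)
  tn <- n - row - col + tp; fp <- col - tp
  precision <- ifelse(col > 0, tp / col, NA_real_)
  recall <- ifelse(row > 0, tp / row, NA_real_)
  f1 <- ifelse(!is.na(precision) & !is.na(recall) & (precision + recall) > 0,
               2 * precision * recall / (precision + recall), NA_real_)
  specificity <- ifelse((tn + fp) > 0, tn / (tn + fp), NA_real_)
  ba_class <- (recall + specificity) / 2
  undefined <- character(0)
  for (i in seq_along(classes)) {
    if (col[[i]] == 0) undefined <- c(undefined,
                                      paste0("precision:", classes[[i]]))
    if (row[[i]] == 0) undefined <- c(undefined,
                                      paste0("recall:", classes[[i]]))
  }
  per_class <- data.frame(class = classes, support = as.integer(row),
                          precision = unname(precision),
                          recall = unname(recall), f1 = unname(f1),
                          specificity = unname(specificity),
                          balanced_accuracy = unname(ba_class),
                          row.names = NULL)
  if (!is.null(auc)) per_class$auc <- unname(auc[classes])
  structure(list(per_class = per_class,
                 balanced_accuracy = mean(recall),
                 weighted_f1 = sum((row / n) * f1),
                 n = as.integer(n),
                 undefined = undefined,
                 confusion = cm),
            class = "hs_metrics")
}

#' @export
print.hs_metrics <- function(x, digits = 2, ...) {
  d <- x$per_class
  num <- vapply(d, is.numeric, logical(1)) & names(d) != "support"
  d[num] <- lapply(d[num], round_half_up, digits = digits)
  cat("Validation metrics (n = ", x$n, "):\n", sep = "")
  print(d, row.names = FALSE)
  cat("Overall balanced accuracy: ",
      format(round_half_up(x$balanced_accuracy, digits), nsmall = digits),
      "; weighted F1: ",
      format(round_half_up(x$weighted_f1, digits), nsmall = digits),
      "\n", sep = "")
  if (length(x$undefined))
    cat("Undefined (empty denominator): ",
        paste(x$undefined, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Balanced accuracy of predictions
#'
#' The unweighted mean of per-class recalls over the classes present in the
#' labels.
#'
#' @param labels True classes.
#' @param predictions Predicted classes.
#' @param classes Class order.
#' @return Numeric scalar.
#' @export
balanced_accuracy <- function(labels, predictions, classes = hs_classes()) {
  cm <- confusion(labels, predictions, classes)
  rec <- diag(cm) / rowSums(cm)
  mean(rec[rowSums(cm) > 0])
}

#' One-vs-rest AUC per class
#'
#' Mann-Whitney ranking AUC of each class's predicted probability against
#' the one-vs-rest labels; ties contribute one half.
#'
#' @param labels True classes.
#' @param probability_matrix n x 4 matrix of class probabilities (columns in
#'   class order).
#' @return Named numeric vector of per-class AUCs; classes without both a
#'   positive and a negative instance raise an error.
#' @export
auc_ovr <- function(labels, probability_matrix, classes = hs_classes()) {
  P <- as.matrix(probability_matrix)
  stopifnot(nrow(P) == length(labels), ncol(P) == length(classes))
  l <- as.character(labels)
  vapply(seq_along(classes), function(ci) {
    pos <- l == classes[[ci]]
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0 || n0 == 0)
      hs_error("hierscore_degenerate_class",
               paste0("class ", classes[[ci]],
                      " lacks positives or negatives"))
    r <- rank(P[, ci])             # average ranks handle ties (1/2 credit)
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, numeric(1), USE.NAMES = FALSE) |> stats::setNames(classes)
}

#' Evaluate a model on a labelled cohort
#'
#' Point mode takes the argmax of the deterministic forward pass; MCD mode
#' takes the argmax of the Monte Carlo dropout mean probabilities (computed
#' per record from `n_samples` stochastic passes). AUC is computed from the
#' same probability matrix that produced the predictions.
#'
#' @param model A trained `hs_model`.
#' @param cohort A labelled `hs_cohort`.
#' @param mode `"point"` or `"mcd"`.
#' @param n_samples MCD sample count (mode `"mcd"`).
#' @param seed Integer seed for the MCD passes.
#' @param schema An `hs_schema` registry.
#' @return List of class `hs_metrics` (see [metrics_from_confusion()]), with
#'   the confusion matrix in `$confusion` and the probability matrix in
#'   `$probabilities`.
#' @export
evaluate_model <- function(model, cohort, mode = c("point", "mcd"),
                           n_samples = 500, seed = 1,
                           schema = load_schema()) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "hs_model"), is_cohort(cohort))
  y <- cohort_labels(cohort)
  if (is.null(y))
    hs_error("hierscore_unlabelled_cohort", "evaluation needs labels")
  X <- encode_cohort(cohort, schema, validate = FALSE)
  if (mode == "point") {
    P <- forward_matrix(model, X)
  } else {
    P <- matrix(0, nrow(X), 4L, dimnames = list(NULL, model$classes))
    for (i in seq_len(nrow(X)))
      P[i, ] <- mcd_predict(model, X[i, ], n_samples = n_samples,
                            seed = seed + i - 1L)$mu
  }
  pred <- factor(model$classes[max.col(P, ties.method = "first")],
                 levels = model$classes)
  cm <- confusion(y, pred, model$classes)
  auc <- tryCatch(auc_ovr(y, P, model$classes),
                  hierscore_degenerate_class = function(e) NULL)
  res <- metrics_from_confusion(cm, auc = auc)
  res$probabilities <- P
  res$predictions <- pred
  res
}
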