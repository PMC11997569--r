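#' Confusion matrix of true vs predicted labels
#'
#' Entry `(i, j)` counts instances of true class `i - 1` predicted as class
#' `j - 1`. The `row_pct` attribute holds the row-normalized variant in
#' percent (empty rows are all-zero).
#'
#' @param truth,pred integer labels in `0..K-1`, equal length.
#' @param K number of classes.
#' @return `K x K` count matrix with attribute `row_pct`.
#' @export
confusion <- function(truth, pred, K = max(c(truth, pred)) + 1L) {
  assert_that(length(truth) == length(pred), "label length mismatch")
  assert_that(all(c(truth, pred) >= 0 & c(truth, pred) < K),
              "labels must lie in [0, K)")
  m <- matrix(0L, K, K, dimnames = list(true = 0:(K - 1), pred = 0:(K - 1)))
  for (i in seq_along(truth))
    m[truth[i] + 1L, pred[i] + 1L] <- m[truth[i] + 1L, pred[i] + 1L] + 1L
  rs <- rowSums(m)
  pct <- 100 * m / ifelse(rs > 0, rs, 1)
  pct[rs == 0, ] <- 0
  attr(m, "row_pct") <- pct
  m
}

#' Classification metrics from a confusion matrix
#'
#' Per class (one-vs-rest): `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `F1 = 2*precision*recall/(precision+recall)`, each defined as 0 (with a
#' `zero_division` flag) when its denominator is 0. Accuracy is
#' `trace/n`; macro averages are unweighted class means, weighted averages
#' are support-weighted.
#'
#' @param cm a `K x K` confusion count matrix from [confusion()].
#' @return An object of class `eval_report`: fields `confusion`, `row_pct`,
#'   `per_class` (data frame), `accuracy`, `macro`, `weighted`, `n`.
#' @export
metrics <- function(cm) {
  K <- nrow(cm)
  n <- sum(cm)
  assert_that(n > 0, "empty confusion matrix")
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  safe <- function(num, den) ifelse(den > 0, num / den, 0)
  prec <- safe(tp, tp + fp)
  rec <- safe(tp, tp + fn)
  f1 <- safe(2 * prec * rec, prec + rec)
  support <- rowSums(cm)
  per_class <- data.frame(class = 0:(K - 1), precision = prec, recall = rec,
                          f1 = f1, support = support,
                          zero_division = (tp + fp) == 0 | (tp + fn) == 0,
                          row.names = NULL)
  wavg <- function(x) sum(x * support) / n
  structure(list(
    confusion = unclass(cm), row_pct = attr(cm, "row_pct"),
    per_class = per_class,
    accuracy = sum(tp) / n,
    macro = c(precision = mean(prec), recall = mean(rec), f1 = mean(f1)),
    weighted = c(precision = wavg(prec), recall = wavg(rec), f1 = wavg(f1)),
    n = n), class = "eval_report")
}

#' Evaluate a trained model on a dataset
#'
#' Deterministic (eval-mode forward), returning the full [metrics()] report.
#'
#' @param model a trained `stress_model`.
#' @param dataset a `feature_dataset`.
#' @return An `eval_report`.
#' @export
evaluate_model <- function(model, dataset) {
  assert_that(length(dataset$y) > 0, "empty dataset")
  pred <- predict_labels(model, dataset)
  metrics(confusion(dataset$y, pred, K = model$config$n_classes))
}

#' @export
print.eval_report <- function(x, ...) {
  cat(format_report(x), sep = "\n")
  invisible(x)
}

#' Render an evaluation report as an aligned text table
#' @param report an `eval_report`.
#' @return Character vector of lines.
#' @export
format_report <- function(report) {
  pc <- report$per_class
  lines <- c(sprintf("%-12s %9s %9s %9s %9s",
                     "class", "precision", "recall", "f1", "support"),
             sprintf("%-12s %9.4f %9.4f %9.4f %9d",
                     as.character(pc$class), pc$precision, pc$recall, pc$f1,
                     pc$support),
             sprintf("%-12s %9.4f %9.4f %9.4f %9d", "macro avg",
                     report$macro["precision"], report$macro["recall"],
                     report$macro["f1"], report$n),
             sprintf("%-12s %9.4f %9.4f %9.4f %9d", "weighted avg",
                     report$weighted["precision"], report$weighted["recall"],
                     report$weighted["f1"], report$n),
             sprintf("%-12s %9.4f", "accuracy", report$accuracy))
  lines
}

#' Serialize an evaluation report to a JSON-ready list
#' @param report an `eval_report`.
#' @return A plain list (confusion counts, row percentages, metrics).
#' @export
report_as_list <- function(report) {
  list(confusion = unname(apply(report$confusion, 1, as.integer, simplify = FALSE)),
       row_pct = unname(apply(round(report$row_pct, 4), 1, as.numeric,
                              simplify = FALSE)),
       per_class = report$per_class[, c("class", "precision", "recall", "f1",
                                        "support")],
       accuracy = report$accuracy,
       macro = as.list(report$macro),
       weighted = as.list(report$weighted),
       n = report$n)
}
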