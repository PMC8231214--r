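#' Confusion matrix
#'
#' Raw counts with entry (i, j) = number of windows of true class i
#' predicted as class j, plus the row-normalised version (each non-empty
#' row sums to 1).
#'
#' @param truth true behaviour labels
#' @param pred predicted behaviour labels (same length)
#' @return list with `counts` and `normalised` 3x3 matrices
#' @export
confusion_matrix <- function(truth, pred) {
  truth <- as_behaviour(truth)
  pred <- as_behaviour(pred)
  if (length(truth) != length(pred)) {
    stop("truth and pred lengths differ", call. = FALSE)
  }
  counts <- table(truth = truth, pred = pred)
  counts <- unclass(counts)
  rs <- rowSums(counts)
  normalised <- counts / ifelse(rs == 0, 1, rs)
  list(counts = counts, normalised = normalised)
}

#' Precision, recall and F1 from count statistics
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`, and F1 their
#' harmonic mean. Degenerate 0/0 cases return 0 by convention.
#'
#' @param tp,fp,fn true positive, false positive and false negative counts
#' @return named vector `(precision, recall, f1)`
#' @export
prf1 <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}

#' Full classification metrics report
#'
#' Per-class TP/FP/FN counts and precision/recall/F1, confusion matrices,
#' and both macro (unweighted class mean) and support-weighted aggregate
#' scores. On a balanced evaluation set macro and weighted coincide; the
#' weighted variant is the appropriate summary for unbalanced full-trace
#' evaluation.
#'
#' @param truth true behaviour labels
#' @param pred predicted behaviour labels
#' @return an object of class `metrics_report`
#' @export
metrics_report <- function(truth, pred) {
  cm <- confusion_matrix(truth, pred)
  counts <- cm$counts
  classes <- behaviour_levels()
  per_class <- t(vapply(classes, function(cl) {
    tp <- counts[cl, cl]
    fp <- sum(counts[, cl]) - tp
    fn <- sum(counts[cl, ]) - tp
    c(tp = tp, fp = fp, fn = fn, support = sum(counts[cl, ]), prf1(tp, fp, fn))
  }, numeric(7)))
  per_class <- as.data.frame(per_class)
  structure(
    list(per_class = per_class,
         confusion = cm,
         macro = list(precision = mean(per_class$precision),
                      recall = mean(per_class$recall),
                      f1 = mean(per_class$f1)),
         weighted = local({
           w <- per_class$support / sum(per_class$support)
           list(precision = sum(w * per_class$precision),
                recall = sum(w * per_class$recall),
                f1 = sum(w * per_class$f1))
         })),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  print(round(x$per_class, 3))
  cat(sprintf("  macro:    P %.3f R %.3f F1 %.3f\n", x$macro$precision,
              x$macro$recall, x$macro$f1))
  cat(sprintf("  weighted: P %.3f R %.3f F1 %.3f\n", x$weighted$precision,
              x$weighted$recall, x$weighted$f1))
  invisible(x)
}

#' Aggregate per-class metrics
#'
#' @param report a [metrics_report()]
#' @param mode `"macro"` (unweighted class mean) or `"weighted"`
#'   (support-weighted mean)
#' @return named list of precision, recall, f1
#' @export
aggregate_metrics <- function(report, mode = c("macro", "weighted")) {
  stopifnot(inherits(report, "metrics_report"))
  mode <- match.arg(mode)
  report[[mode]]
}

#' Percentile bootstrap confidence interval of a mean
#'
#' @param scores numeric vector of at least two per-run scores
#' @param level confidence level
#' @param resamples bootstrap resamples
#' @param seed RNG seed
#' @return numeric vector `(low, high)`
#' @export
bootstrap_ci <- function(scores, level = 0.95, resamples = 1000, seed = 1) {
  scores <- as.numeric(scores)
  if (length(scores) < 2) {
    stop("need at least two scores for a bootstrap interval", call. = FALSE)
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  means <- vapply(seq_len(resamples), function(i) {
    mean(sample(scores, length(scores), replace = TRUE))
  }, 0)
  alpha <- (1 - level) / 2
  as.numeric(stats::quantile(means, c(alpha, 1 - alpha), names = FALSE))
}
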