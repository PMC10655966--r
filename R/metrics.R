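#' Area under the precision-recall curve
#'
#' Step integration of the precision-recall curve (no trapezoids): scores
#' are scanned from the most to the least confident threshold, and each
#' increment of recall contributes the precision at that threshold —
#' equivalent to average precision.
#'
#' @param labels binary vector (1 = positive class, 0 = negative).
#' @param scores numeric scores, larger meaning more confidently positive.
#' @return AUPRC in `[0, 1]`.
#' @export
auprc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores), length(labels) > 0)
  labels <- as.integer(labels)
  P <- sum(labels == 1L)
  if (P == 0L || P == length(labels)) {
    stop("AUPRC undefined error: labels contain a single class")
  }
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]
  sc <- scores[o]
  grp_end <- c(which(diff(sc) != 0), length(sc))  # threshold groups (ties together)
  tp <- cumsum(lab)[grp_end]
  np <- grp_end
  prec <- tp / np
  dtp <- diff(c(0L, tp))
  sum(prec * dtp) / P
}

#' Mean absolute error
#' @param truth,predicted numeric vectors.
#' @return MAE.
#' @export
mae <- function(truth, predicted) mean(abs(predicted - truth))

#' Root mean squared error
#' @param truth,predicted numeric vectors.
#' @return RMSE.
#' @export
rmse <- function(truth, predicted) sqrt(mean((predicted - truth)^2))

#' Mean signed error (bias)
#'
#' Positive values mean over-estimation, negative under-estimation.
#'
#' @param truth,predicted numeric vectors.
#' @return Mean of `predicted - truth`.
#' @export
bias <- function(truth, predicted) mean(predicted - truth)

#' Welch's unequal-variance two-sample t-test
#'
#' The test statistic `t = (mean(a) - mean(b)) / sqrt(va/na + vb/nb)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value.
#'
#' @param a,b numeric samples.
#' @return A list: `t`, `df`, `p`.
#' @export
welch_t <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  se2 <- va + vb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Evaluation metrics for one model/scenario
#'
#' @param truth label vector (binary for classification; natural-scale
#'   values for regression).
#' @param predicted for classification, positive-class scores; for
#'   regression, point estimates.
#' @param task the task name (see [network_spec()]).
#' @return A `metrics_report` list: `task`, `n`, and `auprc` or
#'   `mae`/`rmse`/`bias`, plus the per-example predictions.
#' @export
metrics_report <- function(truth, predicted, task) {
  out <- list(task = task, n = length(truth),
              predictions = data.frame(truth = truth, predicted = predicted))
  if (task == "sweep_classification") {
    out$auprc <- auprc(truth, predicted)
  } else {
    out$mae <- mae(truth, predicted)
    out$rmse <- rmse(truth, predicted)
    out$bias <- bias(truth, predicted)
  }
  structure(out, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  if (!is.null(x$auprc)) {
    cat(sprintf("<metrics_report> %s: n = %d, AUPRC = %.4f\n", x$task, x$n, x$auprc))
  } else {
    cat(sprintf("<metrics_report> %s: n = %d, MAE = %.4g, RMSE = %.4g, bias = %.4g\n",
                x$task, x$n, x$mae, x$rmse, x$bias))
  }
  invisible(x)
}
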