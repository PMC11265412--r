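#' Confusion-matrix metrics for qualitative phenotype validation
#'
#' Accuracy, precision, sensitivity, F-score and false-positive rate from
#' true/false positive/negative counts. Percentages are on the 0-100 scale,
#' F-score on 0-1. The positive-class polarity (growth vs auxotrophy) is the
#' caller's declaration — each validation mode must state which outcome
#' counts as positive.
#'
#' @param tp,fp,tn,fn Non-negative integer counts, total > 0.
#' @return Tibble with one row: `accuracy_pct`, `precision_pct`,
#'   `sensitivity_pct`, `f_score`, `fpr_pct` plus the four counts. A metric
#'   whose denominator is zero is `NA` (undefined), never 0.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  stopifnot(all(counts >= 0), sum(counts) > 0)
  div <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- div(tp, tp + fp)
  sensitivity <- div(tp, tp + fn)
  f_score <- if (is.na(precision) || is.na(sensitivity) ||
                 precision + sensitivity == 0) NA_real_ else
    2 * precision * sensitivity / (precision + sensitivity)
  tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    accuracy_pct = 100 * (tp + tn) / sum(counts),
    precision_pct = 100 * precision,
    sensitivity_pct = 100 * sensitivity,
    f_score = f_score,
    fpr_pct = 100 * div(fp, fp + tn))
}

#' Failure rate of phenotype predictions
#'
#' @param n_failed,n_total Counts with `0 <= n_failed <= n_total`,
#'   `n_total > 0`.
#' @return Percent failed, reported to one decimal.
#' @export
failure_rate <- function(n_failed, n_total) {
  stopifnot(n_total > 0, n_failed >= 0, n_failed <= n_total)
  round(100 * n_failed / n_total, 1)
}

#' Quantitative growth-rate validation metrics
#'
#' Mean absolute percentage error, root mean squared error and Pearson
#' correlation between predicted and observed growth rates.
#'
#' @param predictions,observations Paired numeric vectors of equal length
#'   (at least 2); observations must be positive for MAPE.
#' @return Tibble with one row: `mape_pct`, `rmse`, `pearson_r` (`NA` with a
#'   warning when either vector is constant).
#' @export
quantitative_metrics <- function(predictions, observations) {
  stopifnot(length(predictions) == length(observations),
            length(predictions) >= 2, all(observations > 0))
  r <- if (stats::sd(predictions) < 1e-12 || stats::sd(observations) < 1e-12) {
    warning("constant vector; Pearson correlation undefined")
    NA_real_
  } else stats::cor(predictions, observations)
  tibble::tibble(
    mape_pct = 100 * mean(abs(predictions - observations) / observations),
    rmse = sqrt(mean((predictions - observations)^2)),
    pearson_r = r)
}
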