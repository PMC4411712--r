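#' Two-class confusion counts
#'
#' Tallies TP/FP/TN/FN for a TF-versus-rest evaluation. A positive prediction
#' means "called TF"; unclassifiable queries must be passed as `FALSE`
#' (they count as negative predictions).
#'
#' @param predicted logical vector of predicted TF flags.
#' @param truth logical vector of true TF flags, same length.
#' @return Named integer vector with elements `TP`, `FP`, `TN`, `FN`.
#' @examples
#' confusionCounts(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
#' @export
confusionCounts <- function(predicted, truth) {
  predicted <- as.logical(predicted)
  truth <- as.logical(truth)
  if (length(predicted) != length(truth))
    stop("'predicted' and 'truth' must have the same length")
  if (anyNA(predicted) || anyNA(truth))
    stop("flags must not contain NA; encode unclassifiable as FALSE")
  c(TP = sum(predicted & truth),
    FP = sum(predicted & !truth),
    TN = sum(!predicted & !truth),
    FN = sum(!predicted & truth))
}

#' Classifier performance measures from confusion counts
#'
#' Computes sensitivity TP/(TP+FN), specificity TN/(TN+FP), accuracy
#' (TP+TN)/(TP+TN+FP+FN), precision TP/(TP+FP) and the Matthews correlation
#' coefficient
#' (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
#'
#' A measure whose denominator is zero is reported as `NA` (undefined), not
#' as zero; the MCC with a zero factor in its denominator is reported as 0,
#' with the `mcc_defined` element set to `FALSE`.
#'
#' @param counts named vector as returned by [confusionCounts()].
#' @return Named list: `sensitivity`, `specificity`, `accuracy`, `precision`,
#'   `mcc` (numeric) and `mcc_defined` (logical).
#' @examples
#' classifierMetrics(c(TP = 50, FP = 10, TN = 30, FN = 10))
#' @export
classifierMetrics <- function(counts) {
  need <- c("TP", "FP", "TN", "FN")
  if (!all(need %in% names(counts)))
    stop("'counts' must contain TP, FP, TN and FN")
  tp <- as.numeric(counts[["TP"]]); fp <- as.numeric(counts[["FP"]])
  tn <- as.numeric(counts[["TN"]]); fn <- as.numeric(counts[["FN"]])
  if (any(c(tp, fp, tn, fn) < 0))
    stop("confusion counts must be non-negative")
  total <- tp + fp + tn + fn
  if (total == 0)
    stop("all confusion counts are zero; nothing was evaluated")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  mccDen <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mccDefined <- mccDen > 0
  list(sensitivity = ratio(tp, tp + fn),
       specificity = ratio(tn, tn + fp),
       accuracy    = (tp + tn) / total,
       precision   = ratio(tp, tp + fp),
       mcc         = if (mccDefined) (tp * tn - fp * fn) / sqrt(mccDen) else 0,
       mcc_defined = mccDefined)
}

#' Write a LOOCV performance curve as TSV
#'
#' @param curve data.frame as produced by [sisLoocv()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeMetricsTsv <- function(curve, path) {
  write.table(format(curve, digits = 15, scientific = FALSE, trim = TRUE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
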