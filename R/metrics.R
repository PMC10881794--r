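# Evaluation suite: Dice overlap, confusion-matrix diagnostics with
# likelihood ratios, ROC/AUC with Youden cutoff selection, and Dice
# distribution summaries.  The positive class is "malignant" (label 1)
# throughout.

#' Dice similarity coefficient between two binary masks
#'
#' `2|A∩B| / (|A| + |B|)`.  When both masks are empty the coefficient is
#' defined as 1 (two readers agreeing there is no lesion); the returned
#' value then carries the attribute `both_empty = TRUE`.
#'
#' @param pred,gt Binary (`{0,1}`) arrays of identical shape.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(pred, gt) {
  if (!identical(dim(pred) %||% length(pred), dim(gt) %||% length(gt)))
    stop("pred and gt masks must have the same shape")
  if (!is_binary(pred) || !is_binary(gt))
    stop("masks must be binary {0,1}")
  sa <- sum(pred)
  sb <- sum(gt)
  if (sa + sb == 0) return(structure(1, both_empty = TRUE))
  2 * sum(pred * gt) / (sa + sb)
}

#' Confusion counts for binary labels
#'
#' @param predicted,truth Equal-length vectors with values in `{0, 1}`;
#'   1 = malignant (positive class).
#' @return Object of class `confusion_counts` with fields `TP`, `FP`,
#'   `TN`, `FN`.
#' @export
confusion_counts <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("predicted and truth must have equal length")
  if (!is_binary(predicted) || !is_binary(truth))
    stop("labels must be 0 or 1")
  structure(list(TP = sum(predicted == 1 & truth == 1),
                 FP = sum(predicted == 1 & truth == 0),
                 TN = sum(predicted == 0 & truth == 0),
                 FN = sum(predicted == 0 & truth == 1)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion counts: TP=%d FP=%d TN=%d FN=%d (n=%d)\n",
              x$TP, x$FP, x$TN, x$FN, x$TP + x$FP + x$TN + x$FN))
  invisible(x)
}

#' Diagnostic test metrics from confusion counts
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy
#' `(TP+TN)/total`, PPV `TP/(TP+FP)`, NPV `TN/(TN+FN)`, and the likelihood
#' ratios `+LR = Sen/(1-Spe)`, `-LR = (1-Sen)/Spe`.  A metric whose
#' denominator is zero is reported as `NA` and listed in the `undefined`
#' field rather than silently returned as 0.
#'
#' @param counts A [confusion_counts()] object (or a list with `TP`, `FP`,
#'   `TN`, `FN`).
#' @return Object of class `diagnostic_metrics`: proportions `sen`, `spe`,
#'   `acc`, `ppv`, `npv`, ratios `plr`, `nlr`, the input `counts`, and
#'   `undefined` (character vector of metrics with zero denominators).
#' @export
diagnostic_metrics <- function(counts) {
  tp <- counts$TP; fp <- counts$FP; tn <- counts$TN; fn <- counts$FN
  total <- tp + fp + tn + fn
  if (total <= 0) stop("confusion counts sum to zero")
  undef <- character()
  ratio <- function(num, den, name) {
    if (den == 0) { undef <<- c(undef, name); return(NA_real_) }
    num / den
  }
  sen <- ratio(tp, tp + fn, "sen")
  spe <- ratio(tn, tn + fp, "spe")
  acc <- (tp + tn) / total
  ppv <- ratio(tp, tp + fp, "ppv")
  npv <- ratio(tn, tn + fn, "npv")
  lr <- likelihood_ratios(sen, spe)
  structure(list(sen = sen, spe = spe, acc = acc, ppv = ppv, npv = npv,
                 plr = lr[["plr"]], nlr = lr[["nlr"]],
                 counts = counts, undefined = undef),
            class = "diagnostic_metrics")
}

#' @export
print.diagnostic_metrics <- function(x, digits = 2L, ...) {
  pct <- function(v) if (is.na(v)) "undefined" else
    sprintf(paste0("%.", digits, "f%%"), 100 * v)
  num <- function(v) if (is.na(v)) "undefined" else
    if (is.infinite(v)) "Inf" else sprintf(paste0("%.", digits, "f"), v)
  cat(sprintf("Sen %s  Spe %s  Acc %s  PPV %s  NPV %s  +LR %s  -LR %s\n",
              pct(x$sen), pct(x$spe), pct(x$acc), pct(x$ppv), pct(x$npv),
              num(x$plr), num(x$nlr)))
  invisible(x)
}

#' Positive and negative likelihood ratios
#'
#' `+LR = Sen / (1 - Spe)` and `-LR = (1 - Sen) / Spe`.  A ratio with a
#' zero denominator and nonzero numerator is `Inf` (the conventional
#' reading for a perfectly specific or perfectly insensitive test); `0/0`
#' is `NA`.
#'
#' @param sen,spe Sensitivity and specificity as proportions in `[0, 1]`.
#' @return Named numeric vector `c(plr = , nlr = )`.
#' @export
likelihood_ratios <- function(sen, spe) {
  stopifnot(is.na(sen) || (sen >= 0 && sen <= 1),
            is.na(spe) || (spe >= 0 && spe <= 1))
  safe <- function(num, den) {
    if (is.na(num) || is.na(den)) NA_real_
    else if (den > 0) num / den
    else if (num > 0) Inf
    else NA_real_
  }
  c(plr = safe(sen, 1 - spe), nlr = safe(1 - sen, spe))
}

#' ROC curve and area under the curve
#'
#' Sweeps every distinct score as a threshold (prediction is positive when
#' `score >= threshold`), grouping tied scores, and reports the operating
#' points `(1 - specificity, sensitivity)` from `(0, 0)` to `(1, 1)`.  The
#' AUC is computed by the trapezoidal rule, which on tie-grouped points
#' equals the Mann-Whitney concordance probability.
#'
#' @param scores Numeric vector of malignancy scores (higher = more
#'   malignant).
#' @param labels Binary reference labels, 1 = malignant.
#' @return Object of class `roc_result`: `curve` (data frame with
#'   `threshold`, `fpr`, `sen`, `spe`) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length")
  if (!is_binary(labels)) stop("labels must be 0 or 1")
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0)
    stop("AUC is undefined when only one class is present")
  thr <- sort(unique(scores), decreasing = TRUE)
  sen <- vapply(thr, function(t) sum(scores >= t & labels == 1), 0) / npos
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0), 0) / nneg
  curve <- data.frame(threshold = c(Inf, thr),
                      fpr = c(0, fpr), sen = c(0, sen),
                      spe = 1 - c(0, fpr))
  auc <- sum(diff(curve$fpr) * (utils::head(curve$sen, -1) +
                                  utils::tail(curve$sen, -1)) / 2)
  structure(list(curve = curve, auc = auc), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC with %d operating points, AUC = %.3f\n",
              nrow(x$curve), x$auc))
  invisible(x)
}

#' Choose a classification cutoff on an ROC curve
#'
#' Selects the threshold maximising Youden's `J = Sen + Spe - 1`; ties are
#' broken toward higher specificity (and then toward the higher threshold).
#'
#' @param roc A `roc_result` from [roc_auc()], or its `curve` data frame.
#' @return A list with the chosen `threshold` and its `sen`, `spe`, `j`.
#' @export
choose_cutoff <- function(roc) {
  curve <- if (inherits(roc, "roc_result")) roc$curve else roc
  j <- curve$sen + curve$spe - 1
  best <- which(j == max(j))
  best <- best[order(-curve$spe[best], -curve$threshold[best])][1L]
  list(threshold = curve$threshold[best], sen = curve$sen[best],
       spe = curve$spe[best], j = j[best])
}

#' Summarise a distribution of per-case Dice coefficients
#'
#' Median and quartiles by the linear-interpolation (type 7) convention,
#' plus the box-plot-ready five-number summary.
#'
#' @param values Non-empty numeric vector of Dice coefficients in
#'   `[0, 1]`.
#' @return Object of class `dice_summary`: `median`, `lower_quartile`,
#'   `upper_quartile`, `five_number` (min/Q1/median/Q3/max), `n`, and the
#'   per-case `values`.
#' @export
summarize_dice <- function(values) {
  if (length(values) == 0L) stop("cannot summarise an empty Dice list")
  if (any(values < 0 | values > 1)) stop("Dice values must lie in [0, 1]")
  q <- unname(stats::quantile(values, c(0, 0.25, 0.5, 0.75, 1), type = 7))
  structure(list(median = q[3L], lower_quartile = q[2L],
                 upper_quartile = q[4L],
                 five_number = c(min = q[1L], q1 = q[2L], median = q[3L],
                                 q3 = q[4L], max = q[5L]),
                 n = length(values), values = values),
            class = "dice_summary")
}

#' @export
print.dice_summary <- function(x, ...) {
  cat(sprintf("Dice over %d cases: median %.3f (IQR %.3f-%.3f, range %.3f-%.3f)\n",
              x$n, x$median, x$lower_quartile, x$upper_quartile,
              x$five_number["min"], x$five_number["max"]))
  invisible(x)
}
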