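# Segmentation-quality metrics: confusion counts, precision/recall/TNR/
# accuracy, F1, Dice and precision-recall tabulation.

#' Pixelwise confusion counts
#'
#' @param pred Logical matrix, predicted segmentation.
#' @param truth Logical matrix, ground truth, same shape.
#' @return Named integer vector `c(tp, fp, fn, tn)`; the four counts
#'   partition the image (`tp + fp + fn + tn` equals the pixel count).
#' @export
confusion <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth))) {
    stop("`pred` and `truth` must have the same shape", call. = FALSE)
  }
  p <- as.logical(pred)
  t <- as.logical(truth)
  c(tp = sum(p & t), fp = sum(p & !t), fn = sum(!p & t), tn = sum(!p & !t))
}

#' Segmentation quality metrics from confusion counts
#'
#' Precision `tp/(tp+fp)` (how much of the segmented region matches truth),
#' recall `tp/(tp+fn)` (how much of the truth was found), true negative rate
#' `tn/(tn+fp)` (how much of the background is correctly ignored), accuracy
#' `(tp+tn)/total`, and the F1 score. A metric with a zero denominator is
#' reported as 0 and its name recorded in the `"undefined"` attribute, with
#' a warning, so batch tables stay numeric.
#'
#' @param counts Named vector from [confusion()], or a logical `pred`
#'   matrix when `truth` is given.
#' @param truth Optional ground-truth matrix; when supplied, `counts` is
#'   treated as the prediction and [confusion()] is called first.
#' @return Named list `precision`, `recall`, `tnr`, `accuracy`, `f1`, each
#'   in `[0, 1]`, with attribute `undefined` (character vector).
#' @export
seg_metrics <- function(counts, truth = NULL) {
  if (!is.null(truth)) counts <- confusion(counts, truth)
  stopifnot(all(c("tp", "fp", "fn", "tn") %in% names(counts)))
  tp <- counts[["tp"]]; fp <- counts[["fp"]]
  fn <- counts[["fn"]]; tn <- counts[["tn"]]
  undefined <- character(0)
  safe_div <- function(num, den, name) {
    if (den == 0) {
      undefined <<- c(undefined, name)
      0
    } else {
      num / den
    }
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  tnr <- safe_div(tn, tn + fp, "tnr")
  accuracy <- safe_div(tp + tn, tp + fp + fn + tn, "accuracy")
  f1 <- f1_score(precision, recall)
  if (length(undefined) > 0) {
    warning("undefined metrics reported as 0: ",
            paste(undefined, collapse = ", "), call. = FALSE)
  }
  structure(list(precision = precision, recall = recall, tnr = tnr,
                 accuracy = accuracy, f1 = f1),
            undefined = undefined)
}

#' F1 score
#'
#' Harmonic mean of precision and recall,
#' \eqn{F_1 = 2 P R / (P + R)}, with the convention \eqn{F_1 = 0} when
#' \eqn{P + R = 0}.
#'
#' @param precision,recall Numbers in `[0, 1]`.
#' @return A number in `[0, 1]`.
#' @export
f1_score <- function(precision, recall) {
  stopifnot(precision >= 0, precision <= 1, recall >= 0, recall <= 1)
  if (precision + recall == 0) {
    return(0)
  }
  2 * precision * recall / (precision + recall)
}

#' Dice overlap coefficient
#'
#' \eqn{2 |A \cap B| / (|A| + |B|)}; 1 for identical nonempty masks, and by
#' convention 1 when both masks are empty.
#'
#' @param pred,truth Logical matrices of the same shape.
#' @return A number in `[0, 1]`.
#' @export
dice <- function(pred, truth) {
  stopifnot(all(dim(pred) == dim(truth)))
  denom <- sum(pred) + sum(truth)
  if (denom == 0) {
    return(1)
  }
  2 * sum(pred & truth) / denom
}

#' Precision-recall table with banded summaries
#'
#' Tabulates (precision, recall) pairs from a batch of metric sets for
#' plotting, and summarizes each measure into the bands `[0.9, 1]`,
#' `[0.8, 0.9)`, `[0.7, 0.8)`, `[0.6, 0.7)`, `[0.5, 0.6)` and `< 0.5`; the
#' band shares always sum to 100%.
#'
#' @param results Nonempty list of metric sets from [seg_metrics()] (or any
#'   lists with `precision` and `recall` elements).
#' @return Data frame with columns `precision` and `recall`, one row per
#'   result, plus an attribute `bands`: a data frame of `band`,
#'   `precision_share`, `recall_share` (percentages).
#' @export
pr_table <- function(results) {
  if (length(results) == 0) {
    tab <- data.frame(precision = numeric(0), recall = numeric(0))
    attr(tab, "bands") <- data.frame(band = character(0),
                                     precision_share = numeric(0),
                                     recall_share = numeric(0))
    return(tab)
  }
  tab <- data.frame(
    precision = vapply(results, function(r) r$precision, 0),
    recall = vapply(results, function(r) r$recall, 0)
  )
  cuts <- c(-Inf, 0.5, 0.6, 0.7, 0.8, 0.9, Inf)
  labels <- c("<0.50", ">=0.50", ">=0.60", ">=0.70", ">=0.80", ">=0.90")
  share <- function(x) {
    100 * as.vector(table(cut(x, cuts, labels = labels, right = FALSE))) /
      length(x)
  }
  attr(tab, "bands") <- data.frame(
    band = rev(labels),
    precision_share = rev(share(tab$precision)),
    recall_share = rev(share(tab$recall))
  )
  tab
}
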