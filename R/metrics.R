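# Pixel-wise confusion counts and the five overlap metrics used to score a
# predicted mask against ground truth.

#' Confusion counts between a predicted and a ground-truth mask
#'
#' @param pred,truth 0/1 matrices of equal shape.
#' @return A list with integer fields `tp`, `tn`, `fp`, `fn`; they sum to
#'   the pixel count.
#' @export
confusion_counts <- function(pred, truth) {
  pred <- validate_mask(pred)
  truth <- validate_mask(truth)
  if (!identical(dim(pred), dim(truth))) {
    stop("pred and truth must share a shape", call. = FALSE)
  }
  list(tp = sum(pred == 1L & truth == 1L),
       tn = sum(pred == 0L & truth == 0L),
       fp = sum(pred == 1L & truth == 0L),
       fn = sum(pred == 0L & truth == 1L))
}

#' Overlap metrics from confusion counts
#'
#' Computes the Dice similarity coefficient `2TP / (2TP + FP + FN)`,
#' accuracy `(TP + TN) / (TP + TN + FP + FN)`, specificity
#' `TN / (TN + FP)`, Jaccard index `TP / (TP + FP + FN)` and F1 score
#' `2TP / (2TP + FP + FN)`. As defined on pixel counts the F1 score and
#' the Dice coefficient coincide identically, and
#' `dsc = 2 * jaccard / (1 + jaccard)`.
#'
#' A metric whose denominator is zero (e.g. specificity when the truth has
#' no background) is reported as `NA` rather than coerced to 0 or 1, so
#' averages over image sets are not silently corrupted.
#'
#' @param counts A list with `tp`, `tn`, `fp`, `fn` (see
#'   [confusion_counts()]); at least one count must be positive.
#' @return A list with fields `dsc`, `accuracy`, `specificity`, `jaccard`,
#'   `f1`, each in \[0, 1\] or `NA`.
#' @export
compute_metrics <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  if (any(c(tp, tn, fp, fn) < 0)) stop("counts must be non-negative",
                                       call. = FALSE)
  if (tp + tn + fp + fn == 0) stop("all confusion counts are zero",
                                   call. = FALSE)
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  dsc <- safe_div(2 * tp, 2 * tp + fp + fn)
  list(dsc = dsc,
       accuracy = safe_div(tp + tn, tp + tn + fp + fn),
       specificity = safe_div(tn, tn + fp),
       jaccard = safe_div(tp, tp + fp + fn),
       f1 = dsc)
}

#' Score one or more predicted masks against ground truth
#'
#' Convenience wrapper producing a data frame with one row per mask pair
#' and, when there is more than one pair, a final `"mean"` row with the
#' arithmetic mean of each metric (`NA` values excluded).
#'
#' @param pred,truth A 0/1 matrix each, or lists of matched matrices.
#' @param names Optional row labels.
#' @return A data frame with columns `image`, `dsc`, `accuracy`,
#'   `specificity`, `jaccard`, `f1`.
#' @export
metrics_table <- function(pred, truth, names = NULL) {
  if (is.matrix(pred)) pred <- list(pred)
  if (is.matrix(truth)) truth <- list(truth)
  if (length(pred) != length(truth)) {
    stop("pred and truth lists must have equal length", call. = FALSE)
  }
  if (is.null(names)) names <- sprintf("image%02d", seq_along(pred))
  rows <- mapply(function(p, g) {
    unlist(compute_metrics(confusion_counts(p, g)))
  }, pred, truth, SIMPLIFY = FALSE)
  tab <- data.frame(image = names, do.call(rbind, rows),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (length(rows) > 1L) {
    means <- colMeans(tab[, -1L, drop = FALSE], na.rm = TRUE)
    tab <- rbind(tab, data.frame(image = "mean", t(means)))
  }
  tab
}
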