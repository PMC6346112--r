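#' Confusion counts with mirtron as the positive class
#'
#' @param true_labels,predicted_labels Vectors (character or factor) of equal
#'   length over `{canonical, mirtron}`. Mirtron is the positive class
#'   throughout the package, so `tp` counts mirtrons predicted as mirtrons
#'   and `tn` canonical records predicted canonical.
#' @return A list of class `confusion_counts` with integer fields `tp`, `tn`,
#'   `fp`, `fn`.
#' @examples
#' confusion(c("mirtron", "mirtron", "canonical"),
#'           c("mirtron", "canonical", "canonical"))
#' @export
confusion <- function(true_labels, predicted_labels) {
  if (length(true_labels) != length(predicted_labels)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  if (length(true_labels) < 1) {
    stop("need at least one record", call. = FALSE)
  }
  truth <- factor(as.character(true_labels), levels = class_levels())
  pred <- factor(as.character(predicted_labels), levels = class_levels())
  if (anyNA(truth) || anyNA(pred)) {
    stop("labels must be 'canonical' or 'mirtron'", call. = FALSE)
  }
  pos <- "mirtron"
  confusion_counts(
    tp = sum(truth == pos & pred == pos),
    tn = sum(truth != pos & pred != pos),
    fp = sum(truth != pos & pred == pos),
    fn = sum(truth == pos & pred != pos)
  )
}

#' @rdname confusion
#' @param tp,tn,fp,fn Nonnegative integer counts.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  structure(as.list(as.integer(counts)) |> stats::setNames(names(counts)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("Confusion counts (positive = mirtron): tp", x$tp, "tn", x$tn,
      "fp", x$fp, "fn", x$fn, "\n")
  invisible(x)
}

safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' The five confusion-matrix measures
#'
#' Direct evaluation of the standard formulas with mirtron as the positive
#' class:
#' sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`,
#' F1 `2*tp/(2*tp+fp+fn)`,
#' MCC `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`,
#' accuracy `(tp+tn)/(tp+tn+fp+fn)`.
#' A measure whose denominator is zero is reported as `NA` (rather than
#' coerced to 0) so degenerate predictors stay visible.
#'
#' @param counts A `confusion_counts` object.
#' @return A one-row tibble: `sensitivity`, `specificity`, `f1`, `mcc`,
#'   `accuracy` (full precision; round for display).
#' @examples
#' compute_metrics(confusion_counts(tp = 9, fn = 1, tn = 8, fp = 2))
#' @export
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  total <- tp + tn + fp + fn
  if (total == 0) stop("all counts are zero", call. = FALSE)
  mcc_den <- sqrt(as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  tibble::tibble(
    sensitivity = safe_ratio(tp, tp + fn),
    specificity = safe_ratio(tn, tn + fp),
    f1 = safe_ratio(2 * tp, 2 * tp + fp + fn),
    mcc = if (mcc_den == 0) NA_real_ else {
      (as.numeric(tp) * tn - as.numeric(fp) * fn) / mcc_den
    },
    accuracy = (tp + tn) / total
  )
}

#' Render a comparison table across model variants
#'
#' Stacks one-row metrics tibbles into the usual
#' model-by-measure comparison matrix, rounded to 3 decimals for display.
#'
#' @param ... Named one-row metrics tibbles (names become the `model`
#'   column), or a single named list of them.
#' @param digits Rounding for display (default 3); use `NA` for full
#'   precision.
#' @return A tibble with a `model` column followed by the five measures.
#' @export
compare_models <- function(..., digits = 3) {
  inputs <- list(...)
  if (length(inputs) == 1 && is.list(inputs[[1]]) &&
      !is.data.frame(inputs[[1]])) {
    inputs <- inputs[[1]]
  }
  stopifnot(length(inputs) >= 1, !is.null(names(inputs)))
  out <- dplyr::bind_rows(inputs, .id = "model")
  if (!is.na(digits)) {
    out <- dplyr::mutate(out, dplyr::across(dplyr::where(is.numeric),
                                            ~ round(.x, digits)))
  }
  out
}
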