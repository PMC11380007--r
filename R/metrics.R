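#' Confusion counts
#'
#' @param tp,fp,tn,fn Non-negative integer counts; at least one must be
#'   positive.
#' @return A list of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) < 1) stop("at least one count must be positive")
  structure(as.list(counts), class = "confusion_counts")
}

#' Classification metrics from a binary confusion matrix
#'
#' Computes the six standard indicators as percentages: specificity
#' `TN/(TN+FP)`, sensitivity `TP/(TP+FN)`, accuracy, precision
#' `TP/(TP+FP)`, Matthews correlation coefficient
#' `(TP TN - FP FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, and the F1
#' score `2 P S / (P + S)`. Metrics with a zero denominator are returned
#' as `NA` (flagged undefined).
#'
#' @param counts A [confusion_counts()] object.
#' @param literal_form If `TRUE`, the MCC uses the variant
#'   form `TP*TN - TP*FN` with no square root in the denominator, kept
#'   for comparison against sources printing that corrupted formula.
#' @return Named numeric vector (percent scale): `specificity`,
#'   `sensitivity`, `accuracy`, `precision`, `mcc`, `f1`.
#' @examples
#' classification_metrics(confusion_counts(tp = 9, fp = 2, tn = 8, fn = 1))
#' @export
classification_metrics <- function(counts, literal_form = FALSE) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  specificity <- 100 * safe_div(tn, tn + fp)
  sensitivity <- 100 * safe_div(tp, tp + fn)
  accuracy <- 100 * safe_div(tp + tn, tp + tn + fp + fn)
  precision <- 100 * safe_div(tp, tp + fp)
  den2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (literal_form) {
    100 * safe_div(tp * tn - tp * fn, den2)
  } else {
    100 * safe_div(tp * tn - fp * fn, sqrt(den2))
  }
  f1 <- if (is.na(precision) || is.na(sensitivity) ||
            precision + sensitivity == 0) {
    NA_real_
  } else {
    2 * precision * sensitivity / (precision + sensitivity)
  }
  c(specificity = specificity, sensitivity = sensitivity,
    accuracy = accuracy, precision = precision, mcc = mcc, f1 = f1)
}

#' One-vs-rest confusion counts and metrics from label vectors
#'
#' For a multiclass problem each class is scored against the rest,
#' yielding per-class confusion counts, per-class metrics, and their
#' macro average (unweighted mean over classes).
#'
#' @param predicted,truth Integer labels in `1..n_classes`.
#' @param n_classes Number of classes.
#' @return List with `per_class` (data frame of counts + metrics, one
#'   row per class), `macro` (named vector of macro-averaged metrics),
#'   and `accuracy` (overall percent correct).
#' @export
multiclass_report <- function(predicted, truth, n_classes) {
  if (length(predicted) != length(truth)) stop("label vectors differ in length")
  rows <- lapply(seq_len(n_classes), function(j) {
    tp <- sum(predicted == j & truth == j)
    fp <- sum(predicted == j & truth != j)
    fn <- sum(predicted != j & truth == j)
    tn <- sum(predicted != j & truth != j)
    m <- classification_metrics(confusion_counts(tp, fp, tn, fn))
    data.frame(class = j, tp = tp, fp = fp, tn = tn, fn = fn, t(m))
  })
  per_class <- do.call(rbind, rows)
  macro <- colMeans(per_class[, c("specificity", "sensitivity", "accuracy",
                                  "precision", "mcc", "f1")], na.rm = TRUE)
  list(
    per_class = per_class,
    macro = macro,
    accuracy = 100 * mean(predicted == truth)
  )
}

#' Cost of standard versus depthwise-separable convolution
#'
#' For a layer with `d_in` input channels, `d_out` output channels, an
#' `out_h` by `out_w` output map and a `k` by `k` kernel, the standard
#' convolution costs `Z_N = d_in d_out out_h out_w k^2` multiplications
#' while the separable factorisation (per-channel spatial filtering plus
#' 1x1 channel mixing) costs `Z_s = d_out (k^2 + d_in) out_h out_w`.
#' Their ratio `k^2 d_in / (k^2 + d_in)` quantifies the saving and
#' approaches `k^2` as `d_in` grows.
#'
#' @param d_in,d_out Input/output channel counts (positive integers).
#' @param out_h,out_w Output feature map size.
#' @param kernel Kernel side length k.
#' @return Named list `z_standard`, `z_separable`, `ratio`.
#' @examples
#' separable_cost(d_in = 64, d_out = 128, out_h = 56, out_w = 56, kernel = 3)
#' @export
separable_cost <- function(d_in, d_out, out_h = 1, out_w = 1, kernel = 3) {
  dims <- c(d_in, d_out, out_h, out_w, kernel)
  if (any(dims < 1)) stop("all dimensions must be positive")
  z_standard <- d_in * d_out * out_h * out_w * kernel^2
  z_separable <- d_out * (kernel^2 + d_in) * out_h * out_w
  list(z_standard = z_standard, z_separable = z_separable,
       ratio = kernel^2 * d_in / (kernel^2 + d_in))
}

#' Metrics table from a CSV of per-class confusion counts
#'
#' Reads a CSV with columns `tp,fp,tn,fn` (one row per class, optional
#' `class` column) and returns per-class and macro metric rows.
#'
#' @param path CSV path.
#' @return Data frame: one row per class plus a `macro` row, metric
#'   columns in percent.
#' @export
metrics_from_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("tp", "fp", "tn", "fn")
  names(df) <- tolower(names(df))
  if (!all(needed %in% names(df))) {
    stop("CSV must have columns tp, fp, tn, fn (line 1: header)")
  }
  if (any(df[needed] < 0)) stop("negative counts in confusion CSV")
  rows <- lapply(seq_len(nrow(df)), function(i) {
    m <- classification_metrics(
      confusion_counts(df$tp[i], df$fp[i], df$tn[i], df$fn[i])
    )
    cls <- if ("class" %in% names(df)) as.character(df$class[i]) else as.character(i)
    data.frame(class = cls, t(m))
  })
  out <- do.call(rbind, rows)
  macro <- colMeans(out[, -1], na.rm = TRUE)
  rbind(out, data.frame(class = "macro", t(macro)))
}
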