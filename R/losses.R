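#' Row-wise softmax
#'
#' Max-shifted for numerical stability.
#'
#' @param logits n-by-K numeric matrix of class scores.
#' @return n-by-K matrix of probabilities; rows sum to 1.
#' @export
softmax <- function(logits) {
  logits <- as.matrix(logits)
  if (!all(is.finite(logits))) stop("logits must be finite")
  shifted <- logits - apply(logits, 1, max)
  e <- exp(shifted)
  e / rowSums(e)
}

# probability floor applied inside every logarithm so saturated
# predictions cannot produce -Inf
.prob_floor <- 1e-12

check_batch <- function(logits, onehots) {
  if (!identical(dim(as.matrix(logits)), dim(as.matrix(onehots)))) {
    stop("logits and one-hot targets must have the same shape")
  }
  oh <- as.matrix(onehots)
  if (any(rowSums(oh) != 1) || !all(oh %in% c(0, 1))) {
    stop("targets must be one-hot rows")
  }
  oh
}

#' Cross-entropy loss
#'
#' `-sum_rows z . ln V(y)` with `V` the softmax of the logits.
#'
#' @param logits n-by-K matrix of class scores.
#' @param onehots n-by-K 0/1 matrix, exactly one 1 per row.
#' @param reduction `"sum"` (default, the printed form) or `"mean"`.
#' @return A non-negative scalar.
#' @export
cross_entropy <- function(logits, onehots, reduction = c("sum", "mean")) {
  reduction <- match.arg(reduction)
  oh <- check_batch(logits, onehots)
  p <- pmax(softmax(logits), .prob_floor)
  per_row <- -rowSums(oh * log(p))
  if (reduction == "sum") sum(per_row) else mean(per_row)
}

#' Weighted cross-entropy loss
#'
#' Cross-entropy with a per-class weight vector emphasising selected
#' categories: `-sum_rows z . (w * ln V(y))`.
#'
#' @inheritParams cross_entropy
#' @param weights Non-negative K-vector of class weights.
#' @return A non-negative scalar.
#' @export
weighted_cross_entropy <- function(logits, onehots, weights,
                                   reduction = c("sum", "mean")) {
  reduction <- match.arg(reduction)
  oh <- check_batch(logits, onehots)
  if (length(weights) != ncol(oh)) stop("weights length must equal n_classes")
  if (any(weights < 0)) stop("weights must be non-negative")
  p <- pmax(softmax(logits), .prob_floor)
  w <- matrix(weights, nrow(oh), ncol(oh), byrow = TRUE)
  per_row <- -rowSums(oh * w * log(p))
  if (reduction == "sum") sum(per_row) else mean(per_row)
}

#' Focal loss
#'
#' Cross-entropy modulated by `(1 - V(y))^exponent`, down-weighting
#' confidently classified (easy) examples; `exponent = 0` recovers plain
#' cross-entropy.
#'
#' @inheritParams cross_entropy
#' @param exponent Non-negative focusing exponent.
#' @return A non-negative scalar.
#' @export
focal_loss <- function(logits, onehots, exponent = 2,
                       reduction = c("sum", "mean")) {
  reduction <- match.arg(reduction)
  if (exponent < 0) stop("exponent must be non-negative")
  oh <- check_batch(logits, onehots)
  p <- pmax(softmax(logits), .prob_floor)
  per_row <- -rowSums(oh * (1 - p)^exponent * log(p))
  if (reduction == "sum") sum(per_row) else mean(per_row)
}

#' Per-class recall (actual positive ratio)
#'
#' `TV_j` = correctly predicted samples of class j / true count of
#' class j. Classes with zero true count get `NA` (flagged undefined).
#'
#' @param predicted,truth Integer labels in `1..n_classes`.
#' @param n_classes Number of classes.
#' @return Numeric vector of length `n_classes` in `[0, 1]` (or `NA`).
#' @export
per_class_recall <- function(predicted, truth, n_classes) {
  if (length(predicted) != length(truth)) stop("label vectors differ in length")
  if (any(c(predicted, truth) < 1) || any(c(predicted, truth) > n_classes)) {
    stop("labels must lie in 1..n_classes")
  }
  vapply(seq_len(n_classes), function(j) {
    support <- sum(truth == j)
    if (support == 0) return(NA_real_)
    sum(predicted == j & truth == j) / support
  }, 0)
}

#' Per-class error ratios
#'
#' `Mr_j = 1 - TV_j`: the misclassification proportion of each class,
#' the quantity driving the dynamic class weights.
#'
#' @param recall Recall vector from [per_class_recall()] (entries in
#'   `[0, 1]` or `NA`).
#' @return `1 - recall`, elementwise.
#' @export
error_ratios <- function(recall) {
  finite <- recall[!is.na(recall)]
  if (any(finite < 0) || any(finite > 1)) stop("recall entries must be in [0, 1]")
  1 - recall
}

#' Scalar transforms for the dynamic weighting scheme
#'
#' The error ratio of each class is passed through a monotone transform
#' before normalisation, amplifying (or damping) the emphasis on poorly
#' learned classes. Available transforms: `identity` (y), `ten_y`
#' (10 y), `cube` (y^3), `exp_y` (e^y), `exp_100y` (e^(100 y)), and
#' `ten_pow_y` (10^y, the alternative reading of "10y").
#'
#' @param name Transform name.
#' @param x Numeric input (vectorized).
#' @return Transformed values.
#' @export
alpha_transform <- function(name, x) {
  switch(name,
    identity = x,
    ten_y = 10 * x,
    cube = x^3,
    exp_y = exp(x),
    exp_100y = exp(100 * x),
    ten_pow_y = 10^x,
    stop("unknown transform '", name, "'; available: identity, ten_y, ",
         "cube, exp_y, exp_100y, ten_pow_y")
  )
}

#' Dynamic class weights from error ratios
#'
#' `w_j = alpha(Mr_j) / sum_i alpha(Mr_i)`: classes with larger current
#' error ratios receive larger loss weights (for monotone transforms).
#' Classes with undefined (`NA`) error ratios get weight 0 and the
#' remaining weights renormalise over the defined classes.
#'
#' @param mr Error-ratio vector from [error_ratios()].
#' @param transform Transform name for [alpha_transform()] (default
#'   `"identity"`).
#' @return Non-negative weight vector summing to 1.
#' @export
dynamic_class_weights <- function(mr, transform = "identity") {
  defined <- !is.na(mr)
  if (!any(defined)) stop("all error ratios undefined")
  a <- numeric(length(mr))
  a[defined] <- alpha_transform(transform, mr[defined])
  total <- sum(a[defined])
  if (total <= 0) stop("degenerate normalization: transformed error ratios sum to zero")
  a / total
}
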