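#' Specification of a synthetic tissue-like test image
#'
#' Describes a smooth correlated background texture with class-dependent
#' elliptical lesion blobs. The four classes mirror the label set of a
#' gastric-endoscopy classification task (NT non-tumorous, TA tubular
#' adenoma, MA mucosal adenocarcinoma, PA papillary adenocarcinoma), but
#' all statistics here are invented fixtures for exercising the
#' preprocessing and augmentation code; they make no claim of clinical
#' fidelity. NT images contain no lesions by definition.
#'
#' @param height,width Image size in pixels.
#' @param class One of `"NT"`, `"TA"`, `"MA"`, `"PA"`.
#' @param texture_scale Gaussian blur radius (pixels) of the background
#'   texture; larger values give smoother tissue.
#' @param lesion_rate Mean lesion count (Poisson); defaults per class:
#'   NT 0, TA 2, MA 4, PA 3.
#' @param lesion_size Length-2 range of lesion semi-axes in pixels.
#' @param lesion_contrast Additive peak intensity of a lesion.
#' @return A list of class `image_spec`.
#' @export
image_spec <- function(height = 64, width = 64,
                       class = c("NT", "TA", "MA", "PA"),
                       texture_scale = 4,
                       lesion_rate = NULL,
                       lesion_size = NULL,
                       lesion_contrast = NULL) {
  class <- match.arg(class)
  if (height < 1 || width < 1) stop("image dimensions must be positive")
  defaults <- list(
    NT = list(rate = 0, size = c(0, 0), contrast = 0),
    TA = list(rate = 2, size = c(3, 6), contrast = 0.15),
    MA = list(rate = 4, size = c(4, 8), contrast = 0.25),
    PA = list(rate = 3, size = c(6, 12), contrast = 0.35)
  )[[class]]
  if (is.null(lesion_rate)) lesion_rate <- defaults$rate
  if (is.null(lesion_size)) lesion_size <- defaults$size
  if (is.null(lesion_contrast)) lesion_contrast <- defaults$contrast
  if (class == "NT" && lesion_rate != 0) stop("NT images have no lesions")
  if (class != "NT" && (any(lesion_size < 0) || lesion_contrast < 0)) {
    stop("lesion parameters must be non-negative")
  }
  structure(
    list(height = as.integer(height), width = as.integer(width),
         class = class, texture_scale = texture_scale,
         lesion_rate = lesion_rate, lesion_size = lesion_size,
         lesion_contrast = lesion_contrast),
    class = "image_spec"
  )
}

# separable Gaussian blur with reflected edges (kernel truncated at 3 sigma)
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  blur_1d <- function(m) {
    n <- nrow(m)
    idx <- vapply(-r:r, function(o) reflect_index_r(seq_len(n) + o, n),
                  integer(n))
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) out <- out + k[j] * m[idx[, j], , drop = FALSE]
    out
  }
  t(blur_1d(t(blur_1d(img))))
}

#' Generate a synthetic tissue-like image
#'
#' A smoothed white-noise background rescaled to mid-gray, plus
#' class-dependent elliptical Gaussian lesion bumps. The lesion table is
#' attached as attribute `"lesions"`.
#'
#' @param spec An [image_spec()].
#' @param seed Optional integer seed; the output is fully determined by
#'   `(spec, seed)`.
#' @return Numeric matrix in `[0, 1]`.
#' @export
generate_image <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "image_spec"))
  if (!is.null(seed)) set.seed(seed)
  h <- spec$height; w <- spec$width
  noise <- matrix(rnorm(h * w), h, w)
  bg <- gaussian_blur(noise, spec$texture_scale)
  rng <- range(bg)
  bg <- if (diff(rng) > 0) (bg - rng[1]) / diff(rng) else matrix(0.5, h, w)
  img <- 0.25 + 0.4 * bg  # keep background inside [0.25, 0.65]

  n_lesions <- if (spec$lesion_rate > 0) rpois(1, spec$lesion_rate) else 0L
  lesions <- data.frame(row = numeric(0), col = numeric(0),
                        a = numeric(0), b = numeric(0),
                        angle = numeric(0), contrast = numeric(0))
  if (n_lesions > 0) {
    rows_g <- matrix(seq_len(h), h, w)
    cols_g <- matrix(seq_len(w), h, w, byrow = TRUE)
    for (i in seq_len(n_lesions)) {
      cy <- runif(1, 1, h); cx <- runif(1, 1, w)
      a <- runif(1, spec$lesion_size[1], spec$lesion_size[2])
      b <- runif(1, spec$lesion_size[1], spec$lesion_size[2])
      th <- runif(1, 0, pi)
      contrast <- spec$lesion_contrast * runif(1, 0.7, 1.3)
      u <- (rows_g - cy) * cos(th) + (cols_g - cx) * sin(th)
      v <- -(rows_g - cy) * sin(th) + (cols_g - cx) * cos(th)
      img <- img + contrast * exp(-0.5 * ((u / a)^2 + (v / b)^2))
      lesions <- rbind(lesions, data.frame(row = cy, col = cx, a = a, b = b,
                                           angle = th, contrast = contrast))
    }
  }
  img <- pmin(pmax(img, 0), 1)
  attr(img, "lesions") <- lesions
  attr(img, "class_label") <- spec$class
  img
}

#' Add noise to a unit-scale image
#'
#' Gaussian noise adds independent `N(0, sigma^2)` perturbations;
#' impulse (salt-and-pepper) noise replaces each pixel with 0 or 1
#' (equal odds) with probability `level`. The result is clipped to
#' `[0, 1]`.
#'
#' @param image Numeric matrix or array in `[0, 1]`.
#' @param model `"gaussian"` or `"impulse"`.
#' @param level Noise level: the standard deviation sigma (gaussian) or
#'   the corruption probability (impulse).
#' @param seed Optional integer seed.
#' @return Noisy image, clipped to `[0, 1]`.
#' @export
add_noise <- function(image, model = c("gaussian", "impulse"),
                      level = 0.08, seed = NULL) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  if (model == "gaussian") {
    if (level < 0) stop("sigma must be non-negative")
    out <- image + rnorm(length(image)) * level
  } else {
    if (level < 0 || level > 1) stop("impulse probability must be in [0, 1]")
    out <- image
    hit <- runif(length(image)) < level
    out[hit] <- sample(c(0, 1), sum(hit), replace = TRUE)
  }
  array(pmin(pmax(out, 0), 1), dim = dim(image))
}

#' Allocate class counts by largest-remainder rounding
#'
#' @param n Total number of samples.
#' @param proportions Positive class weights (not necessarily summing
#'   to 1).
#' @return Integer vector summing to `n`, proportional to
#'   `proportions` up to rounding.
#' @export
allocate_counts <- function(n, proportions) {
  if (any(proportions <= 0)) stop("proportions must be positive")
  quota <- n * proportions / sum(proportions)
  counts <- floor(quota)
  remainder <- n - sum(counts)
  if (remainder > 0) {
    order_frac <- order(quota - counts, decreasing = TRUE)
    counts[order_frac[seq_len(remainder)]] <- counts[order_frac[seq_len(remainder)]] + 1
  }
  as.integer(counts)
}

#' Generate an imbalanced four-class feature task
#'
#' Gaussian class-conditional features with unit within-class standard
#' deviation. Class mean c is displaced by `separation` along coordinate
#' axis c (so each class is `separation` within-class standard
#' deviations from the shared origin and class means are pairwise
#' `sqrt(2) * separation` apart). Class counts follow
#' the configured proportions via largest-remainder rounding; the
#' default 895:1292:1495:608 mirrors the NT:TA:MA:PA imbalance of the
#' gastric image dataset.
#'
#' @param n_samples Total sample count (>= number of classes).
#' @param n_features Feature dimension (>= 4 for the default 4 classes).
#' @param separation Displacement of each class mean along its own
#'   axis, in within-class-sd units; 0 makes the classes
#'   indistinguishable.
#' @param proportions Positive class weights (length = n classes).
#' @param seed Optional integer seed.
#' @return List of class `feature_task`: `x` (n-by-d matrix), `y`
#'   (integer labels 1..K), `counts`, `class_names`, `separation`.
#' @export
generate_feature_task <- function(n_samples = 4290, n_features = 8,
                                  separation = 3,
                                  proportions = c(NT = 895, TA = 1292,
                                                  MA = 1495, PA = 608),
                                  seed = NULL) {
  k <- length(proportions)
  if (n_samples < k) stop("n_samples must be at least the number of classes")
  if (n_features < k) stop("n_features must be at least the number of classes")
  if (!is.null(seed)) set.seed(seed)
  counts <- allocate_counts(n_samples, proportions)
  y <- rep(seq_len(k), counts)
  x <- matrix(rnorm(n_samples * n_features), n_samples, n_features)
  for (c in seq_len(k)) {
    x[y == c, c] <- x[y == c, c] + separation
  }
  structure(
    list(x = x, y = y, counts = counts,
         class_names = names(proportions), separation = separation),
    class = "feature_task"
  )
}

#' Stratified train/test split
#'
#' Splits a labelled dataset into disjoint, exhaustive train and test
#' subsets, stratified so every class keeps the train fraction within
#' one sample of its quota.
#'
#' @param task A `feature_task` (or any list with `x` and `y`).
#' @param train_fraction Fraction assigned to training, in `(0, 1)`.
#' @param seed Optional integer seed.
#' @return List with `train` and `test`, each holding `x`, `y`, and the
#'   original row `index`.
#' @export
split_dataset <- function(task, train_fraction = 0.8, seed = NULL) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be strictly between 0 and 1")
  }
  y <- task$y
  n <- length(y)
  if (n == 0) stop("empty dataset")
  if (!is.null(seed)) set.seed(seed)
  classes <- sort(unique(y))
  per_class_n <- vapply(classes, function(c) sum(y == c), 0L)
  target_total <- round(train_fraction * n)
  train_counts <- allocate_counts(target_total, per_class_n)
  train_idx <- integer(0)
  for (i in seq_along(classes)) {
    members <- which(y == classes[i])
    train_idx <- c(train_idx, sample(members, train_counts[i]))
  }
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(n), train_idx)
  subset_of <- function(idx) list(x = task$x[idx, , drop = FALSE],
                                  y = y[idx], index = idx)
  list(train = subset_of(train_idx), test = subset_of(test_idx))
}
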