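#' Parameter ranges for stochastic affine augmentation
#'
#' Defaults follow the augmentation policy used for the pathological
#' image dataset: rotation in degrees, dimensionless shear factors,
#' translations in pixels, per-axis scale factors, and independent
#' horizontal/vertical reflection probabilities.
#'
#' @param rotation_deg Length-2 interval for the rotation angle, degrees.
#' @param shear_x,shear_y Intervals for the shear factors.
#' @param translate_px_x,translate_px_y Intervals for the translations,
#'   pixels.
#' @param scale_x,scale_y Intervals for the per-axis scale factors.
#' @param reflect_x_prob,reflect_y_prob Reflection probabilities.
#' @return A list of class `augment_ranges`.
#' @export
augment_ranges <- function(rotation_deg = c(-100, 100),
                           shear_x = c(-0.04, 0.04),
                           shear_y = c(-0.04, 0.04),
                           translate_px_x = c(-60, 60),
                           translate_px_y = c(-60, 60),
                           scale_x = c(0.6, 5),
                           scale_y = c(0.6, 5),
                           reflect_x_prob = 0.5,
                           reflect_y_prob = 0.5) {
  ranges <- list(rotation_deg = rotation_deg, shear_x = shear_x,
                 shear_y = shear_y, translate_px_x = translate_px_x,
                 translate_px_y = translate_px_y, scale_x = scale_x,
                 scale_y = scale_y, reflect_x_prob = reflect_x_prob,
                 reflect_y_prob = reflect_y_prob)
  for (nm in setdiff(names(ranges), c("reflect_x_prob", "reflect_y_prob"))) {
    iv <- ranges[[nm]]
    if (length(iv) != 2 || iv[1] > iv[2]) {
      stop("range '", nm, "' must be c(lower, upper) with lower <= upper")
    }
  }
  for (nm in c("reflect_x_prob", "reflect_y_prob")) {
    p <- ranges[[nm]]
    if (p < 0 || p > 1) stop(nm, " must be in [0, 1]")
  }
  structure(ranges, class = "augment_ranges")
}

#' Sample one augmentation specification
#'
#' Continuous parameters are drawn uniformly from their intervals;
#' reflections are Bernoulli.
#'
#' @param ranges An [augment_ranges()].
#' @return A list of class `affine_spec` with fields `rotation_deg`,
#'   `shear_x`, `shear_y`, `translate_x`, `translate_y`, `scale_x`,
#'   `scale_y`, `reflect_x`, `reflect_y`.
#' @export
sample_augmentation <- function(ranges = augment_ranges()) {
  stopifnot(inherits(ranges, "augment_ranges"))
  draw <- function(iv) runif(1, iv[1], iv[2])
  structure(
    list(
      rotation_deg = draw(ranges$rotation_deg),
      shear_x = draw(ranges$shear_x),
      shear_y = draw(ranges$shear_y),
      translate_x = draw(ranges$translate_px_x),
      translate_y = draw(ranges$translate_px_y),
      scale_x = draw(ranges$scale_x),
      scale_y = draw(ranges$scale_y),
      reflect_x = runif(1) < ranges$reflect_x_prob,
      reflect_y = runif(1) < ranges$reflect_y_prob
    ),
    class = "affine_spec"
  )
}

#' The identity augmentation specification
#'
#' @return An `affine_spec` whose transform is the identity.
#' @export
identity_spec <- function() {
  structure(
    list(rotation_deg = 0, shear_x = 0, shear_y = 0,
         translate_x = 0, translate_y = 0, scale_x = 1, scale_y = 1,
         reflect_x = FALSE, reflect_y = FALSE),
    class = "affine_spec"
  )
}

#' Compose an affine specification into a homogeneous matrix
#'
#' The component transforms are applied to a point in the order
#' reflect, scale, shear, rotate, translate, all anchored at the image
#' centre. Coordinates are `(x, y)` = (column, row), 0-based.
#'
#' @param spec An `affine_spec`.
#' @param center Numeric `c(x, y)` anchor, typically
#'   `(width - 1) / 2, (height - 1) / 2`.
#' @return A 3-by-3 homogeneous transform matrix mapping input pixel
#'   coordinates to output coordinates.
#' @export
compose_affine <- function(spec, center = c(0, 0)) {
  stopifnot(inherits(spec, "affine_spec"))
  if (spec$scale_x == 0 || spec$scale_y == 0) stop("zero scale is singular")
  theta <- spec$rotation_deg * pi / 180
  reflect <- diag(c(if (spec$reflect_x) -1 else 1,
                    if (spec$reflect_y) -1 else 1, 1))
  scale <- diag(c(spec$scale_x, spec$scale_y, 1))
  shear <- matrix(c(1, spec$shear_y, 0,
                    spec$shear_x, 1, 0,
                    0, 0, 1), 3, 3)
  rot <- matrix(c(cos(theta), sin(theta), 0,
                  -sin(theta), cos(theta), 0,
                  0, 0, 1), 3, 3)
  trans <- diag(3); trans[1, 3] <- spec$translate_x; trans[2, 3] <- spec$translate_y
  to_centre <- diag(3); to_centre[1:2, 3] <- -center
  from_centre <- diag(3); from_centre[1:2, 3] <- center
  from_centre %*% trans %*% rot %*% shear %*% scale %*% reflect %*% to_centre
}

#' Apply an affine transform to an image
#'
#' Output pixels are filled by inverse mapping: each output coordinate is
#' pulled back through the inverse transform and sampled with bilinear
#' (or nearest-neighbour) interpolation; samples outside the source image
#' take the `fill` value.
#'
#' @param image Numeric matrix or H-by-W-by-3 array in `[0, 1]`.
#' @param transform 3-by-3 homogeneous matrix from [compose_affine()].
#' @param interpolation `"bilinear"` (default) or `"nearest"`.
#' @param fill Out-of-domain fill value (default 0).
#' @return Transformed image, same shape as the input.
#' @export
apply_affine <- function(image, transform,
                         interpolation = c("bilinear", "nearest"),
                         fill = 0) {
  interpolation <- match.arg(interpolation)
  if (abs(det(transform)) < 1e-12) stop("singular transform")
  inv <- solve(transform)
  if (is.matrix(image)) {
    return(warp_channel(image, inv, interpolation, fill))
  }
  if (length(dim(image)) == 3) {
    out <- image
    for (k in seq_len(dim(image)[3])) {
      out[, , k] <- warp_channel(image[, , k], inv, interpolation, fill)
    }
    return(out)
  }
  stop("image must be a matrix or 3-d array")
}

warp_channel <- function(img, inv, interpolation, fill) {
  nr <- nrow(img); nc <- ncol(img)
  # output pixel grid in (x, y), 0-based
  xs <- rep(0:(nc - 1), each = nr)
  ys <- rep(0:(nr - 1), times = nc)
  src_x <- inv[1, 1] * xs + inv[1, 2] * ys + inv[1, 3]
  src_y <- inv[2, 1] * xs + inv[2, 2] * ys + inv[2, 3]
  if (interpolation == "nearest") {
    rx <- round(src_x); ry <- round(src_y)
    ok <- rx >= 0 & rx <= nc - 1 & ry >= 0 & ry <= nr - 1
    out <- rep(fill, nr * nc)
    out[ok] <- img[cbind(ry[ok] + 1, rx[ok] + 1)]
    return(matrix(out, nr, nc))
  }
  x0 <- floor(src_x); y0 <- floor(src_y)
  fx <- src_x - x0; fy <- src_y - y0
  sample_at <- function(yy, xx) {
    ok <- xx >= 0 & xx <= nc - 1 & yy >= 0 & yy <= nr - 1
    v <- rep(fill, length(xx))
    v[ok] <- img[cbind(yy[ok] + 1, xx[ok] + 1)]
    v
  }
  out <- (1 - fx) * (1 - fy) * sample_at(y0, x0) +
    fx * (1 - fy) * sample_at(y0, x0 + 1) +
    (1 - fx) * fy * sample_at(y0 + 1, x0) +
    fx * fy * sample_at(y0 + 1, x0 + 1)
  matrix(out, nr, nc)
}

#' Augment a labelled batch of images
#'
#' Produces `multiplier` stochastic affine variants of every input image,
#' each keeping its source label.
#'
#' @param images List of images (matrices or 3-d arrays).
#' @param labels Vector of labels, one per image.
#' @param multiplier Number of variants per source image (>= 1).
#' @param ranges An [augment_ranges()].
#' @param seed Optional integer seed.
#' @return List with `images` (length `length(images) * multiplier`),
#'   `labels`, and `specs` (the sampled `affine_spec`s).
#' @export
augment_batch <- function(images, labels, multiplier = 4,
                          ranges = augment_ranges(), seed = NULL) {
  if (length(images) == 0) stop("empty input batch")
  if (length(images) != length(labels)) stop("images and labels differ in length")
  if (multiplier < 1) stop("multiplier must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  out_images <- vector("list", length(images) * multiplier)
  out_labels <- rep(labels, each = multiplier)
  specs <- vector("list", length(out_images))
  k <- 0L
  for (i in seq_along(images)) {
    img <- images[[i]]
    hw <- dim(img)[1:2]
    centre <- c((hw[2] - 1) / 2, (hw[1] - 1) / 2)
    for (m in seq_len(multiplier)) {
      k <- k + 1L
      spec <- sample_augmentation(ranges)
      specs[[k]] <- spec
      out_images[[k]] <- apply_affine(img, compose_affine(spec, centre))
    }
  }
  list(images = out_images, labels = out_labels, specs = specs)
}
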