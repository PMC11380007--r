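#' Non-local means parameters
#'
#' @param patch_size Odd patch side length N (default 7). Patch
#'   similarity is measured between N-by-N neighbourhoods.
#' @param window_size Odd search window side length W (default 21, must
#'   be >= `patch_size`). Averaging runs over the W-by-W window around
#'   each pixel.
#' @param filter_h Filtering bandwidth h (> 0, default 0.1 on the unit
#'   intensity scale). Larger h averages more aggressively.
#' @return A list of class `nlm_params`.
#' @export
nlm_params <- function(patch_size = 7, window_size = 21, filter_h = 0.1) {
  if (patch_size < 1 || patch_size %% 2 == 0) {
    stop("patch_size must be an odd positive integer")
  }
  if (window_size %% 2 == 0 || window_size < patch_size) {
    stop("window_size must be odd and >= patch_size")
  }
  if (filter_h <= 0) stop("filter_h must be positive")
  structure(
    list(patch_size = as.integer(patch_size),
         window_size = as.integer(window_size),
         filter_h = filter_h),
    class = "nlm_params"
  )
}

# mirror an out-of-range index into [1, n] (edge pixel not repeated)
reflect_index_r <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  period <- 2L * (n - 1L)
  i <- (i - 1L) %% period
  i[i < 0L] <- i[i < 0L] + period
  over <- i >= n
  i[over] <- period - i[over]
  i + 1L
}

#' Extract a square patch around a pixel
#'
#' Out-of-image indices are resolved by reflect padding (mirror about the
#' edge, edge pixel not duplicated).
#'
#' @param image Numeric matrix with intensities in `[0, 1]`.
#' @param center Integer `c(row, col)` (1-based) inside the image.
#' @param patch_size Odd patch side length N.
#' @return An N-by-N matrix of intensities.
#' @export
extract_patch <- function(image, center, patch_size) {
  if (patch_size %% 2 == 0) stop("patch_size must be odd")
  nr <- nrow(image); nc <- ncol(image)
  if (center[1] < 1 || center[1] > nr || center[2] < 1 || center[2] > nc) {
    stop("center must lie inside the image")
  }
  r <- patch_size %/% 2
  rows <- reflect_index_r(center[1] + (-r:r), nr)
  cols <- reflect_index_r(center[2] + (-r:r), nc)
  image[rows, cols, drop = FALSE]
}

#' Gaussian-kernelized similarity weight between two patches
#'
#' `exp(-||a - b||^2 / (2 h^2))`: 1 for identical patches, decaying with
#' the squared Euclidean distance between them.
#'
#' @param patch_a,patch_b Equal-shaped numeric matrices.
#' @param h Filtering bandwidth (> 0).
#' @return A scalar weight in `(0, 1]`.
#' @export
patch_weight <- function(patch_a, patch_b, h) {
  if (h <= 0) stop("h must be positive")
  if (!identical(dim(patch_a), dim(patch_b))) stop("patch shapes differ")
  exp(-sum((patch_a - patch_b)^2) / (2 * h^2))
}

#' Non-local means denoising
#'
#' Replaces every pixel by a weighted average over its search window, the
#' weights coming from [patch_weight()] applied to the surrounding
#' patches. Boundaries use reflect padding. RGB images are processed on
#' the Rec. 601 luminance channel with the colour-difference channels
#' preserved; set `rgb_mode = "per_channel"` to filter each channel
#' independently.
#'
#' @param image Numeric matrix (grayscale) or H-by-W-by-3 array (RGB),
#'   intensities in `[0, 1]`.
#' @param params An [nlm_params()].
#' @param rgb_mode `"luminance"` (default) or `"per_channel"`.
#' @return Denoised image, same shape and range as the input.
#' @export
nlm_denoise <- function(image, params = nlm_params(),
                        rgb_mode = c("luminance", "per_channel")) {
  stopifnot(inherits(params, "nlm_params"))
  rgb_mode <- match.arg(rgb_mode)
  apply_channelwise(image, rgb_mode, function(ch) {
    if (params$window_size > 2 * min(dim(ch)) - 1) {
      stop("search window larger than the reflect-padded image")
    }
    .nlm_denoise_cpp(ch, params$patch_size, params$window_size,
                     params$filter_h)
  })
}

# run a single-channel operation on a grayscale matrix or an RGB array;
# luminance mode shifts every channel by the luminance change so the
# colour differences R-Y and B-Y are preserved exactly
apply_channelwise <- function(image, rgb_mode, op) {
  if (is.matrix(image)) return(op(image))
  if (length(dim(image)) == 3 && dim(image)[3] == 3) {
    if (rgb_mode == "per_channel") {
      out <- image
      for (k in 1:3) out[, , k] <- op(image[, , k])
      return(pmin(pmax(out, 0), 1))
    }
    y <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
    y2 <- op(y)
    out <- image
    for (k in 1:3) out[, , k] <- image[, , k] + (y2 - y)
    return(pmin(pmax(out, 0), 1))
  }
  stop("image must be a matrix or an H x W x 3 array")
}

#' Peak signal-to-noise ratio between two unit-scale images
#'
#' @param image,reference Equal-shaped arrays with intensities in
#'   `[0, 1]`.
#' @return PSNR in dB (peak value 1); `Inf` for identical images.
#' @export
psnr <- function(image, reference) {
  if (!identical(dim(image), dim(reference))) stop("shapes differ")
  mse <- mean((image - reference)^2)
  if (mse == 0) return(Inf)
  -10 * log10(mse)
}
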