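#' CLAHE parameters
#'
#' @param tile_height,tile_width Tile size in pixels (>= 2). Tiles
#'   partition the image; each gets its own clipped equalization mapping.
#' @param clip_limit Contrast limit as a multiple of the uniform bin
#'   level `tile_pixels / n_bins` (>= 1). Histogram mass above the limit
#'   is redistributed uniformly across all bins.
#' @param n_bins Number of histogram bins (default 256).
#' @return A list of class `clahe_params`.
#' @export
clahe_params <- function(tile_height = 64, tile_width = tile_height,
                         clip_limit = 2, n_bins = 256) {
  if (tile_height < 2 || tile_width < 2) stop("tile sizes must be >= 2")
  if (clip_limit < 1) stop("clip_limit must be >= 1")
  if (n_bins < 2) stop("n_bins must be >= 2")
  structure(
    list(tile_height = as.integer(tile_height),
         tile_width = as.integer(tile_width),
         clip_limit = clip_limit,
         n_bins = as.integer(n_bins)),
    class = "clahe_params"
  )
}

#' Clipped-equalization mapping for one tile histogram
#'
#' Bins are clipped at `clip_limit * total / n_bins`; the clipped excess
#' is redistributed uniformly over all bins (a single pass), and the
#' mapping is the normalised cumulative distribution of the result.
#'
#' @param histogram Non-negative bin counts for one tile.
#' @param clip_limit Contrast limit (multiple of the uniform bin level).
#' @param n_bins Number of bins; defaults to `length(histogram)`.
#' @return A monotone non-decreasing vector of length `n_bins` mapping
#'   bin index to an output intensity in `[0, 1]`.
#' @export
clahe_tile_mapping <- function(histogram, clip_limit, n_bins = length(histogram)) {
  if (length(histogram) == 0 || sum(histogram) == 0) {
    stop("empty tile histogram")
  }
  if (length(histogram) != n_bins) stop("histogram length must equal n_bins")
  total <- sum(histogram)
  ceiling_level <- clip_limit * total / n_bins
  clipped <- pmin(histogram, ceiling_level)
  excess <- total - sum(clipped)
  clipped <- clipped + excess / n_bins
  cumsum(clipped) / total
}

#' Contrast-limited adaptive histogram equalization
#'
#' The image is partitioned into tiles; each tile's histogram is clipped
#' and equalized via [clahe_tile_mapping()], and every output pixel is
#' obtained by bilinear interpolation between the mappings of the four
#' nearest tile centres (border tiles replicated), giving a continuous
#' result. RGB images are enhanced on the luminance channel with colour
#' differences preserved.
#'
#' @param image Numeric matrix or H-by-W-by-3 array, intensities in
#'   `[0, 1]`.
#' @param params A [clahe_params()].
#' @param rgb_mode `"luminance"` (default) or `"per_channel"`.
#' @return Enhanced image in `[0, 1]`, same shape as the input.
#' @export
clahe_enhance <- function(image, params = clahe_params(),
                          rgb_mode = c("luminance", "per_channel")) {
  stopifnot(inherits(params, "clahe_params"))
  rgb_mode <- match.arg(rgb_mode)
  apply_channelwise(image, rgb_mode, function(ch) clahe_channel(ch, params))
}

clahe_channel <- function(img, params) {
  nr <- nrow(img); nc <- ncol(img)
  th <- params$tile_height; tw <- params$tile_width
  if (th > nr || tw > nc) {
    stop("tile larger than image; choose tile sizes <= image dimensions")
  }
  n_bins <- params$n_bins
  ntr <- nr %/% th + (nr %% th > 0)  # tiles per column of tiles
  ntc <- nc %/% tw + (nc %% tw > 0)

  # bin index per pixel (continuous values quantized for histogramming only)
  bin <- pmin(floor(img * n_bins) + 1L, n_bins)

  # per-tile mappings, stored as an (ntr*ntc) x n_bins matrix
  maps <- matrix(0, nrow = ntr * ntc, ncol = n_bins)
  tile_row_of <- pmin((seq_len(nr) - 1L) %/% th + 1L, ntr)
  tile_col_of <- pmin((seq_len(nc) - 1L) %/% tw + 1L, ntc)
  for (tr in seq_len(ntr)) {
    rows <- which(tile_row_of == tr)
    for (tc in seq_len(ntc)) {
      cols <- which(tile_col_of == tc)
      hist_t <- tabulate(bin[rows, cols], nbins = n_bins)
      maps[(tc - 1L) * ntr + tr, ] <-
        clahe_tile_mapping(hist_t, params$clip_limit, n_bins)
    }
  }

  # tile centres (pixel coordinates, 1-based); border tiles may be smaller
  centre_r <- vapply(seq_len(ntr), function(tr) mean(which(tile_row_of == tr)), 0)
  centre_c <- vapply(seq_len(ntc), function(tc) mean(which(tile_col_of == tc)), 0)

  # continuous tile coordinates per pixel, clamped so border tiles replicate
  gr <- interp_coords(seq_len(nr), centre_r)
  gc <- interp_coords(seq_len(nc), centre_c)

  r0 <- matrix(gr$i0, nr, nc); fr <- matrix(gr$frac, nr, nc)
  c0 <- matrix(gc$i0, nr, nc, byrow = TRUE)
  fc <- matrix(gc$frac, nr, nc, byrow = TRUE)
  r1 <- pmin(r0 + 1L, ntr); c1 <- pmin(c0 + 1L, ntc)

  gather <- function(tr, tc) {
    maps[cbind(as.vector((tc - 1L) * ntr + tr), as.vector(bin))]
  }
  out <- (1 - fr) * (1 - fc) * gather(r0, c0) +
    (1 - fr) * fc * gather(r0, c1) +
    fr * (1 - fc) * gather(r1, c0) +
    fr * fc * gather(r1, c1)
  matrix(pmin(pmax(out, 0), 1), nr, nc)
}

# for each query coordinate, the index of the centre at/below it and the
# interpolation fraction towards the next centre (clamped at the borders)
interp_coords <- function(q, centres) {
  n <- length(centres)
  i0 <- findInterval(q, centres)
  frac <- numeric(length(q))
  inside <- i0 >= 1 & i0 < n
  frac[inside] <- (q[inside] - centres[i0[inside]]) /
    (centres[i0[inside] + 1] - centres[i0[inside]])
  i0[i0 < 1] <- 1L   # before the first centre: replicate first tile
  frac[i0 >= n] <- 0 # past the last centre: replicate last tile
  i0[i0 > n] <- n
  list(i0 = as.integer(i0), frac = frac)
}

#' Global histogram equalization
#'
#' Plain histogram equalization over the whole image: the mapping is the
#' normalised cumulative histogram. Equivalent to [clahe_enhance()] with
#' a single tile and an unbounded clip limit.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param n_bins Number of histogram bins.
#' @return Equalized matrix in `[0, 1]`.
#' @export
hist_equalize <- function(image, n_bins = 256) {
  bin <- pmin(floor(image * n_bins) + 1L, n_bins)
  cdf <- cumsum(tabulate(bin, nbins = n_bins)) / length(image)
  matrix(cdf[bin], nrow(image), ncol(image))
}
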