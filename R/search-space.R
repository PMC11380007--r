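#' Define a box-constrained search space
#'
#' A search space is a hyper-rectangle given by per-dimension lower and
#' upper bounds. All optimizer moves are clipped back into this box.
#'
#' @param lower Numeric vector of lower bounds (one per dimension).
#' @param upper Numeric vector of upper bounds; must exceed `lower`
#'   componentwise. A scalar is recycled to the length of `lower`.
#' @return An object of class `dpoa_space` with fields `d`, `lower`, `upper`.
#' @examples
#' search_space(c(-1, -1), c(1, 1))
#' @export
search_space <- function(lower, upper) {
  if (length(upper) == 1L) upper <- rep(upper, length(lower))
  if (length(lower) == 1L) lower <- rep(lower, length(upper))
  lower <- as.numeric(lower)
  upper <- as.numeric(upper)
  if (length(lower) != length(upper)) {
    stop("`lower` and `upper` must have the same length")
  }
  if (length(lower) < 1L) stop("search space needs at least one dimension")
  if (!all(is.finite(lower)) || !all(is.finite(upper))) {
    stop("bounds must be finite")
  }
  if (any(lower >= upper)) {
    stop("every lower bound must be strictly below its upper bound")
  }
  structure(
    list(d = length(lower), lower = lower, upper = upper),
    class = "dpoa_space"
  )
}

#' Clip positions into a search space
#'
#' @param x Numeric vector (one position) or matrix (one position per row).
#' @param space A [search_space()].
#' @return `x` with every component forced into `[lower, upper]`.
#' @export
clip_to_space <- function(x, space) {
  stopifnot(inherits(space, "dpoa_space"))
  if (is.matrix(x)) {
    for (j in seq_len(space$d)) {
      x[, j] <- pmin(pmax(x[, j], space$lower[j]), space$upper[j])
    }
    x
  } else {
    pmin(pmax(x, space$lower), space$upper)
  }
}

#' @export
print.dpoa_space <- function(x, ...) {
  cat(sprintf("<search space: %d dimension(s)>\n", x$d))
  invisible(x)
}
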