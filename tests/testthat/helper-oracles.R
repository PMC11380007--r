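# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# mirror an index into [1, n] without repeating the edge pixel
mirror_idx <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 2 - i
    if (i > n) i <- 2 * n - i
  }
  i
}

# naive quadruple-loop non-local means: for every pixel, loop the window;
# for every window pixel, loop the patch to accumulate the squared distance
nlm_oracle <- function(img, patch, window, h) {
  nr <- nrow(img); nc <- ncol(img)
  pr <- patch %/% 2; wr <- window %/% 2
  out <- matrix(0, nr, nc)
  for (r in 1:nr) for (c in 1:nc) {
    wsum <- 0; vsum <- 0
    for (dr in -wr:wr) for (dc in -wr:wr) {
      d2 <- 0
      for (pi in -pr:pr) for (pj in -pr:pr) {
        a <- img[mirror_idx(r + pi, nr), mirror_idx(c + pj, nc)]
        b <- img[mirror_idx(r + dr + pi, nr), mirror_idx(c + dc + pj, nc)]
        d2 <- d2 + (a - b)^2
      }
      w <- exp(-d2 / (2 * h^2))
      wsum <- wsum + w
      vsum <- vsum + w * img[mirror_idx(r + dr, nr), mirror_idx(c + dc, nc)]
    }
    out[r, c] <- vsum / wsum
  }
  out
}

# metric oracle: recount everything directly from raw label vectors
metrics_oracle <- function(pred, truth, positive) {
  tp <- sum(pred == positive & truth == positive)
  fp <- sum(pred == positive & truth != positive)
  fn <- sum(pred != positive & truth == positive)
  tn <- sum(pred != positive & truth != positive)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  prec <- 100 * tp / (tp + fp)
  sens <- 100 * tp / (tp + fn)
  c(specificity = 100 * tn / (tn + fp),
    sensitivity = sens,
    accuracy = 100 * (tp + tn) / length(pred),
    precision = prec,
    mcc = 100 * (tp * tn - fp * fn) / den,
    f1 = 2 * prec * sens / (prec + sens))
}

# deterministic smooth test image (no RNG)
smooth_image <- function(n = 32) {
  g <- outer(seq(0, 1, length.out = n), seq(0, 1, length.out = n),
             function(a, b) 0.5 + 0.3 * sin(2 * pi * a) * cos(2 * pi * b))
  (g - min(g)) / (max(g) - min(g))
}
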