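rand_batch <- function(n, k) {
  logits <- matrix(rnorm(n * k), n, k)
  oh <- matrix(0, n, k)
  oh[cbind(seq_len(n), sample.int(k, n, replace = TRUE))] <- 1
  list(logits = logits, onehots = oh)
}

test_that("softmax rows are probabilities and match closed forms", {
  expect_equal(softmax(matrix(0, 1, 4))[1, ], rep(0.25, 4))
  expect_equal(softmax(matrix(log(1:4), 1, 4))[1, ], (1:4) / 10)
  set.seed(2)
  p <- softmax(matrix(rnorm(40), 10, 4))
  expect_equal(rowSums(p), rep(1, 10))
  expect_true(all(p > 0))
  # max-shift keeps huge logits finite
  expect_equal(rowSums(softmax(matrix(c(1000, 0, 0, 0), 1, 4))), 1)
})

test_that("cross-entropy matches hand values", {
  oh <- matrix(c(1, 0, 0, 0), 1, 4)
  expect_equal(cross_entropy(matrix(0, 1, 4), oh), log(4))
  # near-certain correct prediction: loss near zero
  sure <- matrix(c(50, 0, 0, 0), 1, 4)
  expect_lt(cross_entropy(sure, oh), 1e-12)
  set.seed(3)
  b <- rand_batch(20, 4)
  expect_gte(cross_entropy(b$logits, b$onehots), 0)
  expect_equal(cross_entropy(b$logits, b$onehots, "mean"),
               cross_entropy(b$logits, b$onehots, "sum") / 20)
  expect_error(cross_entropy(matrix(0, 1, 4), matrix(0, 1, 3)), "shape")
})

test_that("weighted cross-entropy generalises cross-entropy", {
  set.seed(4)
  for (i in 1:20) {
    b <- rand_batch(10, 4)
    expect_equal(weighted_cross_entropy(b$logits, b$onehots, rep(1, 4)),
                 cross_entropy(b$logits, b$onehots), tolerance = 1e-12)
  }
  # one sample with true-class probability 1/2 and weight 2 -> 2 ln 2
  logits <- matrix(c(log(2), 0, 0, log(1)), 1, 4)  # probs 1/2, 1/4, ...
  logits <- matrix(c(0, -log(2), -log(2), -Inf), 1, 4)
  logits[1, 4] <- -100  # effectively zero probability
  oh <- matrix(c(1, 0, 0, 0), 1, 4)
  expect_equal(weighted_cross_entropy(logits, oh, c(2, 1, 1, 1)),
               2 * log(2), tolerance = 1e-6)
  # weight zero silences a class entirely
  b <- rand_batch(10, 4)
  w0 <- c(0, 1, 1, 1)
  contrib <- weighted_cross_entropy(b$logits[b$onehots[, 1] == 1, , drop = FALSE],
                                    b$onehots[b$onehots[, 1] == 1, , drop = FALSE],
                                    w0)
  expect_equal(contrib, 0)
  expect_error(weighted_cross_entropy(b$logits, b$onehots, c(-1, 1, 1, 1)),
               "non-negative")
})

test_that("focal loss reduces to cross-entropy at exponent zero", {
  set.seed(5)
  for (i in 1:20) {
    b <- rand_batch(10, 4)
    expect_equal(focal_loss(b$logits, b$onehots, exponent = 0),
                 cross_entropy(b$logits, b$onehots), tolerance = 1e-12)
  }
  # true-class probability 1/2, exponent 2 -> (1/2)^2 ln 2
  logits <- matrix(c(0, -log(2), -log(2), -100), 1, 4)
  oh <- matrix(c(1, 0, 0, 0), 1, 4)
  expect_equal(focal_loss(logits, oh, exponent = 2), 0.25 * log(2),
               tolerance = 1e-6)
  sure <- matrix(c(50, 0, 0, 0), 1, 4)
  expect_lt(focal_loss(sure, oh, exponent = 2), 1e-12)
})

test_that("per-class recall counts correctly and flags empty classes", {
  expect_equal(per_class_recall(c(1, 2, 3), c(1, 2, 3), 3), c(1, 1, 1))
  expect_equal(per_class_recall(c(2, 3, 1), c(1, 2, 3), 3), c(0, 0, 0))
  expect_equal(per_class_recall(c(1, 2, 2, 2), c(1, 1, 2, 2), 2),
               c(0.5, 1.0))
  r <- per_class_recall(c(1, 1), c(1, 1), 3)
  expect_true(is.na(r[2]) && is.na(r[3]))
  expect_error(per_class_recall(c(1, 5), c(1, 1), 4), "1..n_classes")
})

test_that("error ratios complement recall", {
  expect_equal(error_ratios(c(1, 0, 0.5)), c(0, 1, 0.5))
  expect_true(is.na(error_ratios(c(0.5, NA))[2]))
  expect_error(error_ratios(c(1.2, 0)), "\\[0, 1\\]")
})

test_that("alpha transforms compute their formulas", {
  expect_equal(alpha_transform("identity", 0.3), 0.3)
  expect_equal(alpha_transform("ten_y", 0.3), 3)
  expect_equal(alpha_transform("cube", 0.5), 0.125)
  expect_equal(alpha_transform("exp_y", 0), 1)
  expect_equal(alpha_transform("exp_100y", 0.01), exp(1))
  expect_equal(alpha_transform("ten_pow_y", 2), 100)
  expect_error(alpha_transform("log", 1), "unknown transform")
})

test_that("dynamic class weights normalise, stay monotone, and are equivariant", {
  expect_equal(dynamic_class_weights(rep(0.3, 4)), rep(0.25, 4))
  expect_equal(dynamic_class_weights(c(0.1, 0.2, 0.3, 0.4)),
               c(0.1, 0.2, 0.3, 0.4))  # already sums to 1 under identity
  set.seed(6)
  for (tr in c("identity", "cube", "exp_y", "ten_y")) {
    for (i in 1:250) {
      mr <- runif(4)
      w <- dynamic_class_weights(mr, tr)
      expect_equal(sum(w), 1, tolerance = 1e-12)
      # permutation equivariance
      perm <- sample(4)
      expect_equal(dynamic_class_weights(mr[perm], tr), w[perm],
                   tolerance = 1e-12)
      # monotone transform: larger error ratio never gets less weight
      ord <- order(mr)
      expect_true(all(diff(w[ord]) >= -1e-12))
    }
  }
  # undefined class gets weight zero, the rest renormalise
  w <- dynamic_class_weights(c(0.2, NA, 0.6, 0.2))
  expect_equal(w[2], 0)
  expect_equal(sum(w), 1)
  expect_error(dynamic_class_weights(c(0, 0, 0, 0)), "degenerate")
})
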