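test_that("the six metrics match hand arithmetic on a small confusion matrix", {
  m <- classification_metrics(confusion_counts(tp = 9, fp = 2, tn = 8, fn = 1))
  expect_equal(unname(m["sensitivity"]), 90)
  expect_equal(unname(m["specificity"]), 80)
  expect_equal(unname(m["accuracy"]), 85)
  expect_equal(unname(m["precision"]), 900 / 11, tolerance = 1e-10)
  expect_equal(unname(m["f1"]), 2 * (900 / 11) * 90 / (900 / 11 + 90),
               tolerance = 1e-10)
  expect_equal(unname(m["mcc"]), 100 * 70 / sqrt(9900), tolerance = 1e-10)
  # rounded to two decimals these are the reference values
  expect_equal(round(unname(m[c("precision", "f1", "mcc")]), 2),
               c(81.82, 85.71, 70.35))
})

test_that("a perfect classifier scores 100 on every metric", {
  m <- classification_metrics(confusion_counts(tp = 50, fp = 0, tn = 50, fn = 0))
  expect_equal(unname(m), rep(100, 6))
})

test_that("swapping the positive and negative classes swaps sensitivity and specificity", {
  a <- classification_metrics(confusion_counts(tp = 30, fp = 5, tn = 40, fn = 10))
  b <- classification_metrics(confusion_counts(tp = 40, fp = 10, tn = 30, fn = 5))
  expect_equal(a[["sensitivity"]], b[["specificity"]])
  expect_equal(a[["specificity"]], b[["sensitivity"]])
  expect_equal(a[["accuracy"]], b[["accuracy"]])
  expect_equal(a[["mcc"]], b[["mcc"]])
})

test_that("metrics agree with a counting oracle on random label sets", {
  set.seed(8)
  for (i in 1:100) {
    n <- sample(20:60, 1)
    truth <- sample.int(2, n, replace = TRUE)
    pred <- ifelse(runif(n) < 0.7, truth, sample.int(2, n, replace = TRUE))
    tp <- sum(pred == 1 & truth == 1); fp <- sum(pred == 1 & truth == 2)
    tn <- sum(pred == 2 & truth == 2); fn <- sum(pred == 2 & truth == 1)
    if (tp + fp == 0 || tp + fn == 0 || tn + fp == 0 || tn + fn == 0) next
    ours <- classification_metrics(confusion_counts(tp, fp, tn, fn))
    oracle <- metrics_oracle(pred, truth, positive = 1)
    expect_equal(unname(ours), unname(oracle), tolerance = 1e-10)
  }
})

test_that("undefined denominators are flagged rather than invented", {
  m <- classification_metrics(confusion_counts(tp = 0, fp = 0, tn = 10, fn = 5))
  expect_true(is.na(m[["precision"]]))
  expect_equal(m[["specificity"]], 100)
  expect_error(confusion_counts(-1, 0, 1, 0), "non-negative")
})

test_that("the literal-form MCC flag reproduces the alternative formula", {
  m <- classification_metrics(confusion_counts(9, 2, 8, 1),
                              literal_form = TRUE)
  expect_equal(m[["mcc"]], 100 * (9 * 8 - 9 * 1) / 9900, tolerance = 1e-10)
})

test_that("multiclass one-vs-rest reporting is consistent with raw labels", {
  set.seed(9)
  truth <- sample.int(4, 200, replace = TRUE)
  pred <- ifelse(runif(200) < 0.75, truth, sample.int(4, 200, replace = TRUE))
  rep4 <- multiclass_report(pred, truth, 4)
  expect_equal(nrow(rep4$per_class), 4)
  expect_equal(rep4$accuracy, 100 * mean(pred == truth))
  # per-class sensitivity equals a direct recall computation
  expect_equal(rep4$per_class$sensitivity / 100,
               per_class_recall(pred, truth, 4), tolerance = 1e-12)
  expect_equal(unname(rep4$macro["f1"]),
               mean(rep4$per_class$f1, na.rm = TRUE))
})

test_that("separable convolution costs follow the factorised formulas", {
  z <- separable_cost(d_in = 64, d_out = 128, out_h = 7, out_w = 7, kernel = 3)
  expect_equal(z$z_standard, 64 * 128 * 7 * 7 * 9)
  expect_equal(z$z_separable, 128 * (9 + 64) * 7 * 7)
  expect_equal(z$ratio, 576 / 73)
  expect_equal(z$z_standard / z$z_separable, z$ratio, tolerance = 1e-12)
  expect_equal(separable_cost(1, 1, kernel = 1)$ratio, 0.5)
  # the saving grows with the channel count and is bounded by k^2
  ratios <- vapply(c(2, 8, 32, 128, 512),
                   function(d) separable_cost(d, 1, kernel = 3)$ratio, 0)
  expect_true(all(diff(ratios) > 0))
  expect_true(all(ratios < 9))
  expect_error(separable_cost(0, 1), "positive")
})

test_that("metrics tables from confusion CSVs match the direct computation", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(class = c("A", "B"), tp = c(9, 50), fp = c(2, 0),
                       tn = c(8, 50), fn = c(1, 0)),
            path, row.names = FALSE)
  tbl <- metrics_from_csv(path)
  expect_equal(tbl$sensitivity[1], 90)
  expect_equal(tbl$f1[2], 100)
  expect_equal(tbl$class[3], "macro")
  expect_equal(tbl$accuracy[3], mean(c(85, 100)))
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("tp,fp\n1,2", bad)
  expect_error(metrics_from_csv(bad), "columns tp, fp, tn, fn")
  expect_error(metrics_from_csv("does-not-exist.csv"), "not found")
})
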