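#' Read an 8-bit PNG as a unit-interval raster
#'
#' Grayscale PNGs load as a matrix, RGB as an H-by-W-by-3 array; an
#' alpha channel, if present, is dropped.
#'
#' @param path PNG file path.
#' @return Numeric matrix or array with intensities in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) {
    if (dim(img)[3] == 2) img <- img[, , 1]          # gray + alpha
    else if (dim(img)[3] == 4) img <- img[, , 1:3]   # rgb + alpha
  }
  img
}

#' Write a unit-interval raster as an 8-bit PNG
#'
#' @param image Numeric matrix or H-by-W-by-3 array in `[0, 1]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' Preprocessing chain: denoise then enhance
#'
#' Applies non-local means denoising followed by CLAHE contrast
#' enhancement, the order used ahead of classifier training. Dimensions
#' and the unit intensity range are preserved.
#'
#' @param image Numeric matrix or RGB array in `[0, 1]`.
#' @param nlm An [nlm_params()].
#' @param clahe A [clahe_params()].
#' @return List with the processed `image` and a `report` holding the
#'   parameters and 16-bin intensity histograms before and after.
#' @export
preprocess_image <- function(image, nlm = nlm_params(),
                             clahe = clahe_params(
                               tile_height = min(32, nrow(as.matrix(image))),
                               tile_width = min(32, ncol(as.matrix(image)))
                             )) {
  hist16 <- function(x) tabulate(pmin(floor(x * 16) + 1L, 16L), nbins = 16L)
  before <- hist16(image)
  out <- nlm_denoise(image, nlm)
  out <- clahe_enhance(out, clahe)
  list(
    image = out,
    report = list(
      nlm = unclass(nlm), clahe = unclass(clahe),
      histogram_before = before, histogram_after = hist16(out)
    )
  )
}

# linear softmax classifier: parameter vector = c(W (d x k), b (k))
unpack_linear <- function(theta, d, k) {
  list(w = matrix(theta[seq_len(d * k)], d, k),
       b = theta[d * k + seq_len(k)])
}

linear_logits <- function(x, theta, k) {
  p <- unpack_linear(theta, ncol(x), k)
  sweep(x %*% p$w, 2, p$b, `+`)
}

one_hot <- function(y, k) {
  oh <- matrix(0, length(y), k)
  oh[cbind(seq_along(y), y)] <- 1
  oh
}

#' DPOA classifier-tuning demonstration
#'
#' A desk-scale surrogate for coupling the dynamic pelican optimizer to
#' a classifier: DPOA searches the flattened weight and bias parameters
#' of a linear softmax model (d*K + K values in a `[-5, 5]` box),
#' minimising mean weighted cross-entropy on the 80% training split.
#' The class weights are dynamic: at the start of every iteration they
#' are recomputed from the per-class error ratios (1 - recall) of the
#' incumbent best member on the training split, so poorly learned
#' classes gain emphasis as the search proceeds. Final metrics are
#' computed one-vs-rest on the held-out 20%.
#'
#' @param task A `feature_task` from [generate_feature_task()], or
#'   `NULL` to generate one from the remaining arguments.
#' @param n_samples,n_features,separation,proportions Passed to
#'   [generate_feature_task()] when `task` is `NULL`.
#' @param config An [optimizer_config()]; default DPOA with population
#'   40 and 300 iterations (the classifier search runs in d*K + K
#'   dimensions and needs a larger budget than low-dimensional
#'   benchmark runs).
#' @param transform Error-ratio transform for the dynamic weights
#'   (see [alpha_transform()]). Default `"exp_y"`: unlike the identity
#'   it never gives a perfectly learned class weight zero, which keeps
#'   long searches from trading such classes away.
#' @param train_fraction Training fraction (default 0.8).
#' @param seed Integer seed controlling task generation, the split, and
#'   the search.
#' @return List of class `tune_demo_result`: `run` (the optimizer
#'   [run_optimizer()] result), `report` (test-split
#'   [multiclass_report()]), `accuracy` (overall test accuracy, %),
#'   `train_accuracy`, `predictions`, `truth`, `final_weights` (last
#'   dynamic class-weight vector), and `weight_history`.
#' @export
tune_demo <- function(task = NULL, n_samples = 800, n_features = 8,
                      separation = 3,
                      proportions = c(NT = 895, TA = 1292, MA = 1495, PA = 608),
                      config = NULL, transform = "exp_y",
                      train_fraction = 0.8, seed = 1L) {
  if (is.null(task)) {
    task <- generate_feature_task(n_samples, n_features, separation,
                                  proportions, seed = seed)
  }
  k <- length(unique(task$y))
  if (k < 2) stop("degenerate task: a single class cannot be tuned")
  d <- ncol(task$x)
  split <- split_dataset(task, train_fraction, seed = seed + 1L)
  x_tr <- split$train$x; y_tr <- split$train$y
  oh_tr <- one_hot(y_tr, k)

  space <- search_space(rep(-5, d * k + k), rep(5, d * k + k))
  if (is.null(config)) {
    config <- dpoa_config(population_size = 40, max_iterations = 300,
                          seed = seed + 2L)
  } else {
    config$seed <- as.integer(seed + 2L)
  }

  weight_env <- new.env()
  weight_env$w <- rep(1 / k, k)
  weight_env$history <- list()
  make_objective <- function(w) {
    force(w)
    function(theta) {
      weighted_cross_entropy(linear_logits(x_tr, theta, k), oh_tr, w,
                             reduction = "mean")
    }
  }
  update_objective <- function(t, best_position) {
    pred <- max.col(linear_logits(x_tr, best_position, k), ties.method = "first")
    mr <- error_ratios(per_class_recall(pred, y_tr, k))
    w <- dynamic_class_weights(mr, transform)
    weight_env$w <- w
    weight_env$history[[t]] <- w
    make_objective(w)
  }

  run <- run_optimizer(make_objective(weight_env$w), space, config,
                       update_objective = update_objective)

  predict_with <- function(x) {
    max.col(linear_logits(x, run$best_position, k), ties.method = "first")
  }
  pred_te <- predict_with(split$test$x)
  pred_tr <- predict_with(x_tr)
  report <- multiclass_report(pred_te, split$test$y, k)

  structure(
    list(
      run = run,
      report = report,
      accuracy = report$accuracy,
      train_accuracy = 100 * mean(pred_tr == y_tr),
      predictions = pred_te,
      truth = split$test$y,
      final_weights = weight_env$w,
      weight_history = weight_env$history,
      split = split,
      n_classes = k
    ),
    class = "tune_demo_result"
  )
}

#' @export
print.tune_demo_result <- function(x, ...) {
  cat(sprintf(
    "<tuning demo: test accuracy %.2f%%, macro F1 %.2f%%, best loss %.4g>\n",
    x$accuracy, x$report$macro["f1"], x$run$best_fitness
  ))
  invisible(x)
}

#' Load a pipeline configuration file
#'
#' Reads a YAML or JSON configuration with optional sections `nlm`,
#' `clahe`, `augment`, `optimizer`, `task`, plus top-level `seed` and
#' `out_dir`, and materialises the corresponding parameter objects.
#'
#' @param path Configuration file (`.yaml`/`.yml`/`.json`).
#' @return List with validated sub-configurations.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  out <- list(seed = raw$seed %||% 1L, out_dir = raw$out_dir %||% ".")
  out$nlm <- do.call(nlm_params, raw$nlm %||% list())
  out$clahe <- do.call(clahe_params, raw$clahe %||% list())
  out$augment <- do.call(augment_ranges, raw$augment %||% list())
  opt <- raw$optimizer %||% list()
  opt$seed <- opt$seed %||% out$seed
  out$optimizer <- do.call(optimizer_config, opt)
  out$task <- raw$task %||% list()
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
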