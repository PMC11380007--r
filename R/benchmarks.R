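#' @title Benchmark function registry
#' @description Classic unimodal and multimodal test functions used to
#'   exercise the optimizer. All registry entries attain their known
#'   optimum at the origin (Schwefel 2.26 is shifted so its optimum also
#'   sits at a known location with value zero up to double precision).
#' @name benchmarks
NULL

# registry of evaluators; each takes a numeric vector and returns a scalar
.benchmark_registry <- local({
  sch226_x <- 420.968746359982025  # minimizer of -x sin(sqrt|x|) on [0, 500]
  list(
    sphere = list(
      fn = function(x) sum(x^2),
      bounds = c(-100, 100), opt_loc = function(d) rep(0, d), opt_val = 0
    ),
    schwefel_1_2 = list(
      fn = function(x) sum(cumsum(x)^2),
      bounds = c(-100, 100), opt_loc = function(d) rep(0, d), opt_val = 0
    ),
    schwefel_2_22 = list(
      fn = function(x) sum(abs(x)) + prod(abs(x)),
      bounds = c(-10, 10), opt_loc = function(d) rep(0, d), opt_val = 0
    ),
    schwefel_2_21 = list(
      fn = function(x) max(abs(x)),
      bounds = c(-100, 100), opt_loc = function(d) rep(0, d), opt_val = 0
    ),
    rosenbrock = list(
      fn = function(x) {
        if (length(x) < 2) return(0)
        i <- seq_len(length(x) - 1)
        sum(100 * (x[i + 1] - x[i]^2)^2 + (x[i] - 1)^2)
      },
      bounds = c(-30, 30), opt_loc = function(d) rep(1, d), opt_val = 0
    ),
    step = list(
      fn = function(x) sum(floor(x + 0.5)^2),
      bounds = c(-100, 100), opt_loc = function(d) rep(0, d), opt_val = 0
    ),
    quartic_noise = list(
      fn = function(x) sum(seq_along(x) * x^4) + runif(1),
      bounds = c(-1.28, 1.28), opt_loc = function(d) rep(0, d), opt_val = NA_real_,
      stochastic = TRUE
    ),
    schwefel_2_26 = list(
      fn = function(x) {
        418.98288727243374 * length(x) - sum(x * sin(sqrt(abs(x))))
      },
      bounds = c(-500, 500),
      opt_loc = function(d) rep(420.968746359982025, d),
      opt_val = NA_real_  # resolved numerically at construction
    ),
    rastrigin = list(
      fn = function(x) sum(x^2 - 10 * cos(2 * pi * x) + 10),
      bounds = c(-5.12, 5.12), opt_loc = function(d) rep(0, d), opt_val = 0
    ),
    ackley = list(
      fn = function(x) {
        d <- length(x)
        -20 * exp(-0.2 * sqrt(sum(x^2) / d)) -
          exp(sum(cos(2 * pi * x)) / d) + 20 + exp(1)
      },
      bounds = c(-32, 32), opt_loc = function(d) rep(0, d), opt_val = 0
    ),
    griewank = list(
      fn = function(x) {
        sum(x^2) / 4000 - prod(cos(x / sqrt(seq_along(x)))) + 1
      },
      bounds = c(-600, 600), opt_loc = function(d) rep(0, d), opt_val = 0
    )
  )
})

#' List the available benchmark functions
#'
#' @return Character vector of registry names.
#' @export
benchmark_names <- function() names(.benchmark_registry)

#' Construct a benchmark function
#'
#' @param name Registry name; one of [benchmark_names()].
#' @param dimension Problem dimension (default 30).
#' @param bounds Length-2 numeric `c(lower, upper)` applied to every
#'   dimension, or a list `list(lower =, upper =)` of d-vectors. Defaults
#'   to the function's conventional domain.
#' @return An object of class `benchmark_function` with fields `name`,
#'   `dimension`, `space` (a [search_space()]), `fn`,
#'   `known_optimum_value`, `known_optimum_location`, and `stochastic`.
#' @examples
#' f <- make_benchmark("rastrigin", dimension = 3)
#' f$fn(rep(1, 3)) # 3
#' @export
make_benchmark <- function(name, dimension = 30, bounds = NULL) {
  if (!name %in% names(.benchmark_registry)) {
    stop("unknown benchmark '", name, "'; available: ",
         paste(names(.benchmark_registry), collapse = ", "))
  }
  entry <- .benchmark_registry[[name]]
  if (is.null(bounds)) bounds <- entry$bounds
  if (is.list(bounds)) {
    space <- search_space(bounds$lower, bounds$upper)
    if (space$d != dimension) stop("bounds do not match dimension")
  } else {
    space <- search_space(rep(bounds[1], dimension), rep(bounds[2], dimension))
  }
  loc <- entry$opt_loc(dimension)
  val <- entry$opt_val
  stochastic <- isTRUE(entry$stochastic)
  if (is.na(val) && !stochastic) val <- entry$fn(loc)
  structure(
    list(
      name = name,
      dimension = as.integer(dimension),
      space = space,
      fn = entry$fn,
      known_optimum_location = loc,
      known_optimum_value = val,
      stochastic = stochastic
    ),
    class = "benchmark_function"
  )
}

#' @export
print.benchmark_function <- function(x, ...) {
  cat(sprintf("<benchmark '%s', d = %d, bounds [%g, %g]>\n",
              x$name, x$dimension, x$space$lower[1], x$space$upper[1]))
  invisible(x)
}
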