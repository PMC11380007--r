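#' Multi-run benchmark experiment
#'
#' Runs the optimizer independently `runs` times on one benchmark
#' function (seeds `base_seed .. base_seed + runs - 1`) and summarises
#' the per-run best objective values as a mean/standard-deviation row,
#' the layout used by benchmark comparison tables.
#'
#' @param benchmark A [make_benchmark()] object, or a registry name.
#' @param config An [optimizer_config()]; its `seed` field is overridden
#'   per run.
#' @param runs Number of independent runs (default 20).
#' @param base_seed First seed of the run sequence.
#' @param seeds Optional explicit vector of seeds (length `runs`),
#'   overriding the `base_seed` arithmetic.
#' @param algorithm Label stored in the row (default derived from the
#'   intensity mode: `"DPOA"` or `"POA"`).
#' @param dimension,bounds Passed to [make_benchmark()] when `benchmark`
#'   is a name.
#' @return An object of class `dpoa_stats_row`: `benchmark`, `algorithm`,
#'   `avg` (mean of per-run bests), `std` (population standard
#'   deviation, i.e. divide by `runs`), `runs`, `iterations`,
#'   `per_run_best`, and `ledger` with the total `run_iterations`
#'   (`runs * iterations`) and objective evaluation count.
#' @examples
#' cfg <- dpoa_config(population_size = 10, max_iterations = 20)
#' run_experiment("sphere", cfg, runs = 3, base_seed = 1,
#'                dimension = 2, bounds = c(-1, 1))
#' @export
run_experiment <- function(benchmark, config, runs = 20, base_seed = 1,
                           seeds = NULL, algorithm = NULL,
                           dimension = 30, bounds = NULL) {
  if (is.character(benchmark)) {
    benchmark <- make_benchmark(benchmark, dimension = dimension, bounds = bounds)
  }
  stopifnot(inherits(benchmark, "benchmark_function"),
            inherits(config, "dpoa_config"))
  if (runs < 1) stop("runs must be at least 1")
  if (is.null(seeds)) seeds <- base_seed + seq_len(runs) - 1L
  if (length(seeds) != runs) stop("seeds must have length `runs`")
  if (is.null(algorithm)) {
    algorithm <- if (config$intensity_mode == "dynamic") "DPOA" else "POA"
  }

  best <- numeric(runs)
  total_evals <- 0L
  for (r in seq_len(runs)) {
    cfg <- config
    cfg$seed <- as.integer(seeds[r])
    res <- run_optimizer(benchmark$fn, benchmark$space, cfg)
    best[r] <- res$best_fitness
    total_evals <- total_evals + res$ledger$objective_evaluations
  }

  n <- length(best)
  avg <- mean(best)
  std <- sqrt(sum((best - avg)^2) / n)  # population formula

  structure(
    list(
      benchmark = benchmark$name,
      algorithm = algorithm,
      avg = avg,
      std = std,
      runs = as.integer(runs),
      iterations = config$max_iterations,
      per_run_best = best,
      ledger = list(
        run_iterations = as.integer(runs) * config$max_iterations,
        objective_evaluations = total_evals
      )
    ),
    class = "dpoa_stats_row"
  )
}

#' @export
print.dpoa_stats_row <- function(x, ...) {
  cat(sprintf("<%s on %s: AVG %.4g, STD %.4g over %d runs x %d iterations>\n",
              x$algorithm, x$benchmark, x$avg, x$std, x$runs, x$iterations))
  invisible(x)
}

#' Write benchmark statistics rows as a comparison table
#'
#' Produces a CSV mirroring the usual benchmark comparison layout: one
#' row group per function with AVG and STD sub-rows, one column per
#' algorithm.
#'
#' @param rows A list of `dpoa_stats_row` objects from [run_experiment()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_stats_table <- function(rows, path) {
  if (length(rows) == 0) stop("no rows to write")
  if (inherits(rows, "dpoa_stats_row")) rows <- list(rows)
  benches <- unique(vapply(rows, `[[`, "", "benchmark"))
  algos <- unique(vapply(rows, `[[`, "", "algorithm"))
  out <- data.frame(benchmark = rep(benches, each = 2),
                    stat = rep(c("AVG", "STD"), length(benches)),
                    stringsAsFactors = FALSE)
  for (a in algos) out[[a]] <- NA_real_
  for (row in rows) {
    i <- which(out$benchmark == row$benchmark)
    out[[row$algorithm]][i[1]] <- row$avg
    out[[row$algorithm]][i[2]] <- row$std
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a benchmark comparison table written by [write_stats_table()]
#'
#' @param path CSV path.
#' @return A data frame with columns `benchmark`, `stat`, and one numeric
#'   column per algorithm.
#' @export
read_stats_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
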