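#' Optimizer configuration for POA / DPOA
#'
#' Collects the tunable parameters of the pelican optimization algorithm
#' and its dynamic-intensity variant (DPOA).
#'
#' @param population_size Number of pelicans N (>= 2). Default 40.
#' @param max_iterations Iteration budget T (>= 1). Default 120.
#' @param exploitation_radius Local wing-flap radius R. Default 0.2.
#' @param intensity_mode `"fixed_set"` draws the exploration intensity I
#'   uniformly from `fixed_intensity_set` per member per iteration
#'   (baseline POA); `"dynamic"` uses the exponentially decaying schedule
#'   [dynamic_intensity()] (DPOA).
#' @param fixed_intensity_set Candidate intensities for the baseline mode.
#'   Default `c(1, 2)`.
#' @param intensity_max Peak intensity I_max of the dynamic schedule.
#'   Default 2.
#' @param decay_alpha Decay rate alpha of the dynamic schedule (>= 0).
#'   Default 1.
#' @param prey_mode `"per_member"` samples a fresh prey point for every
#'   member in every iteration (default); `"per_iteration"` samples one
#'   shared prey per iteration.
#' @param seed Integer seed making the whole run reproducible.
#' @return An object of class `dpoa_config`.
#' @seealso [run_optimizer()]
#' @export
optimizer_config <- function(population_size = 40,
                             max_iterations = 120,
                             exploitation_radius = 0.2,
                             intensity_mode = c("fixed_set", "dynamic"),
                             fixed_intensity_set = c(1, 2),
                             intensity_max = 2,
                             decay_alpha = 1,
                             prey_mode = c("per_member", "per_iteration"),
                             seed = 1L) {
  intensity_mode <- match.arg(intensity_mode)
  prey_mode <- match.arg(prey_mode)
  if (population_size < 2) stop("population_size must be at least 2")
  if (max_iterations < 1) stop("max_iterations must be at least 1")
  if (exploitation_radius <= 0) stop("exploitation_radius must be positive")
  if (intensity_max <= 0) stop("intensity_max must be positive")
  if (decay_alpha < 0) stop("decay_alpha must be non-negative")
  if (length(fixed_intensity_set) < 1 || any(fixed_intensity_set <= 0)) {
    stop("fixed_intensity_set must contain positive values")
  }
  structure(
    list(
      population_size = as.integer(population_size),
      max_iterations = as.integer(max_iterations),
      exploitation_radius = exploitation_radius,
      intensity_mode = intensity_mode,
      fixed_intensity_set = as.numeric(fixed_intensity_set),
      intensity_max = intensity_max,
      decay_alpha = decay_alpha,
      prey_mode = prey_mode,
      seed = as.integer(seed)
    ),
    class = "dpoa_config"
  )
}

#' DPOA configuration shorthand
#'
#' [optimizer_config()] preset with `intensity_mode = "dynamic"`.
#'
#' @inheritParams optimizer_config
#' @param ... Further arguments passed to [optimizer_config()].
#' @return A `dpoa_config` with the dynamic intensity schedule enabled.
#' @export
dpoa_config <- function(...) {
  optimizer_config(..., intensity_mode = "dynamic")
}

#' Initialize a pelican population uniformly within the bounds
#'
#' Each coordinate is drawn as `lower + u * (upper - lower)` with a fresh
#' uniform variate u per entry.
#'
#' @param space A [search_space()].
#' @param n Population size (>= 2).
#' @param u Optional n-by-d matrix of uniforms in `[0, 1]` overriding the
#'   random draws (used for deterministic checks).
#' @return An n-by-d matrix of positions.
#' @export
init_population <- function(space, n, u = NULL) {
  stopifnot(inherits(space, "dpoa_space"))
  if (n < 2) stop("population size must be at least 2")
  d <- space$d
  if (is.null(u)) {
    u <- matrix(runif(n * d), nrow = n, ncol = d)
  } else {
    u <- matrix(u, nrow = n, ncol = d)
  }
  lo <- matrix(space$lower, nrow = n, ncol = d, byrow = TRUE)
  hi <- matrix(space$upper, nrow = n, ncol = d, byrow = TRUE)
  lo + u * (hi - lo)
}

#' Sample a prey point uniformly within the search space
#'
#' The prey is a random point whose fitness gates the exploration branch:
#' members move towards a prey that beats their own fitness and away from
#' one that does not.
#'
#' @param space A [search_space()].
#' @param objective Objective function mapping a d-vector to a scalar.
#' @param u Optional d-vector of uniforms overriding the random draws.
#' @return A list with `position`, `fitness`, and `evaluations = 1`.
#' @export
sample_prey <- function(space, objective, u = NULL) {
  if (is.null(u)) u <- runif(space$d)
  pos <- space$lower + u * (space$upper - space$lower)
  list(position = pos, fitness = objective(pos), evaluations = 1L)
}

#' Exploration move towards (or away from) the prey
#'
#' If the prey improves on the member's own fitness the candidate is
#' `k + u * (p - I * k)` componentwise; otherwise `k + u * (k - p)`.
#' A fresh uniform u is drawn per component. The caller clips the result
#' back into the search space.
#'
#' @param position Current position k (d-vector).
#' @param own_fitness Fitness of `position`.
#' @param prey A prey list from [sample_prey()] (fields `position`,
#'   `fitness`).
#' @param intensity Exploration intensity I (> 0); an integer from the
#'   fixed set in baseline POA, a continuous decaying value in DPOA.
#' @param u Optional d-vector of uniforms overriding the random draws.
#' @return Candidate position (unclipped).
#' @export
exploration_move <- function(position, own_fitness, prey, intensity, u = NULL) {
  if (!all(is.finite(position))) stop("position must be finite")
  if (intensity <= 0) stop("intensity must be positive")
  if (is.null(u)) u <- runif(length(position))
  if (prey$fitness < own_fitness) {
    position + u * (prey$position - intensity * position)
  } else {
    position + u * (position - prey$position)
  }
}

#' Exploitation move: winging on the water surface
#'
#' Per component, `k + R * (1 - t/T) * (2u - 1) * k` with a fresh uniform
#' u per component: a multiplicative perturbation whose radius shrinks
#' linearly to zero over the iterations.
#'
#' @param position Current position (d-vector).
#' @param t Current iteration, `1 <= t <= max_iterations`.
#' @param max_iterations Iteration budget T.
#' @param radius Neighbourhood constant R (default 0.2).
#' @param u Optional d-vector of uniforms overriding the random draws.
#' @return Candidate position (unclipped).
#' @export
exploitation_move <- function(position, t, max_iterations, radius = 0.2,
                              u = NULL) {
  if (t < 1 || t > max_iterations) stop("iteration t out of range [1, T]")
  if (radius <= 0) stop("radius must be positive")
  if (is.null(u)) u <- runif(length(position))
  position + radius * (1 - t / max_iterations) * (2 * u - 1) * position
}

#' Greedy acceptance of a candidate position
#'
#' The candidate replaces the incumbent only on strict improvement
#' (ties keep the incumbent), so accepted fitness never increases.
#'
#' @param position Incumbent position.
#' @param fitness Incumbent fitness.
#' @param candidate Candidate position (already clipped to bounds).
#' @param objective Objective function.
#' @return List with the surviving `position`, `fitness`, a logical
#'   `accepted`, and `evaluations = 1`.
#' @export
greedy_select <- function(position, fitness, candidate, objective) {
  f_cand <- objective(candidate)
  if (!is.finite(f_cand)) {
    stop("objective returned a non-finite value at candidate ",
         paste(signif(candidate, 6), collapse = ", "))
  }
  if (f_cand < fitness) {
    list(position = candidate, fitness = f_cand, accepted = TRUE,
         evaluations = 1L)
  } else {
    list(position = position, fitness = fitness, accepted = FALSE,
         evaluations = 1L)
  }
}

#' Exponentially decaying exploration intensity (DPOA)
#'
#' `I_i = I_max * exp(-alpha * i / maxiter)`: the intensity starts near
#' `I_max` and decays smoothly, shifting the search from exploration to
#' exploitation. The value is used as a continuous scalar (no rounding).
#'
#' @param i Current iteration, `1 <= i <= maxiter`.
#' @param maxiter Total number of iterations.
#' @param intensity_max Peak intensity I_max (> 0).
#' @param alpha Decay rate (>= 0); `alpha = 0` freezes the intensity at
#'   `I_max`.
#' @return The intensity for iteration `i`, in `(0, I_max]`.
#' @examples
#' dynamic_intensity(120, 120, intensity_max = 2, alpha = 1) # 2 * exp(-1)
#' @export
dynamic_intensity <- function(i, maxiter, intensity_max = 2, alpha = 1) {
  if (maxiter <= 0) stop("maxiter must be positive")
  if (any(i < 1) || any(i > maxiter)) stop("iteration i out of range [1, maxiter]")
  if (intensity_max <= 0) stop("intensity_max must be positive")
  if (alpha < 0) stop("alpha must be non-negative")
  intensity_max * exp(-alpha * i / maxiter)
}

#' Run the pelican optimizer
#'
#' Executes the full POA/DPOA loop: uniform initialization, then per
#' iteration and per member a prey-directed exploration move and a local
#' exploitation move, each accepted greedily. Candidates are clipped to
#' the box bounds before evaluation.
#'
#' @param objective Function mapping a d-vector to a finite scalar to be
#'   minimized.
#' @param space A [search_space()].
#' @param config An [optimizer_config()] (or [dpoa_config()]).
#' @param update_objective Optional hook `function(t, best_position)`
#'   called at the start of every iteration; if it returns a function,
#'   that function becomes the objective for evaluations from then on
#'   (stored fitnesses are kept, preserving a non-increasing trace). Used
#'   by the classifier-tuning demo to refresh dynamic class weights.
#' @return An object of class `dpoa_result`: `best_position`,
#'   `best_fitness`, `trace` (best-so-far fitness per iteration,
#'   non-increasing), and `ledger` (`iterations`, `runs`,
#'   `run_iterations`, `objective_evaluations`).
#' @examples
#' sp <- search_space(c(-1, -1), c(1, 1))
#' cfg <- dpoa_config(population_size = 10, max_iterations = 30, seed = 7)
#' res <- run_optimizer(function(x) sum(x^2), sp, cfg)
#' res$best_fitness
#' @export
run_optimizer <- function(objective, space, config,
                          update_objective = NULL) {
  stopifnot(inherits(space, "dpoa_space"), inherits(config, "dpoa_config"))
  set.seed(config$seed)
  n <- config$population_size
  t_max <- config$max_iterations
  d <- space$d

  positions <- init_population(space, n)
  fitness <- numeric(n)
  for (i in seq_len(n)) fitness[i] <- objective(positions[i, ])
  if (!all(is.finite(fitness))) stop("objective returned non-finite values at initialization")
  evals <- n

  trace <- numeric(t_max)
  best <- min(fitness)

  for (t in seq_len(t_max)) {
    if (!is.null(update_objective)) {
      new_obj <- update_objective(t, positions[which.min(fitness), ])
      if (is.function(new_obj)) objective <- new_obj
    }
    i_dyn <- if (config$intensity_mode == "dynamic") {
      dynamic_intensity(t, t_max, config$intensity_max, config$decay_alpha)
    } else {
      NA_real_
    }
    if (config$prey_mode == "per_iteration") {
      prey <- sample_prey(space, objective)
      evals <- evals + 1L
    }
    for (i in seq_len(n)) {
      if (config$prey_mode == "per_member") {
        prey <- sample_prey(space, objective)
        evals <- evals + 1L
      }
      intensity <- if (config$intensity_mode == "dynamic") {
        i_dyn
      } else {
        config$fixed_intensity_set[sample.int(length(config$fixed_intensity_set), 1L)]
      }
      cand <- clip_to_space(
        exploration_move(positions[i, ], fitness[i], prey, intensity), space
      )
      sel <- greedy_select(positions[i, ], fitness[i], cand, objective)
      evals <- evals + 1L
      positions[i, ] <- sel$position
      fitness[i] <- sel$fitness

      cand <- clip_to_space(
        exploitation_move(positions[i, ], t, t_max, config$exploitation_radius),
        space
      )
      sel <- greedy_select(positions[i, ], fitness[i], cand, objective)
      evals <- evals + 1L
      positions[i, ] <- sel$position
      fitness[i] <- sel$fitness
    }
    best <- min(best, min(fitness))
    trace[t] <- best
  }

  i_best <- which.min(fitness)
  structure(
    list(
      best_position = positions[i_best, ],
      best_fitness = trace[t_max],
      final_population = positions,
      final_fitness = fitness,
      trace = trace,
      ledger = list(
        iterations = t_max,
        runs = 1L,
        run_iterations = t_max,
        objective_evaluations = evals
      ),
      config = config
    ),
    class = "dpoa_result"
  )
}

#' @export
print.dpoa_result <- function(x, ...) {
  cat(sprintf(
    "<pelican optimizer result: best fitness %.6g after %d iterations, %d evaluations>\n",
    x$best_fitness, x$ledger$iterations, x$ledger$objective_evaluations
  ))
  invisible(x)
}

#' Serialize an optimizer result to JSON
#'
#' @param result A `dpoa_result` from [run_optimizer()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_run_result <- function(result, path) {
  stopifnot(inherits(result, "dpoa_result"))
  jsonlite::write_json(
    list(
      best_position = result$best_position,
      best_fitness = result$best_fitness,
      trace = result$trace,
      ledger = result$ledger
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
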