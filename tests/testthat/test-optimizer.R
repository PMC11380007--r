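sphere <- function(x) sum(x^2)

test_that("population initialization follows lower + u * (upper - lower)", {
  sp <- search_space(-1, 3)
  pos <- init_population(sp, 2, u = matrix(c(0.25, 0), 2, 1))
  expect_equal(pos[1, 1], 0)       # -1 + 0.25 * 4
  expect_equal(pos[2, 1], -1)      # u = 0 lands on the lower bound

  cube <- search_space(rep(0, 3), rep(1, 3))
  set.seed(11)
  p <- init_population(cube, 5)
  expect_equal(dim(p), c(5, 3))
  expect_true(all(p >= 0 & p <= 1))
  expect_error(init_population(cube, 1), "at least 2")
})

test_that("prey sampling stays in bounds, is charged, and is reproducible", {
  sp <- search_space(c(0, 0, 0), c(1, 1, 1))
  prey_hi <- sample_prey(sp, sphere, u = rep(1, 3))
  expect_equal(prey_hi$position, sp$upper)
  expect_equal(prey_hi$evaluations, 1L)

  set.seed(5)
  many <- replicate(200, sample_prey(sp, sphere)$position)
  expect_true(all(many >= 0 & many <= 1))

  set.seed(42); a <- replicate(10, sample_prey(sp, sphere)$position)
  set.seed(42); b <- replicate(10, sample_prey(sp, sphere)$position)
  expect_identical(a, b)
})

test_that("exploration move matches its closed form in both branches", {
  better_prey <- list(position = c(0, 0), fitness = 0)
  # prey better, u = 1, I = 1: k + (p - k) lands on the prey
  expect_equal(
    exploration_move(c(2, 2), sphere(c(2, 2)), better_prey, 1, u = c(1, 1)),
    c(0, 0)
  )
  # u = 0 keeps the position in either branch
  expect_equal(
    exploration_move(c(2, 2), 8, better_prey, 2, u = c(0, 0)), c(2, 2)
  )
  worse_prey <- list(position = 3, fitness = 9)
  expect_equal(exploration_move(1, 1, worse_prey, 1, u = 1), -1)
  expect_error(exploration_move(c(NA, 1), 1, better_prey, 1), "finite")
  expect_error(exploration_move(c(1, 1), 2, better_prey, 0), "positive")
})

test_that("exploitation move shrinks its radius linearly to zero", {
  # u = 0.5 makes (2u - 1) vanish
  expect_equal(exploitation_move(c(1, -2), 3, 10, u = c(0.5, 0.5)), c(1, -2))
  # final iteration: radius is zero whatever u
  expect_equal(exploitation_move(c(1, -2), 10, 10, u = c(1, 0)), c(1, -2))
  # half way through, u = 1: factor 1 + R * 0.5
  expect_equal(exploitation_move(c(1, -2), 5, 10, radius = 0.2, u = c(1, 1)),
               c(1.1, -2.2))
  expect_error(exploitation_move(1, 0, 10), "out of range")
  expect_error(exploitation_move(1, 11, 10), "out of range")
})

test_that("greedy selection accepts only strict improvement", {
  sel <- greedy_select(c(1, 1), 2, c(0.5, 0.5), sphere)
  expect_true(sel$accepted)
  expect_equal(sel$fitness, 0.5)

  sel <- greedy_select(c(1, 1), 2, c(2, 2), sphere)
  expect_false(sel$accepted)
  expect_equal(sel$position, c(1, 1))

  # exact tie keeps the incumbent
  sel <- greedy_select(c(1, 1), 2, c(-1, 1), sphere)
  expect_false(sel$accepted)

  expect_error(greedy_select(1, 1, 2, function(x) NaN), "non-finite")
})

test_that("dynamic intensity decays exponentially and stays in (0, I_max]", {
  expect_equal(dynamic_intensity(120, 120, 2, 1), 2 * exp(-1))
  expect_equal(dynamic_intensity(1, 100, 2, 0), 2)  # alpha = 0 freezes I
  seq_i <- dynamic_intensity(1:50, 50, 2, 1.3)
  expect_true(all(diff(seq_i) < 0))
  expect_true(all(seq_i > 0 & seq_i <= 2))
  expect_error(dynamic_intensity(1, 0), "positive")
  expect_error(dynamic_intensity(0, 10), "out of range")
})

test_that("best-so-far trace is non-increasing and within bounds", {
  sp <- search_space(c(-1, -1), c(1, 1))
  objectives <- list(sphere = sphere,
                     rastrigin = function(x) sum(x^2 - 10 * cos(2 * pi * x) + 10),
                     constant = function(x) 7)
  for (nm in names(objectives)) {
    for (s in 1:3) {
      cfg <- dpoa_config(population_size = 8, max_iterations = 25, seed = s)
      res <- run_optimizer(objectives[[nm]], sp, cfg)
      expect_true(all(diff(res$trace) <= 0), info = paste(nm, s))
      expect_equal(res$best_fitness, res$trace[length(res$trace)])
      expect_true(all(res$final_population >= -1 & res$final_population <= 1))
    }
  }
  # constant objective never improves on the initial best
  cfg <- optimizer_config(population_size = 6, max_iterations = 10, seed = 2)
  res <- run_optimizer(function(x) 7, sp, cfg)
  expect_true(all(res$trace == 7))
})

test_that("identical seeds give bit-identical runs, and the ledger adds up", {
  sp <- search_space(c(-2, -2), c(2, 2))
  cfg <- dpoa_config(population_size = 7, max_iterations = 15, seed = 99)
  a <- run_optimizer(sphere, sp, cfg)
  b <- run_optimizer(sphere, sp, cfg)
  expect_identical(a$trace, b$trace)
  expect_identical(a$best_position, b$best_position)
  expect_equal(a$ledger$run_iterations, 15L)
  # N init + per member per iteration: 1 prey + 2 candidate evaluations
  expect_equal(a$ledger$objective_evaluations, 7 + 15 * 7 * 3)
})

test_that("longer searches find better sphere minima (median over seeds)", {
  sp <- search_space(c(-1, -1), c(1, 1))
  best_at <- function(iters, s) {
    cfg <- dpoa_config(population_size = 10, max_iterations = iters, seed = s)
    run_optimizer(sphere, sp, cfg)$best_fitness
  }
  short <- vapply(1:10, function(s) best_at(12, s), 0)
  long <- vapply(1:10, function(s) best_at(120, s), 0)
  expect_lt(median(long), median(short))
})

test_that("both intensity modes and prey granularities run", {
  sp <- search_space(c(-1, -1), c(1, 1))
  for (mode in c("fixed_set", "dynamic")) {
    for (prey in c("per_member", "per_iteration")) {
      cfg <- optimizer_config(population_size = 5, max_iterations = 10,
                              intensity_mode = mode, prey_mode = prey,
                              seed = 3)
      res <- run_optimizer(sphere, sp, cfg)
      expect_true(all(diff(res$trace) <= 0))
    }
  }
})

test_that("configuration invariants are enforced", {
  expect_error(optimizer_config(population_size = 1), "at least 2")
  expect_error(optimizer_config(max_iterations = 0), "at least 1")
  expect_error(optimizer_config(exploitation_radius = 0), "positive")
  expect_error(optimizer_config(decay_alpha = -1), "non-negative")
  expect_error(search_space(c(0, 0), c(1, 0)), "strictly below")
})
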