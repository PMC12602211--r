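# Real-coded genetic algorithm for time-minimal speed allocation, plus a
# brute-force grid oracle.

#' Genetic-algorithm parameters
#'
#' Defaults follow the published configuration for this problem: population
#' 500, at most 200 generations, mutation probability 0.2, crossover
#' probability 0.8. The remaining knobs (penalty weight, elitism,
#' stagnation stop, mutation scale, recombination window) are this
#' package's choices, documented in the methods vignette.
#'
#' @param population_size number of individuals (>= 2).
#' @param max_generations generation cap.
#' @param crossover_prob probability a selected pair is recombined.
#' @param mutation_prob per-gene mutation probability.
#' @param penalty_weight lambda (s/J): seconds of penalty per joule of
#'   budget overspend.
#' @param box_penalty_weight penalty (s per m/s) for speeds outside bounds;
#'   only externally injected strategies can violate bounds.
#' @param seed integer RNG seed; fixed seed gives bit-identical results.
#' @param elitism number of best individuals copied unchanged each
#'   generation (>= 1 guarantees monotone best objective).
#' @param stagnation_patience stop after this many generations without
#'   improvement; `Inf` disables.
#' @param mutation_scale mutation standard deviation as a fraction of each
#'   gene's bound interval.
#' @param smoothness_weight optional secondary objective weight on the
#'   variance of the speed vector (default 0 = pure time).
#' @return A `velo_ga_params` list.
#' @export
ga_params <- function(population_size = 500, max_generations = 200,
                      crossover_prob = 0.8, mutation_prob = 0.2,
                      penalty_weight = 0.01, box_penalty_weight = 1000,
                      seed = 1L, elitism = 1L, stagnation_patience = 30,
                      mutation_scale = 0.1, smoothness_weight = 0) {
  stopifnot_scalar(population_size, "population_size", 2)
  stopifnot_scalar(max_generations, "max_generations", 1)
  stopifnot_scalar(crossover_prob, "crossover_prob", 0, 1)
  stopifnot_scalar(mutation_prob, "mutation_prob", 0, 1)
  stopifnot_scalar(penalty_weight, "penalty_weight", 0)
  stopifnot_scalar(elitism, "elitism", 0)
  structure(list(population_size = as.integer(population_size),
                 max_generations = as.integer(max_generations),
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob,
                 penalty_weight = penalty_weight,
                 box_penalty_weight = box_penalty_weight,
                 seed = as.integer(seed), elitism = as.integer(elitism),
                 stagnation_patience = stagnation_patience,
                 mutation_scale = mutation_scale,
                 smoothness_weight = smoothness_weight),
            class = "velo_ga_params")
}

# objective on a precomputed context; lower is better
evaluate_ctx <- function(v, ctx, bounds, lambda, lambda_box, smooth = 0) {
  sim <- sim_fast(v, ctx, v_mb = bounds$corner_speed)
  viol <- sum(pmax(bounds$lower - v, 0) + pmax(v - bounds$upper, 0))
  obj <- sim$T + lambda * max(sim$W - ctx$w_all, 0) + lambda_box * viol
  if (smooth > 0 && length(v) > 1) obj <- obj + smooth * var(v)
  attr(obj, "T") <- sim$T
  attr(obj, "W") <- sim$W
  obj
}

#' Penalized objective of a strategy
#'
#' The quantity the optimizer minimizes: the simulated total time plus a
#' linear exterior penalty `lambda * max(W - W_all, 0)` for overspending
#' the energy budget, plus a box penalty for speeds outside the bounds.
#' Feasible strategies score exactly their total time; under-spending is
#' not penalized (time minimization itself drives spending toward the
#' budget).
#'
#' @param strategy numeric speed vector, one per segment.
#' @param course a [velo_course()].
#' @param rider a [rider()].
#' @param env a [race_env()].
#' @param lambda penalty weight (s/J).
#' @param lambda_box out-of-bounds penalty weight (s per m/s).
#' @param smoothness_weight optional weight on `var(strategy)`.
#' @return The objective in seconds, with attributes `T` (raw time) and
#'   `W` (spent budget).
#' @export
evaluate_strategy <- function(strategy, course, rider, env, lambda = 0.01,
                              lambda_box = 1000, smoothness_weight = 0) {
  if (length(strategy) != nrow(course))
    vp_validation_error("strategy length does not match the course")
  ctx <- course_context(course, rider, env)
  bounds <- speed_bounds(course, env, rider)
  evaluate_ctx(strategy, ctx, bounds, lambda, lambda_box, smoothness_weight)
}

#' Initialize a GA population
#'
#' Draws `n` speed vectors uniformly within the per-segment bounds. When a
#' `baseline` strategy is supplied it replaces the first member, so a
#' feasible individual is present from generation zero.
#'
#' @param bounds list with numeric `lower` and `upper` vectors.
#' @param n population size (>= 2).
#' @param seed optional integer seed (set once here when used standalone).
#' @param baseline optional strategy injected as member 1.
#' @return A numeric matrix, one row per individual.
#' @export
init_population <- function(bounds, n, seed = NULL, baseline = NULL) {
  if (any(bounds$lower > bounds$upper))
    vp_validation_error("empty bounds interval (lower > upper)")
  if (n < 2) vp_validation_error("population size must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  k <- length(bounds$lower)
  pop <- matrix(runif(n * k), nrow = n)
  pop <- sweep(pop, 2, bounds$upper - bounds$lower, `*`)
  pop <- sweep(pop, 2, bounds$lower, `+`)
  if (!is.null(baseline)) {
    if (length(baseline) != k)
      vp_validation_error("baseline length does not match the bounds")
    pop[1, ] <- pmin(pmax(as.numeric(baseline), bounds$lower), bounds$upper)
  }
  pop
}

#' Extended-intermediate (linear) recombination
#'
#' With probability `p_c` each gene pair is recombined as
#' `a + beta * (b - a)` with `beta` drawn uniformly from
#' `[-0.25, 1.25]` (independently per gene and per offspring), then clipped
#' to the bounds; otherwise the parents are copied unchanged.
#'
#' @param parent_a,parent_b numeric vectors of equal length.
#' @param bounds list with `lower`/`upper`.
#' @param p_c crossover probability for the pair.
#' @return A list of two offspring vectors. Consumes the current RNG
#'   stream.
#' @export
linear_recombination <- function(parent_a, parent_b, bounds, p_c = 0.8) {
  if (length(parent_a) != length(parent_b))
    vp_validation_error("parents must have equal length")
  if (runif(1) > p_c) return(list(parent_a, parent_b))
  k <- length(parent_a)
  mk <- function() {
    beta <- runif(k, -0.25, 1.25)
    pmin(pmax(parent_a + beta * (parent_b - parent_a), bounds$lower),
         bounds$upper)
  }
  list(mk(), mk())
}

#' Real-valued Gaussian mutation
#'
#' Each gene is independently mutated with probability `p_m` by adding a
#' zero-mean Gaussian perturbation with standard deviation
#' `scale * (upper - lower)`, then clipped to the bounds.
#'
#' @param strategy numeric speed vector.
#' @param p_m per-gene mutation probability.
#' @param bounds list with `lower`/`upper`.
#' @param scale perturbation standard deviation as a fraction of the bound
#'   interval.
#' @return The mutated vector. Consumes the current RNG stream.
#' @export
real_mutation <- function(strategy, p_m, bounds, scale = 0.1) {
  k <- length(strategy)
  hit <- runif(k) < p_m
  if (any(hit)) {
    pert <- rnorm(sum(hit), 0, scale * (bounds$upper - bounds$lower)[hit])
    strategy[hit] <- strategy[hit] + pert
    strategy <- pmin(pmax(strategy, bounds$lower), bounds$upper)
  }
  strategy
}

#' Binary tournament selection
#'
#' Draws `n` parents with replacement: each parent is the better (lower
#' penalized objective) of two uniformly drawn individuals, ties broken
#' uniformly at random.
#'
#' @param population numeric matrix, one individual per row.
#' @param objectives numeric vector of penalized objectives.
#' @param n number of parents to return.
#' @return Integer vector of selected row indices. Consumes the current
#'   RNG stream.
#' @export
select_parents <- function(population, objectives, n) {
  m <- nrow(population)
  if (length(objectives) != m)
    vp_validation_error("objectives length does not match the population")
  a <- sample.int(m, n, replace = TRUE)
  b <- sample.int(m, n, replace = TRUE)
  pick_a <- objectives[a] < objectives[b] |
    (objectives[a] == objectives[b] & runif(n) < 0.5)
  ifelse(pick_a, a, b)
}

#' Optimize the pacing strategy with a genetic algorithm
#'
#' Minimizes total course time over per-segment speeds subject to the
#' above-recovery energy budget. Bounds per segment are the recovery speed
#' (lower) and the class/corner cap (upper); the budget constraint is
#' handled by a linear exterior penalty, and the budget-exhausting
#' constant-power baseline is injected into the initial population so a
#' feasible solution exists from the start. The loop is generational with
#' elitism: evaluate, binary-tournament select, extended-intermediate
#' recombination, Gaussian mutation, then the elites replace the worst
#' offspring. Elitism makes the best objective non-increasing across
#' generations.
#'
#' @param course a [velo_course()].
#' @param rider a [rider()].
#' @param env a [race_env()].
#' @param ga a [ga_params()].
#' @return A `velo_ga_result` list: `best` (speed vector), `best_time_s`,
#'   `best_work_J`, `best_objective`, `feasible`, `history` (per-generation
#'   data.frame of best objective/time/work), `evaluations`, `termination`,
#'   `bounds`, `baseline` (the injected constant-power strategy) and
#'   `ga` (the parameters used).
#' @examples
#' \donttest{
#' res <- optimize_pacing(make_bridge_course(mode = "up_down"), rider(),
#'                        race_env(), ga_params(population_size = 60,
#'                                              max_generations = 30))
#' res$best_time_s
#' }
#' @export
optimize_pacing <- function(course, rider, env, ga = ga_params()) {
  ctx <- course_context(course, rider, env)
  bounds <- speed_bounds(course, env, rider)
  bad <- which(bounds$lower > bounds$upper)
  if (length(bad))
    vp_validation_error(sprintf(
      "segment %d has infeasible speed bounds after caps", bad[1]))

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(ga$seed)

  baseline <- constant_power_baseline(course, rider, env)
  n <- ga$population_size
  pop <- init_population(bounds, n, baseline = baseline)

  eval_one <- function(v) evaluate_ctx(v, ctx, bounds, ga$penalty_weight,
                                       ga$box_penalty_weight,
                                       ga$smoothness_weight)
  obj <- apply(pop, 1, function(v) as.numeric(eval_one(v)))
  evals <- n

  best_feasible <- NULL
  best_feasible_T <- Inf
  note_feasible <- function(v) {
    sim <- sim_fast(v, ctx, v_mb = bounds$corner_speed)
    if (sim$W <= ctx$w_all + 1 && sim$T < best_feasible_T) {
      best_feasible <<- v
      best_feasible_T <<- sim$T
    }
  }
  for (i in seq_len(n)) note_feasible(pop[i, ])

  history <- data.frame(generation = integer(0), best_objective = numeric(0),
                        best_time_s = numeric(0), best_work_J = numeric(0))
  stagnant <- 0L
  best_prev <- min(obj)
  termination <- "max_generations"

  for (gen in seq_len(ga$max_generations)) {
    ord <- order(obj)
    n_elite <- min(ga$elitism, n)
    elites <- pop[ord[seq_len(n_elite)], , drop = FALSE]
    elite_obj <- obj[ord[seq_len(n_elite)]]

    n_off <- n - n_elite
    offspring <- matrix(0, nrow = n_off, ncol = ncol(pop))
    filled <- 0L
    while (filled < n_off) {
      par_idx <- select_parents(pop, obj, 2L)
      kids <- linear_recombination(pop[par_idx[1], ], pop[par_idx[2], ],
                                   bounds, ga$crossover_prob)
      for (kid in kids) {
        if (filled >= n_off) break
        kid <- real_mutation(kid, ga$mutation_prob, bounds,
                             ga$mutation_scale)
        filled <- filled + 1L
        offspring[filled, ] <- kid
      }
    }
    off_obj <- apply(offspring, 1, function(v) as.numeric(eval_one(v)))
    evals <- evals + n_off
    for (i in seq_len(n_off)) note_feasible(offspring[i, ])

    pop <- rbind(elites, offspring)
    obj <- c(elite_obj, off_obj)

    best_now <- min(obj)
    i_best <- which.min(obj)
    e <- eval_one(pop[i_best, ])
    history <- rbind(history, data.frame(
      generation = gen, best_objective = best_now,
      best_time_s = attr(e, "T"), best_work_J = attr(e, "W")))

    if (best_now < best_prev - 1e-9) stagnant <- 0L else
      stagnant <- stagnant + 1L
    best_prev <- min(best_prev, best_now)
    if (is.finite(ga$stagnation_patience) &&
        stagnant >= ga$stagnation_patience) {
      termination <- "stagnation"
      break
    }
  }

  i_best <- which.min(obj)
  best <- if (!is.null(best_feasible)) best_feasible else pop[i_best, ]
  e <- eval_one(best)
  sim <- sim_fast(best, ctx, v_mb = bounds$corner_speed)
  structure(list(
    best = as.numeric(best),
    best_time_s = sim$T,
    best_work_J = sim$W,
    best_objective = as.numeric(e),
    feasible = !is.null(best_feasible),
    history = history,
    evaluations = evals,
    termination = termination,
    bounds = bounds,
    baseline = baseline,
    ga = ga
  ), class = "velo_ga_result")
}

#' @export
print.velo_ga_result <- function(x, ...) {
  cat(sprintf(
    "<velo_ga_result> best T = %.3f s, W = %.1f J, %s after %d generations (%d evaluations, %s)\n",
    x$best_time_s, x$best_work_J,
    if (x$feasible) "feasible" else "INFEASIBLE",
    nrow(x$history), x$evaluations, x$termination))
  invisible(x)
}

#' Brute-force grid oracle
#'
#' Exhaustively evaluates every strategy on the Cartesian product of
#' per-segment speed grids (equally spaced within the bounds) and returns
#' the feasible grid point with the minimal total time. Intended as an
#' independent oracle for validating the GA on small courses; refuses grids
#' above `10^7` points.
#'
#' @param course a [velo_course()].
#' @param rider a [rider()].
#' @param env a [race_env()].
#' @param grid_points number of grid points per segment.
#' @return The optimal speed vector with attributes `time_s`, `work_J`,
#'   `n_evaluated`.
#' @export
brute_force_optimum <- function(course, rider, env, grid_points = 11) {
  ctx <- course_context(course, rider, env)
  bounds <- speed_bounds(course, env, rider)
  n_seg <- ctx$n
  total <- grid_points^n_seg
  if (total > 1e7)
    vp_validation_error(sprintf(
      "grid of %g points exceeds the 1e7 guard (%d points x %d segments)",
      total, grid_points, n_seg))
  axes <- lapply(seq_len(n_seg), function(i)
    seq(bounds$lower[i], bounds$upper[i], length.out = grid_points))
  grid <- as.matrix(expand.grid(axes))
  best_v <- NULL; best_T <- Inf; best_W <- NA_real_
  for (i in seq_len(nrow(grid))) {
    sim <- sim_fast(grid[i, ], ctx, v_mb = bounds$corner_speed)
    if (sim$W <= ctx$w_all + 1e-9 && sim$T < best_T) {
      best_v <- grid[i, ]; best_T <- sim$T; best_W <- sim$W
    }
  }
  if (is.null(best_v))
    vp_numerical_error("no feasible grid point found")
  structure(as.numeric(best_v), time_s = best_T, work_J = best_W,
            n_evaluated = nrow(grid))
}
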