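#' Genetic-algorithm configuration
#'
#' @param generations Number of generations (default 300; hard search
#'   problems use up to 1000).
#' @param population_size Models per generation (default 10).
#' @param n_elite Unmutated top models carried over (default 1, preventing
#'   search degeneration).
#' @param mutation_sd Standard deviation of the multiplicative mutation
#'   factor `N(1, sd)`.
#' @param additive_range Half-width of the uniform additive mutation term.
#' @return An `emd_evolution_config`.
#' @export
evolution_config <- function(generations = 300, population_size = 10,
                             n_elite = 1, mutation_sd = 0.1,
                             additive_range = 0.015) {
  if (population_size < 2) stop_invalid("population_size must be >= 2")
  if (n_elite < 1) stop_invalid("n_elite must be >= 1")
  structure(list(generations = generations,
                 population_size = population_size, n_elite = n_elite,
                 mutation_sd = mutation_sd, additive_range = additive_range),
            class = "emd_evolution_config")
}

#' Evolve a circuit with the elitist genetic algorithm
#'
#' Seeds a population of randomized genomes, evaluates their directional
#' fitness, and iterates: the best model is kept intact and seeds the next
#' generation, whose remaining slots are mutated copies of it. Best fitness
#' is therefore non-decreasing. The run is fully determined by
#' `(template, chassis, config, seed)`.
#'
#' @param template An `emd_genome` template (see [genome_template()]).
#' @param chassis An `emd_chassis` (see [build_chassis()]).
#' @param config An [evolution_config()].
#' @param seed Integer master seed.
#' @return An `emd_run` with the best genome, its evaluation, and the
#'   per-generation history; see [tidy.emd_run()] and [autoplot.emd_run()].
#' @export
evolve <- function(template, chassis, config = evolution_config(),
                   seed = NULL) {
  with_seed(seed, {
    pop <- seed_population(template, config$population_size)
    evals <- lapply(pop, evaluate_fitness, chassis = chassis)
    fits <- vapply(evals, `[[`, numeric(1), "fitness")
    history <- vector("list", config$generations + 1L)
    best_i <- which.max(fits)
    best <- pop[[best_i]]; best_eval <- evals[[best_i]]
    history[[1]] <- tibble(generation = 0L, best_fitness = best_eval$fitness,
                           best_dsi = best_eval$mean_dsi)
    for (gen in seq_len(config$generations)) {
      n_mut <- config$population_size - config$n_elite
      children <- lapply(seq_len(n_mut), function(i) {
        mutate_genome(best, config$mutation_sd, config$additive_range)
      })
      child_evals <- lapply(children, evaluate_fitness, chassis = chassis)
      child_fits <- vapply(child_evals, `[[`, numeric(1), "fitness")
      ci <- which.max(child_fits)
      if (child_fits[ci] > best_eval$fitness) {
        best <- children[[ci]]
        best_eval <- child_evals[[ci]]
      }
      history[[gen + 1L]] <- tibble(generation = gen,
                                    best_fitness = best_eval$fitness,
                                    best_dsi = best_eval$mean_dsi)
    }
    structure(list(best = best, best_eval = best_eval,
                   history = bind_rows(history), config = config,
                   template = template, chassis = chassis, seed = seed),
              class = "emd_run")
  })
}

#' @export
print.emd_run <- function(x, ...) {
  cat(sprintf("<emd_run> %d generations, best fitness %.4f, mean DSI %.3f\n",
              max(x$history$generation), x$best_eval$fitness,
              x$best_eval$mean_dsi))
  invisible(x)
}

#' Exhaustive grid search on a minimal model
#'
#' Brute-force evaluation over a parameter lattice, used as an optimization
#' oracle against the genetic algorithm on low-dimensional minimal models.
#'
#' @param template An `emd_genome`.
#' @param chassis An `emd_chassis`.
#' @param grid Named list: `"name.pop.unit" = values`; at most 6 parameters.
#' @param max_points Refusal threshold on the lattice size.
#' @return List with `best` (genome), `best_fitness`, and `landscape` (a
#'   tibble of all evaluated points).
#' @export
grid_search_minimal <- function(template, chassis, grid, max_points = 50000) {
  if (length(grid) > 6) stop_invalid("grid search supports at most 6 free parameters")
  npts <- prod(lengths(grid))
  if (npts > max_points) {
    stop_invalid(sprintf("grid too large: %d points (limit %d)", npts,
                         max_points))
  }
  lattice <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  keys <- strsplit(names(grid), ".", fixed = TRUE)
  fit <- numeric(nrow(lattice))
  best <- NULL; best_fit <- -Inf
  for (r in seq_len(nrow(lattice))) {
    g <- template
    for (j in seq_along(keys)) {
      g <- set_genome_value(g, keys[[j]][1], keys[[j]][2],
                            as.integer(keys[[j]][3]), lattice[r, j])
    }
    fit[r] <- evaluate_fitness(g, chassis)$fitness
    if (fit[r] > best_fit) { best_fit <- fit[r]; best <- g }
  }
  landscape <- as_tibble(lattice)
  landscape$fitness <- fit
  list(best = best, best_fitness = best_fit, landscape = landscape)
}
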