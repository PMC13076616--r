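# genome machinery and the elitist genetic algorithm

test_that("seeded populations respect initialization limits and sharing", {
  tpl <- genome_template(free = c("delay", "rise", "decay"),
                         shared = c("size_x", "size_y"), dt_stim = 5)
  pop <- emdevolve:::with_seed(3, seed_population(tpl, 10))
  expect_length(pop, 10)
  for (g in pop) {
    p <- g$params
    free <- p[p$free, ]
    expect_true(all(free$value >= free$init_lo - 1e-12 &
                      free$value <= free$init_hi + 1e-12))
    # shared parameters identical across the four groups
    sx <- p$value[p$name == "size_x" & p$pop == "exc"]
    expect_equal(length(unique(sx)), 1L)
    # independent parameters differ across groups (almost surely)
    de <- p$value[p$name == "delay" & p$pop == "exc"]
    expect_gt(length(unique(de)), 1L)
  }
  # all-fixed template: every genome identical
  tpl0 <- genome_template(dt_stim = 5)
  pop0 <- emdevolve:::with_seed(3, seed_population(tpl0, 5))
  for (g in pop0) expect_identical(g$params$value, tpl0$params$value)
})

test_that("mutation is bounded, shared-aware, and unbiased", {
  tpl <- genome_template(free = c("rise", "decay"), shared = "size_x",
                         dt_stim = 5)
  parent <- emdevolve:::with_seed(1, emdevolve:::randomize_genome(tpl))
  child <- emdevolve:::with_seed(2, mutate_genome(parent))
  p <- child$params
  expect_true(all(p$value >= p$lower - 1e-12 & p$value <= p$upper + 1e-12))
  sx <- p$value[p$name == "size_x" & p$pop == "exc"]
  expect_equal(length(unique(sx)), 1L)
  # degenerate mutation is the identity
  same <- mutate_genome(parent, sd = 0, additive = 0)
  expect_equal(same$params$value, parent$params$value)
  # long mutation chains never escape the bounds
  g <- parent
  emdevolve:::with_seed(9, for (i in 1:200) g <- mutate_genome(g))
  expect_true(all(g$params$value >= g$params$lower - 1e-12 &
                    g$params$value <= g$params$upper + 1e-12))
  # multiplicative N(1, 0.1) plus symmetric uniform leaves the mean at p
  vals <- emdevolve:::with_seed(5, vapply(1:4000, function(i) {
    mutate_genome(parent)$params$value[
      parent$params$name == "rise" & parent$params$unit == 1][1]
  }, numeric(1)))
  target <- parent$params$value[parent$params$name == "rise" &
                                  parent$params$unit == 1][1]
  expect_equal(mean(vals), target, tolerance = 0.01)
})

test_that("evolution is elitist, monotone, and bit-reproducible", {
  ch <- minimal_chassis()
  tpl <- genome_template(free = "w_syn", shared = c("rise", "decay"),
                         n_groups = 2, dt_stim = 5)
  run <- evolve(tpl, ch, evolution_config(generations = 15), seed = 42)
  expect_true(all(diff(run$history$best_fitness) >= 0))
  run2 <- evolve(tpl, ch, evolution_config(generations = 15), seed = 42)
  expect_identical(run$best$params$value, run2$best$params$value)
  expect_identical(run$history, run2$history)
  expect_identical(tidy(run), run$history)
  expect_equal(glance(run)$best_fitness, run$best_eval$fitness)
})

test_that("fitness is zero for untuned circuits and saturates via tanh", {
  ch <- minimal_chassis()
  tpl <- genome_template(n_groups = 2, dt_stim = 5)  # all fixed, symmetric
  ev <- evaluate_fitness(tpl, ch)
  expect_equal(ev$dsi[1], 0, tolerance = 1e-9)
  expect_equal(ev$fitness, 0, tolerance = 1e-9)
  # doubling every weight (responses) never decreases the metric
  tpl2 <- emdevolve:::set_genome_value(tpl, "w_syn", "exc", 1, 0.6)
  tpl2 <- emdevolve:::set_genome_value(tpl2, "w_syn", "exc", 2, 1.2)
  ev1 <- evaluate_fitness(tpl2, ch)
  tpl3 <- emdevolve:::set_genome_value(tpl, "w_syn", "exc", 1, 1.2)
  tpl3 <- emdevolve:::set_genome_value(tpl3, "w_syn", "exc", 2, 2)
  ev2 <- evaluate_fitness(tpl3, ch)
  expect_gte(ev2$fitness, ev1$fitness - 1e-9)
})

test_that("grid search refuses huge lattices and finds the lattice optimum", {
  ch <- minimal_chassis()
  tpl <- genome_template(free = "w_syn", shared = c("rise", "decay"),
                         n_groups = 2, dt_stim = 5)
  expect_error(grid_search_minimal(tpl, ch,
                                   list(`w_syn.exc.1` = 1:100,
                                        `w_syn.exc.2` = 1:100,
                                        `rise.exc.1` = 1:10),
                                   max_points = 5000),
               class = "emd_invalid_parameter")
  gr <- grid_search_minimal(tpl, ch, list(`w_syn.exc.1` = c(0.5, 1, 2)))
  expect_equal(nrow(gr$landscape), 3)
  expect_equal(gr$best_fitness, max(gr$landscape$fitness))
  # single-point grid returns that point
  g1 <- grid_search_minimal(tpl, ch, list(`w_syn.exc.1` = 0.7))
  expect_equal(emdevolve:::genome_value(g1$best, "w_syn", "exc", 1), 0.7)
})
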