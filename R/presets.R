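# Experiment presets: the packaged circuit-configuration scenarios. Each
# preset declares which parameters are free (per input group), which are
# shared, the back-end, and the stimulus protocol.

preset_registry <- function() {
  list(
    kinetic = list(
      desc = "free temporal dynamics (delay/rise/decay) per excitatory group",
      free = c("delay", "rise", "decay"), shared = c("size_x", "size_y")),
    rf_size = list(
      desc = "free center receptive-field size per excitatory group",
      free = "size_x", size_locked = TRUE,
      shared = c("rise", "decay")),
    orientation = list(
      desc = "free receptive-field orientation per group, elliptical centers",
      free = "orientation", shared = c("size_x", "size_y", "rise", "decay")),
    surround_strength = list(
      desc = "free surround strength per group", surround = TRUE,
      free = "w_surround", shared = c("size_x", "size_y", "rise", "decay",
                                      "sur_size", "sur_rise", "sur_decay")),
    surround_kinetics = list(
      desc = "free surround kinetics per group", surround = TRUE,
      free = c("sur_rise", "sur_decay"),
      shared = c("size_x", "size_y", "rise", "decay", "sur_size",
                 "w_surround")),
    surround_extent = list(
      desc = "free surround size per group", surround = TRUE,
      free = "sur_size",
      shared = c("size_x", "size_y", "rise", "decay", "w_surround")),
    weights = list(
      desc = "free synaptic weight per excitatory cell, single shared RF",
      free = character(), per_cell_weights = TRUE,
      shared = c("size_x", "size_y", "rise", "decay")),
    weights_minimal = list(
      desc = "two-cell minimal model, free weights, shared kinetics",
      backend = "minimal", free = "w_syn", n_groups = 2,
      shared = c("size_x", "size_y", "rise", "decay"),
      speeds = 1, directions = c(0, pi)),
    inhibition_weights = list(
      desc = "symmetric excitation, free inhibitory weight per group",
      n_inh = 100, pops = c("exc", "inh"), free = "inh:w_syn",
      shared = c("size_x", "size_y", "rise", "decay", "inh:size_x",
                 "inh:size_y", "inh:rise", "inh:decay")),
    inhibition_kinetics = list(
      desc = "free inhibitory kinetics per group",
      n_inh = 100, pops = c("exc", "inh"),
      free = c("inh:delay", "inh:rise", "inh:decay"),
      shared = c("size_x", "size_y", "rise", "decay", "inh:size_x",
                 "inh:size_y")),
    inhibition_rf_size = list(
      desc = "free inhibitory receptive-field size per group",
      n_inh = 100, pops = c("exc", "inh"), size_locked = TRUE,
      free = "inh:size_x",
      shared = c("size_x", "size_y", "rise", "decay", "inh:rise",
                 "inh:decay")),
    inhibition_surround = list(
      desc = "free inhibitory surround strength per group",
      n_inh = 100, pops = c("exc", "inh"), inh_surround = TRUE,
      free = "inh:w_surround",
      shared = c("size_x", "size_y", "rise", "decay", "inh:size_x",
                 "inh:size_y", "inh:rise", "inh:decay", "inh:sur_size",
                 "inh:sur_rise", "inh:sur_decay")),
    cortical = list(
      desc = "pyramidal-like morphology, spiking afferents, random wiring",
      placement = "cortex", morph = "pyramidal",
      free = c("delay", "rise", "decay"), shared = c("size_x", "size_y")),
    velocity_noise = list(
      desc = "noise-robustness probing of evolved circuits",
      free = c("delay", "rise", "decay"), shared = c("size_x", "size_y")),
    noise_mapping = list(
      desc = "1-D contrast-noise space-time receptive-field mapping",
      free = c("delay", "rise", "decay"), shared = c("size_x", "size_y")),
    symmetric_control = list(
      desc = "all input groups identical: every parameter shared",
      free = character(),
      shared = c("size_x", "size_y", "rise", "decay", "w_syn"))
  )
}

#' List available experiment presets
#'
#' @return Tibble of preset names and descriptions.
#' @export
preset_names <- function() {
  reg <- preset_registry()
  tibble(name = names(reg),
         description = vapply(reg, `[[`, character(1), "desc"))
}

#' Load an experiment preset
#'
#' Returns a fully populated, validated experiment configuration for one of
#' the packaged circuit scenarios (see [preset_names()]). Any field can be
#' overridden, which is how reduced-scale campaigns are requested.
#'
#' @param name Preset name.
#' @param ... Overrides of configuration fields (e.g. `generations = 50`,
#'   `n_exc = 16`, `morph_segments = 40`).
#' @return An `emd_config`.
#' @export
load_preset <- function(name, ...) {
  reg <- preset_registry()
  if (!name %in% names(reg)) {
    stop_invalid("unknown preset '", name, "'; available: ",
                 paste(names(reg), collapse = ", "))
  }
  p <- reg[[name]]
  cfg <- list(
    preset = name,
    backend = p$backend %||% "compartmental",
    placement = p$placement %||% "retina",
    morph_kind = p$morph %||% "dsgc",
    n_exc = p$n_exc %||% 100, n_inh = p$n_inh %||% 0,
    n_groups = p$n_groups %||% 4,
    pops = p$pops %||% "exc",
    free = p$free, shared = p$shared %||% character(),
    per_cell_weights = isTRUE(p$per_cell_weights),
    size_locked = isTRUE(p$size_locked),
    surround = isTRUE(p$surround), inh_surround = isTRUE(p$inh_surround),
    plasticity = isTRUE(p$plasticity),
    speeds = p$speeds %||% c(0.25, 0.5, 1, 2, 4),
    directions = p$directions %||% (2 * pi * (0:11) / 12),
    protocol = p$protocol %||% "bar",
    arena_width = 800, arena_pixel = 5, dt_stim = 5, dt_v = 0.1,
    morph_segments = if ((p$morph %||% "dsgc") == "pyramidal") 69 else 352,
    morph_radius = 150, placement_radius = 150, g_unit = 0.75,
    generations = 300, population_size = 10, n_elite = 1,
    mutation_sd = 0.1, additive_range = 0.015, n_runs = 20,
    separation = 100, seed = 1L)
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(cfg)) stop_invalid("unknown config field: ", nm)
    cfg[[nm]] <- over[[nm]]
  }
  validate_config(structure(cfg, class = "emd_config"))
}

#' Validate an experiment configuration
#'
#' @param config An `emd_config`.
#' @return The config, invisibly-checked (errors on invalid fields).
#' @export
validate_config <- function(config) {
  stopifnot(is.list(config))
  with(config, {
    check_positive(arena_width, "arena_width")
    check_positive(dt_stim, "dt_stim"); check_positive(dt_v, "dt_v")
    if (population_size < 2) stop_invalid("population_size must be >= 2")
    if (generations < 1) stop_invalid("generations must be >= 1")
    if (!backend %in% c("compartmental", "point", "minimal")) {
      stop_invalid("unknown backend: ", backend)
    }
    if (length(speeds) < 1 || any(speeds <= 0)) {
      stop_invalid("speeds must be positive")
    }
  })
  config
}

#' Write / read an experiment configuration as YAML
#'
#' Configurations round-trip losslessly through their YAML representation.
#'
#' @param config An `emd_config`.
#' @param path File path.
#' @return `read_config()` returns the `emd_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(config)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  validate_config(structure(yaml::read_yaml(path), class = "emd_config"))
}

# materialize template + chassis from a config (chassis seeded per run)
config_template <- function(config) {
  genome_template(
    free = config$free, shared = config$shared, pops = config$pops,
    n_groups = config$n_groups,
    per_cell_weights = config$per_cell_weights,
    n_cells = config$n_exc, dt_stim = config$dt_stim,
    circular = config$size_locked)
}

config_chassis <- function(config, run_seed) {
  ar <- arena(config$arena_width, config$arena_width, config$arena_pixel,
              config$dt_stim)
  morph <- if (config$backend == "compartmental" &&
               config$morph_kind == "pyramidal") {
    generate_pyramidal_morphology(config$morph_segments,
                                  seed = derive_seed(run_seed, "morph"))
  } else NULL
  build_chassis(
    backend = config$backend, n_exc = config$n_exc, n_inh = config$n_inh,
    n_groups = config$n_groups, arena = ar, speeds = config$speeds,
    directions = config$directions, placement = config$placement,
    placement_radius = config$placement_radius, morph = morph,
    morph_segments = config$morph_segments,
    morph_radius = config$morph_radius, g_unit = config$g_unit,
    dt_v = config$dt_v, surround = config$surround,
    inh_surround = config$inh_surround, plasticity = config$plasticity,
    protocol = config$protocol, separation = config$separation,
    seed = run_seed)
}

#' Run a full evolution experiment
#'
#' Orchestrates a preset: for each run, a fresh chassis (placement,
#' morphology) is built from a derived seed and the genetic algorithm is
#' evolved; results are collected into an archive with per-run summaries and
#' full seed provenance.
#'
#' @param config An `emd_config` from [load_preset()].
#' @param seed Master seed (defaults to `config$seed`).
#' @param keep_runs Keep the full `emd_run` objects (memory-heavy for large
#'   campaigns); summaries are always kept.
#' @return An `emd_archive`: list with `config`, `summary` (tibble with one
#'   row per run: fitness, mean DSI, per-speed DSI), `runs` (if kept), and
#'   `seeds`.
#' @export
run_experiment <- function(config, seed = NULL, keep_runs = TRUE) {
  seed <- seed %||% config$seed
  template <- config_template(config)
  ga <- evolution_config(config$generations, config$population_size,
                         config$n_elite, config$mutation_sd,
                         config$additive_range)
  run_seeds <- vapply(seq_len(config$n_runs), function(r) {
    derive_seed(seed, paste0("run", r))
  }, integer(1))
  runs <- vector("list", config$n_runs)
  rows <- vector("list", config$n_runs)
  for (r in seq_len(config$n_runs)) {
    chassis <- config_chassis(config, run_seeds[r])
    fit <- evolve(template, chassis, ga, seed = run_seeds[r])
    rows[[r]] <- tibble(run = r, seed = run_seeds[r],
                        fitness = fit$best_eval$fitness,
                        mean_dsi = fit$best_eval$mean_dsi,
                        dsi = list(fit$best_eval$dsi))
    if (keep_runs) runs[[r]] <- fit
  }
  structure(list(config = config, summary = bind_rows(rows),
                 runs = if (keep_runs) runs, seeds = run_seeds,
                 master_seed = seed),
            class = "emd_archive")
}

#' Summarize an experiment archive
#'
#' @param archive An `emd_archive`.
#' @return The summary tibble, invisibly; prints a human-readable report.
#' @export
report <- function(archive) {
  s <- archive$summary
  cfg <- archive$config
  cat(sprintf("Experiment '%s': %d runs x %d generations (master seed %s)\n",
              cfg$preset, nrow(s), cfg$generations, archive$master_seed))
  cat(sprintf("  fitness: %.4f +/- %.4f\n", mean(s$fitness), sd(s$fitness)))
  cat(sprintf("  mean DSI: %.2f%% +/- %.2f%%\n", 100 * mean(s$mean_dsi),
              100 * sd(s$mean_dsi)))
  conds <- if (cfg$protocol == "grating") "period" else "speed"
  per <- do.call(rbind, s$dsi)
  if (!is.null(per) && ncol(per) == length(cfg$speeds)) {
    cat(sprintf("  per-%s DSI (%%): %s\n", conds,
                paste(sprintf("%g: %.1f", cfg$speeds, 100 * colMeans(per)),
                      collapse = ", ")))
  }
  cat(sprintf("  run seeds: %s\n", paste(archive$seeds, collapse = ", ")))
  invisible(s)
}
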