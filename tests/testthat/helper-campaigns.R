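# Reduced-scale evolution campaigns shared across the acceptance checks.
# Computed lazily once per test session and cached; problem sizes are the
# package's desk-scale study conditions (see the methods vignette).

.campaigns <- new.env(parent = emptyenv())

campaign_cached <- function(key, compute) {
  if (is.null(.campaigns[[key]])) .campaigns[[key]] <- compute()
  .campaigns[[key]]
}

# --- minimal two-cell weight-asymmetry campaign (canonical conditions) ----
minimal_weight_campaign <- function(n_runs = 20, generations = 300) {
  campaign_cached("minimal_weights", function() {
    cfg <- load_preset("weights_minimal", generations = generations,
                       n_runs = n_runs)
    tpl <- emdevolve:::config_template(cfg)
    ch <- emdevolve:::config_chassis(cfg, 1L)
    runs <- lapply(seq_len(n_runs), function(r) {
      evolve(tpl, ch, evolution_config(generations = generations),
             seed = 1000L + r)
    })
    summ <- dplyr::bind_rows(lapply(seq_along(runs), function(r) {
      fit <- runs[[r]]
      p <- fit$best$params
      tibble::tibble(
        run = r, dsi = abs(fit$best_eval$dsi[1]),
        w1 = p$value[p$name == "w_syn" & p$unit == 1][1],
        w2 = p$value[p$name == "w_syn" & p$unit == 2][1],
        rise = p$value[p$name == "rise" & p$pop == "exc"][1],
        decay = p$value[p$name == "decay" & p$pop == "exc"][1])
    }))
    list(runs = runs, summary = summ, chassis = ch, template = tpl)
  })
}

# --- reduced full-model campaigns on the surrogate arbor ------------------
reduced_campaign_chassis <- function(seed, n_exc = 8, n_inh = 0) {
  build_chassis("compartmental", n_exc = n_exc, n_inh = n_inh,
                arena = arena(800, 800, 10, 10), speeds = 1,
                directions = 2 * pi * (0:3) / 4, morph_segments = 32,
                dt_v = 0.4, seed = seed)
}

reduced_template <- function(kind) {
  switch(kind,
    kinetic = genome_template(free = c("delay", "rise", "decay"),
                              shared = c("size_x", "size_y"), dt_stim = 10),
    rf_size = genome_template(free = "size_x", shared = c("rise", "decay"),
                              dt_stim = 10, circular = TRUE),
    inh_weights = genome_template(
      free = "inh:w_syn", pops = c("exc", "inh"),
      shared = c("size_x", "size_y", "rise", "decay", "inh:size_x",
                 "inh:size_y", "inh:rise", "inh:decay"), dt_stim = 10),
    symmetric = genome_template(
      free = character(),
      shared = c("size_x", "size_y", "rise", "decay", "w_syn"),
      dt_stim = 10))
}

reduced_campaign <- function(kind, n_runs = 10, generations = 100) {
  campaign_cached(paste0("reduced_", kind), function() {
    tpl <- reduced_template(kind)
    n_inh <- if (kind == "inh_weights") 8 else 0
    dsis <- vapply(seq_len(n_runs), function(r) {
      ch <- reduced_campaign_chassis(seed = 7000L + 13L * r, n_inh = n_inh)
      run <- evolve(tpl, ch, evolution_config(generations = generations),
                    seed = 7000L + r)
      run$best_eval$mean_dsi
    }, numeric(1))
    dsis
  })
}

# --- point-detector phenotype campaigns (kinetic vs RF size) --------------
point_chassis <- function(seed) {
  build_chassis("point", n_exc = 8, arena = arena(800, 800, 10, 10),
                speeds = 1, directions = 2 * pi * (0:3) / 4, seed = seed)
}

point_campaign <- function(kind, n_runs = 20, generations = 60) {
  campaign_cached(paste0("point_", kind), function() {
    tpl <- reduced_template(kind)
    lapply(seq_len(n_runs), function(r) {
      ch <- point_chassis(seed = 300L + r)
      evolve(tpl, ch, evolution_config(generations = generations),
             seed = 300L + r)
    })
  })
}

group_values <- function(run, name, pop = "exc") {
  p <- run$best$params
  p$value[p$name == name & p$pop == pop]
}
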