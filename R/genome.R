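# Genome: the mutable circuit parameter vector. One row per (parameter,
# population, unit), where unit is an input group (1..n_groups), a single
# cell (per-cell weights), or global (postsynaptic passives). `free` marks
# evolvable rows; `shared` rows mutate once (in the first unit) and the new
# value is copied to the others.

new_genome <- function(params, n_groups, options = list()) {
  structure(list(params = params, n_groups = n_groups, options = options),
            class = "emd_genome")
}

#' @export
print.emd_genome <- function(x, ...) {
  p <- x$params
  cat(sprintf("<emd_genome> %d parameters (%d free%s), %d input groups\n",
              nrow(p), sum(p$free),
              if (any(p$shared & p$free)) paste0(", ",
                sum(p$shared & p$free), " shared") else "",
              x$n_groups))
  invisible(x)
}

param_row <- function(name, pop, unit, value, lower, upper, init_lo, init_hi,
                      free, shared) {
  tibble(name = name, pop = pop, unit = unit, value = value, lower = lower,
         upper = upper, init_lo = init_lo, init_hi = init_hi, free = free,
         shared = shared)
}

# bounds/default table; init ranges follow the stated biologically motivated
# limits, clip bounds keep mutations physical
param_spec <- function(dt_stim) {
  kin_lo <- max(10, dt_stim * 1.1)
  list(
    size_x    = list(def = 50, lo = 2, hi = 200, ilo = 10, ihi = 200),
    size_y    = list(def = 50, lo = 2, hi = 200, ilo = 10, ihi = 200),
    orientation = list(def = 0, lo = 0, hi = pi, ilo = 0, ihi = pi),
    rise      = list(def = 50, lo = dt_stim * 1.05, hi = Inf, ilo = kin_lo, ihi = 300),
    decay     = list(def = 200, lo = dt_stim * 1.05, hi = Inf, ilo = kin_lo, ihi = 300),
    delay     = list(def = 0, lo = 0, hi = 100, ilo = 0, ihi = 50),
    w_syn     = list(def = 1, lo = 0, hi = 2, ilo = 0.2, ihi = 1),
    w_surround = list(def = 0.5, lo = 0, hi = 1, ilo = 0, ihi = 1),
    sur_size  = list(def = 100, lo = 10, hi = Inf, ilo = 10, ihi = 400),
    sur_rise  = list(def = 80, lo = dt_stim * 1.05, hi = Inf, ilo = kin_lo, ihi = 300),
    sur_decay = list(def = 250, lo = dt_stim * 1.05, hi = Inf, ilo = kin_lo, ihi = 300),
    dep_amp   = list(def = 0, lo = 0, hi = 1, ilo = 0, ihi = 1),
    dep_tau   = list(def = 150, lo = 10, hi = Inf, ilo = 10, ihi = 500),
    fac_amp   = list(def = 0, lo = 0, hi = 1, ilo = 0, ihi = 1),
    fac_tau   = list(def = 150, lo = 10, hi = Inf, ilo = 10, ihi = 500),
    g_pas     = list(def = 4e-4, lo = 1e-5, hi = 1e-3, ilo = 1e-5, ihi = 1e-3),
    r_a       = list(def = 150, lo = 50, hi = 200, ilo = 50, ihi = 200)
  )
}

#' Build a circuit genome template
#'
#' Declares which circuit parameters exist, their bounds, and how the
#' genetic algorithm may change them. Free independent parameters vary per
#' input group; free shared parameters mutate jointly across groups;
#' everything else is fixed at its default (or an explicit `fixed` value).
#'
#' @param free Character vector of free, per-group parameters (e.g.
#'   `c("delay", "rise", "decay")`).
#' @param shared Character vector of free parameters mutated jointly across
#'   groups.
#' @param pops Populations carrying per-group parameters: subset of
#'   `c("exc", "inh")`. Names in `free`/`shared` may be prefixed
#'   `"inh:"` to target the inhibitory population only (unprefixed names
#'   target the excitatory one).
#' @param n_groups Number of input groups along the preferred axis.
#' @param fixed Named list of fixed overrides (same prefix convention).
#' @param per_cell_weights Give every excitatory cell its own free synaptic
#'   weight instead of one weight per group (`n_cells` must then be set).
#' @param n_cells Cell count for per-cell weights.
#' @param post_free Evolve the postsynaptic passives (`g_pas`, `r_a`).
#' @param dt_stim Stimulus step (ms), used to bound kinetic parameters from
#'   below.
#' @return An `emd_genome` with all values at their defaults.
#' @export
genome_template <- function(free = character(), shared = character(),
                            pops = "exc", n_groups = 4, fixed = list(),
                            per_cell_weights = FALSE, n_cells = NULL,
                            post_free = FALSE, dt_stim = 5,
                            circular = FALSE) {
  spec <- param_spec(dt_stim)
  rows <- list()
  base_params <- c("size_x", "size_y", "orientation", "rise", "decay",
                   "delay", "w_syn", "w_surround", "sur_size", "sur_rise",
                   "sur_decay", "dep_amp", "dep_tau", "fac_amp", "fac_tau")
  split_name <- function(nm) {
    if (startsWith(nm, "inh:")) c("inh", sub("^inh:", "", nm)) else c("exc", nm)
  }
  free_tab <- vapply(free, split_name, character(2))
  shared_tab <- vapply(shared, split_name, character(2))
  for (pop in pops) {
    for (pm in base_params) {
      s <- spec[[pm]]
      is_free <- length(free) > 0 &&
        any(free_tab[1, ] == pop & free_tab[2, ] == pm)
      is_shared <- length(shared) > 0 &&
        any(shared_tab[1, ] == pop & shared_tab[2, ] == pm)
      if (pm == "w_syn" && pop == "exc" && per_cell_weights) {
        if (is.null(n_cells)) stop_invalid("n_cells required for per-cell weights")
        rows[[length(rows) + 1L]] <- param_row(
          pm, pop, seq_len(n_cells), s$def, s$lo, s$hi, s$ilo, s$ihi,
          free = TRUE, shared = FALSE)
        next
      }
      rows[[length(rows) + 1L]] <- param_row(
        pm, pop, seq_len(n_groups), s$def, s$lo, s$hi, s$ilo, s$ihi,
        free = is_free || is_shared, shared = is_shared)
    }
  }
  for (pm in c("g_pas", "r_a")) {
    s <- spec[[pm]]
    rows[[length(rows) + 1L]] <- param_row(
      pm, "post", 1L, s$def, s$lo, s$hi, s$ilo, s$ihi,
      free = post_free, shared = FALSE)
  }
  params <- bind_rows(rows)
  for (nm in names(fixed)) {
    sp <- split_name(nm)
    sel <- params$name == sp[2] & params$pop == sp[1]
    if (!any(sel)) stop_invalid("unknown fixed parameter: ", nm)
    params$value[sel] <- fixed[[nm]]
  }
  if (!any(params$free)) {
    # permitted: a fully fixed genome (symmetric control uses shared-only)
  }
  new_genome(params, n_groups,
             options = list(per_cell_weights = per_cell_weights,
                            circular = circular))
}

genome_value <- function(genome, name, pop, unit) {
  p <- genome$params
  i <- which(p$name == name & p$pop == pop & p$unit == unit)
  if (length(i) == 0) {
    i <- which(p$name == name & p$pop == pop)[1]
    if (is.na(i)) stop_invalid("parameter not in genome: ", pop, ":", name)
  }
  p$value[i[1]]
}

genome_values <- function(genome, name, pop) {
  p <- genome$params
  sel <- p$name == name & p$pop == pop
  setNames(p$value[sel], p$unit[sel])
}

set_genome_value <- function(genome, name, pop, unit, value) {
  p <- genome$params
  i <- which(p$name == name & p$pop == pop & p$unit == unit)
  if (length(i) == 0) stop_invalid("parameter not in genome")
  genome$params$value[i] <- value
  genome
}

#' Seed an initial population of genomes
#'
#' Free parameters are drawn uniformly within their initialization limits
#' (shared parameters once per parameter, copied across groups); fixed
#' parameters keep the template value.
#'
#' @param template An `emd_genome` template.
#' @param n Population size.
#' @return List of `n` genomes.
#' @export
seed_population <- function(template, n = 10) {
  if (n < 1) stop_invalid("population size must be >= 1")
  lapply(seq_len(n), function(i) randomize_genome(template))
}

randomize_genome <- function(template) {
  p <- template$params
  keys <- paste(p$name, p$pop)
  for (key in unique(keys[p$free])) {
    rows <- which(keys == key & p$free)
    if (p$shared[rows[1]]) {
      v <- runif(1, p$init_lo[rows[1]], p$init_hi[rows[1]])
      p$value[rows] <- v
    } else {
      p$value[rows] <- runif(length(rows), p$init_lo[rows], p$init_hi[rows])
    }
  }
  template$params <- p
  template
}

#' Mutate a genome
#'
#' Every free parameter is scaled by a factor drawn from `N(1, sd)` and
#' shifted by a uniform draw on `[-additive, additive]`, then clipped to its
#' bounds. Shared parameters receive one draw (applied to all groups);
#' independent parameters one draw per group.
#'
#' @param parent An `emd_genome`.
#' @param sd Multiplicative mutation standard deviation (default 0.10).
#' @param additive Half-width of the additive term (default 0.015, applied in
#'   each parameter's native unit).
#' @return The mutated child genome.
#' @export
mutate_genome <- function(parent, sd = 0.1, additive = 0.015) {
  p <- parent$params
  keys <- paste(p$name, p$pop)
  for (key in unique(keys[p$free])) {
    rows <- which(keys == key & p$free)
    if (p$shared[rows[1]]) {
      v <- p$value[rows[1]] * rnorm(1, 1, sd) + runif(1, -additive, additive)
      p$value[rows] <- v
    } else {
      p$value[rows] <- p$value[rows] * rnorm(length(rows), 1, sd) +
        runif(length(rows), -additive, additive)
    }
    p$value[rows] <- pmin(pmax(p$value[rows], p$lower[rows]), p$upper[rows])
  }
  parent$params <- p
  parent
}
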