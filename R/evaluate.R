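# Evaluation engine: genome + chassis -> presynaptic conductances ->
# postsynaptic response -> directional tuning and fitness.

# flatten genome values onto cells (vectors indexed by cell)
genome_cell_params <- function(genome, chassis) {
  cells <- chassis$cells
  n <- nrow(cells)
  nms <- c("size_x", "size_y", "orientation", "rise", "decay", "delay",
           "w_syn", "w_surround", "sur_size", "sur_rise", "sur_decay",
           "dep_amp", "dep_tau", "fac_amp", "fac_tau")
  out <- lapply(nms, function(nm) numeric(n))
  names(out) <- nms
  for (pop in unique(cells$pop)) {
    idx <- which(cells$pop == pop)
    for (nm in nms) {
      gv <- genome_values(genome, nm, pop)
      if (length(gv) == 0) next
      if (nm == "w_syn" && isTRUE(genome$options$per_cell_weights) &&
          pop == "exc") {
        out[[nm]][idx] <- gv[as.character(seq_along(idx))]
      } else {
        out[[nm]][idx] <- gv[as.character(cells$group[idx])]
      }
    }
  }
  if (isTRUE(genome$options$circular)) out$size_y <- out$size_x
  out$x <- cells$x; out$y <- cells$y
  out$pop <- cells$pop; out$group <- cells$group
  out$polarity <- cells$polarity
  out$n <- n
  out
}

genome_passives <- function(genome) {
  passive_properties(g_pas = genome_value(genome, "g_pas", "post", 1L),
                     r_a = genome_value(genome, "r_a", "post", 1L))
}

cell_has_surround <- function(chassis, pop) {
  if (pop == "inh") isTRUE(chassis$inh_surround) else isTRUE(chassis$surround)
}

# per-direction spatial profiles (center and, where enabled, surround)
direction_profiles <- function(cp, chassis, geom, bar_height) {
  u_lo <- -bar_height / 2; u_hi <- bar_height / 2
  center <- vector("list", cp$n); surround <- vector("list", cp$n)
  for (i in seq_len(cp$n)) {
    center[[i]] <- cpp_bar_profile(geom$px, geom$py, geom$pu, cp$x[i],
                                   cp$y[i], cp$size_x[i], cp$size_y[i],
                                   cp$orientation[i], u_lo, u_hi)
    if (cell_has_surround(chassis, cp$pop[i]) && cp$w_surround[i] > 0) {
      surround[[i]] <- cpp_bar_profile(geom$px, geom$py, geom$pu, cp$x[i],
                                       cp$y[i], cp$sur_size[i],
                                       cp$sur_size[i], 0, u_lo, u_hi)
    }
  }
  list(center = center, surround = surround)
}

# conductance matrix (frames x cells) for one bar-type stimulus
traces_from_profiles <- function(cp, chassis, geom, stim, profs) {
  dt <- chassis$arena$dt
  nt <- stim$n_frames
  G <- matrix(0, nt, cp$n)
  for (i in seq_len(cp$n)) {
    pc <- profs$center[[i]]
    area <- cpp_window_sum(geom$ps, pc$csum, pc$denom, stim$lead,
                           stim$bar_width)
    G[, i] <- finish_trace(area, i, cp, chassis, stim, dt, profs$surround[[i]],
                           geom = geom)
  }
  G
}

# temporal filtering, surround subtraction, plasticity, optional spiking
finish_trace <- function(area, i, cp, chassis, stim, dt, sur_prof = NULL,
                         geom = NULL, sur_area = NULL) {
  ct <- cpp_rf_temporal(area, dt, cp$rise[i], cp$decay[i],
                        chassis$adaptation,
                        as.integer(round(cp$delay[i] / dt)))$rf
  st <- NULL
  if (!is.null(sur_prof)) {
    sa <- cpp_window_sum(geom$ps, sur_prof$csum, sur_prof$denom, stim$lead,
                         stim$bar_width)
    st <- cpp_rf_temporal(sa, dt, cp$sur_rise[i], cp$sur_decay[i],
                          chassis$adaptation, 0L)$rf
  } else if (!is.null(sur_area)) {
    st <- cpp_rf_temporal(sur_area, dt, cp$sur_rise[i], cp$sur_decay[i],
                          chassis$adaptation, 0L)$rf
  }
  out <- if (is.null(st)) {
    cp$w_syn[i] * pmax(0, ct)
  } else {
    cp$w_syn[i] * pmax(0, ct - st * cp$w_surround[i])
  }
  if (isTRUE(chassis$plasticity)) {
    if (cp$dep_amp[i] > 0) {
      out <- cpp_depression(out, dt, cp$dep_amp[i], cp$dep_tau[i], FALSE,
                            0, 100)$release
    }
    if (cp$fac_amp[i] > 0) {
      out <- cpp_facilitation(out, dt, cp$fac_amp[i], cp$fac_tau[i])$release
    }
  }
  if (isTRUE(chassis$cortical)) {
    u <- runif(length(out), 0, 0.3)
    out <- as.numeric(u < out)
  }
  out
}

# postsynaptic response magnitude from the conductance matrix
backend_response <- function(G, chassis, passives, periodic = FALSE) {
  if (chassis$backend %in% c("minimal", "point")) {
    resp <- rowSums(G)
    return(list(R = if (periodic) peak_to_peak_tail(resp) else max(0, max(resp)),
                trace = resp))
  }
  v <- cable_response(G, chassis, passives)
  R <- if (isTRUE(chassis$soma_spiking)) {
    count_spikes(v)
  } else if (periodic) {
    peak_to_peak_tail(v)
  } else {
    max(0, max(v) - passives$e_rest)
  }
  list(R = R, trace = v)
}

peak_to_peak_tail <- function(v, frac = 0.3) {
  tl <- v[seq.int(floor(length(v) * (1 - frac)) + 1L, length(v))]
  max(tl) - min(tl)
}

cable_response <- function(G, chassis, passives) {
  # Skip the leading window before any synapse is active (the tree sits
  # exactly at rest there) and truncate 300 ms after the last activity
  # (residual relaxation is below numerical tolerance); pad with rest.
  dt <- chassis$arena$dt
  rs <- rowSums(G)
  active <- which(rs > 1e-5 * max(rs))
  n_full <- as.integer(round(nrow(G) * dt / chassis$dt_v))
  if (length(active) == 0) {
    return(rep(passives$e_rest, n_full + 1L))
  }
  i0 <- max(1L, active[1L] - 1L)
  i1 <- min(nrow(G), active[length(active)] + as.integer(ceiling(300 / dt)))
  head_steps <- as.integer(round((i0 - 1L) * dt / chassis$dt_v))
  if (i0 > 1L || i1 < nrow(G)) {
    G <- G[i0:i1, , drop = FALSE]
  }
  v <- cable_response_core(G, chassis, passives)
  if (head_steps > 0L || length(v) < n_full + 1L) {
    v <- c(rep(passives$e_rest, head_steps), v)
    if (length(v) < n_full + 1L) {
      v <- c(v, rep(passives$e_rest, n_full + 1L - length(v)))
    }
  }
  v
}

cable_response_core <- function(G, chassis, passives) {
  cb <- chassis$cable
  cm <- passives$c_m * cb$area_cm2 * 1e3
  gpas <- passives$g_pas * cb$area_cm2 * 1e6
  r_half <- passives$r_a * cb$half_geom
  gax <- numeric(length(r_half))
  has_p <- cb$parent0 >= 0L
  gax[has_p] <- 1e6 / (r_half[has_p] + r_half[cb$parent_idx[has_p]])
  g_uS <- G * (chassis$g_unit * 1e-3)
  dt <- chassis$arena$dt
  n_steps <- as.integer(round(nrow(G) * dt / chassis$dt_v))
  gna <- 1e4 * 1e-6 * cb$soma_area_um2
  gk <- 2e3 * 1e-6 * cb$soma_area_um2
  cpp_cable_solve(cb$parent0, cm, gpas, gax, passives$e_rest,
                  as.integer(chassis$sites$segment - 1L),
                  chassis$sites$e_syn, g_uS, dt, chassis$dt_v, n_steps,
                  as.integer(cb$soma_idx - 1L), isTRUE(chassis$soma_spiking),
                  gna, gk)
}

#' Evaluate a genome's directional fitness
#'
#' Simulates the circuit for every configured direction and speed (or
#' grating period), computes the direction selectivity index per speed from
#' the peak somatic responses, and returns the fitness: the mean over speeds
#' of `DSI * tanh(max R)`, which rewards selective and large responses.
#'
#' @param genome An `emd_genome`.
#' @param chassis An `emd_chassis`.
#' @param detail Also return per-synapse traces for the preferred direction
#'   (for primitive classification) and the response matrix.
#' @return List with `fitness`, `dsi` (per speed), `mean_dsi`, `R`
#'   (directions x speeds matrix); with `detail`, also `traces`
#'   (frames x cells, preferred direction at the probe speed), `trace_dt`,
#'   and `positions`.
#' @export
evaluate_fitness <- function(genome, chassis, detail = FALSE) {
  cp <- genome_cell_params(genome, chassis)
  passives <- genome_passives(genome)
  dirs <- chassis$directions
  conds <- if (chassis$protocol == "grating") chassis$periods else chassis$speeds
  R <- matrix(0, length(dirs), length(conds))
  probe_cond <- if (chassis$protocol == "grating") {
    which.min(abs(conds - 400))
  } else which.min(abs(conds - 1))
  pref_dir <- which.min(abs(dirs))
  detail_G <- NULL
  for (d in seq_along(dirs)) {
    if (chassis$protocol == "bar") {
      geom <- bar_geometry(chassis$arena, dirs[d])
      profs <- direction_profiles(cp, chassis, geom, bar_height = 1000)
      for (k in seq_along(conds)) {
        stim <- make_moving_bar(chassis$arena, conds[k], dirs[d])
        G <- traces_from_profiles(cp, chassis, geom, stim, profs)
        R[d, k] <- backend_response(G, chassis, passives)$R
        if (detail && d == pref_dir && k == probe_cond) detail_G <- G
      }
    } else {
      for (k in seq_along(conds)) {
        stim <- make_drifting_grating(chassis$arena, conds[k], speed = 1,
                                      direction = dirs[d])
        G <- grating_traces(cp, chassis, stim)
        R[d, k] <- backend_response(G, chassis, passives,
                                    periodic = TRUE)$R
        if (detail && d == pref_dir && k == probe_cond) detail_G <- G
      }
    }
  }
  dsis <- apply(R, 2, dsi, directions = dirs)
  metrics <- dsis * tanh(apply(R, 2, max))
  out <- list(fitness = mean(metrics), dsi = dsis, mean_dsi = mean(dsis),
              R = R)
  if (detail) {
    out$traces <- detail_G
    out$trace_dt <- chassis$arena$dt
    out$positions <- cp$x
  }
  out
}

grating_traces <- function(cp, chassis, stim) {
  dt <- chassis$arena$dt
  g <- grid_pixels(chassis$arena)
  tv <- stim_times(stim)
  G <- matrix(0, stim$n_frames, cp$n)
  kk <- 2 * pi / stim$spatial_period
  om <- 2 * pi * stim$speed / stim$spatial_period
  for (i in seq_len(cp$n)) {
    area <- cpp_grating_area(g$px, g$py, cp$x[i], cp$y[i], cp$size_x[i],
                             cp$size_y[i], cp$orientation[i], stim$direction,
                             kk, om, tv)
    sur_area <- NULL
    if (cell_has_surround(chassis, cp$pop[i]) && cp$w_surround[i] > 0) {
      sur_area <- cpp_grating_area(g$px, g$py, cp$x[i], cp$y[i],
                                   cp$sur_size[i], cp$sur_size[i], 0,
                                   stim$direction, kk, om, tv)
    }
    G[, i] <- finish_trace(area, i, cp, chassis, stim, dt,
                           sur_area = sur_area)
  }
  G
}

#' Postsynaptic response to an arbitrary stimulus
#'
#' Runs a genome on one stimulus (any kind) and returns the response
#' magnitude and trace; used by the velocity-noise and space-time mapping
#' protocols.
#'
#' @inheritParams evaluate_fitness
#' @param stim An `emd_stimulus`.
#' @param periodic Use the steady-state peak-to-peak magnitude instead of
#'   the peak.
#' @return List with `R`, `trace` (somatic voltage or detector output), and
#'   `G` (frames x cells conductances).
#' @export
circuit_response <- function(genome, chassis, stim, periodic = FALSE) {
  cp <- genome_cell_params(genome, chassis)
  passives <- genome_passives(genome)
  dt <- chassis$arena$dt
  G <- if (stim$kind %in% c("bar", "variable_velocity_bar")) {
    geom <- bar_geometry(chassis$arena, stim$direction)
    profs <- direction_profiles(cp, chassis, geom, bar_height = 1000)
    traces_from_profiles(cp, chassis, geom, stim, profs)
  } else if (stim$kind == "grating") {
    grating_traces(cp, chassis, stim)
  } else {
    g_mat <- matrix(0, stim$n_frames, cp$n)
    for (i in seq_len(cp$n)) {
      comp <- rf_component(cp$x[i], cp$y[i], cp$size_x[i], cp$size_y[i],
                           cp$orientation[i])
      area <- rf_area_series(comp, stim)
      sur_area <- NULL
      if (cell_has_surround(chassis, cp$pop[i]) && cp$w_surround[i] > 0) {
        scomp <- rf_component(cp$x[i], cp$y[i], cp$sur_size[i],
                              cp$sur_size[i], 0)
        sur_area <- rf_area_series(scomp, stim)
      }
      g_mat[, i] <- finish_trace(area, i, cp, chassis, stim, dt,
                                 sur_area = sur_area)
    }
    g_mat
  }
  res <- backend_response(G, chassis, passives, periodic = periodic)
  c(res, list(G = G))
}
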