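#' Gaussian receptive-field component
#'
#' One spatial component (center or surround) of a presynaptic receptive
#' field: an elliptical 2-D Gaussian whose `size_x`/`size_y` parameters give
#' the distance from the center at which sensitivity falls to half maximum,
#' plus the temporal parameters of its first-order activation kinetics.
#'
#' @param center_x,center_y Component position (um), arena-centered.
#' @param size_x,size_y Half-maximum half-widths (um), positive.
#' @param orientation Rotation of the x axis of the ellipse (radians).
#' @param rise_time Activation time constant (ms); must exceed the stimulus
#'   step when filtering.
#' @param decay_time Readily-releasable-pool depletion time constant (ms).
#' @param response_delay Response latency shift (ms), `[0, 50]` at
#'   initialization.
#' @param adaptation Logical: simulate pool depletion? When `FALSE` the
#'   adaptation state is held at 1.
#' @return An `emd_rf_component`.
#' @export
rf_component <- function(center_x = 0, center_y = 0, size_x = 50,
                         size_y = size_x, orientation = 0, rise_time = 50,
                         decay_time = 200, response_delay = 0,
                         adaptation = TRUE) {
  check_positive(size_x, "size_x"); check_positive(size_y, "size_y")
  check_positive(rise_time, "rise_time"); check_positive(decay_time, "decay_time")
  if (response_delay < 0) stop_invalid("response_delay must be >= 0")
  structure(list(center_x = center_x, center_y = center_y, size_x = size_x,
                 size_y = size_y, orientation = orientation,
                 rise_time = rise_time, decay_time = decay_time,
                 response_delay = response_delay, adaptation = adaptation),
            class = "emd_rf_component")
}

#' Short-term plasticity parameters
#'
#' @param dep_amp,fac_amp Depression / facilitation amplitude factors in
#'   `[0, 1]`; 0 disables the mechanism.
#' @param dep_tau,fac_tau Recovery / decay time constants (ms), > 10 ms.
#' @param literal Logical: use the as-printed depression recursion, in which
#'   the facilitation amplitude and time constant enter the depression
#'   update, instead of the default self-contained depression with
#'   first-order recovery toward a full pool.
#' @return An `emd_plasticity` parameter set.
#' @export
plasticity_params <- function(dep_amp = 0, dep_tau = 100, fac_amp = 0,
                              fac_tau = 100, literal = FALSE) {
  for (a in c(dep_amp, fac_amp)) {
    if (a < 0 || a > 1) stop_invalid("plasticity amplitudes must lie in [0, 1]")
  }
  check_positive(dep_tau, "dep_tau"); check_positive(fac_tau, "fac_tau")
  structure(list(dep_amp = dep_amp, dep_tau = dep_tau, fac_amp = fac_amp,
                 fac_tau = fac_tau, literal = literal),
            class = "emd_plasticity")
}

#' Presynaptic cell
#'
#' A presynaptic unit: a center component, an optional antagonistic surround
#' spatially aligned with the center, a synaptic weight, surround strength,
#' short-term plasticity, and a polarity. Graded cells emit a conductance
#' trace; spiking cells emit a spike train driven by the same trace.
#'
#' @param center,surround [rf_component()]s; the surround (if given) is
#'   re-centered onto the center position.
#' @param w_syn Synaptic weight (dimensionless, >= 0).
#' @param w_surround Surround strength in `[0, 1]`.
#' @param plasticity Optional [plasticity_params()].
#' @param polarity `"excitatory"` or `"inhibitory"`.
#' @param group Input-group index (1-4) along the preferred axis.
#' @param mode `"graded"` or `"spiking"`.
#' @return An `emd_presyn_cell`.
#' @export
presyn_cell <- function(center, surround = NULL, w_syn = 1, w_surround = 0,
                        plasticity = NULL, polarity = "excitatory",
                        group = NA_integer_, mode = "graded") {
  if (w_syn < 0) stop_invalid("w_syn must be >= 0")
  if (w_surround < 0 || w_surround > 1) {
    stop_invalid("w_surround must lie in [0, 1]")
  }
  polarity <- match.arg(polarity, c("excitatory", "inhibitory"))
  mode <- match.arg(mode, c("graded", "spiking"))
  if (!is.null(surround)) {
    surround$center_x <- center$center_x
    surround$center_y <- center$center_y
  }
  structure(list(center = center, surround = surround, w_syn = w_syn,
                 w_surround = w_surround, plasticity = plasticity,
                 polarity = polarity, group = group, mode = mode),
            class = "emd_presyn_cell")
}

#' Receptive-field / stimulus overlap
#'
#' Normalized fraction of a component's Gaussian mass covered by the stimulus
#' at time `t`: the pixel-by-pixel sum of stimulus intensity weighted by the
#' Gaussian profile, divided by the component's full-arena Gaussian sum, so
#' full-field illumination gives exactly 1. This is the reference (rendered)
#' path; [rf_area_series()] computes the same quantity for a whole stimulus
#' without materializing frames.
#'
#' @param component An [rf_component()].
#' @param stim An `emd_stimulus`.
#' @param t Time (ms).
#' @return Overlap fraction in `[0, 1]`.
#' @export
rf_overlap_area <- function(component, stim, t) {
  a <- stim$arena
  g <- grid_pixels(a)
  w <- cpp_gauss_field(g$xs, g$ys, component$center_x, component$center_y,
                       component$size_x, component$size_y,
                       component$orientation)
  total <- sum(w)
  vapply(t, function(ti) sum(stim_frame(stim, ti) * w) / total, numeric(1))
}

#' Overlap time series for a stimulus (fast path)
#'
#' Computes the overlap fraction of [rf_overlap_area()] at every stimulus
#' frame, using stimulus-specific closed forms over the pixel grid (windowed
#' cumulative sums for bars, trigonometric sums for gratings, per-bar masses
#' for contrast noise).
#'
#' @inheritParams rf_overlap_area
#' @return Numeric vector, one overlap value per frame.
#' @export
rf_area_series <- function(component, stim) {
  a <- stim$arena
  cc <- component
  switch(
    stim$kind,
    bar = ,
    variable_velocity_bar = {
      geom <- bar_geometry(a, stim$direction)
      prof <- cpp_bar_profile(geom$px, geom$py, geom$pu,
                              cc$center_x, cc$center_y, cc$size_x, cc$size_y,
                              cc$orientation, -stim$bar_height / 2,
                              stim$bar_height / 2)
      cpp_window_sum(geom$ps, prof$csum, prof$denom, stim$lead,
                     stim$bar_width)
    },
    grating = {
      g <- grid_pixels(a)
      cpp_grating_area(g$px, g$py, cc$center_x, cc$center_y, cc$size_x,
                       cc$size_y, cc$orientation, stim$direction,
                       2 * pi / stim$spatial_period,
                       2 * pi * stim$speed / stim$spatial_period,
                       stim_times(stim))
    },
    flash = {
      tt <- stim_times(stim)
      as.numeric(tt >= stim$onset & tt < stim$offset)
    },
    bar_noise = {
      g <- grid_pixels(a)
      w <- cpp_noise_bar_weights(g$px, g$py, cc$center_x, cc$center_y,
                                 cc$size_x, cc$size_y, cc$orientation,
                                 stim$direction, stim$edges)
      per_epoch <- as.numeric(crossprod(w, stim$pattern))
      epoch <- pmin(ncol(stim$pattern),
                    1L + floor(stim_times(stim) / stim$update_interval))
      per_epoch[epoch]
    },
    stop_invalid("unknown stimulus kind: ", stim$kind)
  )
}

#' Temporal receptive-field response
#'
#' First-order activation of a component driven by its overlap series, with
#' readily-releasable-pool adaptation:
#' `RF_t = (area_t - RF_{t-1}) * dt / rise + RF_{t-1} * adaptation_{t-1}`,
#' `adaptation_t = max(0, adaptation_{t-1} - RF_t * dt / decay)`.
#' The response delay shifts the overlap series before filtering. With
#' adaptation disabled the adaptation state is held at 1.
#'
#' @param area Numeric overlap series (one value per stimulus frame).
#' @param component The [rf_component()] supplying kinetics.
#' @param dt Time step of `area` (ms); must be smaller than both time
#'   constants.
#' @return List with elements `rf` (activation) and `adaptation` (pool
#'   state), both the length of `area`.
#' @export
rf_temporal_response <- function(area, component, dt) {
  if (dt >= component$rise_time || dt >= component$decay_time) {
    stop_invalid("dt must be smaller than rise_time and decay_time")
  }
  cpp_rf_temporal(area, dt, component$rise_time, component$decay_time,
                  isTRUE(component$adaptation),
                  as.integer(round(component$response_delay / dt)))
}

#' Center-surround integration
#'
#' Net presynaptic drive: the surround activation, scaled by the surround
#' strength, is subtracted from the center activation; the difference is
#' rectified (release cannot be negative) and scaled by the synaptic weight.
#'
#' @param center_trace,surround_trace Activation series on a common time
#'   base; `surround_trace` may be `NULL` for center-only cells.
#' @param cell The [presyn_cell()] supplying `w_syn` and `w_surround`.
#' @return Non-negative conductance series.
#' @export
integrate_center_surround <- function(center_trace, surround_trace, cell) {
  if (is.null(surround_trace)) {
    return(cell$w_syn * pmax(0, center_trace))
  }
  if (length(center_trace) != length(surround_trace)) {
    stop_invalid("center and surround traces must have equal length")
  }
  cell$w_syn * pmax(0, center_trace - surround_trace * cell$w_surround)
}

#' Short-term synaptic depression
#'
#' The depression state starts at 1 (a full readily releasable pool), is
#' multiplicatively depleted by the driven release and recovers toward 1 with
#' first-order kinetics; released output is the input trace scaled by the
#' state. `literal = TRUE` in the parameter set switches to the as-printed
#' recursion (see [plasticity_params()]).
#'
#' @param trace Non-negative release series.
#' @param p A [plasticity_params()].
#' @param dt Time step (ms).
#' @return List with `release` (depressed output) and `state` (pool factor).
#' @export
apply_depression <- function(trace, p, dt) {
  cpp_depression(trace, dt, p$dep_amp, p$dep_tau, isTRUE(p$literal),
                 p$fac_amp, p$fac_tau)
}

#' Short-term synaptic facilitation
#'
#' The facilitation state integrates the driven release, decays with its time
#' constant, and is clipped to `[0, 1]`; release is amplified by
#' `10^state`, so the multiplier spans 1 to 10.
#'
#' @inheritParams apply_depression
#' @return List with `release` (facilitated output) and `state`.
#' @export
apply_facilitation <- function(trace, p, dt) {
  cpp_facilitation(trace, dt, p$fac_amp, p$fac_tau)
}

#' Presynaptic spike generation
#'
#' Converts a graded release trace into a spike train: at each step a uniform
#' draw on `[0, 0.3]` is compared with the trace. By default a spike occurs
#' when the draw falls below the trace, so stronger drive yields more spikes
#' and drive at or above 0.3 fires every step; `literal = TRUE` retains the
#' opposite comparator.
#'
#' @param trace Release series.
#' @param dt Time step (ms).
#' @param seed Integer seed for reproducible spike trains.
#' @param literal Logical; see Details.
#' @return List with `spikes` (logical per step) and `times` (ms).
#' @export
presynaptic_spike_train <- function(trace, dt, seed = NULL, literal = FALSE) {
  u <- with_seed(seed, runif(length(trace), 0, 0.3))
  spikes <- if (literal) u > trace else u < trace
  list(spikes = spikes, times = (which(spikes) - 1L) * dt)
}

#' Full presynaptic conductance pipeline
#'
#' Runs a cell through the complete transformation for one stimulus: spatial
#' overlap, temporal filtering with adaptation (center and surround filtered
#' independently), center-surround subtraction with rectification and weight
#' scaling, then short-term depression and facilitation if configured.
#'
#' @param cell A [presyn_cell()].
#' @param stim An `emd_stimulus`.
#' @return Non-negative conductance series at the stimulus time step.
#' @export
cell_conductance <- function(cell, stim) {
  dt <- stim$arena$dt
  ac <- rf_area_series(cell$center, stim)
  ct <- rf_temporal_response(ac, cell$center, dt)$rf
  st <- NULL
  if (!is.null(cell$surround) && cell$w_surround > 0) {
    as_ <- rf_area_series(cell$surround, stim)
    st <- rf_temporal_response(as_, cell$surround, dt)$rf
  }
  out <- integrate_center_surround(ct, st, cell)
  p <- cell$plasticity
  if (!is.null(p)) {
    if (p$dep_amp > 0 || isTRUE(p$literal)) {
      out <- apply_depression(out, p, dt)$release
    }
    if (p$fac_amp > 0) out <- apply_facilitation(out, p, dt)$release
  }
  out
}

#' Tidy cell response
#'
#' @param cell A [presyn_cell()].
#' @param stim An `emd_stimulus`.
#' @return A tibble with columns `time` (ms), `conductance` (normalized
#'   units) and `polarity`.
#' @export
cell_response <- function(cell, stim) {
  tibble(time = stim_times(stim), conductance = cell_conductance(cell, stim),
         polarity = cell$polarity)
}
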