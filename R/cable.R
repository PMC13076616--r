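# Passive multicompartment simulation: R-side assembly of the tree system
# solved in compiled code (backward Euler on the Hines-ordered tree).

# per-segment electrical constants in solver units (nF, uS)
cable_constants <- function(morph, passive) {
  s <- morph$segments
  area_cm2 <- pi * s$diam * s$length * 1e-8     # um^2 -> cm^2
  cm_nF <- passive$c_m * area_cm2 * 1e3          # uF -> nF
  gpas_uS <- passive$g_pas * area_cm2 * 1e6      # S -> uS
  # axial coupling to parent: two half-cylinder resistances in series
  r_half <- passive$r_a * (s$length / 2 * 1e-4) / (pi * (s$diam / 2 * 1e-4)^2)
  gax_uS <- numeric(nrow(s))
  for (i in seq_len(nrow(s))) {
    if (s$parent[i] > 0L) {
      p <- match(s$parent[i], s$id)
      gax_uS[i] <- 1e6 / (r_half[i] + r_half[p])
    }
  }
  list(cm_nF = cm_nF, gpas_uS = gpas_uS, gax_uS = gax_uS)
}

#' Simulate the passive compartmental model
#'
#' Solves the passive cable equation on the morphology with synaptic
#' conductance inputs `g_i(t) (E_i - V)` using an implicit (backward Euler)
#' step on the branched tree, which is unconditionally stable. Synaptic
#' conductances are supplied on the stimulus time base and linearly
#' interpolated onto the voltage step.
#'
#' @param morph An `emd_morphology` (parents must precede children, as the
#'   generators guarantee).
#' @param passive A [passive_properties()].
#' @param sites Synapse table from [place_synapses()] (`segment`, `e_syn`).
#' @param g_traces Matrix of synaptic conductances (uS), one column per
#'   synapse in `sites` order, one row per stimulus frame.
#' @param dt_stim Time step of `g_traces` (ms).
#' @param duration Simulated time (ms).
#' @param dt_v Voltage solver step (ms), default 0.1.
#' @param spiking Add Hodgkin-Huxley style Na/K conductances at the soma
#'   (densities 10000 and 2000 pS/um^2).
#' @return List with `time` (ms), `v_soma` (mV) and `peak` (maximal somatic
#'   depolarization above rest, mV, floored at 0).
#' @export
simulate_compartmental <- function(morph, passive, sites, g_traces, dt_stim,
                                   duration = NULL, dt_v = 0.1,
                                   spiking = FALSE) {
  if (any(g_traces < 0)) stop_invalid("synaptic conductances must be >= 0")
  s <- morph$segments
  cst <- cable_constants(morph, passive)
  parent0 <- as.integer(ifelse(s$parent == 0L, -1L,
                               match(s$parent, s$id) - 1L))
  if (any(parent0 >= seq_along(parent0) - 1L)) {
    stop_invalid("morphology segments must be ordered parent-before-child")
  }
  soma_idx <- which(s$is_soma)[1]
  duration <- duration %||% (nrow(g_traces) * dt_stim)
  n_steps <- as.integer(round(duration / dt_v))
  soma_area_um2 <- pi * s$diam[soma_idx] * s$length[soma_idx]
  gna <- 1e4 * 1e-6 * soma_area_um2   # 10000 pS/um^2 -> uS
  gk <- 2e3 * 1e-6 * soma_area_um2
  v <- cpp_cable_solve(parent0, cst$cm_nF, cst$gpas_uS, cst$gax_uS,
                       passive$e_rest, as.integer(sites$segment - 1L),
                       sites$e_syn, as.matrix(g_traces), dt_stim, dt_v,
                       n_steps, as.integer(soma_idx - 1L), isTRUE(spiking),
                       gna, gk)
  list(time = seq(0, by = dt_v, length.out = n_steps + 1L), v_soma = v,
       peak = max(0, max(v) - passive$e_rest))
}

#' Two-input linear detector
#'
#' The minimal postsynaptic model: a pure weighted sum of presynaptic
#' waveforms with no cable filtering and no rectification.
#'
#' @param trace_a,trace_b Presynaptic conductance series on a common time
#'   base.
#' @param w_a,w_b Detector weights.
#' @return Numeric response series.
#' @export
simulate_minimal_detector <- function(trace_a, trace_b, w_a = 1, w_b = 1) {
  if (length(trace_a) != length(trace_b)) {
    stop_invalid("traces must share a time base")
  }
  w_a * trace_a + w_b * trace_b
}

#' Count somatic spikes
#'
#' Number of upward crossings of the threshold (default 0 mV).
#'
#' @param v Somatic voltage series (mV).
#' @param threshold Crossing level (mV).
#' @return Integer spike count.
#' @export
count_spikes <- function(v, threshold = 0) {
  above <- v >= threshold
  sum(above[-1] & !above[-length(above)])
}
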