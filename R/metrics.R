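#' Direction selectivity index
#'
#' Vector-sum index `sum(R * cos(theta)) / sum(R)` over the tested motion
#' directions, with `theta = 0` aligned to the designated preferred
#' direction. Responses are floored at zero (peak depolarization relative to
#' rest); if all responses are zero the index is 0 by convention.
#'
#' @param responses Non-negative response magnitudes, one per direction.
#' @param directions Motion directions (radians), same length.
#' @return DSI in `[-1, 1]`.
#' @export
#' @examples
#' dsi(c(2, 1), c(0, pi))  # 1/3
dsi <- function(responses, directions) {
  if (length(responses) != length(directions)) {
    stop_invalid("responses and directions must have equal length")
  }
  r <- pmax(0, responses)
  tot <- sum(r)
  if (tot == 0) return(0)
  sum(r * cos(directions)) / tot
}

#' DSI from drifting-grating voltage responses
#'
#' For periodic stimulation the response magnitude per direction is the
#' steady-state peak-to-peak voltage over the final fraction of the trial
#' (default final 30%), which excludes onset transients; the vector-sum index
#' is then computed as in [dsi()].
#'
#' @param v_by_direction List of voltage traces, one per direction.
#' @param directions Motion directions (radians).
#' @param final_frac Fraction of the trial used (from the end).
#' @return DSI value.
#' @export
grating_dsi <- function(v_by_direction, directions, final_frac = 0.3) {
  r <- vapply(v_by_direction, function(v) {
    tail_v <- v[seq.int(floor(length(v) * (1 - final_frac)) + 1L, length(v))]
    max(tail_v) - min(tail_v)
  }, numeric(1))
  dsi(r, directions)
}

# FWHM duration of a response: width of the largest contiguous run at or
# above half maximum (ms)
response_fwhm <- function(trace, dt) {
  pk <- max(trace)
  if (pk <= 0) return(0)
  above <- trace >= pk / 2
  r <- rle(above)
  runs <- r$lengths[r$values]
  if (length(runs) == 0) return(0)
  max(runs) * dt
}

# shared machinery for the waveform-overlap metrics
overlap_metric <- function(traces, frac, level, align) {
  traces <- as.matrix(traces)
  peaks <- apply(traces, 2, max)
  if (all(peaks <= 0)) {
    warning("all-zero traces; overlap metric set to 0")
    return(0)
  }
  keep <- peaks > 0
  norm <- sweep(traces[, keep, drop = FALSE], 2, peaks[keep], "/")
  if (align) {
    pk_idx <- apply(norm, 2, which.max)
    ref <- round(median(pk_idx))
    norm <- vapply(seq_len(ncol(norm)), function(j) {
      shift_trace(norm[, j], ref - pk_idx[j])
    }, numeric(nrow(norm)))
  }
  support <- rowSums(norm > 0) > 0
  if (!any(support)) return(0)
  qualifies <- rowMeans(norm >= level) >= frac
  overlap <- ifelse(qualifies & support, rowMeans(norm), 0)
  m <- max(overlap)
  if (m <= 0) return(0)
  mean(overlap[support]) / m
}

shift_trace <- function(x, k) {
  n <- length(x)
  out <- numeric(n)
  if (k >= 0) out[seq.int(1 + k, n)] <- x[seq_len(n - k)]
  else out[seq_len(n + k)] <- x[seq.int(1 - k, n)]
  out
}

#' Amplitude-primitive overlap metric
#'
#' Quantifies waveform-shape similarity of the per-synapse motion responses
#' after removing position-dependent lag: traces (preferred direction, 1 mm/s
#' bar) are peak-normalized and temporally aligned on their peaks; at each
#' time where any trace is active, overlap is present if at least 75% of the
#' waveforms exceed 20% of their peaks, in which case the overlap value is
#' the population-mean waveform. The metric is the mean of the overlap
#' waveform over the active times, normalized by its own peak, and lies in
#' `[0, 1]`.
#'
#' @param traces Matrix of per-synapse responses (time in rows, synapses in
#'   columns).
#' @param frac Population fraction required for overlap (default 0.75).
#' @param level Per-trace activity threshold as a fraction of peak.
#' @return Metric in `[0, 1]`.
#' @export
amplitude_metric <- function(traces, frac = 0.75, level = 0.2) {
  overlap_metric(traces, frac, level, align = TRUE)
}

#' Temporal-alignment-primitive overlap metric
#'
#' As [amplitude_metric()], but on the raw (un-aligned) motion responses and
#' requiring only 25% of the population to reach 20% of peak, so it rewards
#' circuits whose responses peak simultaneously during preferred-direction
#' motion.
#'
#' @inheritParams amplitude_metric
#' @return Metric in `[0, 1]`.
#' @export
alignment_metric <- function(traces, frac = 0.25, level = 0.2) {
  overlap_metric(traces, frac, level, align = FALSE)
}

#' Kinetic (delay-and-compare) primitive metric
#'
#' Signed position of a circuit along the kinetic axis. Each synapse's
#' preferred-direction motion response is summarized by its full width at
#' half maximum; a linear fit of duration against position along the
#' preferred axis determines whether responses narrow (positive sign,
#' delay-and-compare with slow preferred-side inputs) or widen (negative
#' sign, the mirrored arrangement) along the axis. The magnitude is
#' `(1 - narrowest/widest)^2`.
#'
#' @param traces Matrix of per-synapse responses (time x synapses).
#' @param positions Synapse positions along the preferred axis (um),
#'   increasing toward the null side.
#' @param dt Trace time step (ms).
#' @return Signed value in `[-1, 1]`; 0 when all durations are equal.
#' @export
hr_metric <- function(traces, positions, dt) {
  traces <- as.matrix(traces)
  if (ncol(traces) != length(positions) || ncol(traces) < 2) {
    stop_invalid("need one position per synapse and at least two synapses")
  }
  dur <- apply(traces, 2, response_fwhm, dt = dt)
  ok <- dur > 0
  if (sum(ok) < 2) return(0)
  dur <- dur[ok]; pos <- positions[ok]
  if (max(dur) == min(dur)) return(0)
  slope <- coef(lm(dur ~ pos))[2]
  mag <- (1 - min(dur) / max(dur))^2
  if (!is.finite(slope) || slope == 0) return(0)
  if (slope < 0) mag else -mag
}

#' Inhibitory-primitive metrics
#'
#' Quantifies the timing and tuning of the inhibitory drive against the
#' excitatory response in the preferred direction. The excitatory response's
#' area under the curve is divided into equal thirds by two time points;
#' the veto (delayed-inhibition) metric is the fraction of the
#' preferred-direction inhibitory drive falling in the last third-window,
#' and its mirror the fraction in the first. Tuned inhibition is
#' `max(0, (ampN - ampP) / (ampN + ampP))` on the per-direction peak
#' inhibitory drives, and the pause metric (computed only when both timing
#' metrics are below 0.20) replaces the preferred peak with the peak inside
#' the middle window.
#'
#' @param exc_pref Summed excitatory conductance, preferred direction.
#' @param inh_pref,inh_null Summed inhibitory conductance per direction.
#' @param dt Time step (ms).
#' @return A one-row tibble with columns `bl`, `anti_bl`, `amp_inhib`,
#'   `pause` (`NA` when the pause criterion does not apply).
#' @export
bl_metrics <- function(exc_pref, inh_pref, inh_null, dt) {
  tot <- sum(exc_pref) * dt
  if (tot <= 0) stop_invalid("excitatory response has zero area")
  # Samples are treated as rectangles of width dt, so the cumulative area is
  # piecewise linear and the third-points can be located exactly.
  t1 <- area_crossing(exc_pref, dt, tot / 3)
  t2 <- area_crossing(exc_pref, dt, 2 * tot / 3)
  on <- which(exc_pref > 0)
  t0 <- (on[1] - 1) * dt
  t3 <- on[length(on)] * dt
  itot <- mass_between(inh_pref, dt, 0, length(inh_pref) * dt)
  first_frac <- if (itot > 0) mass_between(inh_pref, dt, t0, t1) / itot else 0
  last_frac <- if (itot > 0) mass_between(inh_pref, dt, t2, t3) / itot else 0
  amp_n <- max(inh_null); amp_p <- max(inh_pref)
  amp_inhib <- if (amp_n + amp_p > 0) {
    max(0, (amp_n - amp_p) / (amp_n + amp_p))
  } else 0
  pause <- NA_real_
  if (last_frac < 0.2 && first_frac < 0.2) {
    mid <- which((seq_along(inh_pref) - 1) * dt < t2 &
                   seq_along(inh_pref) * dt > t1)
    amp_p_star <- if (length(mid)) max(inh_pref[mid]) else 0
    if (amp_n + amp_p_star > 0) {
      pause <- (amp_n - amp_p_star) / (amp_n + amp_p_star)
    }
  }
  tibble(bl = last_frac, anti_bl = first_frac, amp_inhib = amp_inhib,
         pause = pause)
}

# time at which the running rectangle-rule area of x first reaches `target`
area_crossing <- function(x, dt, target) {
  cum <- c(0, cumsum(x) * dt)
  k <- which(cum >= target)[1]
  if (is.na(k)) return(length(x) * dt)
  if (k == 1L) return(0)
  (k - 2L) * dt + (target - cum[k - 1L]) / x[k - 1L]
}

# rectangle-rule mass of x over [ta, tb] with fractional end bins
mass_between <- function(x, dt, ta, tb) {
  n <- length(x)
  ta <- max(0, ta); tb <- min(n * dt, tb)
  if (tb <= ta) return(0)
  lo <- ta / dt; hi <- tb / dt
  i0 <- floor(lo) + 1L; i1 <- ceiling(hi)
  if (i0 > i1) return(0)
  full <- if (i1 > i0) sum(x[seq.int(i0, i1)]) * dt else x[i0] * dt
  full - x[i0] * (lo - (i0 - 1L)) * dt - x[i1] * (i1 - hi) * dt
}

#' Classify a circuit into computational primitives
#'
#' Places a circuit in the two-dimensional primitive spaces. The excitatory
#' horizontal coordinate is the signed kinetic metric ([hr_metric()]); the
#' vertical coordinate is alignment minus amplitude overlap. With inhibitory
#' traces the inhibitory coordinates are the veto-timing difference
#' (last-third minus first-third fraction) and pause minus tuned-inhibition.
#' A primitive is called present when its coordinate exceeds 0.20 from the
#' origin; two present axes make a hybrid solution.
#'
#' @param exc_traces Per-synapse excitatory responses (time x synapses),
#'   preferred direction, 1 mm/s bar.
#' @param positions Synapse positions along the preferred axis (um).
#' @param dt Trace time step (ms).
#' @param inh_pref,inh_null Optional summed inhibitory drive per direction.
#' @param threshold Presence threshold (default 0.20).
#' @return A one-row tibble: coordinates `x_exc`, `y_exc` (and `x_inh`,
#'   `y_inh` when inhibition is supplied) plus a `primitives` list-column of
#'   present primitive labels.
#' @export
classify_primitives <- function(exc_traces, positions, dt, inh_pref = NULL,
                                inh_null = NULL, threshold = 0.2) {
  x_exc <- hr_metric(exc_traces, positions, dt)
  y_exc <- alignment_metric(exc_traces) - amplitude_metric(exc_traces)
  prim <- character(0)
  if (x_exc > threshold) prim <- c(prim, "HR")
  if (x_exc < -threshold) prim <- c(prim, "anti-HR")
  if (y_exc > threshold) prim <- c(prim, "alignment")
  if (y_exc < -threshold) prim <- c(prim, "amplitude")
  out <- tibble(x_exc = x_exc, y_exc = y_exc)
  if (!is.null(inh_pref)) {
    exc_sum <- rowSums(as.matrix(exc_traces))
    bl <- bl_metrics(exc_sum, inh_pref, inh_null, dt)
    x_inh <- bl$bl - bl$anti_bl
    y_inh <- (if (is.na(bl$pause)) 0 else bl$pause) - bl$amp_inhib
    if (x_inh > threshold) prim <- c(prim, "BL")
    if (x_inh < -threshold) prim <- c(prim, "anti-BL")
    if (y_inh > threshold) prim <- c(prim, "pause")
    if (y_inh < -threshold) prim <- c(prim, "tuned-inhibition")
    out$x_inh <- x_inh
    out$y_inh <- y_inh
  }
  out$primitives <- list(prim)
  out
}
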