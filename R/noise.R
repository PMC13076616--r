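#' Direction selectivity under velocity noise
#'
#' Probes an evolved circuit with variable-velocity bars: per trial one
#' velocity trajectory is sampled and presented in both the preferred and
#' the null direction, giving a single-trial two-direction DSI. Levels are
#' summarized by the mean and standard deviation across trials and
#' normalized to the noise-free baseline.
#'
#' @param genome An evolved `emd_genome`.
#' @param chassis Its `emd_chassis`.
#' @param noise_sd Velocity-noise levels (mm/s standard deviation, within
#'   `[0, 5]`).
#' @param n_trials Trials per level (noise-free levels are deterministic and
#'   use one trial).
#' @param base_speed Mean bar speed (mm/s).
#' @param seed Integer seed.
#' @return A tibble with one row per level: `noise_sd`, `mean_dsi`,
#'   `sd_dsi`, `n`, `norm_dsi` (mean normalized to the no-noise baseline).
#' @export
noise_robustness_curve <- function(genome, chassis,
                                   noise_sd = c(0, 1, 2.5, 5),
                                   n_trials = 50, base_speed = 1,
                                   seed = NULL) {
  if (any(noise_sd < 0 | noise_sd > 5)) {
    stop_invalid("noise_sd levels must lie in [0, 5] mm/s")
  }
  rows <- lapply(seq_along(noise_sd), function(li) {
    lv <- noise_sd[li]
    nt <- if (lv == 0) 1L else n_trials
    ds <- vapply(seq_len(nt), function(tr) {
      s_tr <- derive_seed(seed %||% 0, paste0("noise", li, "_", tr))
      sp <- make_variable_velocity_bar(chassis$arena, direction = 0,
                                       noise_sd = lv, seed = s_tr,
                                       base_speed = base_speed)
      sn <- make_variable_velocity_bar(chassis$arena, direction = pi,
                                       noise_sd = lv, seed = s_tr,
                                       base_speed = base_speed)
      rp <- circuit_response(genome, chassis, sp)$R
      rn <- circuit_response(genome, chassis, sn)$R
      if (rp + rn == 0) 0 else (rp - rn) / (rp + rn)
    }, numeric(1))
    tibble(noise_sd = lv, mean_dsi = mean(ds), sd_dsi = sd(ds), n = nt)
  })
  out <- bind_rows(rows)
  base <- out$mean_dsi[out$noise_sd == 0][1]
  if (is.na(base) || base == 0) {
    warning("zero or missing no-noise baseline; norm_dsi is NA")
    out$norm_dsi <- NA_real_
  } else {
    out$norm_dsi <- out$mean_dsi / base
  }
  out
}

#' Slope of the noise-robustness curve
#'
#' Linear-regression slope of normalized DSI against noise level; circuits
#' that degrade faster under velocity noise have more negative slopes.
#'
#' @param curve Output of [noise_robustness_curve()].
#' @return Slope (per mm/s of noise SD).
#' @export
noise_slope <- function(curve) {
  unname(coef(lm(norm_dsi ~ noise_sd, data = curve))[2])
}

#' Space-time receptive-field map from 1-D noise responses
#'
#' Event-triggered average of the response following white-bar onsets (ON
#' rising phase only): for every bar position, the response fluctuation
#' after each 0-to-1 contrast transition is averaged in 20 ms bins. The
#' derived temporal profile is taken at the central position and the spatial
#' profile across positions at the time of the maximal absolute response.
#'
#' @param response Response series (somatic voltage or detector output).
#' @param stim The `emd_stimulus` of kind `"bar_noise"` that produced it.
#' @param dt Time step of `response` (ms).
#' @param window Post-onset window to average (ms).
#' @param bin Bin width (ms, default 20).
#' @param min_events Warn when a position has fewer onset events.
#' @return An `emd_spacetime`: list with `map` (positions x bins, response
#'   fluctuation), `positions` (bar centers, um), `times` (bin centers, ms),
#'   `n_events`, `temporal_rf`, `spatial_rf`.
#' @export
spacetime_map <- function(response, stim, dt, window = 300, bin = 20,
                          min_events = 5) {
  if (stim$kind != "bar_noise") stop_invalid("stimulus must be 1-D bar noise")
  pat <- stim$pattern
  nb <- nrow(pat)
  n_bins <- floor(window / bin)
  map <- matrix(0, nb, n_bins)
  n_ev <- integer(nb)
  n_resp <- length(response)
  for (b in seq_len(nb)) {
    onsets <- which(pat[b, -1] == 1 & pat[b, -ncol(pat)] == 0)
    times <- onsets * stim$update_interval  # epoch e+1 starts at e*interval
    acc <- matrix(0, 0, n_bins)
    for (t0 in times) {
      i0 <- floor(t0 / dt) + 1L
      i1 <- i0 + ceiling(window / dt) - 1L
      if (i1 > n_resp) next
      seg <- response[i0:i1] - response[i0]
      per <- max(1L, round(bin / dt))
      bins <- vapply(seq_len(n_bins), function(k) {
        mean(seg[seq.int((k - 1L) * per + 1L, min(k * per, length(seg)))])
      }, numeric(1))
      acc <- rbind(acc, bins)
      n_ev[b] <- n_ev[b] + 1L
    }
    if (n_ev[b] > 0) map[b, ] <- colMeans(acc)
  }
  if (any(n_ev < min_events)) {
    warning(sprintf("under-sampled positions: %d with fewer than %d onsets",
                    sum(n_ev < min_events), min_events))
  }
  centers <- (stim$edges[-1] + stim$edges[-length(stim$edges)]) / 2
  peak <- which(abs(map) == max(abs(map)), arr.ind = TRUE)[1, ]
  structure(list(map = map, positions = centers,
                 times = (seq_len(n_bins) - 0.5) * bin, n_events = n_ev,
                 temporal_rf = map[which.min(abs(centers)), ],
                 spatial_rf = map[, peak[2]]),
            class = "emd_spacetime")
}

#' @export
print.emd_spacetime <- function(x, ...) {
  cat(sprintf("<emd_spacetime> %d positions x %d time bins, %d-%d events\n",
              nrow(x$map), ncol(x$map), min(x$n_events), max(x$n_events)))
  invisible(x)
}
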