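#' Define the stimulation arena
#'
#' The arena is the square region of visual space on which all stimuli are
#' rendered, discretized into square pixels and sampled at a fixed stimulus
#' time step. All lengths are in micrometres and times in milliseconds.
#' Coordinates are centered: the arena spans `[-width/2, width/2]`.
#'
#' @param width,height Arena extent (um). Default an 800 um square.
#' @param pixel_size Pixel edge (um). The default 5 um is at most a quarter of
#'   the narrowest admissible receptive-field size, so Gaussian overlap sums
#'   are well converged.
#' @param dt Stimulus sampling step (ms).
#' @return An object of class `emd_arena`.
#' @export
#' @examples
#' a <- arena()
#' a$width
arena <- function(width = 800, height = 800, pixel_size = 5, dt = 5) {
  check_positive(width, "width"); check_positive(height, "height")
  check_positive(pixel_size, "pixel_size"); check_positive(dt, "dt")
  structure(list(width = width, height = height,
                 pixel_size = pixel_size, dt = dt),
            class = "emd_arena")
}

#' @export
print.emd_arena <- function(x, ...) {
  cat(sprintf("<emd_arena> %g x %g um, %g um pixels, dt %g ms\n",
              x$width, x$height, x$pixel_size, x$dt))
  invisible(x)
}

new_stimulus <- function(kind, arena, duration, direction = 0, speed = NA,
                         background = 0, seed = NULL, ...) {
  duration <- ceiling(duration / arena$dt) * arena$dt
  structure(
    list(kind = kind, arena = arena, duration = duration,
         direction = direction, speed = speed, background = background,
         seed = seed, n_frames = as.integer(round(duration / arena$dt)), ...),
    class = "emd_stimulus")
}

#' @export
print.emd_stimulus <- function(x, ...) {
  cat(sprintf("<emd_stimulus:%s> %d frames (%g ms at dt %g ms), direction %.3f rad",
              x$kind, x$n_frames, x$duration, x$arena$dt, x$direction))
  if (is.finite(x$speed)) cat(sprintf(", speed %g mm/s", x$speed))
  cat("\n")
  invisible(x)
}

#' Frame times of a stimulus
#'
#' @param stim An `emd_stimulus`.
#' @return Numeric vector of frame onset times (ms), starting at 0.
#' @export
stim_times <- function(stim) {
  (seq_len(stim$n_frames) - 1L) * stim$arena$dt
}

#' Moving bright bar
#'
#' A full-contrast bar sweeps across the arena at constant speed. The bar is
#' oriented perpendicular to its motion; its extent along the motion axis is
#' `speed * bar_time_width`, so any fixed point is covered for exactly
#' `bar_time_width` regardless of speed (a spatial width can be forced with
#' `bar_width`). Intensity is binary: background 0, bar 1.
#'
#' @param arena An [arena()].
#' @param speed Bar speed (mm/s, equivalently um/ms). Must be positive.
#' @param direction Motion direction (radians; 0 = rightward along +x).
#' @param bar_height Bar extent perpendicular to motion (um), default 1 mm,
#'   clipped to the arena.
#' @param bar_time_width Temporal width (ms): time any point stays covered.
#' @param bar_width Optional spatial width override (um). When given,
#'   `bar_time_width` is ignored.
#' @return An `emd_stimulus` of kind `"bar"`.
#' @export
#' @examples
#' s <- make_moving_bar(arena(), speed = 1, direction = 0)
#' range(stim_frame(s, 500))
make_moving_bar <- function(arena, speed, direction = 0, bar_height = 1000,
                            bar_time_width = 200, bar_width = NULL) {
  check_positive(speed, "speed")
  check_positive(bar_height, "bar_height")
  if (is.null(bar_width)) {
    check_positive(bar_time_width, "bar_time_width")
    bar_width <- speed * bar_time_width
  } else check_positive(bar_width, "bar_width")
  geom <- bar_geometry(arena, direction)
  span <- geom$s_max - geom$s_min
  duration <- (span + bar_width) / speed
  stim <- new_stimulus("bar", arena, duration, direction, speed,
                       bar_width = bar_width, bar_height = bar_height)
  stim$lead <- geom$s_min + speed * stim_times(stim)
  stim
}

#' Moving bar with velocity noise
#'
#' The bar's speed is resampled every `update_interval` from the positive half
#' of a normal distribution centred on `base_speed` with standard deviation
#' `noise_sd`; its position is the running integral of the piecewise-constant
#' speed, so the bar never reverses. `noise_sd = 0` reproduces
#' [make_moving_bar()] at `base_speed`.
#'
#' @inheritParams make_moving_bar
#' @param noise_sd Speed standard deviation (mm/s), in `[0, 5]`.
#' @param seed Integer seed; the trajectory is reproducible given the seed.
#' @param base_speed Mean of the speed distribution (mm/s).
#' @param update_interval Resampling interval (ms).
#' @return An `emd_stimulus` of kind `"variable_velocity_bar"`.
#' @export
make_variable_velocity_bar <- function(arena, direction = 0, noise_sd = 1,
                                       seed = NULL, base_speed = 1,
                                       update_interval = 50,
                                       bar_height = 1000,
                                       bar_time_width = 200) {
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop_invalid("noise_sd must be non-negative")
  }
  if (noise_sd > 5) stop_invalid("noise_sd must not exceed 5 mm/s")
  check_positive(base_speed, "base_speed")
  geom <- bar_geometry(arena, direction)
  bar_width <- base_speed * bar_time_width
  span <- geom$s_max - geom$s_min + bar_width
  speeds <- with_seed(seed, {
    out <- numeric(0); dist <- 0
    while (dist < span && length(out) < 4000L) {
      v <- abs(rnorm(1L, base_speed, noise_sd))
      out <- c(out, v)
      dist <- dist + v * update_interval
    }
    out
  })
  dt <- arena$dt
  n_per <- round(update_interval / dt)
  v_frames <- rep(speeds, each = n_per)
  pos <- cumsum(v_frames * dt)
  n_frames <- min(length(pos), which(pos >= span)[1L])
  if (is.na(n_frames)) n_frames <- length(pos)
  stim <- new_stimulus("variable_velocity_bar", arena, n_frames * dt,
                       direction, base_speed, seed = seed,
                       bar_width = bar_width, bar_height = bar_height,
                       noise_sd = noise_sd, update_interval = update_interval,
                       speeds = speeds)
  stim$lead <- geom$s_min + c(0, pos[seq_len(stim$n_frames - 1L)])
  stim
}

#' Drifting sinusoidal grating
#'
#' Full-field sinusoid at 100% contrast on a gray background (mean intensity
#' 0.5), drifting along `direction` at temporal frequency
#' `speed / spatial_period`.
#'
#' @inheritParams make_moving_bar
#' @param spatial_period Spatial period (um/cycle); canonical values are
#'   100, 200, 400, 800 and 1600.
#' @param duration Presentation time (ms).
#' @return An `emd_stimulus` of kind `"grating"`.
#' @export
make_drifting_grating <- function(arena, spatial_period, speed = 1,
                                  direction = 0, duration = 3000) {
  check_positive(spatial_period, "spatial_period")
  check_positive(speed, "speed")
  new_stimulus("grating", arena, duration, direction, speed,
               background = 0.5, spatial_period = spatial_period)
}

#' One-dimensional contrast-noise bars
#'
#' The arena is tiled with vertical bars spanning the full field; each bar is
#' independently assigned 0 or 1 contrast with equal probability, resampled
#' every `update_interval`. The bar axis is the x (preferred-motion) axis.
#'
#' @inheritParams make_moving_bar
#' @param bar_width Bar width (um); must divide the arena width to within one
#'   pixel.
#' @param update_interval Contrast update interval (ms), in `[20, 200]`.
#' @param seed Integer seed (pattern is reproducible given the seed).
#' @param duration Presentation time (ms).
#' @return An `emd_stimulus` of kind `"bar_noise"` carrying the bar pattern
#'   matrix (`bars x epochs`).
#' @export
make_1d_bar_noise <- function(arena, bar_width = 20, update_interval = 50,
                              seed = NULL, duration = 3000) {
  check_positive(bar_width, "bar_width")
  if (update_interval < 20 || update_interval > 200) {
    stop_invalid("update_interval must lie in [20, 200] ms")
  }
  n_bars <- round(arena$width / bar_width)
  if (abs(arena$width - n_bars * bar_width) > arena$pixel_size) {
    stop_invalid("bar_width must divide the arena width within one pixel")
  }
  n_epochs <- ceiling(duration / update_interval)
  pattern <- with_seed(seed, matrix(
    as.numeric(runif(n_bars * n_epochs) < 0.5), n_bars, n_epochs))
  new_stimulus("bar_noise", arena, duration, direction = 0, speed = NA,
               seed = seed, bar_width = bar_width,
               update_interval = update_interval, pattern = pattern,
               edges = -arena$width / 2 + bar_width * (0:n_bars))
}

#' Full-field flash
#'
#' Intensity 1 everywhere during `[onset, offset)` and 0 elsewhere; activates
#' the entire center and surround of every receptive field.
#'
#' @inheritParams make_moving_bar
#' @param onset,offset Flash window (ms), `0 <= onset < offset`.
#' @param duration Total duration (ms); defaults to `offset`.
#' @return An `emd_stimulus` of kind `"flash"`.
#' @export
make_full_field_flash <- function(arena, onset, offset, duration = NULL) {
  if (onset < 0 || onset >= offset) {
    stop_invalid("need 0 <= onset < offset")
  }
  duration <- duration %||% offset
  if (offset > duration) stop_invalid("offset exceeds duration")
  new_stimulus("flash", arena, duration, onset = onset, offset = offset)
}

#' Render one stimulus frame
#'
#' Renders the intensity field at time `t` as a matrix over the pixel grid
#' (rows follow x, columns follow y). This is the reference rendering path;
#' the overlap fast paths agree with it pixel for pixel.
#'
#' @param stim An `emd_stimulus`.
#' @param t Time (ms) within the stimulus duration.
#' @return Matrix of intensities in `[0, 1]`.
#' @export
stim_frame <- function(stim, t) {
  if (t < 0 || t > stim$duration) stop_invalid("t outside stimulus duration")
  a <- stim$arena
  g <- grid_pixels(a)
  k <- min(stim$n_frames, 1L + floor(t / a$dt))
  val <- switch(
    stim$kind,
    bar = ,
    variable_velocity_bar = {
      s <- g$px * cos(stim$direction) + g$py * sin(stim$direction)
      u <- -g$px * sin(stim$direction) + g$py * cos(stim$direction)
      lead <- stim$lead[k]
      as.numeric(s > lead - stim$bar_width & s <= lead &
                   abs(u) <= stim$bar_height / 2)
    },
    grating = {
      s <- g$px * cos(stim$direction) + g$py * sin(stim$direction)
      kk <- 2 * pi / stim$spatial_period
      om <- 2 * pi * stim$speed / stim$spatial_period
      tt <- (k - 1L) * a$dt
      0.5 + 0.5 * sin(kk * s - om * tt)
    },
    bar_noise = {
      epoch <- min(ncol(stim$pattern), 1L + floor((k - 1L) * a$dt / stim$update_interval))
      b <- findInterval(g$px, stim$edges, rightmost.closed = TRUE)
      b <- pmin(pmax(b, 1L), nrow(stim$pattern))
      stim$pattern[b, epoch]
    },
    flash = {
      tt <- (k - 1L) * a$dt
      rep(as.numeric(tt >= stim$onset && tt < stim$offset), length(g$px))
    },
    stop_invalid("unknown stimulus kind: ", stim$kind)
  )
  matrix(val, length(g$xs), length(g$ys))
}
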