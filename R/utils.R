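# internal helpers: validation, deterministic seeding, geometry caching

stop_invalid <- function(...) {
  abort(paste0(...), class = "emd_invalid_parameter")
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_invalid(name, " must be a single positive number")
  }
  invisible(x)
}

# All stochastic entry points funnel through this so that a single integer
# seed fully determines a run (Mersenne-Twister + inversion, fixed kinds).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  force(code)
}

# Derive a bounded child seed from a master seed and a stream label so each
# component (stimulus, placement, mutation, spiking) is independently
# reproducible. Kept below 2^31 - 1.
derive_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 69069 + h * 2654435) %% 2147483629) + 1L
}

# Sorted-projection pixel geometry per (arena grid, direction), cached:
# every moving-bar overlap reuses it.
.geom_cache <- new.env(parent = emptyenv())

grid_pixels <- function(arena) {
  xs <- arena_axis(arena$width, arena$pixel_size)
  ys <- arena_axis(arena$height, arena$pixel_size)
  list(xs = xs, ys = ys,
       px = rep(xs, times = length(ys)),
       py = rep(ys, each = length(xs)))
}

arena_axis <- function(extent, px) {
  n <- max(1L, round(extent / px))
  (seq_len(n) - (n + 1) / 2) * px
}

bar_geometry <- function(arena, direction) {
  key <- paste(arena$width, arena$height, arena$pixel_size,
               round(direction, 10), sep = "|")
  hit <- .geom_cache[[key]]
  if (!is.null(hit)) return(hit)
  g <- grid_pixels(arena)
  s <- g$px * cos(direction) + g$py * sin(direction)
  u <- -g$px * sin(direction) + g$py * cos(direction)
  ord <- order(s)
  # physical projection span of the arena (grid-independent, so bar
  # trajectories are identical across pixel resolutions)
  smax <- abs(cos(direction)) * arena$width / 2 +
    abs(sin(direction)) * arena$height / 2
  out <- list(px = g$px[ord], py = g$py[ord], ps = s[ord], pu = u[ord],
              s_min = -smax, s_max = smax,
              xs = g$xs, ys = g$ys)
  .geom_cache[[key]] <- out
  out
}
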