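# shared fixtures: small arenas and chassis so the suite stays fast

small_arena <- function(px = 10, dt = 10) arena(800, 800, px, dt)

tiny_arena <- function() arena(200, 200, 5, 5)

minimal_chassis <- function(seed = 1) {
  build_chassis("minimal", arena = arena(), speeds = 1,
                directions = c(0, pi), seed = seed)
}

reduced_chassis <- function(seed = 1, n_exc = 16, n_inh = 0, ...) {
  build_chassis("compartmental", n_exc = n_exc, n_inh = n_inh,
                arena = small_arena(), speeds = 1,
                directions = 2 * pi * (0:7) / 8, morph_segments = 40,
                dt_v = 0.2, seed = seed, ...)
}

# independent R-side reference for the activation recursion
ref_rf_recursion <- function(area, dt, rise, decay, adapt = TRUE) {
  rf <- numeric(length(area)); ad <- numeric(length(area))
  rf_p <- 0; ad_p <- 1
  for (t in seq_along(area)) {
    rf[t] <- (area[t] - rf_p) * dt / rise + rf_p * ad_p
    ad[t] <- if (adapt) max(0, ad_p - rf[t] * dt / decay) else 1
    rf_p <- rf[t]; ad_p <- ad[t]
  }
  list(rf = rf, adaptation = ad)
}
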