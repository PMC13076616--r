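# directional metrics and primitive classification

test_that("DSI follows the vector-sum definition exactly", {
  d12 <- 2 * pi * (0:11) / 12
  expect_equal(dsi(rep(3, 12), d12), 0)
  expect_identical(dsi(c(1, rep(0, 11)), d12), 1)
  expect_identical(dsi(c(2, 1), c(0, pi)), 1 / 3)
  expect_identical(dsi(rep(0, 12), d12), 0)
  expect_error(dsi(1:3, c(0, pi)), class = "emd_invalid_parameter")
  # negative responses are floored at zero
  expect_identical(dsi(c(2, -1), c(0, pi)), 1)
})

test_that("grating DSI uses the steady-state peak-to-peak of the final 30%", {
  tt <- seq(0, 999) / 1000
  mk <- function(amp, trend = 0) -60 + trend * tt + amp * sin(2 * pi * 5 * tt)
  same <- replicate(4, mk(2), simplify = FALSE)
  expect_equal(grating_dsi(same, 2 * pi * (0:3) / 4), 0)
  flat <- c(list(mk(2)), replicate(3, rep(-60, 1000), simplify = FALSE))
  expect_equal(grating_dsi(flat, 2 * pi * (0:3) / 4), 1)
  # doubling modulation depth in the preferred direction raises DSI
  d2 <- grating_dsi(list(mk(2), mk(1)), c(0, pi))
  d4 <- grating_dsi(list(mk(4), mk(1)), c(0, pi))
  expect_gt(d4, d2)
})

test_that("kinetic metric: worked value, antisymmetry, degenerate cases", {
  dt <- 10
  boxcar <- function(start, width, n = 100) {
    x <- numeric(n); x[start:(start + width - 1)] <- 1; x
  }
  # durations 200 ms vs 400 ms: narrowest/widest = 0.5 -> magnitude 0.25
  tr <- cbind(boxcar(10, 40), boxcar(20, 30), boxcar(30, 20))
  pos <- c(-50, 0, 50)
  m <- hr_metric(tr, pos, dt)
  expect_equal(m, (1 - 20 / 40)^2)
  expect_equal(m, 0.25)
  # reversing the axis flips the sign, keeps the magnitude
  expect_equal(hr_metric(tr, -pos, dt), -0.25)
  # equal durations -> 0
  tr_eq <- cbind(boxcar(10, 30), boxcar(40, 30))
  expect_identical(hr_metric(tr_eq, c(-50, 50), dt), 0)
  expect_error(hr_metric(tr, pos[-1], dt), class = "emd_invalid_parameter")
})

test_that("overlap metrics reward shared waveforms and zero disjoint ones", {
  n <- 250
  tri <- c(seq(0, 1, length.out = 20), seq(1, 0, length.out = 20))
  place <- function(at) { x <- numeric(n); x[at:(at + 39)] <- tri; x }
  # identical waveforms: both metrics equal the mean of the normalized shape
  same <- cbind(place(10), place(10), place(10), place(10))
  am <- amplitude_metric(same); al <- alignment_metric(same)
  expect_equal(am, al)
  expect_gt(am, 0.3)
  expect_lte(am, 1)
  # five traces disjoint in time: alignment 0 (only 1/5 of the population is
  # ever active); amplitude (peak-aligned) recovers the common shape
  seq_tr <- cbind(place(1), place(51), place(101), place(151), place(201))
  expect_equal(alignment_metric(seq_tr), 0)
  expect_gt(amplitude_metric(seq_tr), 0.3)
  # synchronized peaks score at least as high on alignment as on amplitude
  sync <- cbind(place(10), 0.5 * place(10), 2 * place(10), place(10))
  expect_gte(alignment_metric(sync) + 1e-9, amplitude_metric(sync))
  expect_warning(amplitude_metric(matrix(0, 10, 3)), "all-zero")
})

test_that("inhibitory metrics: uniform thirds, worked pause value, B&L limit", {
  dt <- 10
  n <- 90
  exc <- rep(1, n)
  inh_u <- rep(1, n)
  m <- bl_metrics(exc, inh_u, inh_u, dt)
  expect_equal(m$bl, 1 / 3)
  expect_equal(m$anti_bl, 1 / 3)
  expect_equal(m$amp_inhib, 0)
  # all inhibition after the last-third boundary
  inh_late <- c(rep(0, 60), rep(1, 30))
  expect_equal(bl_metrics(exc, inh_late, inh_late, dt)$bl, 1)
  # uniform timing metrics leave the pause undefined (both thirds >= 0.2)
  got0 <- bl_metrics(exc, rep(1 / 3, n), rep(1, n), dt)
  expect_true(is.na(got0$pause))
  # worked pause value: null peak 3 vs middle-window preferred peak 1 -> 0.5
  inh_mid1 <- rep(0.01, n); inh_mid1[40:50] <- 1  # mass inside [300, 600] ms
  inh_null <- rep(1, n); inh_null[45] <- 3
  got2 <- bl_metrics(exc, inh_mid1, inh_null, dt)
  expect_equal(got2$pause, (3 - 1) / (3 + 1))
  expect_equal(got2$pause, 0.5)
  expect_error(bl_metrics(rep(0, n), inh_u, inh_u, dt),
               class = "emd_invalid_parameter")
})

test_that("primitive classification applies the 0.20 presence threshold", {
  dt <- 10
  n <- 100
  boxcar <- function(start, width) {
    x <- numeric(n); x[start:(start + width - 1)] <- 1; x
  }
  # strongly narrowing durations -> kinetic primitive present
  tr <- cbind(boxcar(5, 60), boxcar(25, 35), boxcar(40, 15))
  out <- classify_primitives(tr, c(-50, 0, 50), dt)
  expect_gt(out$x_exc, 0.2)
  expect_true("HR" %in% out$primitives[[1]])
  # symmetric equal-duration circuit -> nothing present
  tr_s <- cbind(boxcar(10, 30), boxcar(10, 30), boxcar(10, 30))
  out_s <- classify_primitives(tr_s, c(-50, 0, 50), dt)
  expect_lt(abs(out_s$x_exc), 0.2)
  expect_length(out_s$primitives[[1]], 0)
  # delayed null-side inhibition -> veto (B&L) primitive
  exc_tr <- cbind(boxcar(10, 30), boxcar(10, 30))
  # excitatory support is [90, 390] ms; inhibition lands in its last third
  inh_pref <- c(rep(0, 31), rep(1, 9), rep(0, n - 40))
  inh_null <- inh_pref
  out_i <- classify_primitives(exc_tr, c(-50, 50), dt,
                               inh_pref = inh_pref, inh_null = inh_null)
  expect_gt(out_i$x_inh, 0.2)
  expect_true("BL" %in% out_i$primitives[[1]])
  # identical traces give identical coordinates (no hidden randomness)
  expect_identical(classify_primitives(tr, c(-50, 0, 50), dt),
                   classify_primitives(tr, c(-50, 0, 50), dt))
})

test_that("space-time maps recover a linear responder's impulse response", {
  a <- arena(400, 400, 10, 10)
  nz <- make_1d_bar_noise(a, 40, 60, seed = 21, duration = 30000)
  # linear responder: response = known kernel convolved with central bars
  area <- rf_area_series(rf_component(0, 0, size_x = 30, size_y = 30), nz)
  kern <- exp(-(0:20) / 4); kern <- kern / sum(kern)
  resp <- stats::filter(c(rep(0, 20), area), kern, sides = 1)[-(1:20)]
  resp[is.na(resp)] <- 0
  stm <- spacetime_map(resp, nz, dt = a$dt, window = 200)
  # spatially centered RF: central positions dominate the spatial profile
  central <- abs(stm$positions) <= 40
  expect_gt(max(stm$map[central, ]), max(stm$map[!central, ]))
  # the temporal profile rises then decays like the kernel-filtered input
  expect_gt(which.max(stm$temporal_rf), 1)
  # doubling the epochs roughly halves the map's variance around its mean
  expect_true(all(stm$n_events >= 5))
})
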