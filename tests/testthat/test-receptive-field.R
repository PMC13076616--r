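# receptive-field overlap, activation kinetics, plasticity, spike generation

test_that("overlap normalization: full field gives 1, darkness 0, half-plane 0.5", {
  a <- tiny_arena()
  comp <- rf_component(0, 0, size_x = 30, size_y = 30)
  fl <- make_full_field_flash(a, 0, 200, duration = 400)
  expect_equal(rf_overlap_area(comp, fl, 100), 1)
  expect_equal(rf_overlap_area(comp, fl, 300), 0)
  # a very wide bar whose leading edge sits on the RF center: half-plane
  s <- make_moving_bar(a, 1, 0, bar_height = 1e4, bar_width = 1e4)
  k <- which.min(abs(s$lead - 0))
  half <- rf_overlap_area(comp, s, stim_times(s)[k])
  expect_equal(half, 0.5, tolerance = 0.02)
})

test_that("fast overlap series matches the rendered reference on every kind", {
  a <- arena(400, 400, 10, 10)
  comp <- rf_component(30, -20, size_x = 40, size_y = 25,
                       orientation = 0.4)
  stims <- list(
    make_moving_bar(a, 1, pi / 6),
    make_variable_velocity_bar(a, direction = pi / 6, noise_sd = 2, seed = 2),
    make_drifting_grating(a, 200, 1, pi / 3, duration = 500),
    make_1d_bar_noise(a, 20, 50, seed = 5, duration = 400),
    make_full_field_flash(a, 50, 250, duration = 400))
  for (s in stims) {
    fast <- rf_area_series(comp, s)
    probe <- unique(round(seq(1, s$n_frames, length.out = 7)))
    ref <- rf_overlap_area(comp, s, stim_times(s)[probe])
    expect_equal(fast[probe], ref, tolerance = 1e-8)
    expect_true(all(fast >= -1e-12 & fast <= 1 + 1e-12))
  }
})

test_that("overlap agrees with a dense brute-force sum at half the pixel size", {
  coarse <- arena(400, 400, 10, 10)
  fine <- arena(400, 400, 5, 10)
  comp <- rf_component(20, 10, size_x = 40, size_y = 40)
  s_c <- make_moving_bar(coarse, 1, 0)
  s_f <- make_moving_bar(fine, 1, 0)
  for (tt in c(200, 300, 400)) {
    v_c <- rf_overlap_area(comp, s_c, tt)
    v_f <- rf_overlap_area(comp, s_f, tt)
    expect_lt(abs(v_c - v_f) / max(v_f, 1e-6), 0.01)
  }
})

test_that("rotating an RF by pi leaves the overlap unchanged", {
  a <- arena(400, 400, 10, 10)
  s <- make_moving_bar(a, 1, pi / 5)
  c1 <- rf_component(25, -10, size_x = 60, size_y = 20, orientation = 0.7)
  c2 <- rf_component(25, -10, size_x = 60, size_y = 20,
                     orientation = 0.7 + pi)
  expect_equal(rf_area_series(c1, s), rf_area_series(c2, s),
               tolerance = 1e-12)
})

test_that("activation recursion matches an independent implementation", {
  a <- c(rep(0, 5), rep(1, 40), rep(0, 40))
  comp <- rf_component(rise_time = 30, decay_time = 120)
  got <- rf_temporal_response(a, comp, dt = 5)
  ref <- ref_rf_recursion(a, 5, 30, 120)
  expect_equal(got$rf, ref$rf)
  expect_equal(got$adaptation, ref$adaptation)

  # zero input is a fixed point
  z <- rf_temporal_response(rep(0, 50), comp, dt = 5)
  expect_equal(z$rf, rep(0, 50))
  expect_equal(z$adaptation, rep(1, 50))

  # without adaptation a step input relaxes monotonically toward 1
  comp2 <- rf_component(rise_time = 30, decay_time = 120, adaptation = FALSE)
  r2 <- rf_temporal_response(rep(1, 200), comp2, dt = 5)$rf
  expect_true(all(diff(r2) >= -1e-12))
  expect_true(all(r2 <= 1 + 1e-12))
  expect_gt(r2[200], 0.99)

  # adaptation state is bounded and non-increasing under drive
  r3 <- rf_temporal_response(rep(1, 100), comp, dt = 5)$adaptation
  expect_true(all(r3 >= 0 & r3 <= 1))
  expect_true(all(diff(r3) <= 1e-12))

  # a delay shifts the response
  comp3 <- rf_component(rise_time = 30, decay_time = 120,
                        response_delay = 25)
  r4 <- rf_temporal_response(a, comp3, dt = 5)$rf
  expect_equal(r4[6:85], rf_temporal_response(a, comp, dt = 5)$rf[1:80])

  expect_error(rf_temporal_response(a, rf_component(rise_time = 4), dt = 5),
               class = "emd_invalid_parameter")
})

test_that("center-surround integration rectifies, cancels, and scales", {
  ct <- c(0, 0.5, 1, 0.5, 0)
  st <- c(0.2, 0.2, 0.2, 0.9, 0.9)
  cell0 <- presyn_cell(rf_component(), w_syn = 1.5, w_surround = 0)
  expect_equal(integrate_center_surround(ct, st, cell0), 1.5 * ct)
  cell1 <- presyn_cell(rf_component(), w_syn = 1, w_surround = 1)
  expect_equal(integrate_center_surround(ct, ct, cell1), rep(0, 5))
  cell2 <- presyn_cell(rf_component(), w_syn = 2, w_surround = 0.5)
  expect_equal(integrate_center_surround(ct, st, cell2),
               2 * integrate_center_surround(ct, st,
                 presyn_cell(rf_component(), w_syn = 1, w_surround = 0.5)))
  expect_true(all(integrate_center_surround(ct, st, cell1) >= 0))
  expect_error(integrate_center_surround(ct, st[-1], cell1),
               class = "emd_invalid_parameter")
})

test_that("depression depletes toward a fixed point and recovers", {
  p <- plasticity_params(dep_amp = 0.3, dep_tau = 150)
  drive <- c(rep(1, 100), rep(0, 200))
  out <- apply_depression(drive, p, dt = 5)
  expect_true(all(out$state >= 0 & out$state <= 1))
  expect_true(all(diff(out$state[1:100]) <= 1e-12))
  expect_gt(min(out$state[1:100]), 0)
  # recovery toward 1 with the configured time constant
  rec <- out$state[101:300]
  expect_true(all(diff(rec) >= 0))
  fit <- lm(log(1 - rec[1:30] + 1e-12) ~ I(seq_len(30) * 5))
  expect_equal(unname(-1 / coef(fit)[2]), 150, tolerance = 0.1)
  # amp 0 is the identity
  p0 <- plasticity_params(dep_amp = 0, dep_tau = 150)
  expect_equal(apply_depression(drive, p0, 5)$release, drive)
})

test_that("facilitation multiplier spans [1, 10] and saturates at ten", {
  p <- plasticity_params(fac_amp = 1, fac_tau = 500)
  drive <- rep(1, 200)
  out <- apply_facilitation(drive, p, dt = 5)
  mult <- out$release / drive
  expect_true(all(mult >= 1 - 1e-12 & mult <= 10 + 1e-12))
  expect_equal(max(out$state), 1)
  expect_equal(max(mult), 10)
  p0 <- plasticity_params(fac_amp = 0, fac_tau = 500)
  expect_equal(apply_facilitation(drive, p0, 5)$release, drive)
})

test_that("spike generation follows the rectified rate rule", {
  n <- 4000
  expect_length(presynaptic_spike_train(rep(0, n), 5, seed = 1)$times, 0)
  full <- presynaptic_spike_train(rep(0.3, n), 5, seed = 1)
  expect_true(all(full$spikes))
  half <- presynaptic_spike_train(rep(0.15, n), 5, seed = 1)
  expect_equal(mean(half$spikes), 0.5, tolerance = 0.05)
  # literal comparator inverts the relation
  lit <- presynaptic_spike_train(rep(0.3, n), 5, seed = 1, literal = TRUE)
  expect_false(any(lit$spikes))
})

test_that("cells differing only in spatial RF respond identically to full-field flashes", {
  a <- tiny_arena()
  fl <- make_full_field_flash(a, 50, 250, duration = 500)
  mk <- function(sx, sy, ox) presyn_cell(
    rf_component(ox, 0, size_x = sx, size_y = sy, rise_time = 30,
                 decay_time = 150))
  r1 <- cell_conductance(mk(15, 15, -40), fl)
  r2 <- cell_conductance(mk(60, 25, 30), fl)
  expect_equal(r1, r2)
})
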