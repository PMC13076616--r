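# surrogate morphologies, SWC round-trip, synapse placement, cable solver

test_that("surrogate arbors have the requested size and are proper trees", {
  m <- generate_dsgc_morphology(352, seed = 3)
  s <- m$segments
  expect_equal(nrow(s), 352)
  expect_equal(sum(s$parent == 0L), 1)  # one root
  # every segment has a unique path to the root (no cycles, connected)
  for (i in sample(nrow(s), 20)) {
    id <- s$id[i]; hops <- 0
    while (id != 1L && hops < 1000) {
      id <- s$parent[match(id, s$id)]
      hops <- hops + 1
    }
    expect_identical(id, 1L)
  }
  # parent-before-child ordering (required by the solver)
  expect_true(all(s$parent < s$id))
  # planar and within reach
  expect_true(all(s$z == 0))
  expect_lt(max(sqrt(s$x^2 + s$y^2)), 180)

  p <- generate_pyramidal_morphology(69, seed = 3)
  expect_equal(nrow(p$segments), 69)
  expect_gt(max(p$segments$y), 100)  # apical trunk

  expect_error(generate_dsgc_morphology(5), class = "emd_invalid_parameter")
})

test_that("morphologies are seed-deterministic and round-trip through SWC", {
  m1 <- generate_dsgc_morphology(80, seed = 11)
  m2 <- generate_dsgc_morphology(80, seed = 11)
  expect_identical(m1$segments, m2$segments)
  path <- withr::local_tempfile(fileext = ".swc")
  write_swc(m1, path)
  m3 <- read_swc(path)
  expect_equal(m3$segments$x, m1$segments$x, tolerance = 1e-9)
  expect_equal(m3$segments$diam, m1$segments$diam, tolerance = 1e-9)
  expect_identical(m3$segments$parent, m1$segments$parent)
})

test_that("synapse placement follows the retinal and cortical rules", {
  m <- generate_dsgc_morphology(100, seed = 2)
  pos <- tibble::tibble(x = m$segments$x[c(10, 40, 70)],
                        y = m$segments$y[c(10, 40, 70)])
  sites <- place_synapses(pos, m, mode = "retina")
  expect_identical(sites$segment, m$segments$id[c(10, 40, 70)])
  expect_equal(nrow(sites), 3)

  pos2 <- tibble::tibble(x = runif(100, -100, 100), y = runif(100, -100, 100),
                         polarity = rep(c("excitatory", "inhibitory"), 50))
  s1 <- place_synapses(pos2, m, mode = "cortex", seed = 7)
  s2 <- place_synapses(pos2, m, mode = "cortex", seed = 7)
  expect_identical(s1, s2)
  expect_true(all(s1$segment %in% m$segments$id))
  expect_setequal(unique(s1$e_syn), c(0, -70))
  expect_error(place_synapses(pos[0, ], m), class = "emd_invalid_parameter")
})

test_that("passive solver matches the closed-form RC response within 1%", {
  m1 <- structure(list(segments = tibble::tibble(
    id = 1L, parent = 0L, x = 0, y = 0, z = 0, length = 10, diam = 10,
    is_soma = TRUE)), class = "emd_morphology")
  pass <- passive_properties()
  g_step <- matrix(1e-3, 200, 1)  # 1 nS step
  out <- simulate_compartmental(m1, pass,
                                tibble::tibble(cell = 1, segment = 1L,
                                               e_syn = 0),
                                g_step, dt_stim = 5, dt_v = 0.02)
  A <- pi * 10 * 10 * 1e-8
  Cn <- pass$c_m * A * 1e3; gp <- pass$g_pas * A * 1e6; gs <- 1e-3
  vinf <- (pass$e_rest * gp) / (gp + gs)
  tau <- Cn / (gp + gs)
  vth <- vinf + (pass$e_rest - vinf) * exp(-out$time / tau)
  expect_lt(max(abs(out$v_soma - vth)) / abs(vinf - pass$e_rest), 0.01)
})

test_that("solver is stable, passive, and dt-convergent on a branched tree", {
  m <- generate_dsgc_morphology(60, seed = 5)
  pass <- passive_properties()
  sites <- tibble::tibble(cell = 1:3, segment = c(5L, 25L, 50L),
                          e_syn = c(0, 0, 0))
  g <- matrix(0, 120, 3); g[20:60, ] <- 8e-4
  out <- simulate_compartmental(m, pass, sites, g, dt_stim = 5, dt_v = 0.1)
  # rest before input, passivity bounds during input
  expect_equal(out$v_soma[1], -60)
  expect_true(all(out$v_soma >= -60 - 1e-9 & out$v_soma <= 0))
  # relaxes back toward rest after input ceases
  expect_lt(abs(out$v_soma[length(out$v_soma)] + 60), 0.05)
  # halving dt changes the peak by < 0.5%
  out2 <- simulate_compartmental(m, pass, sites, g, dt_stim = 5, dt_v = 0.05)
  expect_lt(abs(out$peak - out2$peak) / out2$peak, 0.005)
  # doubling excitatory conductance increases the peak, sublinearly
  out3 <- simulate_compartmental(m, pass, sites, 2 * g, dt_stim = 5,
                                 dt_v = 0.1)
  expect_gt(out3$peak, out$peak)
  expect_lt(out3$peak, 2 * out$peak)
  expect_error(simulate_compartmental(m, pass, sites, -g, dt_stim = 5),
               class = "emd_invalid_parameter")
})

test_that("two-compartment response matches the analytic two-exponential solution", {
  # two identical compartments coupled axially, current step onto comp 2:
  # eigen-decomposition of the 2x2 system gives the reference
  m2 <- structure(list(segments = tibble::tibble(
    id = 1:2, parent = c(0L, 1L), x = c(0, 10), y = 0, z = 0, length = 10,
    diam = 10, is_soma = c(TRUE, FALSE))), class = "emd_morphology")
  pass <- passive_properties()
  gs <- 5e-4
  g <- matrix(gs, 400, 1)
  out <- simulate_compartmental(m2, pass,
                                tibble::tibble(cell = 1, segment = 2L,
                                               e_syn = 0),
                                g, dt_stim = 5, dt_v = 0.02)
  A <- pi * 10 * 10 * 1e-8
  Cn <- pass$c_m * A * 1e3
  gp <- pass$g_pas * A * 1e6
  r_half <- pass$r_a * (10 / 2 * 1e-4) / (pi * (5e-4)^2)
  gc <- 1e6 / (2 * r_half)
  # linear system dV/dt = M V + b (V relative to rest)
  M <- matrix(c(-(gp + gc) / Cn, gc / Cn,
                gc / Cn, -(gp + gc + gs) / Cn), 2, 2, byrow = TRUE)
  b <- c(0, gs * (0 - pass$e_rest) / Cn)
  vss <- solve(-M, b)
  eig <- eigen(M)
  coefs <- solve(eig$vectors, -vss)
  vt <- vapply(out$time, function(t) {
    (eig$vectors %*% (coefs * exp(eig$values * t)))[1] + vss[1]
  }, numeric(1))
  expect_lt(max(abs((out$v_soma - pass$e_rest) - vt)) / max(abs(vt)), 0.01)
})

test_that("spiking soma fires with strong drive and spike counting is exact", {
  v <- c(-60, -20, 5, -10, 2, 8, -30, 1, -60)
  expect_equal(count_spikes(v), 3)
  expect_equal(count_spikes(rep(-60, 10)), 0)

  m <- generate_dsgc_morphology(40, seed = 8)
  pass <- passive_properties()
  sites <- tibble::tibble(cell = 1, segment = 1L, e_syn = 0)
  weak <- matrix(2e-4, 200, 1)
  strong <- matrix(0.02, 200, 1)
  out_w <- simulate_compartmental(m, pass, sites, weak, 5, spiking = TRUE)
  out_s <- simulate_compartmental(m, pass, sites, strong, 5, spiking = TRUE)
  expect_equal(count_spikes(out_w$v_soma), 0)
  expect_gt(count_spikes(out_s$v_soma), 0)
  # spike count grows with drive over the tonic-firing range
  counts <- vapply(c(0.002, 0.01, 0.04), function(gg) {
    count_spikes(simulate_compartmental(m, pass, sites,
                                        matrix(gg, 200, 1), 5,
                                        spiking = TRUE)$v_soma)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("the minimal detector is a plain weighted sum", {
  a <- c(0, 1, 2, 1); b <- c(1, 0, 1, 0)
  expect_equal(simulate_minimal_detector(a, b, 2, 3), 2 * a + 3 * b)
  expect_equal(simulate_minimal_detector(a, b, 1, 0), a)
  expect_equal(simulate_minimal_detector(a, b, 2, 3),
               simulate_minimal_detector(b, a, 3, 2))
  expect_error(simulate_minimal_detector(a, b[-1]),
               class = "emd_invalid_parameter")
})
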