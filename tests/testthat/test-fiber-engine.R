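test_that("fibers rest at a stationary point with steady-state gating", {
  for (spec in list(list("MRG", 10, 30000), list("RATTAY", 1, 5000))) {
    fib <- test_fiber(spec[[1]], spec[[2]], spec[[3]])
    wf <- make_waveform(waveform_spec("BIPHASIC_PULSE_TRAIN", pw = 100,
                                      period = 1000, dt = 10, tstop = 20))
    rec <- simulate_fiber(fib, rep(0, length(fib$z)), wf, 0)
    drift <- max(abs(sweep(rec$vm, 2, rec$vm[1, ])))
    expect_lt(drift, 1)
    # gating sits at x_inf of the settled potential
    v0 <- fib$rest_state$vm[fib$node_index[1]]
    gi <- nervestim:::.gating_inf(v0, fib$params$model,
                                  fib$params$celsius, fib$params$vtraub)
    expect_equal(fib$rest_state$g1[fib$node_index[1]], gi[1],
                 tolerance = 1e-6)
    expect_equal(fib$rest_state$g2[fib$node_index[1]], gi[2],
                 tolerance = 1e-6)
  }
})

test_that("MRG compartment counts follow the 11-per-internode pattern", {
  fib <- test_fiber("MRG", 10, 30000)
  n_nodes <- length(fib$node_index)
  expect_equal(length(fib$z), 11 * (n_nodes - 1) + 1)
  expect_equal(table(fib$compartment)[["MYSA"]], 2 * (n_nodes - 1))
  expect_equal(table(fib$compartment)[["STIN"]], 6 * (n_nodes - 1))
})

test_that("zero-amplitude drive and uniform potentials produce no spikes", {
  fib <- test_fiber("MRG", 10, 30000)
  wf <- activation_waveform()
  rec0 <- simulate_fiber(fib, rep(0, length(fib$z)), wf, 0)
  expect_equal(detect_aps(rec0, fib$node_index[5])$count, 0)
  # uniform Ve has zero second difference: no axial drive at any amplitude
  recU <- simulate_fiber(fib, rep(0.5, length(fib$z)), wf, 100)
  expect_equal(detect_aps(recU, fib$node_index[5])$count, 0)
  drift <- max(abs(sweep(recU$vm, 2, recU$vm[1, ])))
  expect_lt(drift, 1)
})

test_that("intracellular pulses evoke propagating APs with diameter-ordered velocity", {
  cv57 <- conduction_velocity(test_fiber("MRG", 5.7, 30000))
  cv115 <- conduction_velocity(test_fiber("MRG", 11.5, 30000))
  expect_gt(cv57, 0)
  expect_gt(cv115, cv57)
  # plausible mammalian myelinated range (m/s)
  expect_gt(cv115, 30)
  expect_lt(cv115, 120)
})

test_that("cathodic threshold is lower than anodic for a point source", {
  fib <- test_fiber("MRG", 10, 30000)
  f <- point_source_field(1000, weight = -1)  # cathodic
  up <- fiber_unit_potentials(fib, f)
  wf <- activation_waveform()
  t_cat <- find_activation_threshold(fib, up, wf)$threshold
  t_an <- find_activation_threshold(fib, -up, wf)$threshold
  expect_lt(t_cat, t_an)
})

test_that("spikes initiate at the node nearest the cathode", {
  fib <- test_fiber("MRG", 10, 30000)
  wf <- activation_waveform()
  nodes <- fib$node_index
  for (z_src in c(-4000, -1200, 0, 2000, 5000)) {
    f <- point_source_field(1000, weight = -1)
    up <- sample_potentials(f, cbind(0, 0, fib$z - z_src))
    th <- find_activation_threshold(fib, up, wf)$threshold
    rec <- simulate_fiber(fib, up, wf, th)
    cross <- apply(rec$vm, 2, function(v) {
      k <- which(v > -30)[1]
      if (is.na(k)) Inf else k
    })
    init <- which.min(cross)
    nearest <- which.min(abs(fib$z[nodes] - z_src))
    expect_lte(abs(init - nearest), 1)
  }
})

test_that("AP detection applies threshold crossing with refractory lockout", {
  # synthetic traces exercise the detector without a simulation
  t <- seq(0, 10, by = 0.01)
  v <- rep(-80, length(t))
  v[t >= 2 & t < 2.2] <- 10
  v[t >= 7 & t < 7.2] <- 10
  rec <- structure(list(t = t, vm = cbind(v), sites = 1L, z_sites = 0,
                        amplitude = 0, dt = 0.01), class = "sim_record")
  expect_equal(detect_aps(rec, 1)$count, 2)
  flat <- rec; flat$vm <- cbind(rep(-80, length(t)))
  expect_equal(detect_aps(flat, 1)$count, 0)
  # two crossings 0.4 ms apart with a 1 ms lockout count once
  v2 <- rep(-80, length(t))
  v2[t >= 2 & t < 2.1] <- 10
  v2[t >= 2.4 & t < 2.5] <- 10
  rec2 <- rec; rec2$vm <- cbind(v2)
  expect_equal(detect_aps(rec2, 1)$count, 1)
  expect_equal(detect_aps(rec2, 1, lockout = 0.2)$count, 2)
  expect_error(detect_aps(rec, 99), "not recorded")
})

test_that("thresholds converge under timestep refinement", {
  fib <- test_fiber("MRG", 10, 30000)
  f <- point_source_field(1000, weight = -1)
  up <- fiber_unit_potentials(fib, f)
  th5 <- find_activation_threshold(fib, up, activation_waveform(dt = 5),
                                   search_params(tol = 0.005))$threshold
  th25 <- find_activation_threshold(fib, up, activation_waveform(dt = 2.5),
                                    search_params(tol = 0.005))$threshold
  expect_lt(abs(th5 - th25) / th25, 0.02)
})
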