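test_that("the returned activation threshold honors the bisection contract", {
  fib <- test_fiber("MRG", 10, 30000)
  f <- point_source_field(1000, weight = -1)
  up <- fiber_unit_potentials(fib, f)
  wf <- activation_waveform()
  res <- find_activation_threshold(fib, up, wf,
                                   search_params(tol = 0.01))
  expect_true(res$converged)
  site <- res$detect_site
  fire <- function(amp) {
    rec <- simulate_fiber(fib, up, wf, amp, record_sites = site)
    detect_aps(rec, site)$count >= 1
  }
  expect_true(fire(res$threshold))
  expect_false(fire(res$threshold * (1 - 2 * res$tol)))
})

test_that("larger fibers and closer sources have lower thresholds", {
  wf <- activation_waveform()
  f <- point_source_field(1000, weight = -1)
  th <- function(fib, field = f) {
    up <- fiber_unit_potentials(fib, field)
    find_activation_threshold(fib, up, wf)$threshold
  }
  t14 <- th(test_fiber("MRG", 14, 30000))
  t57 <- th(test_fiber("MRG", 5.7, 30000))
  expect_lt(t14, t57)
  fib <- test_fiber("MRG", 10, 30000)
  t_near <- th(fib, point_source_field(1000, weight = -1))
  t_far <- th(fib, point_source_field(2000, weight = -1))
  expect_gt(t_far, t_near)
})

test_that("thresholds scale exactly inversely with the basis potential scale", {
  fib <- test_fiber("MRG", 10, 30000)
  f <- point_source_field(1000, weight = -1)
  up <- fiber_unit_potentials(fib, f)
  wf <- activation_waveform()
  # drive = amplitude x unit potentials, so scaling potentials by c and the
  # bracket by 1/c reproduces the identical bisection path
  s1 <- search_params(lower = 0.01, upper = 1, tol = 0.01)
  c_scale <- 2.5
  s2 <- search_params(lower = 0.01 / c_scale, upper = 1 / c_scale,
                      tol = 0.01)
  t1 <- find_activation_threshold(fib, up, wf, s1)$threshold
  t2 <- find_activation_threshold(fib, up * c_scale, wf, s2)$threshold
  expect_equal(t2, t1 / c_scale, tolerance = 1e-12)
})

test_that("threshold is stable under tolerance refinement", {
  fib <- test_fiber("MRG", 10, 30000)
  f <- point_source_field(1000, weight = -1)
  up <- fiber_unit_potentials(fib, f)
  wf <- activation_waveform()
  t_fine <- find_activation_threshold(fib, up, wf,
                                      search_params(tol = 0.005))$threshold
  t_coarse <- find_activation_threshold(fib, up, wf,
                                        search_params(tol = 0.02))$threshold
  expect_lt(abs(t_fine - t_coarse) / t_coarse, 0.03)
})

test_that("non-excitable configurations report a capped search, not an error", {
  fib <- test_fiber("MRG", 10, 30000)
  up <- rep(1e-9, length(fib$z))  # essentially no drive
  wf <- activation_waveform()
  res <- find_activation_threshold(fib, up, wf,
                                   search_params(upper = 0.1, cap = 0.5))
  expect_false(res$converged)
  expect_true(is.na(res$threshold))
})

test_that("kHz block threshold blocks at T and conducts below T", {
  fib <- test_fiber("MRG", 10, 30000)
  f <- point_source_field(1000, weight = -1)
  up <- fiber_unit_potentials(fib, f)
  blk <- make_waveform(waveform_spec("BIPHASIC_FULL_DUTY", frequency = 10,
                                     dt = 5, tstop = 46))
  res <- find_block_threshold(fib, up, blk,
                              search = search_params(lower = 0.05,
                                                     upper = 2))
  expect_true(res$converged)
  expect_equal(res$assay_window[1], 20)
  count <- function(amp) {
    rec <- simulate_fiber(fib, up, blk, amp, istim = res$test_stimulus,
                          record_sites = res$detect_site)
    detect_aps(rec, res$detect_site, t_min = 19)$count
  }
  # control: all three test pulses arrive with no block stimulus
  expect_equal(count(0), 3)
  expect_equal(count(res$threshold), 0)
  expect_gte(count(res$threshold * (1 - 2 * res$tol)), 1)
  # block requires more current than single-pulse activation
  act <- find_activation_threshold(fib, up, activation_waveform())$threshold
  expect_gt(res$threshold, act)
})

test_that("a subthreshold test pulse is flagged as a protocol misconfiguration", {
  fib <- test_fiber("MRG", 10, 30000)
  up <- fiber_unit_potentials(fib, point_source_field(1000, weight = -1))
  blk <- make_waveform(waveform_spec("BIPHASIC_FULL_DUTY", frequency = 10,
                                     dt = 5, tstop = 46))
  weak <- list(node = fib$node_index[2], delay = 20, dur = 0.01,
               amp = 0.001, n_pulses = 3L, interval = 10)
  expect_error(find_block_threshold(fib, up, blk, test_stimulus = weak),
               "subthreshold")
})

test_that("fixed-amplitude runs bracket the threshold with 0 and >= 1 spikes", {
  fib <- test_fiber("MRG", 10, 30000)
  up <- fiber_unit_potentials(fib, point_source_field(1000, weight = -1))
  wf <- activation_waveform()
  tr <- find_activation_threshold(fib, up, wf)
  recs <- run_fixed_amplitudes(fib, up, wf,
                               c(0, 0.5 * tr$threshold, 2 * tr$threshold),
                               detect_site = tr$detect_site)
  counts <- attr(recs, "spike_counts")
  expect_length(recs, 3)
  expect_equal(counts[1], 0L)
  expect_equal(counts[2], 0L)
  expect_gte(counts[3], 1L)
})
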