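test_that("explicit mock generation matches requested ellipses and is deterministic", {
  p <- mock_params("explicit",
                   nerve = list(a = 400, b = 300, center = c(0, 0),
                                rotation = 0),
                   fascicles = list(
                     list(a = 100, b = 50, center = c(100, 0), rotation = 20),
                     list(a = 60, b = 60, center = c(-150, 50))))
  s <- generate_mock_explicit(p)
  expect_length(s$fascicles, 2)
  a1 <- trace_area(s$fascicles[[1]]$inners[[1]])
  expect_lt(abs(a1 - pi * 100 * 50) / (pi * 100 * 50), 0.005)
  s2 <- generate_mock_explicit(p)
  expect_identical(s$fascicles[[1]]$inners[[1]]$points,
                   s2$fascicles[[1]]$inners[[1]]$points)
})

test_that("explicit generation rejects fascicles outside the nerve or overlapping", {
  p_out <- mock_params("explicit",
                       nerve = list(a = 200, b = 200, center = c(0, 0),
                                    rotation = 0),
                       fascicles = list(list(a = 50, b = 50,
                                             center = c(300, 0))))
  expect_error(generate_mock_explicit(p_out), "not inside nerve")
  p_ovl <- mock_params("explicit",
                       nerve = list(a = 400, b = 400, center = c(0, 0),
                                    rotation = 0),
                       fascicles = list(
                         list(a = 80, b = 80, center = c(0, 0)),
                         list(a = 80, b = 80, center = c(50, 0))))
  expect_error(generate_mock_explicit(p_ovl), "overlap")
})

test_that("probabilistic generation honors separation and seed determinism", {
  p <- mock_params("probabilistic", count = 5, seed = 7,
                   nerve = list(a = 500, b = 450, center = c(0, 0),
                                rotation = 0),
                   diameter = list(mean = 150, sd = 30, min = 90, max = 250),
                   min_separation = 12)
  s1 <- generate_mock_probabilistic(p)
  expect_length(s1$fascicles, 5)
  bounds <- lapply(s1$fascicles, nervestim:::fascicle_boundary)
  for (i in 1:4) for (j in (i + 1):5)
    expect_gte(trace_boundary_distance(bounds[[i]], bounds[[j]]), 12)
  for (b in bounds)
    expect_true(trace_inside(b, s1$nerve, margin = 12))
  s2 <- generate_mock_probabilistic(p)
  c1 <- t(vapply(bounds, trace_centroid, numeric(2)))
  c2 <- t(vapply(lapply(s2$fascicles, nervestim:::fascicle_boundary),
                 trace_centroid, numeric(2)))
  expect_identical(c1, c2)
})

test_that("overfull nerves saturate with a skip report", {
  p <- mock_params("probabilistic", count = 40, seed = 2,
                   nerve = list(a = 300, b = 300, center = c(0, 0),
                                rotation = 0),
                   diameter = list(mean = 150, sd = 10, min = 130,
                                   max = 180),
                   min_separation = 10, max_attempts = 20)
  expect_warning(s <- generate_mock_probabilistic(p), "skipped")
  expect_lt(length(s$fascicles), 40)
  expect_equal(attr(s, "skipped"), 40L - length(s$fascicles))
})

test_that("shrinkage correction scales areas by 1/(1-s)^2 about the nerve centroid", {
  s <- small_sample()
  expect_identical(apply_shrinkage_correction(s, 0)$fascicles[[1]]$inners[[1]]$points,
                   s$fascicles[[1]]$inners[[1]]$points)
  a0 <- trace_area(s$fascicles[[1]]$inners[[1]])
  sc <- apply_shrinkage_correction(s, 0.2)
  a1 <- trace_area(sc$fascicles[[1]]$inners[[1]])
  expect_equal(a1 / a0, 1 / 0.64, tolerance = 1e-9)
  # relative centroid offsets scale uniformly
  ctr <- trace_centroid(s$nerve)
  off0 <- trace_centroid(s$fascicles[[2]]$inners[[1]]) - ctr
  off1 <- trace_centroid(sc$fascicles[[2]]$inners[[1]]) -
    trace_centroid(sc$nerve)
  expect_equal(off1, off0 / 0.8, tolerance = 1e-6)
  expect_error(apply_shrinkage_correction(s, 1), "shrinkage")
})

test_that("deformation to the cuff maps the boundary to a circle and preserves fascicle areas", {
  p <- mock_params("explicit",
                   nerve = list(a = 200, b = 100, center = c(0, 0),
                                rotation = 0),
                   fascicles = list(
                     list(a = 40, b = 30, center = c(80, 0)),
                     list(a = 35, b = 35, center = c(-70, 20))),
                   min_separation = 5)
  s <- generate_mock_explicit(p)
  areas0 <- vapply(s$fascicles, function(f) trace_area(f$inners[[1]]), 0)
  d <- deform_to_cuff(s, 300)
  r <- sqrt(rowSums(d$nerve$points^2))
  expect_true(all(abs(r - 150) / 150 < 0.005))
  areas1 <- vapply(d$fascicles, function(f) trace_area(f$inners[[1]]), 0)
  expect_equal(areas1, areas0, tolerance = 1e-3)
  expect_silent(validate_sample(d))

  # already-circular nerve at cuff diameter: near identity
  pc <- mock_params("explicit",
                    nerve = list(a = 150, b = 150, center = c(0, 0),
                                 rotation = 0),
                    fascicles = list(list(a = 40, b = 40,
                                          center = c(50, 0))))
  sc <- generate_mock_explicit(pc)
  dc <- deform_to_cuff(sc, 300)
  expect_equal(trace_centroid(dc$fascicles[[1]]$inners[[1]]),
               trace_centroid(sc$fascicles[[1]]$inners[[1]]),
               tolerance = 1)
  expect_error(deform_to_cuff(sc, 60), "packing")
})

test_that("probabilistic generation invariants hold over many seeds", {
  # a compressed version of the long-run invariant sweep (the full
  # 1000-seed sweep runs in the acceptance suite)
  for (seed in 1:25) {
    p <- mock_params("probabilistic", count = 4, seed = seed,
                     nerve = list(a = 420, b = 380, center = c(0, 0),
                                  rotation = 0),
                     diameter = list(mean = 140, sd = 35, min = 70,
                                     max = 260),
                     min_separation = 10)
    s <- suppressWarnings(generate_mock_probabilistic(p))
    expect_silent(validate_sample(s))
  }
})
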