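test_that("CENTROID mode places one fiber at each inner-trace centroid", {
  s <- small_sample()
  xy <- xy_locations(s, fiber_xy_mode("CENTROID"))
  expect_equal(nrow(xy), 3)
  for (i in 1:3)
    expect_equal(c(xy$x[i], xy$y[i]),
                 trace_centroid(s$fascicles[[i]]$inners[[1]]),
                 tolerance = 1e-9)
})

test_that("UNIFORM_COUNT places the requested fibers strictly inside fascicles", {
  s <- small_sample()
  xy <- xy_locations(s, fiber_xy_mode("UNIFORM_COUNT", count = 10,
                                      seed = 4))
  expect_equal(nrow(xy), 30)
  for (i in seq_len(nrow(xy)))
    expect_true(points_in_trace(cbind(xy$x[i], xy$y[i]),
                                s$fascicles[[xy$fascicle[i]]]$inners[[1]]))
  # seeded determinism
  xy2 <- xy_locations(s, fiber_xy_mode("UNIFORM_COUNT", count = 10,
                                       seed = 4))
  expect_identical(xy, xy2)
  xy3 <- xy_locations(s, fiber_xy_mode("UNIFORM_COUNT", count = 10,
                                       seed = 5))
  expect_false(identical(xy, xy3))
})

test_that("UNIFORM_DENSITY allocates counts proportional to fascicle area", {
  p <- mock_params("explicit",
                   nerve = list(a = 600, b = 600, center = c(0, 0),
                                rotation = 0),
                   fascicles = list(
                     list(a = 200, b = 100, center = c(250, 0)),   # area A
                     list(a = 100, b = 100, center = c(-250, 0))), # area A/2
                   min_separation = 5)
  s <- generate_mock_explicit(p)
  dens <- 500 / (pi * 200 * 100 / 1e6)  # 500 fibers in the big fascicle
  xy <- xy_locations(s, fiber_xy_mode("UNIFORM_DENSITY", density = dens,
                                      seed = 1))
  n1 <- sum(xy$fascicle == 1)
  n2 <- sum(xy$fascicle == 2)
  expect_equal(n1, 2 * n2, tolerance = 0.01)
  # zero-count fascicles warn
  expect_warning(
    xy_locations(s, fiber_xy_mode("UNIFORM_DENSITY", density = 1e-6,
                                  seed = 1)),
    "zero fibers")
})

test_that("EXPLICIT points are validated against fascicle membership", {
  s <- small_sample()
  ctr <- trace_centroid(s$fascicles[[1]]$inners[[1]])
  xy <- xy_locations(s, fiber_xy_mode("EXPLICIT", points = rbind(ctr)))
  expect_equal(xy$fascicle, 1L)
  expect_error(
    xy_locations(s, fiber_xy_mode("EXPLICIT", points = rbind(c(1e4, 1e4)))),
    "outside every fascicle")
})

test_that("MRG geometry interpolation is exact at published anchors and monotone", {
  g10 <- mrg_geometry(10)
  expect_equal(g10$deltaz, 1150)
  expect_equal(g10$flut_length, 46)
  expect_equal(g10$node_diameter, 3.3)
  expect_equal(g10$axon_diameter, 6.9)
  expect_equal(g10$n_lamellae, 120)
  g16 <- mrg_geometry(16)
  expect_equal(g16$deltaz, 1500)  # largest published anchor
  # pattern identity: deltaz = node + 2 MYSA + 2 FLUT + 6 STIN
  for (d in c(2, 3.5, 5.7, 8.2, 10, 12.8, 16)) {
    g <- mrg_geometry(d)
    expect_equal(g$deltaz,
                 g$node_length + 2 * g$mysa_length + 2 * g$flut_length +
                   6 * g$stin_length, tolerance = 1e-9)
  }
  dz <- vapply(seq(2, 16, by = 0.5), function(d) mrg_geometry(d)$deltaz, 0)
  expect_true(all(diff(dz) > 0))
  expect_error(mrg_geometry(1.5), "2, 16")
  expect_error(mrg_geometry(17), "2, 16")
})

test_that("myelinated z grids follow the 11-compartment repeat with a centered node", {
  zg <- nervestim:::fiber_z_grid("MRG", 10, 50000, z0 = 0)
  n_nodes <- sum(zg$compartment == "node")
  expect_equal(n_nodes, 45)            # 44 internodes
  expect_equal(n_nodes %% 2, 1)
  expect_equal(length(zg$z), 44 * 11 + 1)
  mid_node_z <- zg$z[zg$compartment == "node"][(n_nodes + 1) / 2]
  expect_equal(mid_node_z, 25000)      # center node at length/2
  expect_true(all(diff(zg$z) > 0))
  # period pattern between consecutive nodes
  nodes_z <- zg$z[zg$compartment == "node"]
  expect_equal(unique(round(diff(nodes_z), 9)), 1150)
  # symmetry of compartments about the midpoint
  zc <- zg$z - 25000
  expect_equal(sort(abs(zc)), sort(abs(-zc)), tolerance = 1e-9)
})

test_that("unmyelinated grids are uniform with the documented section count", {
  zg <- nervestim:::fiber_z_grid("RATTAY", 1, 5000, z0 = 0, dz_u = 8.333)
  expect_equal(length(zg$z), 601)      # floor(5000/8.333) + 1
  expect_equal(unique(round(diff(zg$z), 9)), 8.333)
})

test_that("build_fiberset attaches identical z grids to all fibers and errors on short fibers", {
  s <- small_sample()
  fs <- build_fiberset(s, fiber_xy_mode("CENTROID"), "MRG", 10, 30000)
  expect_length(fs$fibers, 3)
  expect_identical(fs$fibers[[1]]$z, fs$fibers[[2]]$z)
  expect_error(build_fiberset(s, fiber_xy_mode("CENTROID"), "MRG", 10,
                              2000), "3 internode")
})
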