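# Shared fixtures. Fibers are expensive to settle, so they are memoized for
# the whole test session.

.fixture_env <- new.env(parent = emptyenv())

test_fiber <- function(model = "MRG", diameter = 10, length = 30000) {
  key <- sprintf("%s_%g_%g", model, diameter, length)
  f <- get0(key, .fixture_env)
  if (is.null(f)) {
    zg <- nervestim:::fiber_z_grid(model, diameter, length)
    f <- build_fiber(model, diameter, zg$z, zg$compartment)
    assign(key, f, .fixture_env)
  }
  f
}

# point current source at (0, dist_um, 0) with cathodic weighting, evaluated
# in homogeneous endoneurium
point_source_field <- function(dist_um = 1000, weight = -1,
                               sigma = get_material("endoneurium")) {
  cuff <- cuff_preset("monopolar_ring", inner_diameter = 2 * dist_um)
  pl <- place_cuff(cuff, add_ang = 90)
  superpose(list(solve_basis_analytic(pl, 1, sigma)), weight)
}

fiber_unit_potentials <- function(fiber, field, x = 0, y = 0) {
  sample_potentials(field, cbind(x, y, fiber$z))
}

activation_waveform <- function(dt = 5, tstop = 5)
  make_waveform(waveform_spec("BIPHASIC_PULSE_TRAIN", pw = 100,
                              period = 5000, dt = dt, tstop = tstop,
                              delay = 100))

# small deterministic 3-fascicle sample
small_sample <- function(seed = 11) {
  generate_mock_probabilistic(mock_params(
    "probabilistic", count = 3, seed = seed,
    nerve = list(a = 350, b = 300, center = c(0, 0), rotation = 0),
    diameter = list(mean = 140, sd = 25, min = 80, max = 220),
    min_separation = 15))
}

# a simple mock placement whose only contact sits at (r, 0, 0)
unit_placement <- function(r = 1000, z = 0) {
  cuff <- cuff_preset("monopolar_ring", inner_diameter = 2 * r)
  place_cuff(cuff, add_ang = 0, z_center = z)
}
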