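#' Build a biophysical fiber instance
#'
#' Constructs the per-compartment electrical parameters of a cable-model
#' fiber on a fiberset z grid and settles it to its resting steady state.
#'
#' `"MRG"` is the myelinated double-cable model: nodes of Ranvier carry
#' fast Na+, persistent Na+, slow K+ and leak conductances; MYSA, FLUT and
#' STIN internodal compartments are passive, with an explicit myelin sheath
#' (per-lamella conductance and capacitance in series) and a periaxonal
#' axial pathway. `"RATTAY"` is an unmyelinated fiber with uniform HH-type
#' membrane. Ends are sealed.
#'
#' @param model `"MRG"` or `"RATTAY"`
#' @param diameter fiber diameter (um)
#' @param z compartment z coordinates (um) from [build_fiberset()] /
#'   `fiber_z_grid`
#' @param compartment compartment labels (required for MRG)
#' @param celsius temperature; default 36 for MRG (the model's native
#'   temperature), 37 for RATTAY
#' @param settle_ms settling time used to locate the resting state
#' @return an object of class `fiber_instance`
#' @export
build_fiber <- function(model = c("MRG", "RATTAY"), diameter, z,
                        compartment = NULL, celsius = NULL,
                        settle_ms = 500) {
  model <- match.arg(model)
  n <- length(z)
  stopifnot(n >= 3L, all(diff(z) > 0))
  if (model == "MRG") {
    if (is.null(compartment) || length(compartment) != n)
      stop("MRG fibers need compartment labels matching the z grid")
    if (is.null(celsius)) celsius <- 36
    g <- mrg_geometry(diameter)
    lab <- compartment
    L <- ifelse(lab == "node", g$node_length,
         ifelse(lab == "MYSA", g$mysa_length,
         ifelse(lab == "FLUT", g$flut_length, g$stin_length)))
    d_ax <- ifelse(lab %in% c("node", "MYSA"), g$node_diameter,
                   g$axon_diameter)
    space <- ifelse(lab %in% c("node", "MYSA"), 0.002, 0.004)
    area <- pi * d_ax * L                      # axolemma area, um^2
    area_my <- pi * diameter * L               # myelin area, um^2
    is_node <- lab == "node"
    rhoa <- 70                                  # Ohm cm, axoplasm+periaxonal
    cmv <- 2 * area * 1e-5                      # nF
    gpas <- ifelse(is_node, 0.007,
            ifelse(lab == "MYSA", 0.001, 0.0001)) * area * 1e-2  # uS
    epas <- ifelse(is_node, -90, -80)
    gnaf <- ifelse(is_node, 3.0 * area * 1e-2, 0)
    gnap <- ifelse(is_node, 0.01 * area * 1e-2, 0)
    gks <- ifelse(is_node, 0.08 * area * 1e-2, 0)
    nlam <- 2 * g$n_lamellae                    # membranes in the sheath
    xg <- ifelse(is_node, 1e6, 0.001 / nlam * area_my * 1e-2)
    xc <- ifelse(is_node, 0, 0.1 / nlam * area_my * 1e-5)
    half_R <- rhoa * 1e4 * (L / 2) / (pi * d_ax^2 / 4)       # Ohm
    ga <- 1e6 / (half_R[-n] + half_R[-1])                    # uS
    ann <- pi * ((d_ax / 2 + space)^2 - (d_ax / 2)^2)
    half_Rp <- rhoa * 1e4 * (L / 2) / ann
    gp <- 1e6 / (half_Rp[-n] + half_Rp[-1])
    fib <- list(model = 0L, cm = cmv, gpas = gpas, epas = epas,
                gnaf = gnaf, gnap = gnap, gks = gks,
                ga = ga, gp = gp, xg = xg, xc = xc,
                active = ifelse(is_node, 1L, 0L),
                ena = 50, ek = -90, celsius = celsius, vtraub = -80)
    vrest <- -80
  } else {
    if (is.null(celsius)) celsius <- 37
    dz <- diff(z)
    L <- c(dz[1], (dz[-1] + dz[-length(dz)]) / 2, dz[length(dz)])
    L <- pmax(L, 1e-6)
    area <- pi * diameter * L
    rhoa <- 100                                 # Ohm cm
    vtraub <- -70
    cmv <- 1 * area * 1e-5
    gpas <- 0.0003 * area * 1e-2
    epas <- rep(vtraub + 10.6, n)
    gnaf <- 0.120 * area * 1e-2
    gks <- 0.036 * area * 1e-2
    half_R <- rhoa * 1e4 * (L / 2) / (pi * diameter^2 / 4)
    ga <- 1e6 / (half_R[-n] + half_R[-1])
    fib <- list(model = 1L, cm = cmv, gpas = gpas, epas = rep(epas, length.out = n),
                gnaf = gnaf, gnap = rep(0, n), gks = gks,
                ga = ga, gp = rep(0, n - 1L), xg = rep(1e6, n),
                xc = rep(0, n), active = rep(2L, n),
                ena = vtraub + 115, ek = vtraub - 12, celsius = celsius,
                vtraub = vtraub, hh_tref = 37)
    vrest <- vtraub
  }

  gi <- .gating_inf(vrest, fib$model, celsius, fib$vtraub)
  state <- list(vm = rep(vrest, n), vp = rep(0, n),
                g1 = rep(gi[1], n), g2 = rep(gi[2], n),
                g3 = rep(gi[3], n), g4 = rep(gi[4], n))
  # settle to the true resting fixed point (no stimulus, coarse dt)
  nset <- 2L * as.integer(settle_ms) + 1L
  res <- .run_cable(fib, rep(0, n), rep(0, nset), 0, 0.5,
                    0L, numeric(0), -1L, state, nset)
  state <- res$state

  structure(list(model = model, diameter = diameter, z = z,
                 compartment = if (model == "MRG") compartment
                               else rep("section", n),
                 params = fib, rest_state = state,
                 vrest = mean(res$state$vm),
                 node_index = if (model == "MRG") which(compartment == "node")
                              else seq_len(n)),
            class = "fiber_instance")
}

#' @exportS3Method base::print
print.fiber_instance <- function(x, ...) {
  cat(sprintf("<fiber_instance> %s %g um, %d compartments (%d nodes), rest %.2f mV\n",
              x$model, x$diameter, length(x$z), length(x$node_index),
              mean(x$rest_state$vm[x$node_index])))
  invisible(x)
}

#' Simulate a fiber driven by extracellular potentials
#'
#' The extracellular drive at compartment k is
#' `Ve_k(t) = amplitude * waveform(t) * unit_potentials[k]` (unit
#' potentials are the 1 mA basis potentials sampled at the compartment
#' coordinates). Integration is backward Euler with a staggered gating
#' update; the timestep equals the waveform timestep. An optional
#' intracellular test stimulus (rectangular current pulses at one
#' compartment) supports block protocols and conduction tests.
#'
#' @param fiber a `fiber_instance`
#' @param unit_potentials per-compartment potentials (V) for the 1
#'   mA-weighted bases; length must match the compartment count
#' @param waveform a `waveform` (its `dt` sets the integration step)
#' @param amplitude stimulus amplitude (mA); the drive scales linearly
#' @param istim optional intracellular stimulus:
#'   `list(node, delay, dur, amp, n_pulses = 1, interval = 0)` with `node` a
#'   compartment index, times in ms and `amp` in nA
#' @param record_sites compartment indices to record (default: all nodes)
#' @param record_stride record every `record_stride`-th step (default 1)
#' @return an object of class `sim_record`: list with `t` (ms), `vm`
#'   (time x site matrix, mV), `sites`, `z_sites`, `amplitude`
#' @export
simulate_fiber <- function(fiber, unit_potentials, waveform, amplitude,
                           istim = NULL, record_sites = NULL,
                           record_stride = 1L) {
  stopifnot(inherits(fiber, "fiber_instance"), inherits(waveform, "waveform"))
  n <- length(fiber$z)
  if (length(unit_potentials) != n)
    stop("unit_potentials length must equal the compartment count")
  if (is.null(record_sites)) record_sites <- fiber$node_index
  dt_ms <- waveform$dt / 1000
  nt <- length(waveform$samples)
  ist <- numeric(0)
  ist_idx <- -1L
  if (!is.null(istim)) {
    ist <- numeric(nt)
    t_ms <- (seq_len(nt) - 1L) * dt_ms
    np <- istim$n_pulses %||% 1L
    iv <- istim$interval %||% 0
    for (p in seq_len(np)) {
      t0 <- istim$delay + (p - 1) * iv
      ist[t_ms >= t0 & t_ms < t0 + istim$dur] <- istim$amp
    }
    ist_idx <- as.integer(istim$node) - 1L
  }
  res <- .run_cable(fiber$params, unit_potentials * 1000, waveform$samples,
                    amplitude, dt_ms, as.integer(record_sites) - 1L,
                    ist, ist_idx, fiber$rest_state,
                    as.integer(record_stride))
  structure(list(t = res$t_rec, vm = res$vm_rec, sites = record_sites,
                 z_sites = fiber$z[record_sites], amplitude = amplitude,
                 dt = dt_ms, final_state = res$state),
            class = "sim_record")
}

#' @exportS3Method base::print
print.sim_record <- function(x, ...) {
  cat(sprintf("<sim_record> %.3g ms at %d site(s), amplitude %g mA\n",
              max(x$t), length(x$sites), x$amplitude))
  invisible(x)
}

#' Detect action potentials in a recorded trace
#'
#' Counts upward crossings of `vthresh` with a refractory lockout: after a
#' detection, further crossings within `lockout` ms are ignored.
#' Deterministic.
#'
#' @param record a `sim_record`
#' @param site compartment index (must be among the recorded sites)
#' @param vthresh detection threshold (mV, default -30)
#' @param lockout refractory lockout (ms, default 1)
#' @param t_min,t_max restrict detection to a time window (ms)
#' @return list(count, times)
#' @export
detect_aps <- function(record, site, vthresh = -30, lockout = 1,
                       t_min = -Inf, t_max = Inf) {
  j <- match(site, record$sites)
  if (is.na(j)) stop("site was not recorded")
  v <- record$vm[, j]
  t <- record$t
  up <- which(v[-1] >= vthresh & v[-length(v)] < vthresh) + 1L
  up <- up[t[up] >= t_min & t[up] <= t_max]
  times <- numeric(0)
  last <- -Inf
  for (k in up) {
    if (t[k] - last >= lockout) {
      times <- c(times, t[k])
      last <- t[k]
    }
  }
  list(count = length(times), times = times)
}

#' Conduction velocity from node-to-node spike latencies
#'
#' Fires the fiber with an intracellular suprathreshold pulse at one end
#' and regresses first-spike time on node z coordinate over the central
#' half of the fiber.
#'
#' @param fiber a `fiber_instance`
#' @param dt timestep (us)
#' @param pulse_nA intracellular pulse amplitude (nA)
#' @param tstop simulation time (ms)
#' @return conduction velocity (m/s)
#' @export
conduction_velocity <- function(fiber, dt = 5, pulse_nA = 10, tstop = 5) {
  wf <- make_waveform(waveform_spec("MONOPHASIC_PULSE_TRAIN", pw = dt,
                                    period = 2 * dt, dt = dt,
                                    tstop = tstop, delay = 0))
  wf$samples[] <- 0; wf$samples[1] <- 1  # drive is zero; istim does the work
  rec <- simulate_fiber(fiber, rep(0, length(fiber$z)), wf, 0,
                        istim = list(node = fiber$node_index[1],
                                     delay = 0.1, dur = 0.1, amp = pulse_nA))
  nodes <- fiber$node_index
  nn <- length(nodes)
  sel <- nodes[seq.int(ceiling(nn * 0.3), floor(nn * 0.8))]
  tt <- vapply(sel, function(s) {
    d <- detect_aps(rec, s)
    if (d$count < 1) NA_real_ else d$times[1]
  }, 0)
  if (any(is.na(tt))) stop("action potential did not propagate the fiber")
  zz <- fiber$z[sel] * 1e-6  # m
  fit <- stats::lm(tt * 1e-3 ~ zz)
  1 / stats::coef(fit)[["zz"]]
}
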