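---
title: "Modeling extracellular stimulation and block of peripheral nerve fibers"
author: "nervestim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling extracellular stimulation and block of peripheral nerve fibers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model structure

`nervestim` simulates how nerve fibers inside a peripheral nerve respond to
electrical stimulation delivered through a cuff electrode. The computation
has three coupled layers:

1. **Morphology.** The nerve cross section at z = 0 — a nerve boundary and a
   set of fascicles, each bounded by perineurium — is represented as closed
   polygons ("traces", micrometers, y axis up, angles counter-clockwise from
   +x). Cross sections come either from segmented binary masks or from a
   mock generator that places elliptical fascicles explicitly or
   probabilistically.
2. **Volume conductor.** Each cuff contact is reduced to a point current
   source delivering 1 mA; the potential field of each contact (a *basis*)
   is computed once, and the field of any stimulus configuration is the dot
   product of the bases with a vector of contact weights, by linearity of
   the quasi-static equation `div(sigma grad phi) = 0`.
3. **Fibers.** Cable-model fibers are placed at (x, y) locations inside
   fascicles, discretized along z, driven by the time-varying extracellular
   potentials `Ve_k(t) = amplitude * waveform(t) * basis_k`, and integrated
   implicitly. Threshold protocols wrap the simulator in bisection
   searches.

The pipeline (`run_pipeline()`) batches this over models (cuff placements)
and sims (fibersets, waveforms, protocols), with stage breakpoints, basis
caching, and skip-and-log error handling, so a study is a pure function of
its configuration files and seeds.

# Morphology

## Mock generator

The probabilistic mode draws per-fascicle effective diameters from a
truncated normal, eccentricities and rotations from uniform distributions,
and centroids by uniform disk point picking inside the nerve ellipse. A
placement is accepted only if the fascicle boundary keeps a user-set
minimum separation (default 10 um) from the nerve boundary and all placed
fascicles; after `max_attempts` (default 100) failures the fascicle is
skipped with a warning. Everything is driven by a private RNG stream, so a
sample is a pure function of (parameters, seed).

What this emulates: the fascicle count, size dispersion, and packing
typical of small multifascicular nerves. What it does not emulate: real
fascicle shapes (real perineurium traces are not ellipses), peanut
fascicles (supported by the data model, not generated), spatial clustering
of fascicles, and any variation along the nerve length. Tests passing on
mock samples therefore validate the machinery, not histological realism.

## Masks

Binary masks (nerve `n`, inners `i`, optional outers `o`, scale bar `s`)
are read from TIFF/PNG; the scale is the declared scale-bar length divided
by its longest horizontal pixel run. Connected components are contoured;
because a contour passes through boundary-pixel centers while the region
extends half a pixel beyond, each contour is inflated by a half-pixel
offset (area correction `P/2 + pi/4` pixels) before scaling to
micrometers. This keeps areas within 2 % of truth for objects with radius
of 10 px or more.

## Shrinkage and cuff deformation

Histological shrinkage correction scales all traces about the nerve
centroid by `1/(1 - shrinkage)`. Deformation into a circular cuff aperture
is deliberately geometric, not mechanical: the nerve boundary is mapped
onto the target circle by per-vertex radial scaling about the centroid;
each fascicle is translated rigidly by the displacement interpolated at its
centroid (areas untouched); residual overlaps or escapes are resolved by
iterative pairwise repulsion along centroid–centroid axes (step = overlap
depth plus the separation deficit, capped at 200 iterations). This
preserves fascicle topology and areas and is fully testable, at the cost of
not modeling tissue mechanics; a mechanical model would need constitutive
assumptions the package does not want to hide. Samples whose fascicles
cannot pack into the target circle are rejected.

# Volume conductor

## Materials

The built-in library (S/m): endoneurium {0.167, 0.167, 0.571} (anisotropic,
longitudinally conductive), perineurium 0.0008703, epineurium 0.159,
encapsulation 0.159, muscle medium {0.086, 0.086, 0.35}, saline 1.76, and a
near-insulating cuff material. Users can override any of these per model
configuration.

## Analytic bases

For a homogeneous medium with diagonal tensor `sigma` the point-source
potential is

    phi = I / (4 pi sqrt(sx sy sz) sqrt(dx^2/sx + dy^2/sy + dz^2/sz))

reducing to `I/(4 pi sigma r)` when isotropic. This is the default solver:
it is exact, instantaneous, and sufficient whenever the medium can be
approximated as uniform (the fiber tests and examples use endoneurium
everywhere). Its fidelity limits are explicit: no perineurium barrier, no
epineurium/medium contrast, no grounded boundary.

## Finite-difference bases

The inhomogeneous solver discretizes `div(sigma grad phi) = 0` on a
rectilinear node grid with the 7-point stencil. Face conductances are
harmonic means of the adjacent node conductivities times face area over
pitch, which is the standard flux-conserving choice at material
interfaces. The perineurium is a thin-layer: faces crossing a registered
fascicle boundary get an extra series resistance `rho_s = thickness /
sigma_perineurium`; the default thickness is 3 % of the inner trace's
effective diameter and is always reported, never silent. 1 mA is injected
at the node nearest the contact; the symmetric positive-definite system is
solved by Jacobi-preconditioned conjugate gradients to a relative residual
of 1e-8 (configurable). Discrete current conservation then holds to the
solver tolerance through any node box around the source.

Boundary conditions: grounded (phi = 0, the default — a distant return
electrode), insulating (zero flux, one reference node pinned), or fixed
caller-supplied values. The fixed mode exists for verification: imposing
the closed form on the boundary makes the FD problem and the analytic
problem the same boundary-value problem, so the comparison measures pure
discretization error. Against the free-space closed form with a grounded
box, near-boundary nodes disagree by construction, which no refinement
cures; verification must control the boundary, and the package makes that
explicit rather than quietly comparing incompatible problems.

Cells may have per-axis spacing. For strongly anisotropic media the
recommended choice is spacing proportional to `sqrt(sigma_k)` per axis:
under the substitution `x_k -> x_k / sqrt(sigma_k)` the operator becomes an
isotropic Laplacian, and this choice makes cells cubic in that frame,
equalizing the near-source discretization error across directions (with
cubic cells the error concentrates along the high-conductivity axis).

Idle contacts are a stated fidelity gap: a floating metal contact
redistributes current in a full FEM, and a point-source basis cannot
represent that. The package documents this rather than approximating it.

## Superposition and sampling

`superpose()` forms weighted fields; analytic superposition is exact to
machine precision, grid superposition to solver tolerance. `sample_potentials()`
evaluates analytic fields exactly and grid fields by trilinear
interpolation. `super_sample()` caches a dense axial profile (default step
10 um) at a fiber's (x, y) so later discretizations interpolate without
re-querying the solver; profiles are stored as two-column text files keyed
by a content hash.

# Fibers

## Fiberset geometry

Placement modes: CENTROID, UNIFORM_COUNT (seeded rejection sampling inside
the inner trace), UNIFORM_DENSITY (count = density times inner area), and
EXPLICIT (validated). Fibers are never placed outside fascicle inners —
placement in the epineurium is treated as a configuration error.

Myelinated fibers follow the MRG double-cable geometry: the published
anchor table (diameters 5.7–16 um) gives internode period, paranode
lengths, node/axon diameters, and lamella counts; geometry at intermediate
diameters is piecewise-linear through the anchors and exact at them. The
published polynomial fit is not reproduced; users comparing small-fiber
thresholds across interpolation flavors should expect differences. Below
5.7 um (supported range reaches down to 2 um) all geometric parameters are
scaled proportionally to diameter from the 5.7 um anchor — linear
extrapolation of the anchors would drive the internode period negative,
while proportional scaling keeps every length positive and the period
strictly increasing. The 11-compartment repeat is node, MYSA, FLUT, 6 STIN,
FLUT, MYSA; the number of internodes is rounded up to even so the node
count is odd, and the default offset policy centers the middle node at the
fiber midpoint (node alignment with the cuff measurably shifts thresholds,
so the policy is explicit). Unmyelinated fibers use uniform sections,
default 8.333 um.

## Membrane models and integration

MRG nodes carry fast Na+, persistent Na+, slow K+, and leak conductances
with the published rate equations and Q10 factors, at the model's native
36 C; MYSA/FLUT/STIN compartments are passive with an explicit myelin
sheath (0.001 S/cm^2 and 0.1 uF/cm^2 per lamella membrane, 2 x lamellae in
series) and a periaxonal axial pathway (axoplasmic resistivity 70 Ohm cm;
periaxonal space widths 2 nm at node/MYSA, 4 nm at FLUT/STIN).

The unmyelinated model is an HH-type membrane (gNa 0.120, gK 0.036, gL
0.0003 S/cm^2) resting at -70 mV. Its rate constants are treated as valid
at the operating temperature of 37 C, with Q10 = 3 applied only to
deviations from it: scaling the classical 6.3 C rates up to body
temperature produces heat block (action potentials fail to propagate above
roughly 31 C), which we verified numerically; this referencing is how the
model family is used for body-temperature stimulation modeling.

Integration is backward Euler with a staggered gating update: gating
variables advance by exact exponential integration of their rate equations
at the previous step's voltage, then the voltage system — interleaved
(Vm, Vperiaxonal) per compartment, bandwidth 3 — is solved by a banded LU
(LAPACK `dgbsv`) each step. Backward Euler is unconditionally stable,
which a bisection protocol needs (an explicit scheme that diverges at a
probe amplitude would corrupt the search); its first-order damping is
controlled by the timestep, default 5 us for myelinated and 10 us for
unmyelinated fibers, and threshold changes under dt halving are verified
below 2 %. Ends are sealed. At build time each fiber is settled to its
resting fixed point (500 ms at dt 0.5 ms, no stimulus), so resting
stationarity is a property of the initial state, not an accident of
initialization.

The extracellular drive enters through the myelin/extracellular face of
each compartment; a spatially uniform Ve therefore shifts all
intracellular potentials rigidly and produces no transmembrane response at
any amplitude — the discrete second difference of a constant is zero —
which the tests assert.

# Protocols

Activation: bracket [0.01, 1] mA, upper bound doubled until the fiber
fires (cap 100 mA), then bisection to 1 % relative width; the returned
threshold is the upper bracket, so re-simulation at the threshold is
guaranteed active and at `T (1 - 2 tol)` inactive. Detection counts upward
crossings of -30 mV with a 1 ms lockout at a site 5 nodes in from the
fiber end with the weakest drive (far from the cuff), all configurable and
reported. Thresholds scale exactly as 1/c when the basis potentials scale
by c, because the drive is a product — this is asserted to machine
precision.

Block: the kHz waveform (full-duty square wave, default 10 kHz) runs
continuously; three intracellular test pulses at 10 ms spacing start 20 ms
after onset, delivered two nodes from the proximal end, with detection 5
nodes from the distal end. Block at amplitude A means zero test-evoked
spikes in the assay window (the onset response before 20 ms is excluded
and the exclusion is reported in the result). A zero-amplitude control
must pass all test pulses or the protocol aborts as misconfigured. The
smallest blocking amplitude is found by the same bisection machinery.

# Numerical and design choices

* Ellipses are polygonized at 100 vertices (< 0.1 % area error);
  point-in-polygon via `mgcv::in.out`; polygon distances by vectorized
  point-to-segment minimization.
* Waveform edges use half-open `[start, start + pw)` sample windows on the
  grid `round(tstop/dt) + 1`; nonzero waveforms are normalized to unit
  maximum magnitude. Polarity lives in the contact weights (cathodic
  monopolar stimulation is weight -1), keeping waveforms and cuff
  weighting orthogonal.
* The full-duty kHz waveform is a 50/50 square wave with no inter-pulse
  interval; that is this package's reading of the conventional block
  waveform family.
* CG tolerance 1e-8 relative; basis and super-sample caches are keyed by
  content hashes of geometry, materials, and grid, and cache reuse is
  asserted to leave results bit-identical.
* Test problem sizes are chosen as the smallest that exercise the physics:
  30 mm fibers (27 nodes at 10 um) for threshold work, 81^3 grids for
  solver verification, 5-fascicle mock nerves for the rotation experiment,
  1000 seeds for morphology invariants, 10^4 draws for recruitment
  statistics.

# Analysis products

`heatmap_table()` joins fiber coordinates with thresholds for rendering
(`plot_heatmap()` overlays fascicle outlines and the contact arc; compared
placements should share `color_range` over the union).
`recruitment_curve()` draws a diameter population per fascicle
(Normal(8.85, 3.1) um, 100 fibers per fascicle by default), rounds to the
0.5 um modeled grid (clipping to the modeled range with a warning), assigns
each drawn fiber one modeled threshold of its (fascicle, diameter)
uniformly at random, and reports the activated fraction versus amplitude —
an empirical CDF, hence non-decreasing and reaching 1 at the maximum drawn
threshold.

# Known limitations

* Contacts are point sources; contact span, recess geometry, and
  electrode–tissue interface impedance are not electrically represented.
* Idle ("floating") metal contacts do not perturb the field.
* The analytic solver is homogeneous; fascicle-level contrasts require the
  FD solver, whose accuracy is grid-limited near sources.
* The cross section is constant along z (extrusion); no 3D morphology
  variation.
* The mock deformation is geometric, not mechanical.
* Myelinated geometry below the smallest published anchor is a documented
  proportional-scaling extrapolation.
* Only the MRG-interpolated myelinated and one HH-type unmyelinated
  membrane are built in; the engine's compartment tables accept
  user-supplied variants of the same structure.
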